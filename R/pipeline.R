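#' Run the full single-subject analysis
#'
#' End-to-end workflow from marker trajectories to breathing maps:
#' chest-wall volume trace (closed 89-marker mesh per frame), respiratory
#' phase detection (RV / FRC / FRCVT / TLC), geometry summaries of the
#' smoothed models at the four phases, ventilatory pattern with
#' compartmental contributions, and the three signed displacement vector
#' fields (FRC to FRCVT = tidal volume, FRC to TLC = inspiratory capacity,
#' TLC to RV = vital capacity). When \code{out_dir} is given, meshes
#' (STL), vector fields (text), phases (JSON), the geometry table (CSV),
#' figures (PNG) and a reproducibility manifest with file checksums are
#' written there.
#'
#' @param traj an \code{oep_traj}.
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @param level subdivision iterations for the smoothed models.
#' @param quiet_window quiet-breathing window (s) passed to
#'   \code{\link{detect_phases}}.
#' @param subject_id label carried into the vector fields.
#' @param write_figures render heatmaps alongside the data files.
#' @return object of class \code{oep_subject}: list with \code{trace},
#'   \code{phases}, \code{pattern}, \code{geometry} (one summary per
#'   phase), \code{meshes} (smoothed, per phase), \code{fields} (3 signed
#'   vector fields), \code{center_ids}, \code{manifest}.
#' @export
run_subject <- function(traj, out_dir = NULL, level = 1L,
                        quiet_window = NULL, subject_id = "subject",
                        write_figures = !is.null(out_dir)) {
  layout <- traj$layout
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  trace <- stage("volume_trace", chest_volume_trace(traj))
  phases <- stage("phase_detection", detect_phases(trace, quiet_window))
  pattern <- stage("ventilatory_pattern", ventilatory_pattern(phases))
  comp_traces <- stage("compartment_traces", lapply(
    c(RCp = "RCp", RCa = "RCa", AB = "AB"),
    function(cp) chest_volume_trace(traj, cp)))
  deltas <- function(i0, i1) vapply(comp_traces, function(tr)
    tr$V[i1] - tr$V[i0], numeric(1))
  idx <- phases$idx
  pattern$compartments <- rbind(
    VT = compartmental_contributions(deltas(idx[["FRC"]], idx[["FRCVT"]])),
    IC = compartmental_contributions(deltas(idx[["FRC"]], idx[["TLC"]])),
    VC = compartmental_contributions(deltas(idx[["RV"]], idx[["TLC"]])))
  phase_names <- c("RV", "FRC", "FRCVT", "TLC")
  meshes <- list()
  geometry <- list()
  for (ph in phase_names) {
    fr <- idx[[ph]]
    geometry[[ph]] <- stage(paste0("geometry_", ph),
                            geometry_summary(traj, fr, phase = ph,
                                             level = level))
    closed <- add_closure_markers(traj_frame(traj, fr), layout, "trunk",
                                  frame_index = fr)
    m0 <- build_trunk_mesh(closed, layout)
    meshes[[ph]] <- if (level > 0L) subdivide(m0, level)$mesh else m0
  }
  pairs <- list(VT = c("FRC", "FRCVT"), IC = c("FRC", "TLC"),
                VC = c("TLC", "RV"))
  fields <- lapply(names(pairs), function(nm) {
    pr <- pairs[[nm]]
    vf <- build_vector_field(meshes[[pr[1L]]], meshes[[pr[2L]]],
                             phase_pair = paste(pr, collapse = ":"),
                             subject_id = subject_id)
    stage(paste0("signs_", nm), assign_signs(vf, meshes[[pr[1L]]]))
  })
  names(fields) <- names(pairs)
  level_rows <- unlist(layout$level_rows)
  center_ids <- which(layout$markers$row %in% level_rows)
  out <- structure(
    list(trace = trace, phases = phases, pattern = pattern,
         geometry = geometry, meshes = meshes, fields = fields,
         center_ids = center_ids, subject_id = subject_id,
         level = level, manifest = NULL),
    class = "oep_subject")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (ph in phase_names) {
      fp <- file.path(out_dir, paste0("mesh_", ph, ".stl"))
      write_stl(meshes[[ph]], fp)
      files <- c(files, fp)
    }
    for (nm in names(fields)) {
      fp <- file.path(out_dir, paste0("vf_", nm, ".txt"))
      export_vector_field(fields[[nm]], fp)
      files <- c(files, fp)
    }
    fp <- file.path(out_dir, "phases.json")
    jsonlite::write_json(list(
      volumes_L = phases[c("RV", "FRC", "FRCVT", "TLC")],
      frame_indices = as.list(phases$idx),
      pattern = pattern[c("VT", "IC", "VC", "RR", "MV")],
      compartments_pct = as.data.frame(pattern$compartments)),
      fp, auto_unbox = TRUE, digits = NA)
    files <- c(files, fp)
    fp <- file.path(out_dir, "geometry.csv")
    utils::write.csv(geometry_table(geometry), fp, row.names = FALSE)
    files <- c(files, fp)
    if (write_figures) {
      for (nm in names(fields)) {
        fp <- file.path(out_dir, paste0("heatmap_", nm, ".png"))
        vf <- fields[[nm]]
        render_heatmap(meshes[[pairs[[nm]][1L]]], vf$modulus,
                       render_spec("front"), fp)
        files <- c(files, fp)
      }
    }
    out$manifest <- write_manifest(
      file.path(out_dir, "manifest.json"),
      inputs = list(subject_id = subject_id,
                    frames = dim(traj$positions)[1],
                    sample_rate = traj$sample_rate,
                    markers = layout$total_markers),
      parameters = list(level = level,
                        quiet_window = phases$quiet_window,
                        smooth_window = 0.25),
      files = files)
  }
  out
}

#' @export
print.oep_subject <- function(x, ...) {
  cat("Single-subject OEP analysis:", x$subject_id, "\n")
  print(x$phases)
  print(x$pattern)
  invisible(x)
}

# Long-format table of geometry summaries (one row per quantity x phase).
geometry_table <- function(geometry) {
  rows <- list()
  for (ph in names(geometry)) {
    g <- geometry[[ph]]
    add <- function(quantity, unit, value)
      rows[[length(rows) + 1L]] <<- data.frame(
        phase = ph, quantity = quantity, unit = unit, value = value)
    add("trunk_height", "cm", g$trunk_height)
    for (lv in c("louis_angle", "xiphoid", "umbilicus")) {
      add(paste0("AP_", lv), "cm", g$AP[[lv]])
      add(paste0("ML_", lv), "cm", g$ML[[lv]])
      add(paste0("perimeter_", lv), "cm", g$perimeter[[lv]])
      add(paste0("area_", lv), "dm2", g$section_area[[lv]])
    }
    add("surface_area_CW", "dm2", g$surface_area)
    for (cp in c("RCp", "RCa", "AB")) add(paste0("volume_", cp), "L", g[[cp]])
    add("volume_CW_sum", "L", g$CW_sum)
    add("volume_CW_obj", "L", g$CW_obj)
  }
  do.call(rbind, rows)
}

write_manifest <- function(path, inputs, parameters, files) {
  ver <- tryCatch(as.character(utils::packageVersion("thoraco")),
                  error = function(e) "dev")
  manifest <- list(
    tool = paste0("thoraco ", ver),
    inputs = inputs, parameters = parameters,
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Compare two groups of analysed subjects
#'
#' Joint normalization and per-triangle significance maps for the three
#' ventilatory phases (VT, IC, VC). Subjects are the outputs of
#' \code{\link{run_subject}}; both groups must share the marker layout
#' and subdivision level.
#'
#' @param group1,group2 lists of \code{oep_subject} (>= 2 each).
#' @param alpha significance threshold.
#' @param out_dir optional output directory for map renderings and the
#'   comparison manifest.
#' @param correction multiplicity handling passed to
#'   \code{\link{significance_map}}.
#' @return list of class \code{oep_comparison}: per phase pair, the
#'   \code{oep_sigmap}, plus the joint \code{scale} (cm) used for
#'   normalized figures.
#' @export
compare_groups <- function(group1, group2, alpha = 0.05, out_dir = NULL,
                           correction = "none") {
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 subjects")
  all_subj <- c(group1, group2)
  nv <- vapply(all_subj, function(s)
    nrow(s$fields[[1L]]$start), integer(1))
  if (length(unique(nv)) != 1L)
    stop("groups mix different layouts or subdivision levels")
  maps <- list()
  for (nm in c("VT", "IC", "VC")) {
    f1 <- lapply(group1, function(s) s$fields[[nm]])
    f2 <- lapply(group2, function(s) s$fields[[nm]])
    norm <- normalize_fields(c(f1, f2))
    maps[[nm]] <- list(
      map = significance_map(f1, f2, alpha = alpha, correction = correction,
                             center_ids = group1[[1L]]$center_ids),
      scale = norm$scale,
      normalized = norm$fields)
  }
  out <- structure(c(maps, list(alpha = alpha)), class = "oep_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in c("VT", "IC", "VC")) {
      fp <- file.path(out_dir, paste0("statmap_", nm, ".png"))
      render_significance_map(maps[[nm]]$map, render_spec("front"), fp)
      files <- c(files, fp)
    }
    write_manifest(file.path(out_dir, "comparison_manifest.json"),
                   inputs = list(n_group1 = length(group1),
                                 n_group2 = length(group2)),
                   parameters = list(alpha = alpha, correction = correction),
                   files = files)
  }
  out
}
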