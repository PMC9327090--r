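#' Marker layout for the seated OEP protocol
#'
#' Describes how the reflective markers cover the trunk: a grid of
#' circumferential rows with front and back columns, per-side lateral
#' markers, optional extra ring markers, the anatomical reference rows
#' (angle of Louis, xiphoid, umbilicus) and the row ranges of the three
#' chest-wall compartments (pulmonary ribcage RCp, abdominal ribcage RCa,
#' abdomen AB). The default is the canonical 89-marker seated layout:
#' 7 rows x 5 front columns (35), 7 x 5 back (35), right and left lateral
#' markers on every row (14) and 5 extra pelvic-ring markers in the lowest
#' row. The exact anatomical positions are a declared convention of this
#' package; every element is configuration-driven.
#'
#' Angles are nominal circumferential stations in degrees, measured
#' counter-clockwise from the subject's right side (0 = right lateral,
#' 90 = front centre, 180 = left lateral, 270 = back centre). Rows are
#' numbered from the top (row 1) down.
#'
#' @param rows number of circumferential marker rows.
#' @param front_cols,back_cols number of columns on the front/back sheet.
#' @param lateral_right_rows,lateral_left_rows rows carrying a lateral
#'   marker on each side.
#' @param extra_row,extra_angles row index and angular stations (deg) of
#'   additional ring markers (none if \code{extra_angles} is empty).
#' @param level_rows named integer vector with elements
#'   \code{louis_angle}, \code{xiphoid}, \code{umbilicus}: row index of
#'   each anatomical reference level, strictly increasing.
#' @param compartment_rows named list \code{RCp}, \code{RCa}, \code{AB} of
#'   inclusive row ranges; together they must cover rows 1..rows
#'   contiguously, adjacent compartments sharing exactly their boundary row.
#' @param total_markers declared marker count, validated against the
#'   generated marker table.
#' @return an object of class \code{oep_layout} with the fields above plus
#'   \code{markers}, a data frame with one row per marker: \code{label},
#'   \code{row}, \code{region} (front/back/right/left/extra), \code{col},
#'   \code{angle}.
#' @export
marker_layout <- function(rows = 7L, front_cols = 5L, back_cols = 5L,
                          lateral_right_rows = seq_len(rows),
                          lateral_left_rows = seq_len(rows),
                          extra_row = rows,
                          extra_angles = c(15, 105, 195, 285, 345),
                          level_rows = c(louis_angle = 2L, xiphoid = 4L,
                                         umbilicus = 6L),
                          compartment_rows = list(RCp = 1:4, RCa = 4:5,
                                                  AB = 5:7),
                          total_markers = NULL) {
  rows <- as.integer(rows)
  if (rows < 2L) stop("layout needs at least 2 rows")
  front_angles <- 180 * seq_len(front_cols) / (front_cols + 1)
  back_angles <- 180 + 180 * seq_len(back_cols) / (back_cols + 1)
  mk <- list()
  for (r in seq_len(rows)) {
    tab <- data.frame(
      label = c(paste0("F", r, "C", seq_len(front_cols)),
                paste0("B", r, "C", seq_len(back_cols))),
      row = r,
      region = rep(c("front", "back"), c(front_cols, back_cols)),
      col = c(seq_len(front_cols), seq_len(back_cols)),
      angle = c(front_angles, back_angles),
      stringsAsFactors = FALSE)
    if (r %in% lateral_right_rows)
      tab <- rbind(tab, data.frame(label = paste0("R", r), row = r,
                                   region = "right", col = NA_integer_,
                                   angle = 0, stringsAsFactors = FALSE))
    if (r %in% lateral_left_rows)
      tab <- rbind(tab, data.frame(label = paste0("L", r), row = r,
                                   region = "left", col = NA_integer_,
                                   angle = 180, stringsAsFactors = FALSE))
    if (length(extra_angles) && r == extra_row)
      tab <- rbind(tab, data.frame(label = paste0("E", seq_along(extra_angles)),
                                   row = r, region = "extra",
                                   col = NA_integer_, angle = extra_angles,
                                   stringsAsFactors = FALSE))
    tab <- tab[order(tab$angle), ]
    mk[[r]] <- tab
  }
  markers <- do.call(rbind, mk)
  rownames(markers) <- NULL
  if (anyDuplicated(markers$label))
    stop("duplicate marker labels in layout")
  if (any(duplicated(markers[c("row", "angle")])))
    stop("two markers share a row and angular station")
  lay <- structure(
    list(rows = rows, front_cols = as.integer(front_cols),
         back_cols = as.integer(back_cols),
         lateral_spec = list(right = as.integer(lateral_right_rows),
                             left = as.integer(lateral_left_rows)),
         extra = list(row = as.integer(extra_row),
                      angles = as.numeric(extra_angles)),
         level_rows = level_rows, compartment_rows = compartment_rows,
         markers = markers, total_markers = nrow(markers)),
    class = "oep_layout")
  validate_layout(lay, declared_total = total_markers)
  lay
}

#' @rdname marker_layout
#' @export
default_layout <- function() marker_layout()

validate_layout <- function(layout, declared_total = NULL) {
  if (!is.null(declared_total) && declared_total != layout$total_markers)
    stop("layout validation: total_markers declared as ", declared_total,
         " but the marker table has ", layout$total_markers, " labels")
  lv <- layout$level_rows
  need <- c("louis_angle", "xiphoid", "umbilicus")
  if (!all(need %in% names(lv)))
    stop("layout validation: level_rows must name ",
         paste(need, collapse = ", "))
  lv <- as.integer(lv[need])
  if (any(lv < 1L) || any(lv > layout$rows))
    stop("layout validation: level_rows outside 1..rows")
  if (!(lv[1] < lv[2] && lv[2] < lv[3]))
    stop("layout validation: level rows must be strictly increasing ",
         "from louis_angle to umbilicus")
  cr <- layout$compartment_rows
  if (!identical(sort(names(cr)), sort(c("RCp", "RCa", "AB"))))
    stop("layout validation: compartment_rows must name RCp, RCa, AB")
  ord <- list(cr$RCp, cr$RCa, cr$AB)
  if (ord[[1]][1] != 1L || ord[[3]][length(ord[[3]])] != layout$rows)
    stop("layout validation: compartments must cover rows 1..rows")
  for (i in 1:2) {
    a <- ord[[i]]; b <- ord[[i + 1]]
    if (a[length(a)] != b[1])
      stop("layout validation: adjacent compartments must share exactly ",
           "their boundary row")
  }
  for (nm in names(cr))
    if (length(cr[[nm]]) < 2L)
      stop("layout validation: compartment ", nm, " has fewer than 2 rows")
  invisible(layout)
}

#' @export
print.oep_layout <- function(x, ...) {
  cat(sprintf(
    "OEP marker layout: %d markers, %d rows (front %d cols, back %d cols)\n",
    x$total_markers, x$rows, x$front_cols, x$back_cols))
  cat(sprintf("  levels: louis row %d, xiphoid row %d, umbilicus row %d\n",
              x$level_rows[["louis_angle"]], x$level_rows[["xiphoid"]],
              x$level_rows[["umbilicus"]]))
  cat(sprintf("  compartments: RCp rows %s; RCa rows %s; AB rows %s\n",
              paste(range(x$compartment_rows$RCp), collapse = "-"),
              paste(range(x$compartment_rows$RCa), collapse = "-"),
              paste(range(x$compartment_rows$AB), collapse = "-")))
  invisible(x)
}

# Marker indices of one circumferential ring, in angular order.
layout_ring <- function(layout, row) {
  idx <- which(layout$markers$row == row)
  idx[order(layout$markers$angle[idx])]
}

# Designated markers for AP/ML diameters at a reference level.
layout_diameter_markers <- function(layout, level) {
  r <- layout$level_rows[[level]]
  mk <- layout$markers
  centre <- function(region, cols) {
    sel <- which(mk$row == r & mk$region == region &
                   mk$col == ceiling(cols / 2))
    if (!length(sel)) stop("designated ", region, " marker missing at row ", r)
    sel
  }
  lat <- function(region) {
    sel <- which(mk$row == r & mk$region == region)
    if (!length(sel)) stop("designated ", region, " lateral marker missing ",
                           "at row ", r)
    sel
  }
  list(front = centre("front", layout$front_cols),
       back = centre("back", layout$back_cols),
       right = lat("right"), left = lat("left"))
}

#' Read a marker layout from a flat key-value configuration file
#'
#' The file holds \code{key = value} lines (\code{#} comments allowed).
#' Integer ranges are written \code{a:b}, lists comma-separated. Recognised
#' keys: \code{rows}, \code{front_cols}, \code{back_cols},
#' \code{lateral_right_rows}, \code{lateral_left_rows}, \code{extra_row},
#' \code{extra_angles}, \code{level_louis}, \code{level_xiphoid},
#' \code{level_umbilicus}, \code{rows_rcp}, \code{rows_rca}, \code{rows_ab},
#' \code{total_markers}. Omitted keys fall back to the canonical 89-marker
#' defaults; \code{load_layout()} with no path returns the default layout.
#'
#' @param path configuration file path, or \code{NULL} for the default.
#' @return a validated \code{oep_layout}.
#' @export
load_layout <- function(path = NULL) {
  if (is.null(path)) return(default_layout())
  if (!file.exists(path)) stop("layout file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("layout parse error: line without '=': '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  num_vec <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- kv[[key]]
    out <- tryCatch({
      if (grepl(":", v, fixed = TRUE)) {
        ab <- as.numeric(strsplit(v, ":", fixed = TRUE)[[1]])
        seq(ab[1], ab[2])
      } else if (!nzchar(v)) numeric(0)
      else as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
    }, warning = function(w) NA, error = function(e) NA)
    if (anyNA(out)) stop("layout parse error in key '", key, "': '", v, "'")
    out
  }
  num1 <- function(key, default) {
    v <- num_vec(key, default)
    if (length(v) != 1L) stop("layout parse error: key '", key,
                              "' must be a single number")
    v
  }
  def <- formals(marker_layout)
  rows <- as.integer(num1("rows", 7))
  marker_layout(
    rows = rows,
    front_cols = as.integer(num1("front_cols", 5)),
    back_cols = as.integer(num1("back_cols", 5)),
    lateral_right_rows = as.integer(num_vec("lateral_right_rows", seq_len(rows))),
    lateral_left_rows = as.integer(num_vec("lateral_left_rows", seq_len(rows))),
    extra_row = as.integer(num1("extra_row", rows)),
    extra_angles = num_vec("extra_angles", eval(def$extra_angles)),
    level_rows = c(louis_angle = as.integer(num1("level_louis", 2)),
                   xiphoid = as.integer(num1("level_xiphoid", 4)),
                   umbilicus = as.integer(num1("level_umbilicus", 6))),
    compartment_rows = list(RCp = as.integer(num_vec("rows_rcp", 1:4)),
                            RCa = as.integer(num_vec("rows_rca", 4:5)),
                            AB = as.integer(num_vec("rows_ab", 5:7))),
    total_markers = if (is.null(kv$total_markers)) NULL
                    else num1("total_markers", NULL))
}
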