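#' Average model of a group of meshes
#'
#' Vertex-wise arithmetic mean of topologically identical meshes, each
#' centered first (centroid of the designated reference vertices moved to
#' the origin) so that inter-subject placement in the lab does not bias
#' the average.
#'
#' @param meshes list of \code{oep_mesh} with identical topology.
#' @param center_ids vertex indices whose centroid defines the center
#'   (default: all vertices; the pipeline passes the reference-level
#'   marker vertices).
#' @return the averaged \code{oep_mesh} (uncolored).
#' @export
average_model <- function(meshes, center_ids = NULL) {
  if (!length(meshes)) stop("no meshes supplied")
  f0 <- meshes[[1L]]$faces
  for (m in meshes)
    if (!identical(m$faces, f0)) stop("meshes are not topologically identical")
  if (is.null(center_ids)) center_ids <- seq_len(nrow(meshes[[1L]]$vertices))
  acc <- 0
  for (m in meshes) {
    ctr <- colMeans(m$vertices[center_ids, , drop = FALSE])
    acc <- acc + sweep(m$vertices, 2L, ctr)
  }
  out <- meshes[[1L]]
  out$vertices <- acc / length(meshes)
  out
}

#' Per-triangle magnitude of a vector field
#'
#' Absolute displacement magnitude per mesh triangle: the mean of the
#' absolute signed moduli of its three vertices (cm).
#'
#' @param vf an \code{oep_vf}.
#' @return numeric vector, one value per face.
#' @export
triangle_magnitudes <- function(vf) {
  am <- abs(vf$modulus)
  (am[vf$faces[, 1L]] + am[vf$faces[, 2L]] + am[vf$faces[, 3L]]) / 3
}

#' Exact two-sided Wilcoxon-Mann-Whitney p-value
#'
#' For combined sample sizes n + m <= \code{exact_limit} (default 20) the
#' p-value is exact: the rank-sum distribution is enumerated by a
#' shift/counting algorithm over all C(n+m, n) assignments, with mid-ranks
#' for ties, and the smaller tail is doubled (capped at 1). Larger samples
#' use the normal approximation with tie correction.
#'
#' @param x,y numeric samples (group 1, group 2), each non-empty.
#' @param exact_limit largest n + m for which the exact distribution is
#'   enumerated.
#' @return two-sided p-value in (0, 1].
#' @export
mwu_exact <- function(x, y, exact_limit = 20L) {
  n <- length(x); m <- length(y)
  if (!n || !m) stop("both groups must be non-empty")
  N <- n + m
  r2 <- as.integer(round(2 * rank(c(x, y))))   # doubled mid-ranks: integers
  w <- sum(r2[seq_len(n)])
  if (N <= exact_limit) {
    cdf <- ranksum_distribution(r2, n)
    total <- choose(N, n)
    p_le <- sum(cdf$count[cdf$sum <= w]) / total
    p_ge <- sum(cdf$count[cdf$sum >= w]) / total
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n * (N + 1)                            # doubled-rank scale
  ties <- table(r2)
  tie_term <- sum(ties^3 - ties)
  v <- n * m / 3 * ((N + 1) - tie_term / (N * (N - 1)))  # var of doubled W
  z <- (w - mu) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Counts of subsets of size n of the doubled-rank multiset by sum
# (dynamic programming over items; exact and deterministic).
ranksum_distribution <- function(r2, n) {
  S <- sum(r2)
  # counts[k + 1, s + 1] = number of size-k subsets with sum s
  counts <- matrix(0, n + 1L, S + 1L)
  counts[1L, 1L] <- 1
  for (r in r2) {
    kmax <- min(n, nrow(counts) - 1L)
    for (k in seq.int(kmax, 1L)) {
      shifted <- c(rep(0, r), counts[k, seq_len(S + 1L - r)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  sel <- which(counts[n + 1L, ] > 0)
  list(sum = sel - 1L, count = counts[n + 1L, sel])
}

# Exact rank-sum CDF for the untied case depends only on (n, m): cache it.
.mwu_cache <- new.env(parent = emptyenv())

mwu_exact_untied_batch <- function(W2, n, m) {
  key <- paste0("n", n, "m", m)
  dist <- get0(key, envir = .mwu_cache)
  if (is.null(dist)) {
    dist <- ranksum_distribution(2L * seq_len(n + m), n)
    assign(key, dist, envir = .mwu_cache)
  }
  total <- choose(n + m, n)
  cum <- cumsum(dist$count)
  rev_cum <- rev(cumsum(rev(dist$count)))
  idx <- match(W2, dist$sum)
  p_le <- cum[idx] / total
  p_ge <- rev_cum[idx] / total
  pmin(1, 2 * pmin(p_le, p_ge))
}

#' Per-triangle significance map between two groups of vector fields
#'
#' Compares the two groups triangle by triangle: each subject contributes
#' one absolute magnitude per triangle (\code{\link{triangle_magnitudes}}),
#' the exact Wilcoxon-Mann-Whitney test is applied across subjects, and
#' triangles with p below \code{alpha} are labelled by direction: red
#' (\code{group1_greater}) when group 1 shows the larger mean
#' displacement, blue (\code{group2_greater}) otherwise. The map is
#' painted on the vertex-wise averaged, uncolored model of all subjects.
#' No multiple-testing correction is applied by default (exploratory map);
#' Benjamini-Hochberg FDR is available via \code{correction = "BH"}.
#'
#' @param group1,group2 lists of \code{oep_vf} (>= 2 subjects each, all
#'   sharing topology).
#' @param alpha significance threshold.
#' @param correction \code{"none"} (default) or \code{"BH"}.
#' @param center_ids vertex indices used to center meshes before
#'   averaging.
#' @return object of class \code{oep_sigmap}: list with \code{base_mesh},
#'   \code{p_values}, \code{direction} (per triangle:
#'   \code{group1_greater} / \code{group2_greater} / \code{none}),
#'   \code{alpha}, \code{n_significant}.
#' @export
significance_map <- function(group1, group2, alpha = 0.05,
                             correction = c("none", "BH"),
                             center_ids = NULL) {
  correction <- match.arg(correction)
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 subjects")
  fields <- c(group1, group2)
  f0 <- fields[[1L]]$faces
  for (f in fields)
    if (!identical(f$faces, f0)) stop("vector fields differ in topology")
  M1 <- vapply(group1, triangle_magnitudes, numeric(nrow(f0)))
  M2 <- vapply(group2, triangle_magnitudes, numeric(nrow(f0)))
  n <- ncol(M1); m <- ncol(M2)
  nt <- nrow(f0)
  p <- numeric(nt)
  r2all <- t(apply(cbind(M1, M2), 1L, function(v) round(2 * rank(v))))
  untied <- apply(r2all, 1L, function(r) !anyDuplicated(r)) & (n + m) <= 20L
  if (any(untied)) {
    W2 <- rowSums(r2all[untied, seq_len(n), drop = FALSE])
    p[untied] <- mwu_exact_untied_batch(as.integer(W2), n, m)
  }
  for (i in which(!untied))
    p[i] <- mwu_exact(M1[i, ], M2[i, ])
  p_eff <- if (correction == "BH") stats::p.adjust(p, "BH") else p
  mean1 <- rowMeans(M1); mean2 <- rowMeans(M2)
  direction <- rep("none", nt)
  sig <- p_eff < alpha
  direction[sig & mean1 > mean2] <- "group1_greater"
  direction[sig & mean2 >= mean1] <- "group2_greater"
  meshes <- lapply(fields, function(f)
    trimesh(f$start, f$faces, validate = FALSE))
  base <- average_model(meshes, center_ids)
  structure(list(base_mesh = base, p_values = p, p_adjusted = p_eff,
                 direction = direction, alpha = alpha,
                 n_significant = sum(sig), correction = correction),
            class = "oep_sigmap")
}

#' @export
print.oep_sigmap <- function(x, ...) {
  cat(sprintf(
    "Significance map: %d / %d triangles below alpha = %g (%s correction)\n",
    x$n_significant, length(x$p_values), x$alpha,
    ifelse(x$correction == "none", "no", x$correction)))
  tb <- table(x$direction)
  cat(sprintf("  group1 greater (red): %d; group2 greater (blue): %d\n",
              tb["group1_greater"][[1]] %||% 0,
              tb["group2_greater"][[1]] %||% 0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
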