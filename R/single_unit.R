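#' Circular Gaussian smoothing of tuning curves
#'
#' Smooths each unit's position-binned curve with a Gaussian kernel
#' (SD in bins) that wraps around the circular track. The kernel is
#' normalized, so each unit's total mass over bins is preserved and
#' constant curves are unchanged.
#'
#' @param curves A [compute_tuning_curves()] object, or a `P x N` matrix.
#' @param sd_bins Kernel standard deviation in bins (default 2).
#' @return Object of the same type with smoothed curves.
#' @export
smooth_curves <- function(curves, sd_bins = 2) {
  smooth_mat <- function(m) {
    P <- nrow(m)
    if (P < 5) stop("need at least 5 bins to smooth.", call. = FALSE)
    # circulant kernel: entry (i, j) = Gaussian at circular bin offset |i - j|
    km <- outer(seq_len(P), seq_len(P), function(i, j) {
      d <- abs(i - j)
      dnorm(pmin(d, P - d), 0, sd_bins)
    })
    km <- km / rowSums(km)
    km %*% m
  }
  if (inherits(curves, "tuning_curves")) {
    out <- curves
    for (kk in seq_len(dim(curves)[3])) out[, , kk] <- smooth_mat(unclass(curves)[, , kk])
    out
  } else {
    smooth_mat(as.matrix(curves))
  }
}

#' Rate-remapping score for one unit
#'
#' The percent change in peak rate between a unit's (smoothed) curves in
#' two maps, referenced to the first map's peak:
#' `|max(c1) - max(c2)| / max(c1) * 100` (or referenced to the mean of the
#' two peaks with `reference = "mean"`). Undefined (NA) when the reference
#' peak is not positive.
#'
#' @param c1,c2 Per-unit binned curves (numeric vectors).
#' @param reference `"first"` (map 1's peak) or `"mean"` (mean of peaks).
#' @return Percent change (nonnegative), or `NA` if undefined.
#' @export
rate_remapping_score <- function(c1, c2, reference = c("first", "mean")) {
  reference <- match.arg(reference)
  ref <- switch(reference, first = max(c1), mean = (max(c1) + max(c2)) / 2)
  if (!is.finite(ref) || ref <= 0) return(NA_real_)
  abs(max(c1) - max(c2)) / ref * 100
}

#' Spatial dissimilarity (global remapping) score for one unit
#'
#' One minus the cosine similarity between the unit's binned curves in the
#' two maps: 0 for identical spatial firing, 1 for orthogonal (fully
#' relocated) spatial firing. Undefined (NA) for a zero curve.
#'
#' @param c1,c2 Per-unit binned curves (numeric vectors).
#' @return Score in `[0, 2]` (about `[0, 1]` for nonnegative rates), or `NA`.
#' @export
spatial_dissimilarity <- function(c1, c2) {
  n1 <- sqrt(sum(c1^2))
  n2 <- sqrt(sum(c2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  1 - sum(c1 * c2) / (n1 * n2)
}

#' Per-unit remapping characterization
#'
#' Smooths both maps' tuning curves (circular Gaussian, SD 2 bins) and
#' scores each unit's remapping on two axes: rate remapping (percent change
#' in peak rate) and global remapping (spatial dissimilarity). Units with
#' an undefined score (zero curve or zero reference peak) are flagged.
#'
#' @param curves A [compute_tuning_curves()] object (or list of two
#'   `P x N` matrices).
#' @param map_i,map_j Maps to compare.
#' @param sd_bins Smoothing SD in bins.
#' @param reference Reference for the rate score (see
#'   [rate_remapping_score()]).
#' @return Tibble with `unit`, `rate_change_pct`, `spatial_dissimilarity`,
#'   `flagged`.
#' @export
unit_remap_scores <- function(curves, map_i = 1, map_j = 2, sd_bins = 2,
                              reference = "first") {
  ci <- if (inherits(curves, "tuning_curves")) map_curves(curves, map_i) else as.matrix(curves[[map_i]])
  cj <- if (inherits(curves, "tuning_curves")) map_curves(curves, map_j) else as.matrix(curves[[map_j]])
  ci <- smooth_curves(ci, sd_bins)
  cj <- smooth_curves(cj, sd_bins)
  n <- ncol(ci)
  rate <- vapply(seq_len(n), function(u) {
    rate_remapping_score(ci[, u], cj[, u], reference)
  }, numeric(1))
  diss <- vapply(seq_len(n), function(u) {
    spatial_dissimilarity(ci[, u], cj[, u])
  }, numeric(1))
  tibble::tibble(
    unit = seq_len(n), rate_change_pct = rate,
    spatial_dissimilarity = diss,
    flagged = !is.finite(rate) | !is.finite(diss)
  )
}
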