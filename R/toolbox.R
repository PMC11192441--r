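#' Conventional laterality-index formula
#'
#' `(L - R) / (L + R)` where `L` and `R` summarise activation on each side
#' (summed suprathreshold statistic values, or voxel counts). Bounded in
#' [-1, 1] only when both totals are positive; with negative inputs (task
#' deactivation) the ratio can exceed 1 -- e.g. L = 2, R = -1 gives 3 --
#' which is why deactivation breaks the conventional LI.
#'
#' @param left_total,right_total per-side activation totals.
#' @return The laterality index.
#' @export
li_formula <- function(left_total, right_total) {
  denom <- left_total + right_total
  if (any(denom == 0))
    stop("zero denominator: left and right totals sum to zero", call. = FALSE)
  (left_total - right_total) / denom
}

#' Equally spaced threshold grid
#'
#' `n_thresholds` equally spaced t values from 0 to the maximum statistic in
#' the region, endpoints included (spacing `max / (n - 1)`).
#'
#' @param values_in_mask statistic values inside the ROI.
#' @param n_thresholds number of thresholds (default 20).
#' @return Ascending numeric vector of thresholds.
#' @export
make_thresholds <- function(values_in_mask, n_thresholds = 20) {
  mx <- max(values_in_mask)
  if (!is.finite(mx) || mx <= 0)
    stop("no positive activation: all statistic values are <= 0",
         call. = FALSE)
  seq(0, mx, length.out = n_thresholds)
}

#' Per-resample sample size
#'
#' `max(1, round(fraction * n_available))`: e.g. 40 suprathreshold voxels at
#' the default 25% fraction give resamples of 10 values, 24 give 6.
#'
#' @param n_available suprathreshold voxel count on one side.
#' @param fraction resampling fraction (default 0.25).
#' @return Integer resample size, at least 1.
#' @export
resample_size <- function(n_available, fraction = 0.25) {
  max(1L, as.integer(round(fraction * n_available)))
}

#' Toolbox-method configuration
#'
#' Defaults follow the standard threshold-bootstrap procedure: 20 thresholds,
#' a 10-voxel-per-side retention gate, 100 resamples of 25% per side (so
#' 100 x 100 = 10,000 LI values per threshold), 25% trimming, and the
#' threshold-weighted mean as the combined estimate. `statistic` selects
#' whether each resample is summarised by the sum (default) or mean of its
#' statistic values before entering the LI formula.
#'
#' @param n_thresholds,min_voxels,n_boot,resample_fraction,trim,combine,statistic
#'   see Description.
#' @return A list of class `toolbox_config`.
#' @export
toolbox_config <- function(n_thresholds = 20, min_voxels = 10, n_boot = 100,
                           resample_fraction = 0.25, trim = 0.25,
                           combine = c("weighted", "mean", "trimmed"),
                           statistic = c("sum", "mean")) {
  stopifnot(resample_fraction > 0, resample_fraction <= 1,
            trim >= 0, trim < 0.5, n_thresholds >= 2, n_boot >= 1)
  structure(list(n_thresholds = n_thresholds, min_voxels = min_voxels,
                 n_boot = n_boot, resample_fraction = resample_fraction,
                 trim = trim, combine = match.arg(combine),
                 statistic = match.arg(statistic)),
            class = "toolbox_config")
}

#' Split suprathreshold values by hemisphere at one threshold
#'
#' Values strictly above the threshold are collected per side; the level is
#' retained only if both sides have at least `min_voxels` suprathreshold
#' voxels. A non-retained level is a state, not an error.
#'
#' @param volume a [stat_volume()].
#' @param mask a midline-excluded [roi_mask()].
#' @param threshold t threshold.
#' @param min_voxels per-side retention gate (default 10).
#' @return An object of class `threshold_level`.
#' @export
suprathreshold_split <- function(volume, mask, threshold, min_voxels = 10) {
  hv <- hemisphere_values(volume, mask)
  left <- hv$left[hv$left > threshold]
  right <- hv$right[hv$right > threshold]
  structure(
    list(threshold = threshold, left_values = left, right_values = right,
         retained = length(left) >= min_voxels && length(right) >= min_voxels,
         boot_lis = NULL, trimmed_mean_li = NA_real_),
    class = "threshold_level")
}

#' Count-based trimmed mean
#'
#' Sorts the values, drops `floor(trim * n)` from each end, and averages the
#' remainder. Count-based trimming keeps the result deterministic for lengths
#' not divisible by `1 / trim`.
#'
#' @param values numeric vector.
#' @param trim fraction to drop from each end (default 0.25, i.e. the middle
#'   50%).
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(values, trim = 0.25) {
  n <- length(values)
  if (n == 0L) stop("empty value list", call. = FALSE)
  stopifnot(trim >= 0, trim < 0.5)
  k <- floor(trim * n)
  s <- sort(values)
  mean(s[(k + 1):(n - k)])
}

# middle values retained by count-based trimming (used for the weighted
# histogram: same convention as trimmed_mean)
trim_retained <- function(values, trim) {
  n <- length(values)
  k <- floor(trim * n)
  sort(values)[(k + 1):(n - k)]
}

#' Bootstrap the laterality index at one threshold
#'
#' Draws `n_boot` resamples with replacement per side, each of
#' [resample_size()] values, summarises each resample (sum or mean of its
#' statistic values), and computes the LI for every left x right resample
#' combination -- `n_boot^2` LI values. Stores the values and their
#' `trim`-trimmed mean.
#'
#' @param level a retained [suprathreshold_split()] result.
#' @param config a [toolbox_config()].
#' @param seed integer RNG seed.
#' @return The `threshold_level` with `boot_lis` and `trimmed_mean_li` filled.
#' @export
bootstrap_threshold <- function(level, config = toolbox_config(),
                                seed = NULL) {
  if (!isTRUE(level$retained))
    stop("cannot bootstrap a non-retained threshold level", call. = FALSE)
  nl <- length(level$left_values)
  nr <- length(level$right_values)
  ml <- resample_size(nl, config$resample_fraction)
  mr <- resample_size(nr, config$resample_fraction)
  agg <- if (config$statistic == "sum") colSums else colMeans
  lis <- with_seed(seed, {
    ldraw <- matrix(level$left_values[
      sample.int(nl, ml * config$n_boot, replace = TRUE)], nrow = ml)
    rdraw <- matrix(level$right_values[
      sample.int(nr, mr * config$n_boot, replace = TRUE)], nrow = mr)
    L <- agg(ldraw)
    R <- agg(rdraw)
    outer(L, R, function(l, r) (l - r) / (l + r))
  })
  level$boot_lis <- as.numeric(lis)
  level$trimmed_mean_li <- trimmed_mean(level$boot_lis, config$trim)
  level
}

#' Combine per-threshold trimmed-mean LIs
#'
#' Three summaries over the retained levels: the plain mean of the trimmed
#' means, a further trimmed mean of them, or (the default and recommended
#' choice) a weighted mean with weight equal to the threshold, so that voxels
#' most strongly correlated with the task dominate. The 95% CI comes from
#' [weighted_histogram_ci()]. Note threshold 0 necessarily carries zero
#' weight in the weighted mean and histogram.
#'
#' @param levels list of bootstrapped `threshold_level`s.
#' @param config a [toolbox_config()].
#' @return A `c("li_toolbox", "li_result")` object.
#' @export
combine_levels <- function(levels, config = toolbox_config()) {
  ret <- Filter(function(l) isTRUE(l$retained), levels)
  if (length(ret) == 0L) {
    tab <- level_table(levels)
    stop("insufficient activation: no threshold level retained both >= ",
         config$min_voxels, " voxels per side\n",
         paste(utils::capture.output(print(tab)), collapse = "\n"),
         call. = FALSE)
  }
  th <- vapply(ret, `[[`, numeric(1), "threshold")
  tm <- vapply(ret, `[[`, numeric(1), "trimmed_mean_li")
  est <- switch(config$combine,
    mean = mean(tm),
    trimmed = trimmed_mean(tm, config$trim),
    weighted = {
      if (all(th == 0)) stop("degenerate weights: only threshold 0 retained",
                             call. = FALSE)
      sum(th * tm) / sum(th)
    })
  ci <- weighted_histogram_ci(ret, trim = config$trim)
  new_li_result(est, ci[1], ci[2], method = "toolbox",
                n_units = length(ret),
                combine = config$combine, config = config,
                levels = level_table(levels))
}

level_table <- function(levels) {
  data.frame(
    threshold = vapply(levels, `[[`, numeric(1), "threshold"),
    n_left = vapply(levels, function(l) length(l$left_values), integer(1)),
    n_right = vapply(levels, function(l) length(l$right_values), integer(1)),
    trimmed_li = vapply(levels, `[[`, numeric(1), "trimmed_mean_li"),
    retained = vapply(levels, function(l) isTRUE(l$retained), logical(1)))
}

#' Threshold-weighted percentile confidence interval
#'
#' Pools the trim-retained (middle 50% by default) bootstrap LIs of every
#' retained level, weights each value by its level's threshold, and returns
#' the 2.5th and 97.5th percentiles of the pooled weighted distribution
#' (inverse of the right-continuous weighted ECDF, weights normalised to 1).
#' Because every retained level contributes the same number of values, the
#' weighted mean of this pooled distribution equals the threshold-weighted
#' mean of the per-level trimmed means.
#'
#' @param levels list of bootstrapped, retained `threshold_level`s.
#' @param trim trimming fraction applied per level before pooling.
#' @param probs percentile pair (default 95% interval).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
weighted_histogram_ci <- function(levels, trim = 0.25,
                                  probs = c(0.025, 0.975)) {
  levels <- Filter(function(l) isTRUE(l$retained), levels)
  if (length(levels) == 0L) stop("no retained levels", call. = FALSE)
  th <- vapply(levels, `[[`, numeric(1), "threshold")
  if (all(th == 0))
    stop("degenerate weights: only threshold 0 retained", call. = FALSE)
  vals <- unlist(lapply(levels, function(l) trim_retained(l$boot_lis, trim)))
  wts <- rep(th, vapply(levels, function(l)
    length(trim_retained(l$boot_lis, trim)), integer(1)))
  weighted_quantile(vals, wts, probs)
}

#' Weighted empirical quantile
#'
#' Inverse of the right-continuous weighted ECDF with weights normalised to
#' sum to 1: the p-quantile is the smallest value whose cumulative weight
#' reaches p. Zero-weight values can never be selected.
#'
#' @param x values.
#' @param w non-negative weights.
#' @param probs probabilities.
#' @return Quantile(s) of the weighted distribution.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Threshold-bootstrap ("toolbox") laterality index
#'
#' The iterative suprathreshold LI: an equally spaced grid of t thresholds
#' from 0 to the in-mask maximum is built; at each threshold the
#' suprathreshold voxels per side are resampled with replacement (100 draws
#' of 25% per side by default) and an LI computed for every left x right
#' resample pair; per-threshold 25%-trimmed means are combined across
#' thresholds (threshold-weighted mean by default) with a weighted-histogram
#' 95% CI. Thresholds leaving fewer than `min_voxels` suprathreshold voxels
#' on either side are discarded. Voxels with negative statistic values can
#' never exceed a non-negative threshold, so the method is blind to
#' deactivation by construction.
#'
#' @param volume a [stat_volume()].
#' @param mask a [roi_mask()]; midline excluded automatically unless already
#'   applied.
#' @param config a [toolbox_config()].
#' @param half_width_mm midline exclusion half-width (default 5 mm).
#' @param seed integer RNG seed; the per-threshold bootstrap consumes one
#'   stream in ascending threshold order.
#' @return A `c("li_toolbox", "li_result")` object; `$levels` holds the
#'   per-threshold table (threshold, per-side counts, trimmed LI, retained).
#' @examples
#' syn <- synth_tmap(blobs = list(blob(c(-20, 0, 0), 12, 5, 2)),
#'                   noise_sd = 0.5, seed = 1)
#' li_toolbox(syn$volume, syn$masks[[1]], seed = 1)
#' @export
li_toolbox <- function(volume, mask, config = toolbox_config(),
                       half_width_mm = 5, seed = NULL) {
  if (!isTRUE(mask$midline_excluded))
    mask <- exclude_midline(mask, half_width_mm)
  hv <- hemisphere_values(volume, mask)
  thr <- make_thresholds(c(hv$left, hv$right), config$n_thresholds)
  levels <- lapply(thr, function(t)
    suprathreshold_split(volume, mask, t, config$min_voxels))
  levels <- with_seed(seed, lapply(levels, function(l) {
    if (isTRUE(l$retained)) bootstrap_threshold(l, config, seed = NULL) else l
  }))
  res <- combine_levels(levels, config)
  res$seed <- seed %||% NA_integer_
  res$roi <- mask$name
  res
}
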