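#' Flip a volume across the midsagittal plane
#'
#' Returns a volume whose value at world (x, y, z) equals the input value at
#' (-x, y, z). Requires a grid symmetric about world x = 0 (see
#' [check_symmetric_grid()]); shape and affine are preserved, so flipping is
#' an exact involution.
#'
#' @param volume a [stat_volume()].
#' @return The flipped [stat_volume()].
#' @export
mirror_flip <- function(volume) {
  p <- lr_partner(volume)
  d <- lr_centres(volume)$dim
  idx <- rep(list(quote(expr = )), 3)
  idx[[d]] <- p
  volume$data <- do.call(`[`, c(list(volume$data), idx, list(drop = FALSE)))
  volume
}

#' Build a homologous left-minus-right difference map
#'
#' For every left-hemisphere mask voxel whose reflection across the midline is
#' also in the mask, stores the left statistic value minus the homologous
#' right value. All values are used regardless of sign -- no threshold is
#' applied, so asymmetric deactivation contributes exactly like asymmetric
#' activation. Voxels without a homolog inside the mask are dropped and
#' counted per side.
#'
#' @param volume a [stat_volume()].
#' @param mask a midline-excluded [roi_mask()] on the same grid.
#' @return An object of class `difference_map`: `values` (named by the linear
#'   index of the left voxel), `n_pairs`, `n_dropped_left`, `n_dropped_right`.
#' @export
build_difference_map <- function(volume, mask) {
  check_same_grid(volume, mask)
  if (!isTRUE(mask$midline_excluded))
    stop("mask must be midline-excluded before building a difference map",
         call. = FALSE)
  p <- lr_partner(volume)
  d <- lr_centres(volume)$dim
  wx <- worldx_array(volume)

  # linear index of the mirror partner of every voxel
  dims <- volume$shape
  grid <- arrayInd(seq_len(prod(dims)), dims)
  grid[, d] <- p[grid[, d]]
  partner <- as.integer(
    (grid[, 3] - 1) * dims[1] * dims[2] + (grid[, 2] - 1) * dims[1] + grid[, 1])

  left_idx <- which(mask$data & wx < 0)
  right_idx <- which(mask$data & wx > 0)
  if (length(left_idx) == 0L)
    stop("empty left-hemisphere mask", call. = FALSE)

  has_homolog <- mask$data[partner[left_idx]]
  paired <- left_idx[has_homolog]
  if (length(paired) == 0L)
    stop("zero homologous pairs in mask", call. = FALSE)
  values <- volume$data[paired] - volume$data[partner[paired]]
  if (any(!is.finite(values)))
    stop("non-finite differences in difference map", call. = FALSE)
  names(values) <- paired

  structure(
    list(values = values,
         n_pairs = length(paired),
         n_dropped_left = sum(!has_homolog),
         n_dropped_right = sum(!mask$data[partner[right_idx]])),
    class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat("<difference_map> ", x$n_pairs, " homologous pairs (",
      x$n_dropped_left, " left / ", x$n_dropped_right,
      " right voxels without homolog)\n", sep = "")
  invisible(x)
}

#' Subsample a difference map into a laterality index
#'
#' Draws `n_samples` independent subsets, each a random `sample_fraction` of
#' the homologous pairs taken without replacement, and records the mean
#' difference score of each subset. The LI estimate is the mean of the subset
#' means; the 95% CI is their 2.5th/97.5th percentile. Subsampling a small
#' fraction keeps spatial dependence between voxels within a subset low.
#'
#' @param diff a [build_difference_map()] result.
#' @param sample_fraction fraction of pairs per subset (default 0.05).
#' @param n_samples number of subsets (default 1000).
#' @param seed integer RNG seed; draws are reproducible given the seed.
#' @return An object of class `c("li_mirror", "li_result")`; `$subset_means`
#'   holds the per-subset means.
#' @export
mirror_bootstrap <- function(diff, sample_fraction = 0.05, n_samples = 1000,
                             seed = NULL) {
  n <- diff$n_pairs
  if (n < 20L)
    stop("too few homologous pairs (", n, "); need at least 20", call. = FALSE)
  m <- max(1L, round(sample_fraction * n))
  vals <- unname(diff$values)
  means <- with_seed(seed, {
    vapply(seq_len(n_samples),
           function(i) mean(vals[sample.int(n, m)]), numeric(1))
  })
  ci <- unname(stats::quantile(means, c(0.025, 0.975), type = 7))
  new_li_result(mean(means), ci[1], ci[2], method = "mirror",
                n_units = n_samples, seed = seed %||% NA_integer_,
                subset_means = means, subset_size = m, n_pairs = n)
}

#' Mirror-method laterality index
#'
#' The threshold-free "mirror" LI: the right hemisphere of the statistic map
#' is flipped onto the left, homologous voxel values inside the region of
#' interest are subtracted (left minus right), and the resulting difference
#' map is repeatedly subsampled to give a mean difference score with a
#' percentile 95% CI. Because no threshold is applied, laterality carried by
#' bilateral deactivation (both hemispheres negative but one more so) is
#' detected, unlike suprathreshold methods. Note the estimate is a simple
#' difference in statistic units, not a bounded proportional LI.
#'
#' @param volume a [stat_volume()].
#' @param mask a [roi_mask()] on the same grid; midline is excluded
#'   automatically with `half_width_mm` unless already applied.
#' @param sample_fraction,n_samples subsampling scheme (defaults 5%, 1000).
#' @param scale_divisor optional display divisor (e.g. 2.7); applied via
#'   [scale_li()].
#' @param half_width_mm midline exclusion half-width (default 5 mm).
#' @param seed integer RNG seed.
#' @return A `c("li_mirror", "li_result")` object.
#' @examples
#' syn <- synth_tmap(blobs = list(blob(c(-20, 0, 0), 12, 4, 1)),
#'                   noise_sd = 0.5, seed = 1)
#' li_mirror(syn$volume, syn$masks[[1]], seed = 1)
#' @export
li_mirror <- function(volume, mask, sample_fraction = 0.05, n_samples = 1000,
                      scale_divisor = NULL, half_width_mm = 5, seed = NULL) {
  if (!isTRUE(mask$midline_excluded))
    mask <- exclude_midline(mask, half_width_mm)
  dm <- build_difference_map(volume, mask)
  res <- mirror_bootstrap(dm, sample_fraction, n_samples, seed)
  res$n_dropped_left <- dm$n_dropped_left
  res$n_dropped_right <- dm$n_dropped_right
  res$roi <- mask$name
  if (!is.null(scale_divisor)) res <- scale_li(res, scale_divisor)
  res
}
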