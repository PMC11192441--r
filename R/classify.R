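#' Categorise laterality from a confidence interval
#'
#' Left-lateralised if the lower 95% bound exceeds zero, right-lateralised if
#' the upper bound is below zero, and bilateral if zero is included in the
#' interval (bounds exactly at zero count as inclusion). The category is
#' derived from the interval, never from the point estimate alone, so a
#' precise method and a noisy method can categorise the same estimate
#' differently.
#'
#' @param ci_low,ci_high interval bounds (vectorised), or `ci_low` may be an
#'   object inheriting `li_result`.
#' @return Character vector in {"left", "bilateral", "right"}.
#' @export
categorise <- function(ci_low, ci_high = NULL) {
  if (inherits(ci_low, "li_result")) {
    ci_high <- ci_low$ci_high
    ci_low <- ci_low$ci_low
  }
  if (any(ci_low > ci_high))
    stop("reversed interval bounds", call. = FALSE)
  ifelse(ci_low > 0, "left", ifelse(ci_high < 0, "right", "bilateral"))
}

#' Spearman correlation with a bootstrap confidence interval
#'
#' Rank correlation (average ranks for ties) with a case-resampling
#' percentile 95% CI: pairs are resampled with replacement `n_boot` times
#' and rho recomputed; the odd default count gives unambiguous percentile
#' indices. Pairs with a missing value are dropped (count reported).
#'
#' @param x,y numeric vectors of equal length (>= 5 complete pairs).
#' @param n_boot bootstrap resamples (default 1999).
#' @param seed integer RNG seed.
#' @return list with `rho`, `ci_low`, `ci_high`, `n` (complete pairs used)
#'   and `n_dropped`.
#' @export
spearman_with_ci <- function(x, y, n_boot = 1999, seed = NULL) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant input vector: Spearman correlation undefined",
         call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(x[i])) < 2L || length(unique(y[i])) < 2L)
      return(NA_real_)
    stats::cor(x[i], y[i], method = "spearman")
  }, numeric(1)))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                               type = 7))
  list(rho = rho, ci_low = ci[1], ci_high = ci[2], n = n,
       n_dropped = n_dropped)
}

#' Between-method agreement report
#'
#' For paired laterality results from two methods on the same subjects:
#' the Spearman correlation of the estimates with a bootstrap 95% CI, the
#' 3x3 cross-tabulation of laterality categories, and the percentage of
#' subjects categorised bilateral under each method (the headline contrast
#' between wide- and narrow-CI methods).
#'
#' @param results_a,results_b lists of `li_result` objects (paired by
#'   position), or data.frames with columns `estimate`, `ci_low`, `ci_high`.
#' @param n_boot,seed passed to [spearman_with_ci()].
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(results_a, results_b, n_boot = 1999,
                             seed = NULL) {
  a <- as_li_frame(results_a)
  b <- as_li_frame(results_b)
  if (nrow(a) != nrow(b))
    stop("length mismatch: the two result lists must be paired",
         call. = FALSE)
  sp <- spearman_with_ci(a$estimate, b$estimate, n_boot = n_boot,
                         seed = seed)
  lev <- c("left", "bilateral", "right")
  ca <- factor(categorise(a$ci_low, a$ci_high), levels = lev)
  cb <- factor(categorise(b$ci_low, b$ci_high), levels = lev)
  structure(
    list(rho = sp$rho, rho_ci = c(sp$ci_low, sp$ci_high), n = nrow(a),
         cross_tab = table(a = ca, b = cb),
         pct_bilateral = c(a = 100 * mean(ca == "bilateral"),
                           b = 100 * mean(cb == "bilateral"))),
    class = "agreement_report")
}

as_li_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("estimate", "ci_low", "ci_high") %in% names(x)))
    return(x)
  }
  data.frame(
    estimate = vapply(x, `[[`, numeric(1), "estimate"),
    ci_low = vapply(x, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(x, `[[`, numeric(1), "ci_high"))
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Between-method agreement (n = ", x$n, ")\n", sep = "")
  cat("  Spearman rho = ", format(x$rho, digits = digits),
      "  95% CI [", format(x$rho_ci[1], digits = digits), ", ",
      format(x$rho_ci[2], digits = digits), "]\n", sep = "")
  cat("  % bilateral: method a = ", format(x$pct_bilateral[["a"]],
      digits = digits), ", method b = ",
      format(x$pct_bilateral[["b"]], digits = digits), "\n", sep = "")
  print(x$cross_tab)
  invisible(x)
}
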