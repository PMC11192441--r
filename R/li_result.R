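#' Laterality-index results
#'
#' All three estimators (`li_mirror`, `li_toolbox`, `li_ftcd`) return objects
#' inheriting class `li_result`: a point estimate of the laterality index
#' (positive = left dominant), a 95% confidence interval, and the laterality
#' category derived from the interval via [categorise()].
#'
#' @param estimate LI point estimate.
#' @param ci_low,ci_high 95% interval bounds.
#' @param method one of "mirror", "toolbox", "gam".
#' @param n_units number of units the estimate rests on (subsamples, retained
#'   thresholds, or kept trials).
#' @param seed RNG seed used, or NA for deterministic fits.
#' @param ... extra method-specific fields stored on the object.
#' @return An object of class `c("li_<method>", "li_result")`.
#' @keywords internal
new_li_result <- function(estimate, ci_low, ci_high, method, n_units,
                          seed = NA_integer_, ...) {
  stopifnot(ci_low <= ci_high + 1e-12)
  structure(
    c(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
           method = method, category = categorise(ci_low, ci_high),
           n_units = n_units, seed = seed),
      list(...)),
    class = c(paste0("li_", method), "li_result"))
}

#' @export
print.li_result <- function(x, digits = 4, ...) {
  cat("Laterality index (", x$method, " method)\n", sep = "")
  cat("  LI = ", format(x$estimate, digits = digits),
      "  95% CI [", format(x$ci_low, digits = digits), ", ",
      format(x$ci_high, digits = digits), "]\n", sep = "")
  cat("  category: ", x$category, "   n_units: ", x$n_units, "\n", sep = "")
  invisible(x)
}

#' @export
summary.li_result <- function(object, ...) {
  out <- data.frame(method = object$method, estimate = object$estimate,
                    ci_low = object$ci_low, ci_high = object$ci_high,
                    category = object$category, n_units = object$n_units,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.li_result", "data.frame")
  out
}

#' @export
coef.li_result <- function(object, ...) c(li = object$estimate)

#' @export
confint.li_result <- function(object, parm, level = 0.95, ...) {
  if (!missing(level) && level != 0.95)
    stop("only the 95% interval computed at fit time is available",
         call. = FALSE)
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("li", c("2.5 %", "97.5 %")))
}

#' Rescale a laterality index for display
#'
#' Divides the estimate and both interval bounds (and, where present, the
#' standard error) by a positive constant. A linear transform: the laterality
#' category and any rank correlation with other estimates are unchanged.
#' Conventional divisors are 2.7 for mirror difference scores and 6 for fTCD
#' interaction LIs, chosen so the scaled values lie near the [-1, 1] range of
#' conventional LIs.
#'
#' @param result an object inheriting `li_result`.
#' @param divisor positive scalar.
#' @return The rescaled object; `$scaled_by` records the divisor applied.
#' @export
scale_li <- function(result, divisor) {
  if (!is.numeric(divisor) || length(divisor) != 1L || divisor <= 0)
    stop("divisor must be a positive scalar", call. = FALSE)
  result$estimate <- result$estimate / divisor
  result$ci_low <- result$ci_low / divisor
  result$ci_high <- result$ci_high / divisor
  if (!is.null(result$se)) result$se <- result$se / divisor
  result$scaled_by <- divisor * (result$scaled_by %||% 1)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}
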