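#' Construct a bilateral CBFV recording
#'
#' Cerebral blood-flow-velocity samples from the left and right middle
#' cerebral arteries, with trial-onset markers (1-based sample indices) and
#' the sampling rate. Preprocessing stages annotate the object as they are
#' applied; the pipeline order is enforced (see [ftcd_preprocess()]).
#'
#' @param left,right velocity samples (equal length, arbitrary units).
#' @param fs sampling rate in Hz.
#' @param markers strictly increasing 1-based trial-onset sample indices.
#' @return An object of class `cbfv_recording`.
#' @export
cbfv_recording <- function(left, right, fs, markers) {
  if (length(left) != length(right))
    stop("left and right channels must have equal length", call. = FALSE)
  markers <- as.integer(markers)
  if (length(markers) && (any(diff(markers) <= 0) ||
      min(markers) < 1L || max(markers) > length(left)))
    stop("markers must be strictly increasing sample indices within range",
         call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(
    list(left = as.numeric(left), right = as.numeric(right), fs = fs,
         markers = markers, flagged = logical(length(left)),
         channel_means = NULL, stages = character()),
    class = "cbfv_recording")
}

#' Read a CBFV recording from delimited text
#'
#' Expects columns `left`, `right` and `marker` (nonzero marks a trial
#' onset); any `time` or `sample` column is ignored beyond ordering.
#'
#' @param path CSV/TSV path.
#' @param fs sampling rate in Hz.
#' @param sep field separator (default auto: comma for .csv, tab otherwise).
#' @return A [cbfv_recording()].
#' @export
read_cbfv <- function(path, fs, sep = NULL) {
  if (!file.exists(path)) stop("missing file: '", path, "'", call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("left", "right", "marker")
  if (!all(need %in% names(tab)))
    stop("input must have columns left, right, marker", call. = FALSE)
  cbfv_recording(tab$left, tab$right, fs, which(tab$marker != 0))
}

#' @export
print.cbfv_recording <- function(x, ...) {
  cat("<cbfv_recording> ", length(x$left), " samples @ ", x$fs, " Hz, ",
      length(x$markers), " trial markers\n", sep = "")
  if (length(x$stages))
    cat("  stages applied: ", paste(x$stages, collapse = " -> "), "\n",
        sep = "")
  invisible(x)
}

add_stage <- function(rec, stage) {
  rec$stages <- c(rec$stages, stage)
  rec
}

require_stage_order <- function(rec, stage, after = NULL, before = NULL) {
  for (s in after) if (!(s %in% rec$stages))
    stop("pipeline order violation: '", stage, "' requires '", s,
         "' to have been applied first", call. = FALSE)
  for (s in before) if (s %in% rec$stages)
    stop("pipeline order violation: '", stage, "' must precede '", s, "'",
         call. = FALSE)
  invisible(TRUE)
}

#' Downsample a recording by an integer factor
#'
#' Keeps every (fs / target_fs)-th sample of both channels (decimation,
#' matching the convention of taking the 100 Hz stream down to 25 Hz);
#' marker indices are rescaled and floored onto the new grid.
#'
#' @param rec a [cbfv_recording()].
#' @param target_fs target sampling rate, must divide `fs` (default 25 Hz).
#' @return The downsampled recording.
#' @export
downsample <- function(rec, target_fs = 25) {
  fct <- rec$fs / target_fs
  if (abs(fct - round(fct)) > 1e-9 || fct < 1)
    stop("non-integer downsampling factor: fs = ", rec$fs, ", target = ",
         target_fs, call. = FALSE)
  require_stage_order(rec, "downsample",
                      before = c("artefact", "normalise", "integrate"))
  fct <- as.integer(round(fct))
  keep <- seq(1L, length(rec$left), by = fct)
  rec$left <- rec$left[keep]
  rec$right <- rec$right[keep]
  rec$flagged <- rec$flagged[keep]
  rec$markers <- as.integer((rec$markers - 1L) %/% fct + 1L)
  rec$fs <- target_fs
  add_stage(rec, "downsample")
}

#' Flag extreme samples by empirical quantiles
#'
#' Samples outside the per-channel (`q_low`, `q_high`) empirical quantile
#' band -- by default the 0.0001-0.9999 band, catching roughly the most
#' extreme 0.02% of samples -- are flagged as artefacts. Flagged samples are
#' excluded from channel-mean computation. Under the default "flag-epoch"
#' policy any epoch overlapping a flagged sample is later rejected; under
#' "interpolate" the flagged samples are replaced by linear interpolation
#' from their unflagged neighbours and no epoch is rejected on their
#' account. A constant channel has a degenerate band and yields no flags.
#' Gross artefacts known from visual inspection can be supplied as `manual`
#' sample indices.
#'
#' @param rec a [cbfv_recording()].
#' @param q_low,q_high quantile bounds (defaults 0.0001 and 0.9999).
#' @param manual integer sample indices to flag unconditionally.
#' @param policy "flag-epoch" (default) or "interpolate".
#' @return The recording with `$flagged` (and, for "interpolate", the
#'   channels) updated.
#' @export
reject_extreme_samples <- function(rec, q_low = 0.0001, q_high = 0.9999,
                                   manual = integer(),
                                   policy = c("flag-epoch", "interpolate")) {
  require_stage_order(rec, "artefact", before = c("normalise", "integrate"))
  policy <- match.arg(policy)
  for (ch in c("left", "right")) {
    x <- rec[[ch]]
    qs <- stats::quantile(x, c(q_low, q_high), type = 7, names = FALSE)
    if (qs[2] > qs[1])
      rec$flagged <- rec$flagged | x < qs[1] | x > qs[2]
  }
  rec$flagged[manual] <- TRUE
  if (policy == "interpolate" && any(rec$flagged) && !all(rec$flagged)) {
    ok <- which(!rec$flagged)
    bad <- which(rec$flagged)
    for (ch in c("left", "right"))
      rec[[ch]][bad] <- stats::approx(ok, rec[[ch]][ok], xout = bad,
                                      rule = 2)$y
    rec$n_interpolated <- length(bad)
    rec$flagged[] <- FALSE
  }
  add_stage(rec, "artefact")
}

#' Normalise each channel to percent of its mean
#'
#' Divides each channel by its own mean over unflagged samples and multiplies
#' by 100, so each channel's mean is 100%. This removes between-side and
#' between-session differences in absolute velocity and insonation angle.
#'
#' @param rec a [cbfv_recording()] (after artefact flagging).
#' @return The normalised recording; `$channel_means` stores the raw means.
#' @export
normalise <- function(rec) {
  require_stage_order(rec, "normalise", before = "integrate")
  ok <- !rec$flagged
  m <- c(left = mean(rec$left[ok]), right = mean(rec$right[ok]))
  if (any(!is.finite(m)) || any(m <= 0))
    stop("non-positive channel mean; cannot normalise", call. = FALSE)
  rec$left <- rec$left / m[["left"]] * 100
  rec$right <- rec$right / m[["right"]] * 100
  rec$channel_means <- m
  add_stage(rec, "normalise")
}

# Local-maximum peak scan with a minimum separation, greedily keeping the
# taller of two conflicting peaks (amplitude changes cannot move locations).
find_peaks <- function(x, min_dist, min_height) {
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (length(cand) == 0L) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer()
  for (p in cand)
    if (!length(keep) || min(abs(keep - p)) >= min_dist) keep <- c(keep, p)
  sort(keep)
}

#' Heart-cycle integration
#'
#' Detects cardiac cycles from the summed channels (local maxima with a
#' minimum separation of 60/150 s, i.e. assuming a heart rate of at most 150
#' bpm, and a height gate scaled to the signal's interquartile range) and
#' replaces every sample within a cycle, on both channels, by that channel's
#' mean over the cycle. This removes pulsatility while preserving
#' cycle-to-cycle velocity. A constant signal is returned unchanged (its
#' integral is itself for any boundaries); a non-constant signal with no
#' detectable peaks raises an error suggesting a rate-band override.
#'
#' @param rec a normalised [cbfv_recording()].
#' @param rate_band plausible heart-rate band in bpm (default c(40, 150));
#'   only the upper bound (minimum peak separation) is used by the detector.
#' @return The cycle-integrated recording.
#' @export
heart_cycle_integrate <- function(rec, rate_band = c(40, 150)) {
  require_stage_order(rec, "integrate", after = "normalise")
  s <- rec$left + rec$right
  if (max(rec$left) - min(rec$left) < 1e-12 &&
      max(rec$right) - min(rec$right) < 1e-12) {
    rec$cycle <- seq_along(rec$left)
    return(add_stage(rec, "integrate"))
  }
  min_dist <- max(1L, floor(rec$fs * 60 / rate_band[2]))
  ht <- stats::median(s) + 0.25 * stats::IQR(s)
  pk <- find_peaks(s, min_dist, ht)
  if (length(pk) < 2L)
    stop("no cardiac peaks detected; override rate_band if the heart rate ",
         "is outside ", rate_band[1], "-", rate_band[2], " bpm",
         call. = FALSE)
  bounds <- unique(c(1L, pk, length(s) + 1L))
  cyc <- findInterval(seq_along(s), bounds, rightmost.closed = FALSE)
  rec$left <- stats::ave(rec$left, cyc)
  rec$right <- stats::ave(rec$right, cyc)
  rec$cycle <- cyc
  add_stage(rec, "integrate")
}

#' Cut a recording into peri-stimulus epochs
#'
#' One epoch per trial marker, spanning `window` seconds around the onset
#' (default -12 s to 30 s). Trials whose window exceeds the recording are
#' flagged "truncated" (data NA-padded), and under the flag-epoch artefact
#' policy trials overlapping flagged samples are flagged "artefact"; neither
#' is silently dropped.
#'
#' @param rec a preprocessed [cbfv_recording()].
#' @param window epoch window in seconds relative to onset.
#' @return An object of class `cbfv_epochs`: `epochs` (time x side x trial
#'   array), `time_axis`, `kept` flags with `reasons`, and the recording
#'   metadata.
#' @export
epochize <- function(rec, window = c(-12, 30)) {
  if (length(rec$markers) == 0L) stop("no trial markers", call. = FALSE)
  offs <- seq.int(round(window[1] * rec$fs),
                  round(window[2] * rec$fs) - 1L)
  time_axis <- offs / rec$fs
  n <- length(rec$left)
  nt <- length(rec$markers)
  epochs <- array(NA_real_, dim = c(length(offs), 2L, nt),
                  dimnames = list(NULL, c("left", "right"), NULL))
  kept <- rep(TRUE, nt)
  reasons <- rep("", nt)
  cycles <- if (!is.null(rec$cycle))
    matrix(NA_integer_, length(offs), nt) else NULL
  for (i in seq_len(nt)) {
    idx <- rec$markers[i] + offs
    ok <- idx >= 1L & idx <= n
    epochs[ok, "left", i] <- rec$left[idx[ok]]
    epochs[ok, "right", i] <- rec$right[idx[ok]]
    if (!is.null(cycles)) cycles[ok, i] <- rec$cycle[idx[ok]]
    if (!all(ok)) {
      kept[i] <- FALSE
      reasons[i] <- "truncated"
    } else if (any(rec$flagged[idx])) {
      kept[i] <- FALSE
      reasons[i] <- "artefact"
    }
  }
  structure(
    list(epochs = epochs, raw = epochs, time_axis = time_axis, fs = rec$fs,
         kept = kept, reasons = reasons, cycles = cycles,
         baseline_corrected = FALSE, stages = rec$stages),
    class = "cbfv_epochs")
}

#' @export
print.cbfv_epochs <- function(x, ...) {
  cat("<cbfv_epochs> ", dim(x$epochs)[3], " trials (", sum(x$kept),
      " kept), ", dim(x$epochs)[1], " samples @ ", x$fs,
      " Hz, t in [", min(x$time_axis), ", ",
      max(x$time_axis) + 1 / x$fs, ") s\n", sep = "")
  invisible(x)
}

#' Baseline-correct each epoch
#'
#' Subtracts, per trial and per side, the mean over the baseline window
#' (default the 10 s of rest immediately preceding trial onset), so each
#' trial's baseline-window mean is exactly zero per side.
#'
#' @param epochs a [epochize()] result.
#' @param baseline window in seconds, default c(-10, 0) (half-open at 0).
#' @return The corrected `cbfv_epochs`.
#' @export
baseline_correct <- function(epochs, baseline = c(-10, 0)) {
  sel <- epochs$time_axis >= baseline[1] & epochs$time_axis < baseline[2]
  if (!any(sel)) stop("empty baseline window", call. = FALSE)
  if (baseline[1] < min(epochs$time_axis))
    stop("baseline window outside epoch span", call. = FALSE)
  for (i in seq_len(dim(epochs$epochs)[3]))
    for (ch in 1:2) {
      b <- mean(epochs$epochs[sel, ch, i])
      epochs$epochs[, ch, i] <- epochs$epochs[, ch, i] - b
    }
  epochs$baseline <- baseline
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Reject trials with out-of-band signal
#'
#' Flags any trial containing a pre-baseline-correction normalised sample
#' below `low_pct` or above `high_pct` percent of the channel mean. The
#' lower default (60) is the conventional dropout gate; the upper default is
#' 140 because normalised pulsatile signal routinely exceeds 100% of its own
#' mean, so a literal upper bound of 100 (selectable) would reject nearly
#' every trial.
#'
#' @param epochs a `cbfv_epochs` (epochs must be in normalised % units).
#' @param low_pct,high_pct rejection bounds in percent (defaults 60, 140).
#' @return The `cbfv_epochs` with `kept`/`reasons` updated.
#' @export
reject_trials <- function(epochs, low_pct = 60, high_pct = 140) {
  for (i in seq_len(dim(epochs$raw)[3])) {
    if (!epochs$kept[i]) next
    x <- epochs$raw[, , i]
    if (any(x < low_pct, na.rm = TRUE)) {
      epochs$kept[i] <- FALSE
      epochs$reasons[i] <- "low-signal"
    } else if (any(x > high_pct, na.rm = TRUE)) {
      epochs$kept[i] <- FALSE
      epochs$reasons[i] <- "high-signal"
    }
  }
  epochs
}

#' Participant-level exclusion rule
#'
#' A participant is excluded when strictly more than `max_reject_fraction` of
#' their trials were rejected: the threshold count is
#' `floor(max_reject_fraction * n_trials)` rejected trials allowed (3 of 15
#' at the default 20%), and one more triggers exclusion.
#'
#' @param epochs a `cbfv_epochs`, or an integer vector
#'   `c(n_rejected, n_trials)`.
#' @param max_reject_fraction maximum tolerated rejected fraction (default
#'   0.20).
#' @return list with `excluded`, `n_rejected`, `n_trials` and the
#'   `threshold` count used.
#' @export
participant_exclusion <- function(epochs, max_reject_fraction = 0.20) {
  if (inherits(epochs, "cbfv_epochs")) {
    n_trials <- length(epochs$kept)
    n_rejected <- sum(!epochs$kept)
  } else {
    n_rejected <- epochs[1]
    n_trials <- epochs[2]
  }
  thr <- floor(max_reject_fraction * n_trials)
  list(excluded = n_rejected > thr, n_rejected = n_rejected,
       n_trials = n_trials, threshold = thr)
}

#' Average kept epochs
#'
#' Pointwise mean over kept trials per side, plus the left-minus-right
#' difference trace (the classic averaged-trial laterality curve).
#'
#' @param epochs a `cbfv_epochs`.
#' @return data.frame with columns `time`, `left`, `right`, `diff`.
#' @export
average_epochs <- function(epochs) {
  k <- which(epochs$kept)
  if (length(k) == 0L) stop("zero kept trials", call. = FALSE)
  L <- rowMeans(epochs$epochs[, "left", k, drop = FALSE], dims = 1)
  R <- rowMeans(epochs$epochs[, "right", k, drop = FALSE], dims = 1)
  data.frame(time = epochs$time_axis, left = L, right = R, diff = L - R)
}

#' Run the standard fTCD preprocessing pipeline
#'
#' Applies, in the canonical order: downsampling, quantile artefact
#' flagging, normalisation to percent of channel mean, heart-cycle
#' integration, epoching, trial rejection and baseline correction. Each
#' stage records itself on the object and refuses to run out of order.
#'
#' @param rec a raw [cbfv_recording()].
#' @param target_fs downsampling target (default 25 Hz).
#' @param window epoch window (default c(-12, 30) s).
#' @param baseline baseline window (default c(-10, 0) s).
#' @param low_pct,high_pct trial-rejection bounds (defaults 60, 140).
#' @param manual_artefacts sample indices to flag unconditionally.
#' @param artefact_policy passed to [reject_extreme_samples()].
#' @return A `cbfv_epochs` ready for [li_ftcd()] / [average_epochs()].
#' @export
ftcd_preprocess <- function(rec, target_fs = 25, window = c(-12, 30),
                            baseline = c(-10, 0), low_pct = 60,
                            high_pct = 140, manual_artefacts = integer(),
                            artefact_policy = "flag-epoch") {
  rec <- downsample(rec, target_fs)
  rec <- reject_extreme_samples(rec, manual = manual_artefacts,
                                policy = artefact_policy)
  rec <- normalise(rec)
  rec <- heart_cycle_integrate(rec)
  ep <- epochize(rec, window)
  ep <- reject_trials(ep, low_pct, high_pct)
  baseline_correct(ep, baseline)
}

#' fTCD laterality index from an additive interaction model
#'
#' Fits, by ordinary least squares on the long-format kept epochs, an
#' additive model of the normalised baseline-corrected signal: a cubic
#' B-spline smooth over time in epoch (absorbing the shared task-locked
#' response shape), a side main effect, a period-of-interest (POI) boxcar
#' main effect, a categorical per-epoch effect, and the side-by-POI
#' interaction. The LI is the interaction coefficient: the percentage
#' difference in blood flow between left and right channels specific to the
#' POI, with positive values meaning left dominance. The 95% CI is the
#' Wald interval `li +/- 1.96 se`.
#'
#' After heart-cycle integration all samples within a cardiac cycle are
#' identical, so the model is fitted on one observation per (epoch, side,
#' cycle, POI-membership) group; treating the duplicated samples as
#' independent observations would understate the standard error by roughly
#' the square root of the samples-per-cycle count. When no cycle ids are
#' available (epochs built outside the pipeline) the fit uses every sample.
#'
#' @param epochs a baseline-corrected `cbfv_epochs`.
#' @param poi period of interest in seconds relative to trial onset;
#'   conventional defaults are c(7, 17) for word generation and c(7, 27)
#'   for semantic matching.
#' @param spline_df degrees of freedom of the B-spline time basis (default
#'   10).
#' @param scale_divisor optional display divisor (e.g. 6); applied via
#'   [scale_li()].
#' @return A `c("li_gam", "li_result")` object with fields `se`,
#'   `n_trials_used` and the underlying `lm` fit in `$fit`.
#' @examples
#' syn <- synth_cbfv(n_trials = 8, delta = 6, fs = 25, seed = 1)
#' ep <- ftcd_preprocess(syn$recording, target_fs = 25)
#' li_ftcd(ep, poi = c(7, 17))
#' @export
li_ftcd <- function(epochs, poi = c(7, 17), spline_df = 10,
                    scale_divisor = NULL) {
  if (!isTRUE(epochs$baseline_corrected))
    stop("epochs must be baseline-corrected before model fitting",
         call. = FALSE)
  k <- which(epochs$kept)
  if (length(k) < 2L) stop("need at least 2 kept trials", call. = FALSE)
  ta <- epochs$time_axis
  if (poi[1] < min(ta) || poi[2] > max(ta) + 1 / epochs$fs)
    stop("POI outside epoch span", call. = FALSE)
  in_poi <- ta >= poi[1] & ta < poi[2]
  if (all(in_poi) || !any(in_poi))
    stop("rank-deficient design: POI must cover part, not all or none, ",
         "of the epoch", call. = FALSE)

  nt <- length(ta)
  dat <- data.frame(
    y = c(epochs$epochs[, "left", k], epochs$epochs[, "right", k]),
    time = rep(ta, times = 2 * length(k)),
    poi = rep(in_poi, times = 2 * length(k)),
    side = factor(rep(c("left", "right"), each = nt * length(k)),
                  levels = c("right", "left")),
    epoch = factor(rep(rep(k, each = nt), times = 2)))
  if (!is.null(epochs$cycles)) {
    # collapse duplicated within-cycle samples to one observation per group
    cyc <- rep(c(epochs$cycles[, k]), times = 2)
    g <- interaction(dat$epoch, dat$side, cyc, dat$poi, drop = TRUE)
    dat <- data.frame(
      y = as.numeric(tapply(dat$y, g, mean)),
      time = as.numeric(tapply(dat$time, g, mean)),
      poi = as.logical(tapply(dat$poi, g, `[`, 1L)),
      side = factor(as.character(tapply(as.character(dat$side), g, `[`, 1L)),
                    levels = c("right", "left")),
      epoch = factor(as.character(tapply(as.character(dat$epoch), g,
                                         `[`, 1L))))
  }
  fit <- stats::lm(
    y ~ splines::bs(time, df = spline_df) + side + poi + epoch + side:poi,
    data = dat)
  cf <- summary(fit)$coefficients
  term <- "sideleft:poiTRUE"
  if (!(term %in% rownames(cf)) || any(is.na(stats::coef(fit))))
    stop("rank-deficient design: interaction term not estimable",
         call. = FALSE)
  li <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  res <- new_li_result(li, li - 1.96 * se, li + 1.96 * se, method = "gam",
                       n_units = length(k), se = se,
                       n_trials_used = length(k), poi = poi,
                       spline_df = spline_df, fit = fit)
  if (!is.null(scale_divisor)) res <- scale_li(res, scale_divisor)
  res
}

#' @export
residuals.li_gam <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.li_gam <- function(object, ...) stats::fitted(object$fit)

# Plain subtraction reference LI: mean(L - R) inside the POI minus outside,
# over kept epochs. Used as the flat-limit cross-check for the model fit.
subtraction_li <- function(epochs, poi) {
  k <- which(epochs$kept)
  ta <- epochs$time_axis
  in_poi <- ta >= poi[1] & ta < poi[2]
  d <- epochs$epochs[, "left", k, drop = FALSE] -
    epochs$epochs[, "right", k, drop = FALSE]
  mean(d[in_poi, , ]) - mean(d[!in_poi, , ])
}
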