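#' Describe one bilateral activation blob
#'
#' A spherical activation (or deactivation, for negative amplitudes) placed
#' at `centre` on the left (the x coordinate is forced negative) with
#' amplitude `amp_left`, and at the mirrored centre with amplitude
#' `amp_right`.
#'
#' @param centre world-mm centre c(x, y, z) of the left-hemisphere sphere.
#' @param radius_mm sphere radius.
#' @param amp_left,amp_right statistic amplitude per side; sign models
#'   activation vs deactivation.
#' @return A list of class `blob`.
#' @export
blob <- function(centre, radius_mm, amp_left, amp_right) {
  stopifnot(radius_mm > 0, length(centre) == 3)
  centre[1] <- -abs(centre[1])
  structure(list(centre = centre, radius = radius_mm,
                 amp_left = amp_left, amp_right = amp_right),
            class = "blob")
}

gauss_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3 * sd_vox))
  k <- exp(-(( -r:r)^2) / (2 * sd_vox^2))
  k / sum(k)
}

smooth3d <- function(a, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(a)
  k <- gauss_kernel_1d(fwhm_mm, voxel_mm)
  r <- (length(k) - 1L) / 2L
  conv1 <- function(v) {
    # reflect-padded 1-D convolution
    n <- length(v)
    vp <- c(v[pmin(r:1, n)], v, v[pmax(n - (1:r) + 1, 1)])
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  for (d in 1:3) a <- apply(a, setdiff(1:3, d), conv1) |>
      aperm(order(c(d, setdiff(1:3, d))))
  a
}

#' Generate a synthetic lateralised statistic volume
#'
#' Builds a t-statistic-like volume on a grid symmetric about world x = 0
#' (default 32x32x32 at 2 mm, a desk-scale stand-in for a 2 mm standard
#' grid): the sum of spherical blobs with per-side amplitudes, optionally
#' Gaussian-smoothed, plus voxelwise Gaussian noise. Each blob also yields a
#' bilateral ROI mask (sphere plus its mirror). The truth record carries the
#' per-ROI amplitude gap so downstream tests know the expected laterality
#' sign without re-reading generator internals.
#'
#' @param shape grid dimensions (default c(32, 32, 32)).
#' @param voxel_mm isotropic voxel size (default 2).
#' @param blobs list of [blob()] specifications.
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param smooth_fwhm Gaussian smoothing FWHM in mm applied to the blob
#'   pattern before noise (default 0 = none).
#' @param seed integer RNG seed; output is a pure function of (spec, seed).
#' @return list with `volume` ([stat_volume()]), `masks` (one [roi_mask()]
#'   per blob, not midline-excluded) and `truth` (data.frame with per-blob
#'   `amp_left`, `amp_right`, `gap = amp_left - amp_right` and
#'   `sign = sign(gap)`).
#' @export
synth_tmap <- function(shape = c(32, 32, 32), voxel_mm = 2,
                       blobs = list(blob(c(-20, 0, 0), 12, 4, 1)),
                       noise_sd = 1, smooth_fwhm = 0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  # grid centred so voxel centres pair across x = 0 (none sits at 0)
  origin <- -(shape + 1) / 2 * voxel_mm  # world coord of 0-based voxel -0.5
  transform <- diag(4)
  diag(transform)[1:3] <- voxel_mm
  transform[1:3, 4] <- origin + voxel_mm
  cx <- transform[1, 4] + voxel_mm * (seq_len(shape[1]) - 1)
  cy <- transform[2, 4] + voxel_mm * (seq_len(shape[2]) - 1)
  cz <- transform[3, 4] + voxel_mm * (seq_len(shape[3]) - 1)

  base <- array(0, dim = shape)
  masks <- vector("list", length(blobs))
  for (bi in seq_along(blobs)) {
    b <- blobs[[bi]]
    lim <- abs(b$centre) + b$radius
    if (any(lim > c(max(abs(cx)), max(abs(cy)), max(abs(cz))) + voxel_mm / 2))
      stop("blob outside grid", call. = FALSE)
    d2l <- outer(outer((cx - b$centre[1])^2, (cy - b$centre[2])^2, `+`),
                 (cz - b$centre[3])^2, `+`)
    d2r <- outer(outer((cx + b$centre[1])^2, (cy - b$centre[2])^2, `+`),
                 (cz - b$centre[3])^2, `+`)
    inl <- d2l <= b$radius^2
    inr <- d2r <= b$radius^2
    base <- base + b$amp_left * inl + b$amp_right * inr
    masks[[bi]] <- roi_mask(inl | inr, transform,
                            name = paste0("blob", bi))
  }
  base <- smooth3d(base, smooth_fwhm, voxel_mm)
  data <- with_seed(seed, base +
    if (noise_sd > 0) array(stats::rnorm(prod(shape), 0, noise_sd), shape)
    else 0)
  truth <- data.frame(
    blob = seq_along(blobs),
    amp_left = vapply(blobs, `[[`, numeric(1), "amp_left"),
    amp_right = vapply(blobs, `[[`, numeric(1), "amp_right"))
  truth$gap <- truth$amp_left - truth$amp_right
  truth$sign <- sign(truth$gap)
  list(volume = stat_volume(data, transform), masks = masks, truth = truth)
}

#' Generate a synthetic bilateral CBFV recording
#'
#' Emulates a word-generation-style fTCD session: a pulsatile baseline
#' (raised-cosine pulse train at the given heart rate around per-channel
#' base velocities), a shared task-locked velocity increase in every trial,
#' a lateralised offset `delta` (in percent of the channel base) added to
#' the left channel during the period of interest, Gaussian noise, and
#' optional injected artefact spikes. Trials follow the 5 s cue / 20 s task
#' / 25 s rest structure with markers at cue onset.
#'
#' @param n_trials number of trials (default 23, a standard word-generation
#'   protocol length).
#' @param trial_structure seconds for cue, task and rest phases (default
#'   c(cue = 5, task = 20, rest = 25)).
#' @param fs sampling rate in Hz (default 100, downsampled to 25 by the
#'   pipeline).
#' @param heart_rate heart rate in bpm (default 70).
#' @param base velocity baseline per channel, c(left, right) (default
#'   c(60, 55) cm/s -- typical adult MCA values).
#' @param pulse_amp pulsatility amplitude as a fraction of base (default
#'   0.25).
#' @param response_amp shared task response in percent of base (default 5).
#' @param delta lateralised left-channel offset in percent of base during
#'   the POI (default 6).
#' @param poi period of interest in seconds from trial onset (default
#'   c(7, 17)).
#' @param noise_sd Gaussian noise SD in raw velocity units (default 1).
#' @param spikes list of c(time_s, magnitude) artefacts; each sets both
#'   channels to magnitude times their base at that time.
#' @param lead_s,tail_s recording padding before the first / after the last
#'   trial (defaults 15 and 35 s, enough for full epochs).
#' @param seed integer RNG seed.
#' @return list with `recording` ([cbfv_recording()]) and `truth`
#'   (delta, poi, spike sample indices, heart rate).
#' @export
synth_cbfv <- function(n_trials = 23,
                       trial_structure = c(cue = 5, task = 20, rest = 25),
                       fs = 100, heart_rate = 70, base = c(60, 55),
                       pulse_amp = 0.25, response_amp = 5, delta = 6,
                       poi = c(7, 17), noise_sd = 1, spikes = list(),
                       lead_s = 15, tail_s = 35, seed = NULL) {
  stopifnot(n_trials >= 1, noise_sd >= 0, all(trial_structure > 0))
  trial_len <- sum(trial_structure)
  total_s <- lead_s + n_trials * trial_len + tail_s
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  onsets_s <- lead_s + (seq_len(n_trials) - 1) * trial_len
  markers <- round(onsets_s * fs) + 1L

  # raised-cosine pulse train: periodic, one systolic peak per cycle
  pulse <- 0.5 * (1 - cos(2 * pi * heart_rate / 60 * t))^2

  # shared task response with 4 s raised-cosine ramps (haemodynamic onset
  # and offset are gradual); lateralised offset is a boxcar over the POI
  ramp_box <- function(t, on, off, ramp = 4) {
    u <- rep(0, length(t))
    rise <- t >= on & t < on + ramp
    fall <- t >= off - ramp & t < off
    u[t >= on + ramp & t < off - ramp] <- 1
    u[rise] <- 0.5 * (1 - cos(pi * (t[rise] - on) / ramp))
    u[fall] <- 0.5 * (1 - cos(pi * (off - t[fall]) / ramp))
    u
  }
  task_on <- rep(0, n)
  lat_on <- rep(0, n)
  cue <- trial_structure[[1]]
  task <- trial_structure[[2]]
  for (o in onsets_s) {
    w <- t >= o & t < o + trial_len
    task_on[w] <- task_on[w] +
      ramp_box(t[w], o + cue, o + cue + task)
    lat_on[t >= o + poi[1] & t < o + poi[2]] <- 1
  }

  # contributions are demeaned so each channel's mean equals its base
  # velocity exactly and normalised units recover delta without bias
  shape_ch <- function(b, extra) {
    b * (1 + pulse_amp * (pulse - mean(pulse)) +
           (response_amp / 100) * (task_on - mean(task_on)) +
           (extra - mean(extra)))
  }
  left <- shape_ch(base[1], (delta / 100) * lat_on)
  right <- shape_ch(base[2], rep(0, n))
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(2 * n, 0, noise_sd), ncol = 2))
    left <- left + noise[, 1]
    right <- right + noise[, 2]
  }
  spike_idx <- integer()
  for (sp in spikes) {
    i <- round(sp[1] * fs) + 1L
    left[i] <- base[1] * sp[2]
    right[i] <- base[2] * sp[2]
    spike_idx <- c(spike_idx, i)
  }
  list(recording = cbfv_recording(left, right, fs, markers),
       truth = list(delta = delta, poi = poi, spike_samples = spike_idx,
                    heart_rate = heart_rate, onsets_s = onsets_s))
}

#' Generate a synthetic cohort of lateralised statistic volumes
#'
#' Emulates a cohort of weakly left-lateralised individuals whose maps show
#' threshold-dependent laterality: a broad, weak left-biased activation
#' (right amplitude 2, left amplitude 2 plus a subject-specific gap drawn
#' from N(`gap_mean`, `gap_sd`)) combined with a small contralateral
#' high-statistic core in the right hemisphere (extra amplitude from
#' N(`core_mean`, `core_sd`)). At low thresholds the broad left bias
#' dominates; at the highest thresholds the right core does, so the
#' suprathreshold LI drifts and can reverse sign across the threshold grid
#' -- the regime in which threshold-averaging methods produce wide
#' confidence intervals while the threshold-free mirror difference remains
#' decisive.
#'
#' @param n_subjects cohort size (default 30).
#' @param gap_mean,gap_sd broad left-bias distribution (defaults 0.8, 0.3).
#' @param core_mean,core_sd contralateral core amplitude distribution
#'   (defaults 4, 0.5).
#' @param radius_mm,core_radius_mm blob radii (defaults 14 and 4 mm).
#' @param noise_sd voxel noise (default 1).
#' @param seed integer RNG seed for the whole cohort.
#' @return list of per-subject lists: `volume`, `mask` (combined bilateral
#'   ROI, not midline-excluded), `truth` (gap, core).
#' @export
synth_cohort_tmaps <- function(n_subjects = 30, gap_mean = 0.8,
                               gap_sd = 0.3, core_mean = 4, core_sd = 0.5,
                               radius_mm = 14, core_radius_mm = 4,
                               noise_sd = 1, seed = NULL) {
  pars <- with_seed(seed, data.frame(
    gap = stats::rnorm(n_subjects, gap_mean, gap_sd),
    core = stats::rnorm(n_subjects, core_mean, core_sd),
    map_seed = sample.int(.Machine$integer.max / 2, n_subjects)))
  lapply(seq_len(n_subjects), function(i) {
    syn <- synth_tmap(
      blobs = list(blob(c(-16, 0, 0), radius_mm, 2 + pars$gap[i], 2),
                   blob(c(-16, 0, 0), core_radius_mm, 0, pars$core[i])),
      noise_sd = noise_sd, seed = pars$map_seed[i])
    mask <- roi_mask(syn$masks[[1]]$data | syn$masks[[2]]$data,
                     syn$volume$transform, name = "combined")
    list(volume = syn$volume, mask = mask,
         truth = list(gap = pars$gap[i], core = pars$core[i]))
  })
}
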