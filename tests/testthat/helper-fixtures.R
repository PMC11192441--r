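# Shared fixtures, built in code.

# A small symmetric grid: n voxels per axis at voxel_mm spacing, centres
# paired across world x = 0 (matching the synth_tmap grid convention).
sym_transform <- function(n = 8, voxel_mm = 2) {
  tr <- diag(4)
  diag(tr)[1:3] <- voxel_mm
  tr[1:3, 4] <- -(n + 1) / 2 * voxel_mm + voxel_mm
  tr
}

sym_volume <- function(data, voxel_mm = 2) {
  stat_volume(data, sym_transform(dim(data)[1], voxel_mm))
}

# Volume whose value at each voxel equals its world-x coordinate.
worldx_volume <- function(n = 8, voxel_mm = 2) {
  tr <- sym_transform(n, voxel_mm)
  xs <- tr[1, 4] + voxel_mm * (0:(n - 1))
  sym_volume(array(rep(xs, times = n * n), dim = c(n, n, n)), voxel_mm)
}

full_mask <- function(vol, midline_excluded = FALSE, name = "custom") {
  roi_mask(array(TRUE, dim = vol$shape), vol$transform, name = name,
           midline_excluded = midline_excluded)
}

# Directly constructed epochs: flat shared response, iid Gaussian noise,
# an interaction delta added to the left channel inside the POI. These are
# the "known-truth" epochs used for model-calibration checks (no
# pulsatility, no cycle structure).
make_flat_epochs <- function(n_trials = 6, fs = 25, delta = 0,
                             noise_sd = 1, poi = c(7, 17),
                             window = c(-12, 30), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  offs <- seq.int(round(window[1] * fs), round(window[2] * fs) - 1L)
  ta <- offs / fs
  nt <- length(ta)
  ep <- array(rnorm(nt * 2 * n_trials, 0, noise_sd),
              dim = c(nt, 2, n_trials),
              dimnames = list(NULL, c("left", "right"), NULL))
  in_poi <- ta >= poi[1] & ta < poi[2]
  ep[in_poi, "left", ] <- ep[in_poi, "left", ] + delta
  structure(
    list(epochs = ep, raw = ep + 100, time_axis = ta, fs = fs,
         kept = rep(TRUE, n_trials), reasons = rep("", n_trials),
         cycles = NULL, baseline_corrected = TRUE, stages = character()),
    class = "cbfv_epochs")
}
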