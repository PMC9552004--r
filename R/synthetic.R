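#' Condition-effect specification for the synthetic cohort
#'
#' Describes how the tonic cold (CPT) condition differs from baseline in the
#' generated EEG. `complexity_shift` changes the fraction of band-limited
#' stochastic content mixed into the target band's oscillation on the affected
#' channels (positive values make the signal more irregular, raising
#' permutation entropy); `phase_lag_shift` adds a fixed phase offset (radians)
#' to the affected channels' band oscillator, altering cross-channel lead/lag
#' asymmetry (dPLI). With both shifts zero the two conditions are generated
#' from identical distributions.
#'
#' @param target_band One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param complexity_shift Signed shift of the stochastic mixing fraction
#'   (dimensionless, typically in \[-0.5, 0.5\]).
#' @param phase_lag_shift Signed phase offset in radians.
#' @param affected_channels Channel labels receiving the effect.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(target_band = "theta", complexity_shift = 0,
                        phase_lag_shift = 0, affected_channels = character()) {
  target_band <- match.arg(target_band, c("delta", "theta", "alpha", "beta"))
  structure(list(target_band = target_band,
                 complexity_shift = complexity_shift,
                 phase_lag_shift = phase_lag_shift,
                 affected_channels = affected_channels),
            class = "effect_spec")
}

#' Default moderate CPT effect used in demonstrations
#'
#' A theta-band irregularity increase plus a phase-lag offset over ten
#' frontal/central/parietal channels, sized so that the per-channel theta
#' permutation-entropy shift is on the order of one pooled standard deviation
#' across epochs.
#'
#' @return An `effect_spec`.
#' @export
demo_effect <- function() {
  effect_spec(target_band = "theta", complexity_shift = 0.5,
              phase_lag_shift = 0.4,
              affected_channels = c("Fp1", "Fp2", "F3", "Fz", "F4",
                                    "C3", "Cz", "C4", "P3", "Pz"))
}

#' Cohort configuration for the synthetic-EEG generator
#'
#' @param n_subjects_per_group Subjects per group (healthy, pain).
#' @param epochs_per_condition Named integer vector
#'   `c(baseline = ..., cpt = ...)`: number of 10-s epochs each recording
#'   must yield. Defaults 8 baseline / 7 CPT.
#' @param band_powers Named amplitude scales (microvolts) per band.
#' @param noise_amp Amplitude of the 1/f background noise (microvolts).
#' @param noise_exponent Spectral exponent of the background noise.
#' @param shared_frac Fraction of each band oscillation drawn from the shared
#'   cross-channel generator (controls connectivity strength), in \[0,1\].
#' @param base_noise_mix Baseline stochastic mixing fraction per band
#'   oscillation (controls baseline permutation entropy), in \[0,1).
#' @param lag_gradient Phase lag step (radians) between successive channels
#'   of the first shared generator; gives a known anterior-to-posterior
#'   lead/lag direction for dPLI validation.
#' @param lag_jitter Standard deviation (radians) of the per-channel random
#'   component of each generator's lag pattern.
#' @param n_generators Shared oscillators per band (default 3; one
#'   generator gives a strictly one-dimensional phase geometry whose
#'   thresholded graphs are unrealistically triangle-poor).
#' @param movement_fraction Fraction of subjects flagged as movers at baseline.
#' @param burst_rate Motor-artifact bursts per minute for movers.
#' @param burst_amplitude Motor-artifact burst amplitude (microvolts).
#' @param effect An [effect_spec()] applied to CPT recordings.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group = 10,
                          epochs_per_condition = c(baseline = 8, cpt = 7),
                          band_powers = c(delta = 20, theta = 10,
                                          alpha = 15, beta = 5),
                          noise_amp = 5,
                          noise_exponent = 1,
                          shared_frac = 0.6,
                          base_noise_mix = 0.25,
                          lag_gradient = 0.15,
                          lag_jitter = 0.2,
                          n_generators = 3,
                          movement_fraction = 0,
                          burst_rate = 25,
                          burst_amplitude = 60,
                          effect = effect_spec(),
                          seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_subjects_per_group < 1) stop("n_subjects_per_group must be >= 1")
  if (any(epochs_per_condition < 1)) stop("epoch counts must be >= 1")
  if (movement_fraction < 0 || movement_fraction > 1) {
    stop("movement_fraction must be in [0, 1]")
  }
  if (burst_rate < 0 || burst_amplitude < 0) {
    stop("burst_rate and burst_amplitude must be non-negative")
  }
  stopifnot(all(c("baseline", "cpt") %in% names(epochs_per_condition)))
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 epochs_per_condition = epochs_per_condition,
                 band_powers = band_powers, noise_amp = noise_amp,
                 noise_exponent = noise_exponent, shared_frac = shared_frac,
                 base_noise_mix = base_noise_mix, lag_gradient = lag_gradient,
                 lag_jitter = lag_jitter, n_generators = n_generators,
                 movement_fraction = movement_fraction,
                 burst_rate = burst_rate, burst_amplitude = burst_amplitude,
                 effect = effect, seed = as.integer(seed)),
            class = "cohort_config")
}

# FFT-shaped coloured noise: amplitude ~ f^(-exponent/2), unit variance.
# Returns an nch x n matrix; channels are generated in one batched FFT.
shaped_noise <- function(n, exponent = 1, nch = 1) {
  X <- stats::mvfft(matrix(stats::rnorm(n * nch), n, nch))
  f <- c(1, seq_len(n - 1))        # avoid DC blow-up
  f <- pmin(f, n - f + 1)          # symmetric about Nyquist
  X <- X * f^(-exponent / 2)
  X[1, ] <- 0
  y <- Re(stats::mvfft(X, inverse = TRUE)) / n
  y <- sweep(y, 2, apply(y, 2, stats::sd), "/")
  t(y)
}

col_unit_sd <- function(y) {
  m <- colMeans(y)
  s <- sqrt(pmax(colMeans(y^2) - m^2, 0))
  s[s == 0] <- 1
  sweep(y, 2, s, "/")
}

# Band-limited unit-variance noise via an FFT brick-wall mask (nch x n).
band_noise <- function(n, low, high, fs, nch = 1) {
  X <- stats::mvfft(matrix(stats::rnorm(n * nch), n, nch))
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  X[freqs < low | freqs > high, ] <- 0
  t(col_unit_sd(Re(stats::mvfft(X, inverse = TRUE)) / n))
}

# A full-band noise field and its band-centre (regular) part, derived from
# one white field so only one forward FFT is needed. Mixing between the two
# tilts each channel's spectrum from centre-concentrated (regular, low
# permutation entropy) to flat across the band (irregular, high entropy).
band_noise_pair <- function(n, low, high, clow, chigh, fs, nch) {
  X <- stats::mvfft(matrix(stats::rnorm(n * nch), n, nch))
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  Xb <- X
  Xb[freqs < low | freqs > high, ] <- 0
  Xn <- X
  Xn[freqs < clow | freqs > chigh, ] <- 0
  list(broad = t(col_unit_sd(Re(stats::mvfft(Xb, inverse = TRUE)) / n)),
       narrow = t(col_unit_sd(Re(stats::mvfft(Xn, inverse = TRUE)) / n)))
}

# Slowly drifting unit signal in [-1, 1] (lowpass-shaped noise, squashed).
# Sub-hertz content is generated on a coarse grid and interpolated: a
# full-rate FFT would spend almost all its work above the cutoff.
slow_drift <- function(n, fs, cutoff = 0.2) {
  dec <- max(1L, floor(fs / (8 * cutoff)))
  nd <- ceiling(n / dec) + 2L
  d <- band_noise(nd, 0, cutoff, fs / dec)[1, ]
  tanh(stats::approx(seq_len(nd), d, xout = 1 + (seq_len(n) - 1) / dec,
                     rule = 2)$y)
}

# One band oscillation for all channels: a small set of shared
# amplitude-modulated oscillators (drifting instantaneous frequency inside
# the band), which each channel receives through its loading weights and
# channel-specific fixed phase lags, mixed with channel-specific band
# noise. Several generators (rather than one) give the cross-channel phase
# geometry enough dimensionality for thresholded connectivity graphs to
# contain triangles, as real scalp networks do.
synth_band_component <- function(n, fs, low, high, lags, loadings,
                                 noise_mix, shared_frac) {
  mid <- (low + high) / 2
  half <- (high - low) / 2
  nch <- nrow(loadings)
  n_gen <- ncol(loadings)
  # each generator reaches channel c as cos(phase - lag_c); expanding the
  # cosine turns the whole montage into two rank-1 updates per generator
  SIG <- matrix(0, nch, n)
  for (g in seq_len(n_gen)) {
    finst <- mid + 0.6 * half * slow_drift(n, fs)
    phase <- 2 * pi * cumsum(finst) / fs
    env <- pmax(1 + 0.3 * slow_drift(n, fs, cutoff = 0.5), 0.1)
    S <- env * cos(phase)
    C <- env * sin(phase)
    w <- sqrt(loadings[, g])
    SIG <- SIG + (w * cos(lags[, g])) %o% S + (w * sin(lags[, g])) %o% C
  }
  SIG <- SIG / sqrt(pmax(rowMeans(SIG^2) - rowMeans(SIG)^2, 1e-12))
  # channel-specific independent activity: a regular (band-centre) part
  # and an irregular (full-band) part from one noise field. The noise_mix
  # balance between them is the handle on signal complexity (permutation
  # entropy): it changes how disordered each channel's own activity is
  # without altering the shared fraction, so phase-lag connectivity is
  # left alone.
  halfw <- 0.04 * (high - low)
  nf <- band_noise_pair(n, low, high, mid - halfw, mid + halfw, fs, nch)
  wmix <- pmin(pmax(noise_mix, 0), 1)          # length nch, recycles by row
  IND <- (1 - wmix) * nf$narrow + wmix * nf$broad
  IND <- IND / sqrt(pmax(rowMeans(IND^2) - rowMeans(IND)^2, 1e-12))
  sqrt(shared_frac) * SIG + sqrt(1 - shared_frac) * IND
}

# Subject-stable generative traits: EEG signatures are idiosyncratic and
# epochs within a subject are correlated (the premise of LOSO validation),
# so band amplitudes, coupling strength, irregularity and the cross-channel
# lag pattern are drawn once per subject and reused for both conditions.
subject_traits <- function(config, nch, bands) {
  nb <- nrow(bands)
  n_gen <- config$n_generators
  list(amp_mult = exp(stats::rnorm(nb, 0, 0.20)),
       shared_frac = min(max(config$shared_frac +
                               stats::runif(1, -0.10, 0.10), 0.05), 0.95),
       noise_mix = min(max(config$base_noise_mix +
                             stats::rnorm(1, 0, 0.05), 0), 0.9),
       noise_mult = exp(stats::rnorm(1, 0, 0.15)),
       # per band: how strongly each channel loads on each generator
       # (Dirichlet-like), and each generator's fixed lag pattern; the
       # first generator keeps the anterior-posterior gradient in channel
       # order so an injected lead/lag direction is identifiable
       loadings = lapply(seq_len(nb), function(b) {
         L <- matrix(stats::rgamma(nch * n_gen, shape = 1), nch, n_gen)
         L / rowSums(L)
       }),
       lags = lapply(seq_len(nb), function(b) {
         vapply(seq_len(n_gen), function(g) {
           ord <- if (g == 1) seq_len(nch) else sample.int(nch)
           (ord - 1) * config$lag_gradient +
             stats::rnorm(nch, sd = config$lag_jitter)
         }, numeric(nch))
       }))
}

synth_recording <- function(config, montage, subject_id, group, condition,
                            traits, bands = default_bands()) {
  fs <- montage$sampling_rate
  labels <- montage$channel_labels
  nch <- length(labels)
  n_epochs <- config$epochs_per_condition[[condition]]
  n <- as.integer(n_epochs * 10 * fs)
  eff <- config$effect
  data <- matrix(0, nch, n)
  for (b in seq_len(nrow(bands))) {
    bname <- bands$name[b]
    amp <- config$band_powers[[bname]] * traits$amp_mult[b]
    lags <- traits$lags[[b]]
    mix <- rep(traits$noise_mix, nch)
    if (condition == "cpt" && bname == eff$target_band) {
      hit <- labels %in% eff$affected_channels
      mix[hit] <- mix[hit] + eff$complexity_shift
      lags[hit, ] <- lags[hit, ] + eff$phase_lag_shift
    }
    data <- data + amp * synth_band_component(
      n, fs, bands$low[b], bands$high[b], lags, traits$loadings[[b]],
      mix, traits$shared_frac)
  }
  data <- data + config$noise_amp * traits$noise_mult *
    shaped_noise(n, config$noise_exponent, nch = nch)
  eeg_recording(data, montage, subject_id, group, condition, mover = FALSE)
}

#' Generate a synthetic EEG cohort
#'
#' For every subject in each group one baseline and one CPT recording is
#' produced. Each recording is a sum over the four canonical bands of an
#' amplitude-modulated shared oscillator (drifting instantaneous frequency
#' inside the band, channel-specific fixed phase lags) mixed with
#' channel-specific band-limited noise, plus 1/f background noise. CPT
#' recordings apply the configured [effect_spec()]; a `movement_fraction`
#' subset of subjects receives broadband motor-artifact bursts at baseline
#' via [inject_motor_artifact()].
#'
#' @param config A [cohort_config()].
#' @param montage An [eeg_montage()].
#' @param groups Groups to generate (default both; the classification
#'   analyses run per group, so single-group cohorts are often enough).
#' @return List of `eeg_recording` objects
#'   (groups x n_subjects x 2 conditions).
#' @export
generate_cohort <- function(config, montage = eeg_montage(),
                            groups = c("healthy", "pain")) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- match.arg(groups, several.ok = TRUE)
  set.seed(config$seed)
  recs <- list()
  for (group in groups) {
    n_sub <- config$n_subjects_per_group
    n_movers <- round(config$movement_fraction * n_sub)
    movers <- sample(seq_len(n_sub), n_movers)
    for (s in seq_len(n_sub)) {
      sid <- sprintf("%s_%02d", substr(group, 1, 1), s)
      traits <- subject_traits(config, length(montage$channel_labels),
                               default_bands())
      base <- synth_recording(config, montage, sid, group, "baseline",
                              traits)
      if (s %in% movers) {
        base <- inject_motor_artifact(base, burst_rate = config$burst_rate,
                                      amplitude = config$burst_amplitude,
                                      seed = NULL)
      }
      cpt <- synth_recording(config, montage, sid, group, "cpt", traits)
      recs[[length(recs) + 1L]] <- base
      recs[[length(recs) + 1L]] <- cpt
    }
  }
  recs
}

#' Inject broadband motor-artifact bursts into a baseline recording
#'
#' Adds transient (~2 s) Hanning-enveloped bursts at random onsets,
#' mimicking the EEG signature of small voluntary movements (e.g. operating
#' a visual analogue scale) during the resting assessment. Each burst
#' combines a large slow (0.5-3.5 Hz) movement/electrode potential shared
#' with zero lag across the montage and a milder EMG-band (13-50 Hz)
#' component that is mostly independent across channels. Returns a new
#' recording flagged `mover = TRUE`; the input is unchanged.
#'
#' @param rec A baseline `eeg_recording`.
#' @param burst_rate Expected bursts per minute (>= 0; the default 25 with
#'   2-s bursts gives the near-continuous contamination of a subject
#'   fiddling with a slider).
#' @param amplitude Slow-component burst amplitude in microvolts (>= 0;
#'   movement artifacts dwarf the ongoing EEG). The EMG component is scaled
#'   at 0.4 x this.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used inside [generate_cohort()]).
#' @return A new `eeg_recording` with `mover = TRUE`.
#' @export
inject_motor_artifact <- function(rec, burst_rate = 25, amplitude = 60,
                                  seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$condition != "baseline") {
    stop("motor artifacts are injected into baseline recordings only")
  }
  if (burst_rate < 0 || amplitude < 0) {
    stop("burst_rate and amplitude must be non-negative")
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- rec$montage$sampling_rate
  n <- ncol(rec$data)
  nch <- nrow(rec$data)
  data <- rec$data
  n_bursts <- stats::rpois(1, burst_rate * n / fs / 60)
  if (amplitude > 0 && n_bursts > 0) {
    blen <- round(2.0 * fs)
    env <- 0.5 - 0.5 * cos(2 * pi * seq_len(blen) / (blen + 1))
    onsets <- sort(sample(seq_len(max(n - blen - 4, 1)), n_bursts,
                          replace = TRUE))
    for (on in onsets) {
      gains <- stats::runif(nch, 0.5, 1.5)
      # two artifact components, as in real movement-contaminated EEG:
      # (1) a slow (0.5-3.5 Hz) movement/electrode potential, shared with
      # zero lag across the montage (scaled copies carry no lagged phase
      # information, so spectral power inflates while phase-lag
      # connectivity is untouched); (2) a milder EMG component
      # (13-50 Hz), mostly independent across channels, which dilutes
      # genuine beta-band phase coupling
      slow <- band_noise(blen, 0.5, 3.5, fs)[1, ]
      emg_shared <- band_noise(blen, 13, 50, fs)[1, ]
      emg_indep <- band_noise(blen, 13, 50, fs, nch = nch)
      idx <- on:(on + blen - 1)
      for (c in seq_len(nch)) {
        data[c, idx] <- data[c, idx] + amplitude * gains[c] * env *
          (slow + 0.4 * (0.3 * emg_shared + 0.7 * emg_indep[c, ]))
      }
    }
  }
  out <- rec
  out$data <- data
  out$mover <- TRUE
  out
}
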