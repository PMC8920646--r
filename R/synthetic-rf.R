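# Synthetic RF and envelope generators with known ground truth. The physics
# is deliberately minimal: a Gaussian-modulated cosine pulse convolved with a
# sparse random scatterer train per line, an optional constant-phase periodic
# component controlling the coherent-to-diffuse ratio, and linear
# frequency-dependent attenuation applied in the frequency domain in depth
# blocks. No diffraction or beamforming is modeled.

#' Draw Nakagami-distributed envelope amplitudes
#'
#' Amplitudes are square roots of gamma variates with shape `m` and mean
#' `omega`, so that `E[R^2] = omega` and the intensity moment ratio
#' `omega^2 / var(R^2) = m`.
#'
#' @param m shape parameter (> 0); m = 1 gives a Rayleigh envelope
#' @param omega scale, the mean squared amplitude (> 0)
#' @param n number of samples (>= 1)
#' @param seed optional integer seed; fixed seed gives identical draws
#' @return numeric vector of nonnegative amplitudes
#' @export
sample_nakagami_envelope <- function(m, omega, n, seed = NULL) {
  if (!is.numeric(m) || m <= 0) stopf("`m` must be positive")
  if (!is.numeric(omega) || omega <= 0) stopf("`omega` must be positive")
  if (!is.numeric(n) || n < 1) stopf("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sqrt(stats::rgamma(n, shape = m, scale = omega / m))
}

#' Draw homodyned-K distributed envelope amplitudes
#'
#' Uses the compound representation: conditional on a gamma-distributed
#' diffuse energy `g^2` (shape `mu`, mean `sigma2`), the amplitude is Rician,
#' `A = |s + g (z1 + i z2) / sqrt(2)|` with `s = k * sqrt(sigma2)` a fixed
#' coherent component and `z1, z2` standard normal. `k = s / sigma` is the
#' coherent-to-diffuse ratio, `mu` the effective number of scatterers per
#' resolution cell. `k = 0, mu -> Inf` recovers the Rayleigh envelope;
#' `k = 0` at finite `mu` gives the K distribution.
#'
#' @param k coherent-to-diffuse signal ratio (>= 0)
#' @param mu effective scatterer number (> 0)
#' @param sigma2 diffuse signal energy (> 0, default 1)
#' @param n number of samples
#' @param seed optional integer seed
#' @return numeric vector of amplitudes
#' @export
sample_homodyned_k <- function(k, mu, sigma2 = 1, n, seed = NULL) {
  if (!is.numeric(k) || k < 0) stopf("`k` must be >= 0")
  if (!is.numeric(mu) || mu <= 0) stopf("`mu` must be positive")
  if (!is.numeric(sigma2) || sigma2 <= 0) stopf("`sigma2` must be positive")
  if (!is.numeric(n) || n < 1) stopf("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g2 <- stats::rgamma(n, shape = mu, scale = sigma2 / mu)
  s <- k * sqrt(sigma2)
  re <- s + sqrt(g2 / 2) * stats::rnorm(n)
  im <- sqrt(g2 / 2) * stats::rnorm(n)
  sqrt(re^2 + im^2)
}

#' Simulation configuration for synthetic RF frames
#'
#' @param n_lines,n_samples frame geometry (scan lines, axial samples)
#' @param sampling_frequency,pulse_center_frequency Hz
#' @param pulse_fractional_bandwidth -6 dB fractional bandwidth of the
#'   Gaussian pulse spectrum (default 0.5)
#' @param scatterers_per_cell mean diffuse scatterer count per axial
#'   resolution cell (drives the envelope's mu and m); Poisson-distributed
#'   per cell, so the target is effective, not exact
#' @param coherent_amplitude_ratio target coherent-to-diffuse ratio k of a
#'   periodic constant-amplitude scatterer component (>= 0)
#' @param attenuation linear frequency-dependent attenuation in dB/MHz-cm
#'   (>= 0), applied with the round-trip factor 2 in the exponent
#' @param sound_speed m/s
#' @param tumor optional list overriding `scatterers_per_cell` and
#'   `coherent_amplitude_ratio` inside an elliptical lesion region
#' @param seed integer; a fixed seed yields bit-identical frames
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_lines = 64, n_samples = 2048,
                       sampling_frequency = 40e6,
                       pulse_center_frequency = 10e6,
                       pulse_fractional_bandwidth = 0.5,
                       scatterers_per_cell = 10,
                       coherent_amplitude_ratio = 0,
                       attenuation = 0,
                       sound_speed = 1540,
                       tumor = NULL,
                       seed = 1L) {
  stopifnot(n_lines >= 1, n_samples >= 16,
            sampling_frequency > 0, pulse_center_frequency > 0,
            pulse_fractional_bandwidth > 0,
            scatterers_per_cell > 0,
            coherent_amplitude_ratio >= 0, attenuation >= 0,
            sound_speed > 0)
  structure(list(n_lines = as.integer(n_lines),
                 n_samples = as.integer(n_samples),
                 sampling_frequency = sampling_frequency,
                 pulse_center_frequency = pulse_center_frequency,
                 pulse_fractional_bandwidth = pulse_fractional_bandwidth,
                 scatterers_per_cell = scatterers_per_cell,
                 coherent_amplitude_ratio = coherent_amplitude_ratio,
                 attenuation = attenuation,
                 sound_speed = sound_speed,
                 tumor = tumor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Gaussian-modulated cosine pulse and its -6 dB envelope length in samples.
# sigma_t chosen so the -6 dB (half-amplitude) full spectral width equals
# bw * fc: |S(f)| = exp(-2 pi^2 sigma_t^2 (f - fc)^2).
gaussian_pulse <- function(fs, fc, bw) {
  sigma_t <- sqrt(2 * log(2)) / (pi * bw * fc)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  p <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * fc * t)
  cell_len <- max(2L, ceiling(2 * sigma_t * sqrt(2 * log(2)) * fs))
  list(p = p, half = half, sigma_t = sigma_t, cell_len = cell_len)
}

#' Simulate one RF frame with an elliptical lesion
#'
#' Per scan line, a sparse reflectivity train is drawn (Poisson scatterer
#' counts per sample at the density implied by `scatterers_per_cell`, normal
#' amplitudes), an optional constant-amplitude periodic component is added at
#' one spike per resolution cell with amplitude
#' `k * sqrt(scatterers_per_cell)` (which sets the coherent-to-diffuse energy
#' ratio to ~`k^2`), attenuation is applied in the frequency domain per depth
#' block as an amplitude gain `10^(-2 * a * d * f / 20)` (`d` one-way depth in
#' cm, `f` in MHz), and the result is convolved with the Gaussian pulse.
#' The lesion is an axis-aligned ellipse covering the middle of the frame;
#' scatterer statistics inside may differ via `config$tumor`.
#'
#' @param config a [sim_config]
#' @return list with `frame` ([rf_frame]), `mask` ([roi_mask], intratumoral,
#'   on the RF sample grid), and `truth` (all generating parameters, incl.
#'   the resolution-cell length in samples)
#' @export
simulate_rf_frame <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_frequency
  pl <- gaussian_pulse(fs, config$pulse_center_frequency,
                       config$pulse_fractional_bandwidth)
  n <- config$n_samples
  nl <- config$n_lines
  cell <- pl$cell_len

  # elliptical tumor mask on the RF grid
  rows <- matrix(seq_len(n), n, nl)
  cols <- matrix(seq_len(nl), n, nl, byrow = TRUE)
  mask <- ((rows - n / 2) / (n / 3.2))^2 + ((cols - nl / 2) / (nl / 2.8))^2 <= 1

  dens_bg <- config$scatterers_per_cell / cell
  co_bg <- config$coherent_amplitude_ratio
  dens_tum <- (config$tumor$scatterers_per_cell %||% config$scatterers_per_cell) / cell
  co_tum <- config$tumor$coherent_amplitude_ratio %||% config$coherent_amplitude_ratio

  nfft <- 2^ceiling(log2(n + length(pl$p)))
  Pf <- stats::fft(c(pl$p, numeric(nfft - length(pl$p))))
  fgrid <- c(0:(nfft / 2), -(nfft / 2 - 1):-1) * fs / nfft  # Hz, signed
  absf_mhz <- abs(fgrid) / 1e6
  dz_cm <- config$sound_speed / (2 * fs) * 100
  block <- cell                              # depth-block size in samples
  starts <- seq(1L, n, by = block)
  a_ln <- config$attenuation * log(10) / 20  # dB -> natural-log amplitude

  rf <- matrix(0, n, nl)
  spikes <- seq(1L, n, by = cell)            # periodic coherent positions
  for (j in seq_len(nl)) {
    dens <- ifelse(mask[, j], dens_tum, dens_bg)
    counts <- stats::rpois(n, dens)
    train <- stats::rnorm(n) * sqrt(counts)
    co <- ifelse(mask[spikes, j], co_tum, co_bg)
    mu_loc <- ifelse(mask[spikes, j], dens_tum, dens_bg) * cell
    train[spikes] <- train[spikes] + co * sqrt(mu_loc)
    if (config$attenuation > 0) {
      Y <- complex(real = numeric(nfft))
      for (s0 in starts) {
        idx <- s0:min(s0 + block - 1L, n)
        seg <- numeric(nfft)
        seg[idx] <- train[idx]
        d_cm <- (mean(idx) - 1) * dz_cm
        Y <- Y + stats::fft(seg) * exp(-2 * a_ln * d_cm * absf_mhz)
      }
    } else {
      Y <- stats::fft(c(train, numeric(nfft - n)))
    }
    full <- Re(stats::fft(Y * Pf, inverse = TRUE)) / nfft
    rf[, j] <- full[(pl$half + 1L):(pl$half + n)]
  }

  frame <- rf_frame(rf, fs, config$pulse_center_frequency,
                    sound_speed = config$sound_speed,
                    lesion_id = sprintf("sim_seed%d", config$seed))
  truth <- c(unclass(config),
             list(cell_len_samples = cell,
                  pulse_sigma_t = pl$sigma_t,
                  tumor_fraction = mean(mask)))
  list(frame = frame, mask = roi_mask(mask, "intratumoral"), truth = truth)
}

# Table of class-conditional feature means/sds observed on a balanced
# clinical breast-RF cohort; used as the default separation for simulated
# feature tables.
default_feature_spec <- function() {
  canon <- qus_feature_names()
  benign_mean <- c(88.25, 4.61, 95.19, 14.98, -4.54, 2.09,
                   0.73, 0.18, 0.58, 0.54, 408736.82, 219.74,
                   2.51, 0.59, 0.135, 0.67)
  benign_sd <- c(6.84, 0.86, 4.25, 0.78, 0.84, 0.12,
                 0.08, 0.10, 0.03, 0.06, 134753.77, 55.23,
                 1.11, 0.06, 0.09, 0.07)
  malignant_mean <- c(92.06, 5.08, 91.8, 15.32, -4.52, 2.12,
                      0.84, 0.28, 0.55, 0.67, 189811.2, 119.24,
                      2.01, 0.61, 0.18, 0.7)
  malignant_sd <- c(9.25, 1.19, 6.56, 0.76, 1.01, 0.08,
                    0.23, 0.26, 0.08, 0.17, 166031.05, 98.33,
                    1.02, 0.07, 0.10, 0.08)
  list(benign = list(mean = stats::setNames(benign_mean, canon),
                     sd = stats::setNames(benign_sd, canon)),
       malignant = list(mean = stats::setNames(malignant_mean, canon),
                        sd = stats::setNames(malignant_sd, canon)))
}

# clip features to their valid ranges after normal sampling
clip_features <- function(df) {
  eps <- 1e-6
  pos <- c("mbf_sd", "int_sd", "sl_sd", "hk_k", "glcm_contrast")
  for (col in pos) df[[col]] <- pmax(df[[col]], 0)
  for (col in c("hk_mu", "nak_omega", "nak_alpha")) df[[col]] <- pmax(df[[col]], eps)
  df$nak_m <- pmax(df$nak_m, eps)
  for (col in c("glcm_energy", "glcm_homogeneity")) df[[col]] <- pmin(pmax(df[[col]], eps), 1)
  df$hk_h <- pmin(pmax(df$hk_h, eps), 1)
  df$glcm_correlation <- pmin(pmax(df$glcm_correlation, -1), 1)
  df
}

#' Simulate a two-class QUS feature table
#'
#' Draws independent normal feature values per class around configurable
#' class means/sds (defaults reproduce the separation reported for a balanced
#' clinical breast cohort), then clips each feature to its valid range
#' (energy/homogeneity in (0,1], h in (0,1], positive scales, correlation in
#' \[-1,1\]). The counts control the imbalance ratio; 104 benign / 26
#' malignant reproduces the 4:1 clinical imbalance scenario.
#'
#' @param n_benign,n_malignant class sizes (>= 1)
#' @param class_means,class_sds optional lists with `benign`/`malignant`
#'   16-vectors named by [qus_feature_names()]
#' @param seed integer seed
#' @return a `qus_feature_table` with provenance `"original"`
#' @export
simulate_feature_table <- function(n_benign, n_malignant,
                                   class_means = NULL, class_sds = NULL,
                                   seed = 1L) {
  stopifnot(n_benign >= 1, n_malignant >= 1)
  spec <- default_feature_spec()
  canon <- qus_feature_names()
  means <- list(benign = class_means$benign %||% spec$benign$mean,
                malignant = class_means$malignant %||% spec$malignant$mean)
  sds <- list(benign = class_sds$benign %||% spec$benign$sd,
              malignant = class_sds$malignant %||% spec$malignant$sd)
  for (cl in c("benign", "malignant")) {
    if (length(means[[cl]]) != 16L || length(sds[[cl]]) != 16L)
      stopf("class_means/class_sds for '%s' must have 16 entries", cl)
  }
  set.seed(seed)
  draw <- function(n, cl) {
    m <- matrix(stats::rnorm(n * 16, mean = rep(means[[cl]], each = n),
                             sd = rep(sds[[cl]], each = n)), n, 16)
    colnames(m) <- canon
    clip_features(as.data.frame(m))
  }
  xb <- draw(n_benign, "benign")
  xm <- draw(n_malignant, "malignant")
  feature_table(rbind(xb, xm),
                c(rep("benign", n_benign), rep("malignant", n_malignant)),
                provenance = "original")
}
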