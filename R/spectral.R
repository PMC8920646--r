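# Spectral parameterization: sliding-window power spectra, linear fits over
# the usable band (slope / intercept / midband fit), attenuation correction,
# parametric images, and intratumoral statistics.

#' Spectral analysis configuration
#'
#' @param window_length_mm axial Hamming window length in mm (default 2.4)
#' @param overlap_fraction window overlap in \[0, 1) (default 0.875)
#' @param band_drop dB below the spectral peak defining the usable band
#'   (default 6)
#' @param attenuation_coefficient effective attenuation in dB/MHz-cm used by
#'   the correction (default 1.0, a muscle-like value)
#' @param correction_sign `"compensate"` adds the 2*alpha*d term back to the
#'   measured slope (physical compensation, the default); `"paper_literal"`
#'   subtracts it, replicating the printed form of the correction
#' @param db_floor floor in dB substituted for log of zero power
#' @return object of class `spectral_config`
#' @export
spectral_config <- function(window_length_mm = 2.4,
                            overlap_fraction = 0.875,
                            band_drop = 6,
                            attenuation_coefficient = 1.0,
                            correction_sign = c("compensate", "paper_literal"),
                            db_floor = -200) {
  correction_sign <- match.arg(correction_sign)
  stopifnot(window_length_mm > 0,
            overlap_fraction >= 0, overlap_fraction < 1,
            band_drop >= 0, attenuation_coefficient >= 0)
  structure(list(window_length_mm = window_length_mm,
                 overlap_fraction = overlap_fraction,
                 band_drop = band_drop,
                 attenuation_coefficient = attenuation_coefficient,
                 correction_sign = correction_sign,
                 db_floor = db_floor),
            class = "spectral_config")
}

#' One-sided Hamming-tapered power spectrum of an RF segment
#'
#' The one-sided periodogram convention is used (non-DC, non-Nyquist bins
#' doubled, scaled by 1/N) so the linear-power bins sum to the tapered
#' segment's energy (Parseval). Power is returned in dB.
#'
#' @param segment RF sample vector, one window long
#' @param sampling_frequency Hz
#' @param db_floor dB value substituted where power is zero; if triggered,
#'   the result carries attribute `flagged = TRUE`
#' @return list with `frequency` (MHz, 0..fs/2), `power_db`, and
#'   `power_linear`
#' @export
windowed_power_spectrum <- function(segment, sampling_frequency,
                                    db_floor = -200) {
  n <- length(segment)
  if (n < 8L) stopf("window of %d samples is too short", n)
  w <- as.numeric(signal::hamming(n))
  y <- segment * w
  sp <- Mod(stats::fft(y))^2 / n
  half <- floor(n / 2) + 1L
  one <- sp[seq_len(half)]
  dbl <- rep(2, half)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[half] <- 1
  one <- one * dbl
  freq <- (seq_len(half) - 1L) * sampling_frequency / n / 1e6
  flagged <- any(one <= 0)
  db <- ifelse(one > 0, 10 * log10(one), db_floor)
  structure(list(frequency = freq, power_db = db, power_linear = one),
            flagged = flagged)
}

#' Find the usable band around the spectral peak
#'
#' The band is the contiguous frequency interval around the global spectral
#' peak (ties broken toward the lowest frequency) where power stays within
#' `band_drop` dB of the peak. A band clipped at the grid edge is flagged.
#'
#' @param frequency MHz grid
#' @param power_db spectrum in dB
#' @param band_drop dB drop defining the band (default 6)
#' @return numeric `c(f_low, f_high)` with attributes `bins` (indices) and
#'   `clipped`
#' @export
determine_band <- function(frequency, power_db, band_drop = 6) {
  stopifnot(length(frequency) == length(power_db))
  pk <- which.max(power_db)            # first max = lowest-frequency tie
  thr <- power_db[pk] - band_drop
  lo <- pk
  while (lo > 1L && power_db[lo - 1L] >= thr) lo <- lo - 1L
  hi <- pk
  n <- length(power_db)
  while (hi < n && power_db[hi + 1L] >= thr) hi <- hi + 1L
  if (hi - lo + 1L < 3L)
    stopf("usable band spans only %d bin(s); use a longer window or larger band_drop",
          hi - lo + 1L)
  structure(c(frequency[lo], frequency[hi]),
            bins = lo:hi, clipped = (lo == 1L || hi == n))
}

#' Fit the spectral regression line over a band
#'
#' Ordinary least squares of dB power on frequency within `band`. The slope
#' `s` is in dB/MHz, the intercept `I` is the fitted value at zero frequency,
#' and the midband fit is `M = I + s * f0` with `f0` the band center.
#'
#' @param frequency MHz grid
#' @param power_db spectrum in dB
#' @param band `c(f_low, f_high)` in MHz, inside the grid, covering >= 3 bins
#' @param depth one-way depth of the window center in cm (carried for the
#'   attenuation correction; default 0)
#' @return object of class `spectral_fit` with fields `slope`, `intercept`,
#'   `midband`, `f0`, `depth`
#' @export
fit_spectral_line <- function(frequency, power_db, band, depth = 0) {
  if (band[1] < min(frequency) - 1e-9 || band[2] > max(frequency) + 1e-9)
    stopf("band [%g, %g] MHz lies outside the frequency grid", band[1], band[2])
  idx <- which(frequency >= band[1] - 1e-12 & frequency <= band[2] + 1e-12)
  if (length(idx) < 3L) stopf("band must contain at least 3 frequency bins")
  f <- frequency[idx]
  p <- power_db[idx]
  fm <- mean(f)
  s <- sum((f - fm) * (p - mean(p))) / sum((f - fm)^2)
  I <- mean(p) - s * fm
  f0 <- mean(band)
  structure(list(slope = s, intercept = I, midband = I + s * f0,
                 f0 = f0, depth = depth),
            class = "spectral_fit")
}

#' Correct a spectral fit for frequency-dependent attenuation
#'
#' Attenuation in dB is assumed linear in frequency with coefficient `alpha`
#' (dB/MHz-cm); the intercept is invariant under such attenuation, while the
#' slope acquires the term `c = 2 * alpha * d` over a one-way depth `d` (cm,
#' taken from `fit$depth`). `"compensate"` restores the unattenuated slope
#' (`s' = s + c`); `"paper_literal"` applies the printed form (`s' = s - c`).
#' The midband fit is recomputed from the corrected slope.
#'
#' @param fit a [fit_spectral_line] result carrying its depth
#' @param alpha attenuation coefficient in dB/MHz-cm (>= 0)
#' @param sign correction mode
#' @return a corrected `spectral_fit`
#' @export
correct_attenuation <- function(fit, alpha,
                                sign = c("compensate", "paper_literal")) {
  sign <- match.arg(sign)
  stopifnot(inherits(fit, "spectral_fit"), alpha >= 0, fit$depth >= 0)
  cc <- 2 * alpha * fit$depth
  s2 <- if (sign == "compensate") fit$slope + cc else fit$slope - cc
  structure(list(slope = s2, intercept = fit$intercept,
                 midband = fit$intercept + s2 * fit$f0,
                 f0 = fit$f0, depth = fit$depth),
            class = "spectral_fit")
}

#' Build MBF / INT / SL parametric images from an RF frame
#'
#' A Hamming window of `window_length_mm` (converted to samples via the
#' axial spacing `c / (2 fs)`) slides down each line with the configured
#' overlap. The usable band is fixed once per frame from the average linear
#' power spectrum over all windows and lines, so the band center `f0` is a
#' frame constant. Per window the spectral line is fitted and corrected for
#' attenuation at the window-center depth (one-way, measured from the first
#' axial sample, in cm).
#'
#' @param frame an [rf_frame]
#' @param config a [spectral_config]
#' @return object of class `parametric_images` with matrices `mbf`, `int`,
#'   `sl` (window position x scan line), `window_centers` (axial sample
#'   index of each window center), `depths_cm`, `band`, and the config
#' @export
build_parametric_images <- function(frame, config = spectral_config()) {
  stopifnot(inherits(frame, "rf_frame"), inherits(config, "spectral_config"))
  fs <- frame$sampling_frequency
  dz <- frame$sound_speed / (2 * fs)              # axial sample spacing, m
  nw <- round(config$window_length_mm * 1e-3 / dz)
  if (nw < 8L) stopf("window length converts to %d samples (< 8)", nw)
  n <- nrow(frame$samples)
  nl <- ncol(frame$samples)
  if (n < nw) stopf("frame (%d samples) is shorter than one window (%d)", n, nw)
  hop <- max(1L, round(nw * (1 - config$overlap_fraction)))
  starts <- seq(1L, n - nw + 1L, by = hop)
  centers <- starts + (nw - 1) / 2
  depths <- (centers - 1) * dz * 100              # one-way depth, cm
  w <- as.numeric(signal::hamming(nw))
  half <- floor(nw / 2) + 1L
  dbl <- rep(2, half); dbl[1L] <- 1
  if (nw %% 2L == 0L) dbl[half] <- 1
  freq <- (seq_len(half) - 1L) * fs / nw / 1e6

  # linear one-sided power spectra for every (window, line), kept as a
  # half x (nwin*nl) matrix; mvfft over windows of a line at a time
  nwin <- length(starts)
  pow <- matrix(0, half, nwin * nl)
  for (j in seq_len(nl)) {
    segs <- vapply(starts, function(s0) frame$samples[s0:(s0 + nw - 1L), j] * w,
                   numeric(nw))
    sp <- Mod(stats::mvfft(segs))^2 / nw
    pow[, ((j - 1L) * nwin + 1L):(j * nwin)] <- sp[seq_len(half), , drop = FALSE] * dbl
  }

  avg_db <- 10 * log10(pmax(rowMeans(pow), 10^(config$db_floor / 10)))
  band <- determine_band(freq, avg_db, config$band_drop)
  bidx <- attr(band, "bins")
  f0 <- mean(band)

  fb <- freq[bidx]
  fbm <- mean(fb)
  fc <- fb - fbm
  denom <- sum(fc^2)
  P <- 10 * log10(pmax(pow[bidx, , drop = FALSE], 10^(config$db_floor / 10)))
  slope <- as.numeric(crossprod(fc, P)) / denom
  intercept <- colMeans(P) - slope * fbm
  # attenuation correction per window depth; intercept is invariant
  csign <- if (config$correction_sign == "compensate") 1 else -1
  corr <- csign * 2 * config$attenuation_coefficient * rep(depths, times = nl)
  slope_c <- slope + corr
  mbf <- intercept + slope_c * f0

  shape <- function(v) matrix(v, nwin, nl)
  structure(list(mbf = shape(mbf), int = shape(intercept), sl = shape(slope_c),
                 sl_uncorrected = shape(slope),
                 window_centers = centers, depths_cm = depths,
                 band = as.numeric(band), f0 = f0, config = config),
            class = "parametric_images")
}

#' Map an RF-grid ROI mask onto the parametric-image window grid
#'
#' A window-grid pixel (window position, line) is inside the ROI when the RF
#' mask is true at the RF sample nearest the window center on that line
#' (nearest-window rule).
#'
#' @param mask an [roi_mask] on the RF sample grid
#' @param images a [build_parametric_images] result
#' @return an [roi_mask] congruent with the parametric images
#' @export
map_mask_to_windows <- function(mask, images) {
  stopifnot(inherits(mask, "roi_mask"), inherits(images, "parametric_images"))
  centers <- pmin(pmax(round(images$window_centers), 1L), nrow(mask$mask))
  roi_mask(mask$mask[centers, , drop = FALSE], mask$kind)
}

#' Mean and standard deviation of image pixels inside an ROI
#'
#' Descriptive statistics (sd with the n-1 denominator) over the masked
#' pixels. A single-pixel ROI returns sd = 0 with a warning.
#'
#' @param image numeric matrix
#' @param mask an [roi_mask] congruent with `image`
#' @return named numeric `c(mean, sd)`
#' @export
roi_statistics <- function(image, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(image), dim(mask$mask)))
    stopf("image shape %s does not match mask shape %s",
          paste(dim(image), collapse = "x"), paste(dim(mask$mask), collapse = "x"))
  v <- image[mask$mask]
  if (length(v) == 0L) stopf("empty ROI")
  if (length(v) == 1L) {
    warnf("single-pixel ROI: standard deviation defined as 0")
    return(c(mean = v, sd = 0))
  }
  c(mean = mean(v), sd = stats::sd(v))
}
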