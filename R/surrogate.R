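#' Self-navigated respiratory surrogate from k-space centre samples
#'
#' Extracts the per-spoke k-space origin moduli for every coil, low-pass
#' filters each channel with a zero-phase Kaiser-window FIR, performs PCA
#' across the channels, and returns the standardized principal component
#' whose power spectral density integrated over the respiratory band is
#' largest.  The sign is fixed so the surrogate correlates positively
#' with the first (filtered) channel.
#'
#' @param ks a `kspace_series` (every spoke carries a `k = 0` sample).
#' @param band_hz respiratory frequency band for component selection.
#' @param cutoff_hz FIR low-pass cutoff.
#' @param atten_db stop-band attenuation for the Kaiser design.
#' @param trans_hz transition width.
#' @return An object of class `surrogate_signal`: `values` (zero mean,
#'   unit variance, one per spoke), `sample_dt_ms`, `n_samples`.
#' @export
extract_surrogate <- function(ks, band_hz = c(0.1, 0.5), cutoff_hz = 1.0,
                              atten_db = 60, trans_hz = 0.5) {
  stopifnot(inherits(ks, "kspace_series"))
  k0 <- which.min(abs(ks$radii))
  if (abs(ks$radii[k0]) > 1e-9)
    stop("spokes do not contain a k = 0 sample")
  # channels: the k-space origin sample of every spoke, per coil.  The
  # real and imaginary parts form separate channels: with few (or a
  # single uniform) coil(s) the modulus alone discards the
  # phase-encoded component of the respiratory modulation.
  nav <- ks$samples[k0, , , , drop = FALSE]          # [1, spf, ncoil, nt]
  ns <- ks$spokes_per_frame * ks$n_t
  ch <- matrix(0, ns, 2L * ks$n_coils)
  for (c in seq_len(ks$n_coils)) {
    ch[, 2L * c - 1L] <- as.vector(Re(nav[1, , c, ]))
    ch[, 2L * c] <- as.vector(Im(nav[1, , c, ]))
  }
  fs <- 1000 / ks$TR_ms

  filt <- kaiser_lowpass(ns, fs, cutoff_hz, atten_db, trans_hz)
  for (c in seq_len(ncol(ch))) ch[, c] <- filt(ch[, c])

  pc <- stats::prcomp(ch, center = TRUE, scale. = FALSE)
  scores <- pc$x
  bp <- apply(scores, 2L, band_power, fs = fs, band_hz = band_hz)
  sel <- which.max(bp)
  s <- scores[, sel]
  if (sd(s) == 0) stop("surrogate has no variance")
  if (cor(s, ch[, 1]) < 0) s <- -s
  s <- (s - mean(s)) / sd(s)
  structure(list(values = s, sample_dt_ms = ks$TR_ms, n_samples = ns,
                 band_hz = band_hz, fs_hz = fs, selected_component = sel),
            class = "surrogate_signal")
}

# zero-phase Kaiser-window FIR low-pass; returns a filtering closure.
# The design length follows the Kaiser formulas for the requested
# attenuation/transition width, shortened if the series is short.  The
# symmetric (linear-phase) FIR is applied by FFT convolution with
# mirror padding and exact group-delay compensation, which is zero-phase
# in one pass.
kaiser_lowpass <- function(n, fs, cutoff_hz, atten_db, trans_hz) {
  if (cutoff_hz >= fs / 2) return(identity)
  beta <- if (atten_db > 50) 0.1102 * (atten_db - 8.7)
          else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
          else 0
  ntaps <- ceiling((atten_db - 7.95) / (2.285 * 2 * pi * trans_hz / fs))
  ntaps <- min(ntaps, max(9, 2 * floor(n / 8) + 1))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  if (n <= 3 * (ntaps - 1))
    stop("series shorter than the low-pass filter length")
  h <- signal::fir1(ntaps - 1, cutoff_hz / (fs / 2), type = "low",
                    window = signal::kaiser(ntaps, beta))
  h <- as.numeric(h) / sum(h)          # exact unit DC gain
  half <- (ntaps - 1) / 2
  function(x) {
    xp <- c(rev(x[2:(half + 1)]), x, rev(x[(n - half):(n - 1)]))
    y <- stats::convolve(xp, rev(h), type = "filter")
    as.numeric(y)
  }
}

# integrated periodogram power within a frequency band
band_power <- function(x, fs, band_hz) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x))[seq_len(floor(n / 2))])^2
  fr <- (seq_len(floor(n / 2)) - 1) * fs / n
  sum(sp[fr >= band_hz[1] & fr <= band_hz[2]])
}

#' Amplitude binning of the respiratory surrogate
#'
#' Sorts spokes into `n_bins` equal-count amplitude bins (quantile
#' binning).  The end-of-exhale bin is the extremal bin on the side with
#' the larger dwell: breathing lingers at the exhale plateau, so the
#' exhale-side extreme decile is densely clustered in amplitude while
#' the inhale side stretches over the deep troughs; ties default to the
#' upper extremum of the standardized surrogate.
#'
#' @param surrogate a [extract_surrogate()] result (or any numeric
#'   vector wrapped in one).
#' @param n_bins number of respiratory bins (default 10).
#' @return An object of class `bin_assignment`: integer `bin_of_spoke`
#'   in `1..n_bins` (bin 1 = lowest amplitude), `exhale_bin`, `n_bins`.
#' @export
sort_bins <- function(surrogate, n_bins = 10) {
  stopifnot(n_bins >= 2)
  v <- if (inherits(surrogate, "surrogate_signal")) surrogate$values
       else as.numeric(surrogate)
  if (max(v) - min(v) < 1e-12)
    stop("constant surrogate: no respiratory structure to bin")
  n <- length(v)
  r <- rank(v, ties.method = "first")
  bins <- as.integer(ceiling(r * n_bins / n))
  # dwell detection: breathing lingers at the exhale plateau, so the
  # extreme decile on the exhale side is densely clustered (narrow in
  # amplitude) while the inhale side stretches over the deep troughs.
  # Ties (symmetric waveforms) default to the upper extremum.
  qs <- quantile(v, c(0.1, 0.9))
  top_width <- max(v) - qs[2]
  bottom_width <- qs[1] - min(v)
  exhale_bin <- if (top_width <= 1.1 * bottom_width) n_bins else 1L
  structure(list(bin_of_spoke = bins, n_bins = as.integer(n_bins),
                 exhale_bin = as.integer(exhale_bin)),
            class = "bin_assignment")
}
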