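# Spectral outcome measures: Welch spectra of the binned population rate and
# the beta/gamma band-power ratio used to score every phase-sweep run.

welch_spectrum <- function(x, fs, segment = fs, overlap = 0.5) {
  n <- length(x)
  x <- x - mean(x)
  step <- max(1, round(segment * (1 - overlap)))
  starts <- seq(1, n - segment + 1, by = step)
  if (!length(starts)) stop("signal shorter than one segment")
  nf <- floor(segment / 2)
  acc <- numeric(nf + 1)
  msq <- 0
  for (s in starts) {
    seg <- x[s:(s + segment - 1)]
    seg <- seg - mean(seg)
    msq <- msq + mean(seg^2)
    X <- fft(seg)
    p <- Mod(X[1:(nf + 1)])^2 / (fs * segment)
    # one-sided: double everything except DC (and Nyquist when even)
    dbl <- rep(2, nf + 1); dbl[1] <- 1
    if (segment %% 2 == 0) dbl[nf + 1] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (0:nf) * fs / segment, power = acc / length(starts),
       n_segments = length(starts), df = fs / segment,
       var_segments = msq / length(starts))
}

band_power <- function(freq, power, band, df) {
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) stop("band outside the frequency grid")
  sum(power[sel]) * df
}

#' Power spectrum of a population's firing rate
#'
#' Bins spikes into a population rate (default 1 ms bins), removes the mean
#' and averages periodograms over 1 s segments with 50% overlap (Welch,
#' rectangular window, each segment demeaned).  Also reports the power in
#' the stimulation-sensitive beta band and the stimulation-insensitive
#' gamma reference band, and their ratio -- the outcome measure of all
#' phase-sweep experiments.
#'
#' @param spikes a `spike_record`.
#' @param population population to analyze (default: the record's
#'   oscillating population).
#' @param t_start analysis start (ms), discarding the initial transient.
#' @param t_end analysis end (ms; default: end of the record).
#' @param bin_ms rate bin (ms).
#' @param segment_s Welch segment length (s).
#' @param overlap segment overlap fraction.
#' @param beta_band,gamma_band frequency bands (Hz).
#' @return A `spectral_summary` list: `freq`, `power`, `beta_power`,
#'   `gamma_power`, `beta_gamma_ratio`, `peak_freq` (in 20-60 Hz),
#'   `n_segments`.
#' @export
population_spectrum <- function(spikes, population = NULL, t_start = 500,
                                t_end = NULL, bin_ms = 1, segment_s = 1,
                                overlap = 0.5, beta_band = c(31, 36),
                                gamma_band = c(60, 64)) {
  t_end <- t_end %||% attr(spikes, "duration") %||% max(spikes$t)
  if ((t_end - t_start) < 2 * segment_s * 1000)
    stop("need at least two Welch segments; lengthen the run")
  r <- bin_rate(spikes, population, bin_ms, t_start, t_end)
  if (all(r$rate == 0)) stop("empty spike set")
  fs <- 1000 / bin_ms
  w <- welch_spectrum(r$rate, fs, segment = round(segment_s * fs), overlap)
  bp <- band_power(w$freq, w$power, beta_band, w$df)
  gp <- band_power(w$freq, w$power, gamma_band, w$df)
  sel <- w$freq >= 20 & w$freq <= 60
  out <- list(freq = w$freq, power = w$power,
              beta_band = beta_band, gamma_band = gamma_band,
              beta_power = bp, gamma_power = gp,
              beta_gamma_ratio = bp / gp,
              peak_freq = w$freq[sel][which.max(w$power[sel])],
              n_segments = w$n_segments, df = w$df,
              var_signal = w$var_segments)
  class(out) <- "spectral_summary"
  out
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> peak %.0f Hz | beta(%g-%g) %.3g | gamma(%g-%g) %.3g | ratio %.2f\n",
              x$peak_freq, x$beta_band[1], x$beta_band[2], x$beta_power,
              x$gamma_band[1], x$gamma_band[2], x$gamma_power,
              x$beta_gamma_ratio))
  invisible(x)
}

#' Spectral peak frequency within a band
#'
#' @param spec a `spectral_summary`.
#' @param band frequency band (Hz) searched for the maximum.
#' @return Frequency (Hz) of the maximum power in the band.
#' @export
peak_frequency <- function(spec, band = c(20, 60)) {
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  spec$freq[sel][which.max(spec$power[sel])]
}

#' Fine estimate of the oscillation frequency
#'
#' Periodogram of the binned population rate over the whole record with
#' quadratic interpolation of the peak, giving a frequency estimate well
#' below the 1 Hz Welch grid.  Used to fix the frequency at which pre/post
#' Fourier coefficients are fit: a mismatch of `df` Hz biases every phase
#' advance by `df * window_gap` cycles, so the 1 Hz grid is not enough.
#'
#' @param spikes a `spike_record`.
#' @param band search band (Hz).
#' @param population,t_start,bin_ms as in [population_spectrum()].
#' @return Peak frequency (Hz).
#' @export
estimate_f0 <- function(spikes, band = c(20, 60), population = NULL,
                        t_start = 500, bin_ms = 1) {
  r <- bin_rate(spikes, population, bin_ms, t_start)
  x <- r$rate - mean(r$rate)
  n <- length(x)
  fs <- 1000 / bin_ms
  p <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  sel <- which(freq >= band[1] & freq <= band[2])
  i <- sel[which.max(p[sel])]
  # quadratic (log-parabolic) interpolation around the peak
  if (i > 1 && i < n) {
    y1 <- log(p[i - 1] + 1e-300); y2 <- log(p[i] + 1e-300); y3 <- log(p[i + 1] + 1e-300)
    d <- (y1 - y3) / (2 * (y1 - 2 * y2 + y3))
    if (is.finite(d) && abs(d) <= 0.5) return(freq[i] + d * fs / n)
  }
  freq[i]
}

#' Per-phase percent change of the beta/gamma ratio
#'
#' For each stimulation run, computes the beta/gamma ratio and expresses it
#' as a percent change from the stimulation-off run, keyed by the mean
#' estimated phase at (first) pulse delivery.
#'
#' @param runs list of `spike_record`s from stimulation runs (each carrying
#'   its delivered `stim` attribute).
#' @param off_run the matching stimulation-off `spike_record`.
#' @param outcome `"ratio"` (beta/gamma, the default) or `"beta"` (raw beta
#'   power).  The gamma band is a stimulation-insensitive reference for
#'   spiking-network output, but for a near-coherent phase-oscillator
#'   population the entrained rhythm's second harmonic can leak into it;
#'   use `"beta"` there.
#' @param ... passed to [population_spectrum()].
#' @return data.frame: `run`, `mean_phase`, `ratio`, `pct_change`.
#' @export
phase_sweep_outcome <- function(runs, off_run, outcome = c("ratio", "beta"),
                                ...) {
  outcome <- match.arg(outcome)
  dur <- vapply(runs, function(r) attr(r, "duration"), numeric(1))
  if (any(abs(dur - attr(off_run, "duration")) > 1e-6))
    stop("all runs must have the same duration as the off run")
  score <- function(spec)
    if (outcome == "ratio") spec$beta_gamma_ratio else spec$beta_power
  ratio_off <- score(population_spectrum(off_run, ...))
  res <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    ratio <- score(population_spectrum(r, ...))
    st <- attr(r, "stim")
    ph <- NA_real_
    if (!is.null(st) && nrow(st)) {
      first <- !duplicated(st$burst)
      p <- st$phase[first]
      p <- p[!is.na(p)]
      if (length(p)) ph <- circ_mean(p, positive = TRUE)
    }
    data.frame(run = names(runs)[i] %||% i, mean_phase = ph, ratio = ratio,
               pct_change = 100 * (ratio - ratio_off) / ratio_off)
  })
  out <- do.call(rbind, res)
  attr(out, "ratio_off") <- ratio_off
  out
}

#' Write a spectrum as columnar text
#' @param spec a `spectral_summary`.
#' @param path output file.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# beta(%g-%g)=%g gamma(%g-%g)=%g ratio=%g peak=%g",
                     spec$beta_band[1], spec$beta_band[2], spec$beta_power,
                     spec$gamma_band[1], spec$gamma_band[2], spec$gamma_power,
                     spec$beta_gamma_ratio, spec$peak_freq), con)
  write.table(data.frame(freq_hz = spec$freq, power = spec$power), con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
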