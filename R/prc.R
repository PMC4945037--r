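# Population PRC estimation: the phase advance of the population oscillation
# as a function of the phase at which a (sub-threshold) stimulus arrives,
# measured from Fourier coefficients fit to windows before and after each
# stimulus, with wrapped-normal statistics per phase bin.

#' Oscillation phase at a stimulus onset
#'
#' Assigns a probe to a phase bin using the online phase estimate at pulse
#' onset.
#'
#' @param spikes a `spike_record`.
#' @param stim_time pulse onset (ms); should be at least one tracker window.
#' @param config a [phase_tracker_config()].
#' @return Phase in cycles, `NA` if the estimate is invalid (the stimulus is
#'   then excluded from the PRC and counted in the exclusion log).
#' @export
stim_phase <- function(spikes, stim_time, config = phase_tracker_config()) {
  as.numeric(instantaneous_phase(spikes, stim_time, config))
}

#' Phase advance caused by one stimulus (or burst)
#'
#' Fits the complex Fourier coefficient at the oscillation frequency `f0` to
#' a `window_len` window ending at the stimulus onset and another starting
#' at the burst offset, and returns the angular difference mapped to
#' `(-0.5, 0.5]` cycles.  Both coefficients are referenced to absolute time,
#' so the deterministic drift of one period per cycle cancels and an
#' unperturbed oscillation yields zero.  Positive values are phase advances.
#'
#' @param spikes a `spike_record` (oscillating population is used).
#' @param stim_time onset of the (first) pulse (ms).
#' @param window_len fit window length (ms); default 94 ms, about three
#'   cycles of a 34 Hz oscillation.
#' @param f0 oscillation frequency (Hz) at which the coefficient is fit.
#' @param stim_end end of the stimulus (last pulse onset + width); default
#'   `stim_time`.
#' @param guard guard interval (ms) skipped on each side of the stimulus.
#' @return Advance in cycles, or `NA` if either window holds no spikes.
#' @export
phase_advance <- function(spikes, stim_time, window_len = 94, f0 = 34,
                          stim_end = NULL, guard = 0) {
  stim_end <- stim_end %||% stim_time
  s <- if (is.numeric(spikes) && !is.unsorted(spikes)) spikes else
    spike_times(spikes)
  lo <- findInterval(c(stim_time - guard - window_len, stim_time - guard,
                       stim_end + guard, stim_end + guard + window_len), s)
  if (lo[2] <= lo[1] || lo[4] <= lo[3]) return(NA_real_)
  pre <- s[(lo[1] + 1):lo[2]]
  pre <- pre[pre < stim_time - guard]          # findInterval is <=
  post <- s[(lo[3] + 1):lo[4]]
  if (!length(pre) || !length(post)) return(NA_real_)
  cf <- function(x) sum(exp(-2i * pi * f0 * x / 1000))
  wrap_signed((Arg(cf(post)) - Arg(cf(pre))) / (2 * pi))
}

#' Estimate a population PRC from probe stimuli
#'
#' Each burst of probe pulses contributes one sample: its phase is the
#' online estimate at the first pulse's onset and its advance comes from
#' [phase_advance()] around the burst.  Samples are binned by phase; each
#' bin's mean and dispersion come from a wrapped normal fit (circular mean,
#' `sqrt(-2 log R)` dispersion).
#'
#' @param spikes a `spike_record` from a probe run.
#' @param stims [stim_events()] actually delivered (with burst ids; if the
#'   engine recorded onset phases in `stims$phase` they are used, otherwise
#'   phases are recomputed with [stim_phase()]).
#' @param n_bins number of phase bins (at least 4).
#' @param pulses_per_burst 1 or 3; defaults to the maximum burst size found.
#' @param config a [phase_tracker_config()] for phase assignment.
#' @param f0 oscillation frequency (Hz) for the advance fit.
#' @param window_len,guard see [phase_advance()].
#' @return A `prc_estimate`: data.frame with `bin_center`, `mean_advance`,
#'   `circ_std`, `count`, plus attributes (`pulses_per_burst`, `f0`,
#'   `excluded`, and the raw `samples`).
#' @export
estimate_prc <- function(spikes, stims, n_bins = 16, pulses_per_burst = NULL,
                         config = phase_tracker_config(), f0 = 34,
                         window_len = 94, guard = 0) {
  if (n_bins < 4) stop("n_bins must be at least 4")
  if (!nrow(stims)) stop("no stimuli supplied")
  bursts <- split(seq_len(nrow(stims)), stims$burst)
  pulses_per_burst <- pulses_per_burst %||% max(lengths(bursts))
  s_sorted <- spike_times(spikes)
  phi <- adv <- rep(NA_real_, length(bursts))
  for (i in seq_along(bursts)) {
    rows <- stims[bursts[[i]], , drop = FALSE]
    first <- rows[which.min(rows$t_on), ]
    last <- rows[which.max(rows$t_on), ]
    p <- first$phase
    if (is.na(p)) p <- stim_phase(s_sorted, first$t_on, config)
    if (is.na(p)) next
    phi[i] <- p
    adv[i] <- phase_advance(s_sorted, first$t_on, window_len = window_len,
                            f0 = f0, stim_end = last$t_on + last$width,
                            guard = guard)
  }
  ok <- !is.na(phi) & !is.na(adv)
  excluded <- sum(!ok)
  phi <- phi[ok]; adv <- adv[ok]
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  bin <- pmin(floor(phi * n_bins) + 1, n_bins)
  mean_advance <- circ_std <- rep(NA_real_, n_bins)
  count <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    x <- adv[bin == b]
    count[b] <- length(x)
    if (length(x)) {
      mean_advance[b] <- circ_mean(x)
      circ_std[b] <- circ_sd(x)
    }
  }
  out <- data.frame(bin_center = centers, mean_advance = mean_advance,
                    circ_std = circ_std, count = count)
  class(out) <- c("prc_estimate", "data.frame")
  attr(out, "pulses_per_burst") <- pulses_per_burst
  attr(out, "f0") <- f0
  attr(out, "window_len") <- window_len
  attr(out, "excluded") <- excluded
  attr(out, "samples") <- data.frame(phase = phi, advance = adv)
  out
}

#' @export
print.prc_estimate <- function(x, ...) {
  cat(sprintf("<prc_estimate> %d bins, %d samples (%d excluded), %d pulse(s)/burst, f0=%.1f Hz\n",
              nrow(x), sum(x$count), attr(x, "excluded"),
              attr(x, "pulses_per_burst"), attr(x, "f0")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a PRC table as columnar text
#' @param prc a `prc_estimate`.
#' @param path output file.
#' @export
write_prc <- function(prc, path) {
  hdr <- sprintf("# pulses_per_burst=%d f0=%g window_len=%g",
                 attr(prc, "pulses_per_burst") %||% 1L,
                 attr(prc, "f0") %||% 34, attr(prc, "window_len") %||% 94)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(data.frame(bin_center = prc$bin_center,
                         mean_advance = prc$mean_advance,
                         circ_std = prc$circ_std, count = prc$count),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PRC table written by [write_prc()]
#' @param path input file.
#' @export
read_prc <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1 else 0
  df <- read.table(path, header = TRUE, skip = skip)
  out <- data.frame(bin_center = df$bin_center, mean_advance = df$mean_advance,
                    circ_std = df$circ_std, count = df$count)
  class(out) <- c("prc_estimate", "data.frame")
  if (skip) {
    kv <- regmatches(first, gregexpr("[a-z_0-9]+=[-0-9.eE]+", first))[[1]]
    for (p in kv) {
      nm <- sub("=.*", "", p); val <- as.numeric(sub(".*=", "", p))
      attr(out, nm) <- if (nm == "pulses_per_burst") as.integer(val) else val
    }
  }
  attr(out, "excluded") <- 0L
  out
}
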