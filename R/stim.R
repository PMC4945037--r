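# Stimulus events: one row per pulse.  Amplitudes are fractions of the
# reference clinical amplitude (the smallest amplitude that entrains STN
# firing at 136 Hz, calibrated in the shipped default config).

#' Construct a stimulus event list
#'
#' @param t_on pulse onset times (ms).
#' @param amplitude amplitude as a fraction of the reference amplitude.
#' @param width pulse width (ms).
#' @param target stimulated population (the engine injects into STN).
#' @param burst integer burst id grouping pulses triggered together.
#' @param phase estimated oscillation phase at pulse onset, if known.
#' @return A `stim_events` data.frame sorted by onset time.
#' @export
stim_events <- function(t_on, amplitude = 0.1, width = 0.5, target = "STN",
                        burst = seq_along(t_on), phase = NA_real_) {
  stopifnot(all(amplitude >= 0), all(width > 0))
  if (!length(t_on)) {
    x <- data.frame(t_on = numeric(0), amplitude = numeric(0),
                    width = numeric(0), target = character(0),
                    burst = integer(0), phase = numeric(0))
    class(x) <- c("stim_events", "data.frame")
    return(x)
  }
  x <- data.frame(t_on = t_on, amplitude = amplitude, width = width,
                  target = target, burst = as.integer(burst), phase = phase)
  x <- x[order(x$t_on), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("stim_events", "data.frame")
  x
}

#' @export
print.stim_events <- function(x, ...) {
  cat(sprintf("<stim_events> %d pulses in %d bursts, amplitude %s, charge %.2f\n",
              nrow(x), length(unique(x$burst)),
              paste(format(unique(x$amplitude)), collapse = "/"),
              delivered_charge(x)))
  invisible(x)
}

#' Total delivered charge of a protocol
#'
#' Sum of amplitude x width over all pulses, in units of
#' (reference amplitude) x ms.  Used for energy accounting between
#' open-loop and phase-locked protocols.
#'
#' @param stim a `stim_events` table.
#' @export
delivered_charge <- function(stim) {
  if (!nrow(stim)) return(0)
  sum(stim$amplitude * stim$width)
}

#' Write stimulus events as columnar text
#' @param stim a `stim_events` table.
#' @param path output file.
#' @export
write_stim <- function(stim, path) {
  df <- data.frame(t_on_ms = stim$t_on, amplitude = stim$amplitude,
                   width_ms = stim$width, target = stim$target,
                   burst = stim$burst)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read stimulus events from columnar text
#' @param path file written by [write_stim()].
#' @export
read_stim <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stim_events(df$t_on_ms, df$amplitude, df$width_ms,
              df$target %||% "STN", df$burst %||% seq_len(nrow(df)))
}

# stim_events -> matrix for the C++ engine (t_on, amp, width, volley)
as_stim_matrix <- function(stim, volley = FALSE) {
  if (is.null(stim) || !nrow(stim))
    return(matrix(numeric(0), ncol = 4))
  cbind(stim$t_on, stim$amplitude, stim$width, as.numeric(volley))
}
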