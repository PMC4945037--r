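# Spike records: the common currency between the simulators and every
# analysis module.  A spike record is a data.frame with columns
# population (factor), neuron (integer, 1-based within population) and
# t (ms), sorted by time, plus attributes describing how it was produced.

#' Construct a spike record
#'
#' @param population character or factor; one of `"STN"`, `"GPe"`, `"GPi"`,
#'   `"OSC"` per spike.
#' @param neuron integer neuron index within its population (1-based).
#' @param t spike time in ms.
#' @param osc_population which population carries the tracked oscillation
#'   (`"GPe"` for the network backend, `"OSC"` for the phase backend).
#' @param duration total simulated time in ms (defaults to `max(t)`).
#' @return A `spike_record` data.frame sorted by spike time.
#' @export
spike_record <- function(population, neuron, t, osc_population = "GPe",
                         duration = NULL) {
  population <- factor(as.character(population), levels = POPULATIONS)
  if (anyNA(population)) stop("unknown population label")
  neuron <- as.integer(neuron)
  if (any(neuron < 1L)) stop("neuron indices are 1-based")
  o <- order(t, population, neuron)   # stable for simultaneous spikes
  x <- data.frame(population = population[o], neuron = neuron[o], t = t[o])
  class(x) <- c("spike_record", "data.frame")
  attr(x, "osc_population") <- osc_population
  attr(x, "duration") <- duration %||% (if (nrow(x)) max(x$t) else 0)
  x
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d spikes, %.1f ms, populations: %s\n",
              nrow(x), attr(x, "duration"),
              paste(levels(droplevels(x$population)), collapse = ", ")))
  invisible(x)
}

#' Extract spike times, optionally for one population
#'
#' @param spikes a `spike_record`, or a bare numeric vector of times.
#' @param population population label; `NULL` selects the record's
#'   oscillating population when present, else all spikes.
#' @return Sorted numeric vector of spike times (ms).
#' @export
spike_times <- function(spikes, population = NULL) {
  if (is.numeric(spikes)) return(sort(spikes))
  stopifnot(inherits(spikes, "spike_record") || is.data.frame(spikes))
  population <- population %||% attr(spikes, "osc_population")
  if (!is.null(population) && "population" %in% names(spikes))
    spikes <- spikes[spikes$population == population, , drop = FALSE]
  sort(spikes$t)
}

#' Population firing rate binned on a regular grid
#'
#' @param spikes a `spike_record`.
#' @param population population label (default: all spikes in the record).
#' @param bin_ms bin width in ms.
#' @param t_start,t_end analysis interval in ms.
#' @return data.frame with bin centre `t` (ms) and `rate` in spikes/s summed
#'   over the population.
#' @export
bin_rate <- function(spikes, population = NULL, bin_ms = 1,
                     t_start = 0, t_end = NULL) {
  t_end <- t_end %||% attr(spikes, "duration") %||% max(spikes$t)
  ts <- spike_times(spikes, population)
  ts <- ts[ts > t_start & ts <= t_end]
  edges <- seq(t_start, t_end, by = bin_ms)
  counts <- tabulate(findInterval(ts, edges, left.open = TRUE),
                     nbins = length(edges) - 1)
  data.frame(t = edges[-length(edges)] + bin_ms / 2,
             rate = counts / (bin_ms / 1000))
}

#' Write spikes as columnar text
#'
#' Columns: `population`, `neuron`, `t_ms`, tab-separated with a header.
#'
#' @param spikes a `spike_record`.
#' @param path output file.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(population = as.character(spikes$population),
                   neuron = spikes$neuron, t_ms = spikes$t)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spikes from columnar text
#'
#' @param path file written by [write_spikes()] (or any tab/whitespace table
#'   with columns population, neuron, t_ms).
#' @param osc_population oscillating population label for downstream modules.
#' @return A `spike_record`.
#' @export
read_spikes <- function(path, osc_population = "GPe") {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(df) <- sub("^t_ms$", "t", names(df))
  spike_record(df$population, df$neuron, df$t, osc_population = osc_population)
}
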