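#' Read and write spike rasters as TSV
#'
#' Rasters are exchanged as two plain-text tab-separated files: a spike
#' table with columns `neuron_id` (0-based) and `spike_time_ms`, and a
#' coordinate table with columns `neuron_id`, `x_mm`, `y_mm`. Neurons with
#' no spikes appear only in the coordinate table.
#'
#' @param raster a [spike_raster()].
#' @param spikes_file,coords_file file paths.
#' @return `write_raster_tsv()` returns the raster invisibly;
#'   `read_raster_tsv()` returns a [spike_raster()].
#' @export
write_raster_tsv <- function(raster, spikes_file, coords_file) {
  n <- n_neurons(raster)
  spk <- data.frame(
    neuron_id = rep(seq_len(n) - 1L, lengths(raster$spikes)),
    spike_time_ms = unlist(raster$spikes, use.names = FALSE))
  write.table(spk, spikes_file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  co <- data.frame(neuron_id = seq_len(n) - 1L, x_mm = raster$x,
                   y_mm = raster$y)
  write.table(co, coords_file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(raster)
}

#' @rdname write_raster_tsv
#' @param L torus side length (mm).
#' @param duration raster duration (ms); default the latest spike time,
#'   rounded up.
#' @export
read_raster_tsv <- function(spikes_file, coords_file, L = 1,
                            duration = NULL) {
  spk <- read.table(spikes_file, header = TRUE, sep = "\t")
  co <- read.table(coords_file, header = TRUE, sep = "\t")
  co <- co[order(co$neuron_id), ]
  if (is.null(duration))
    duration <- if (nrow(spk)) ceiling(max(spk$spike_time_ms)) else 0
  spikes <- lapply(co$neuron_id, function(id)
    sort(spk$spike_time_ms[spk$neuron_id == id]))
  spike_raster(spikes, co$x_mm, co$y_mm, L, duration)
}

#' Write a mean-field trace with a JSON sidecar
#'
#' The trace data.frame goes to TSV; bin widths and units go to a JSON
#' sidecar so the files are self-describing.
#'
#' @param trace trace data.frame (from a simulation).
#' @param file TSV path; the sidecar is `paste0(file, ".json")`.
#' @param trace_bin trace sampling bin (ms).
#' @export
write_trace_tsv <- function(trace, file, trace_bin) {
  write.table(trace, file, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(trace_bin_ms = trace_bin,
               units = list(t = "ms", v = "mV", w = "mV", sd_v = "mV",
                            i_syn = "nA", i_int = "nA"))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(trace)
}
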