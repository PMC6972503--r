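#' Read and write spike rasters, edge lists and drive vectors
#'
#' Plain tab-delimited interchange formats: rasters as two columns
#' (`neuron`, `time` in ms), connectivity as two columns (`pre`, `post`),
#' drive vectors as a single `I_app_pA` column.  All three round-trip
#' through their readers.
#'
#' @param raster spike raster `data.frame` or `sim_result`.
#' @param path file path.
#' @param N population size to attach to the raster read back (optional).
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_raster <- function(raster, path) {
  df <- raster_df(raster)
  utils::write.table(df[, c("neuron", "time")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_raster <- function(path, N = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric"))
  if (!is.null(N)) attr(df, "N") <- as.integer(N)
  df
}

#' @rdname raster_io
#' @param conn a `connectivity` edge list.
#' @export
write_edge_list <- function(conn, path) {
  utils::write.table(as.data.frame(conn)[, c("pre", "post")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_edge_list <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "integer"))
}

#' @rdname raster_io
#' @param drive numeric drive vector (pA).
#' @export
write_drive <- function(drive, path) {
  utils::write.table(data.frame(I_app_pA = drive), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_drive <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")$I_app_pA
}
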