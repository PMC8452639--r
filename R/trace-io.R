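#' Read and write traces as two-column text
#'
#' Plain-text interchange format: a one-line header `# fs=<Hz> units=<label>`
#' followed by whitespace-separated columns `time_s value`. Ground-truth
#' event annotations travel in JSON sidecar files.
#'
#' @param trace a `trace_recording`.
#' @param path output file path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g units=%s", trace$sampling_rate, trace$units),
             con)
  utils::write.table(
    data.frame(time_s = trace_times(trace), value = trace$samples),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("fs=([0-9.eE+-]+)\\s+units=(\\S+)", hdr))[[1]]
  if (length(m) != 3L)
    stop("missing '# fs=<Hz> units=<label>' header in ", path, call. = FALSE)
  d <- utils::read.table(path, skip = 1L,
                         col.names = c("time_s", "value"))
  trace_recording(d$value, as.numeric(m[2]), units = m[3])
}

#' Write / read ground-truth annotations as JSON
#'
#' @param truth list with `event_times` (s), `event_amps`, and optionally
#'   `epochs` (data.frame start/end/label).
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
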