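## Text formats: TA maps as delimited matrices with a JSON sidecar,
## ensemble populations as CSV.

#' Write / read a TA map as a delimited text matrix
#'
#' Layout: first row = probe photon energies (eV) with an empty leading
#' cell, first column = pump-probe delays (fs), body = \eqn{\Delta A}. A
#' JSON sidecar `<path>.json` carries the metadata. The same layout is used
#' to ingest externally deposited experimental maps; `read_tamap` tolerates
#' a missing sidecar.
#'
#' @param map a `ta_map`.
#' @param path output file (tab-separated text).
#' @return `write_tamap` returns `path` invisibly; `read_tamap` returns a
#'   `ta_map` (components are not serialized, only the total).
#' @export
write_tamap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", format(map$probe_ev, digits = 12)), collapse = "\t"), con)
  body <- cbind(map$delays_fs, map$delta_a)
  utils::write.table(format(body, digits = 12), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- map$metadata
  if (length(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_tamap
#' @export
read_tamap <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("not a TA map file: fewer than two lines")
  split_row <- function(x) strsplit(x, "\t", fixed = TRUE)[[1]]
  head <- split_row(lines[1])
  probe <- suppressWarnings(as.numeric(head[-1]))
  if (any(is.na(probe))) stop("line 1: probe-energy header is not numeric")
  ne <- length(probe)
  nd <- length(lines) - 1L
  delays <- numeric(nd)
  A <- matrix(NA_real_, nd, ne)
  for (i in seq_len(nd)) {
    v <- suppressWarnings(as.numeric(split_row(lines[i + 1L])))
    if (length(v) != ne + 1L) {
      stop("line ", i + 1L, ": expected ", ne + 1L, " fields, found ", length(v))
    }
    if (any(is.na(v))) stop("line ", i + 1L, ": non-numeric field")
    delays[i] <- v[1]
    A[i, ] <- v[-1]
  }
  if (any(diff(delays) <= 0)) stop("delay column is not strictly increasing")
  if (any(diff(probe) <= 0)) stop("probe-energy header is not strictly increasing")
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  ta_map(delays, probe, A, metadata = meta)
}

#' Export ensemble population traces as CSV
#'
#' Columns: `time_fs` and one `P_<label>` column per state.
#'
#' @param ensemble an `ensemble`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_populations_csv <- function(ensemble, path) {
  utils::write.csv(ensemble$populations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
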