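#' Write a trace to a plain-text file
#'
#' Two-column numeric text (time, amplitude) preceded by '#'-prefixed
#' header lines carrying the metadata as JSON (units, seed, generating
#' parameters, schema version). The round trip through [read_trace()] is
#' lossless.
#'
#' @param trace An [epr_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- trace$meta
  meta$schema <- "dressedEPR-trace/1"
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(t = trace$t, y = trace$y), con,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a trace from a plain-text file
#'
#' Accepts files written by [write_trace()] (JSON header) and, with a
#' warning, legacy headerless two-column files, which are assumed to be in
#' us and dimensionless amplitude. A header that parses but lacks the time
#' unit is rejected.
#'
#' @param path Input file path.
#' @return An [epr_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  if (length(hdr) > 0) {
    json <- sub("^#\\s*", "", paste(lines[hdr], collapse = ""))
    meta <- try(jsonlite::fromJSON(json, simplifyVector = TRUE),
                silent = TRUE)
    if (inherits(meta, "try-error"))
      stop("malformed trace header (line ", hdr[1], "): not valid JSON")
    if (is.null(meta$time_unit))
      stop("trace header is missing the time unit")
  } else {
    warning("headerless trace file: assuming time in us, ",
            "dimensionless amplitude")
    meta <- list(time_unit = "us", amplitude_unit = "dimensionless")
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "[\t ,]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || !(ncol %in% c(2, 3))) {
    bad <- which(lengths(fields) != lengths(fields)[1])[1]
    stop("malformed trace body near line ",
         setdiff(seq_along(lines), hdr)[if (is.na(bad)) 1 else bad],
         ": expected 2 numeric columns")
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop("malformed trace body near data row ", bad, ": non-numeric value")
  }
  tr <- epr_trace(vals[, 1], vals[, 2])
  tr$meta <- meta
  if (meta$time_unit == "ns") {       # ns accepted, converted to us
    tr$t <- tr$t / 1000
    tr$meta$time_unit <- "us"
  }
  tr
}

#' Write a dipolar spectrum to a plain-text file
#'
#' Same dialect as [write_trace()]: two columns (frequency in MHz,
#' amplitude) with a JSON metadata header.
#'
#' @param spec A [dipolar_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  meta <- spec$meta
  meta$schema <- "dressedEPR-spectrum/1"
  meta$frequency_unit <- "MHz"
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(f = spec$frequency, a = spec$amplitude),
                     con, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}
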