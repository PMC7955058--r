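#' @useDynLib me2vec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SPECIALTY_UNKNOWN <- "UNKNOWN"

#' Construct a journey table
#'
#' A journey table is the canonical in-memory form of longitudinal EHR
#' records: one row per administered medical service, carrying the patient,
#' the doctor (with the doctor's primary specialty), the service code and an
#' integer time index (days, or minutes for ICU-style data). Rows are kept in
#' a canonical deterministic order: `(patient_id, date, service_code,
#' doctor_id)`. Duplicate rows are retained, because downstream edge weights
#' are occurrence counts.
#'
#' @param records data.frame with columns `patient_id`, `doctor_id`,
#'   `specialty`, `service_code`, `date` (integer time index, >= 0).
#' @return An object of class `journey_table`: the canonically sorted record
#'   data.frame plus vocabularies (`patients`, `doctors`, `services`,
#'   `specialties`) holding the distinct values present.
#' @export
journey_table <- function(records) {
  required <- c("patient_id", "doctor_id", "specialty", "service_code", "date")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("journey records missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[required]
  for (col in c("patient_id", "doctor_id", "specialty", "service_code")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$date <- as.integer(records$date)
  if (nrow(records) > 0) {
    if (anyNA(records$date) || any(records$date < 0)) {
      stop("journey dates must be finite non-negative integers")
    }
    if (any(!nzchar(records$patient_id)) || any(!nzchar(records$doctor_id)) ||
        any(!nzchar(records$service_code))) {
      stop("patient_id, doctor_id and service_code must be non-empty")
    }
    records$specialty[is.na(records$specialty) | !nzchar(records$specialty)] <-
      SPECIALTY_UNKNOWN
    ord <- order(records$patient_id, records$date, records$service_code,
                 records$doctor_id, method = "radix")
    records <- records[ord, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(
    list(
      records = records,
      patients = sort(unique(records$patient_id)),
      doctors = sort(unique(records$doctor_id)),
      services = sort(unique(records$service_code)),
      specialties = sort(unique(records$specialty))
    ),
    class = "journey_table"
  )
}

#' @export
print.journey_table <- function(x, ...) {
  cat(sprintf(
    "journey_table: %d records | %d patients, %d doctors, %d services, %d specialties\n",
    nrow(x$records), length(x$patients), length(x$doctors),
    length(x$services), length(x$specialties)))
  invisible(x)
}

#' Read a journey table from CSV/TSV
#'
#' The file must be UTF-8 with a header row and columns `patient_id`,
#' `doctor_id`, `specialty`, `service_code`, `date`. Dates are converted to
#' 0-based integer indices relative to the earliest date in the file so that
#' window arithmetic downstream is exact. Missing specialties become the
#' sentinel `"UNKNOWN"`; duplicate rows are retained.
#'
#' @param path file path.
#' @param date_format one of `"auto"` (integer passthrough or `YYYY-MM-DD`),
#'   `"days"` (integer day index), `"date"` (`YYYY-MM-DD`), `"minutes"`
#'   (integer minute index, for sub-day timestamped data).
#' @param sep field separator; `","` for CSV (default), `"\t"` for TSV.
#' @return A [journey_table].
#' @export
read_journeys <- function(path, date_format = c("auto", "days", "date", "minutes"),
                          sep = ",") {
  date_format <- match.arg(date_format)
  if (!file.exists(path)) stop("journey file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           encoding = "UTF-8", na.strings = character(0))
  required <- c("patient_id", "doctor_id", "specialty", "service_code", "date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("journey file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0) {
    return(journey_table(data.frame(patient_id = character(0),
                                    doctor_id = character(0),
                                    specialty = character(0),
                                    service_code = character(0),
                                    date = integer(0))))
  }
  dates <- parse_dates(raw$date, date_format)
  bad <- which(is.na(dates))
  if (length(bad) > 0) {
    stop(sprintf("unparsable date '%s' at data line %d of %s",
                 raw$date[bad[1]], bad[1], path))
  }
  dates <- dates - min(dates)
  journey_table(data.frame(patient_id = raw$patient_id,
                           doctor_id = raw$doctor_id,
                           specialty = raw$specialty,
                           service_code = raw$service_code,
                           date = dates))
}

parse_dates <- function(x, date_format) {
  x <- trimws(x)
  as_int <- suppressWarnings(as.integer(x))
  if (date_format %in% c("days", "minutes")) return(as_int)
  looks_iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (date_format == "date" || (date_format == "auto" && any(looks_iso))) {
    d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
    return(as.integer(d - as.Date("1970-01-01")))
  }
  as_int
}

#' Write a journey table to CSV
#'
#' @param journeys a [journey_table].
#' @param path output file path.
#' @export
write_journeys <- function(journeys, path) {
  stopifnot(inherits(journeys, "journey_table"))
  utils::write.csv(journeys$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an embedding table
#'
#' @param ids character vector of unique entity ids.
#' @param vectors numeric matrix, one row per id, all entries finite.
#' @return Object of class `embedding_table` with fields `ids`, `vectors`
#'   (rownames set to ids) and `dim`.
#' @export
embedding_table <- function(ids, vectors) {
  ids <- as.character(ids)
  vectors <- as.matrix(vectors)
  if (anyDuplicated(ids)) stop("embedding ids must be unique")
  if (length(ids) != nrow(vectors)) stop("row count must equal id count")
  if (length(vectors) > 0 && !all(is.finite(vectors))) {
    stop("embedding vectors must be finite")
  }
  rownames(vectors) <- ids
  structure(list(ids = ids, vectors = vectors, dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d ids x %d dims\n", length(x$ids), x$dim))
  invisible(x)
}

#' Look up embedding vectors by id
#'
#' @param table an [embedding_table].
#' @param ids character vector of ids; all must be present.
#' @return numeric matrix of the requested rows, in the requested order.
#' @export
embedding_lookup <- function(table, ids) {
  idx <- match(ids, table$ids)
  if (anyNA(idx)) {
    stop("id(s) absent from embedding table: ",
         paste(ids[is.na(idx)][seq_len(min(5, sum(is.na(idx))))], collapse = ", "))
  }
  table$vectors[idx, , drop = FALSE]
}

#' Write / read embeddings in word2vec text format
#'
#' The format is a header line `"<count> <dim>"` followed by one line per
#' entity: the id then `dim` whitespace-separated floats. Round-trip
#' reproduces ids exactly and vectors to <= 1e-6 absolute.
#'
#' @param table an [embedding_table].
#' @param path file path.
#' @export
write_embeddings <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(table$ids), table$dim), con)
  if (length(table$ids) > 0) {
    body <- vapply(seq_along(table$ids), function(i) {
      paste(table$ids[i], paste(sprintf("%.8g", table$vectors[i, ]), collapse = " "))
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @return `read_embeddings` returns an [embedding_table].
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty embedding file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2) stop("malformed embedding header: ", lines[1])
  n <- as.integer(header[1]); d <- as.integer(header[2])
  if (length(lines) - 1 != n) {
    stop(sprintf("embedding file declares %d rows but has %d", n, length(lines) - 1))
  }
  ids <- character(n)
  vec <- matrix(NA_real_, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != d + 1) {
      stop(sprintf("embedding row %d has %d values, expected %d (dim mismatch)",
                   i, length(parts) - 1, d))
    }
    ids[i] <- parts[1]
    vec[i, ] <- as.numeric(parts[-1])
  }
  embedding_table(ids, vec)
}
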