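#' Build the service co-occurrence graph
#'
#' Traverses each patient's journey with non-overlapping context windows of
#' `T` days (half-open intervals `[t0, t0+T)`, `[t0+T, t0+2T)`, ... anchored
#' at the patient's first service day) and, within each window, increments the
#' symmetric adjacency entry of every unordered pair of distinct services.
#' Counts from all patients are summed. `T` controls sparsity: smaller windows
#' give a sparser adjacency.
#'
#' @param journeys a [journey_table].
#' @param T_window window span in day (or minute) units, >= 1. Default 8 days;
#'   use 60 for minute-indexed ICU data.
#' @param pair_counting `"product"` (default): a window holding service A
#'   twice and B once adds 2 to (A,B) — the occurrence-count product;
#'   `"binary"`: each window adds at most 1 per pair.
#' @param services optional character vector fixing vertex order (defaults to
#'   the journey vocabulary); services never co-occurring stay isolated but
#'   keep a vertex.
#' @return Object of class `cooccurrence_graph`: `services` (vertex order),
#'   `adjacency` (symmetric integer matrix, zero diagonal), `window_T`.
#' @export
build_cooccurrence <- function(journeys, T_window = 8L,
                               pair_counting = c("product", "binary"),
                               services = NULL) {
  stopifnot(inherits(journeys, "journey_table"))
  pair_counting <- match.arg(pair_counting)
  T_window <- as.integer(T_window)
  if (is.na(T_window) || T_window < 1) stop("T_window must be a positive integer")
  if (is.null(services)) services <- journeys$services
  services <- as.character(services)
  if (anyDuplicated(services)) stop("service vocabulary must be unique")
  M <- length(services)
  A <- matrix(0, nrow = M, ncol = M, dimnames = list(services, services))
  rec <- journeys$records
  if (nrow(rec) > 0) {
    svc_idx <- match(rec$service_code, services)
    if (anyNA(svc_idx)) stop("journey contains service codes outside the vocabulary")
    first_day <- tapply(rec$date, rec$patient_id, min)
    win <- (rec$date - first_day[rec$patient_id]) %/% T_window
    key <- paste(rec$patient_id, win, sep = "\r")
    for (grp in split(svc_idx, key)) {
      counts <- tabulate(grp, nbins = M)
      present <- which(counts > 0)
      if (length(present) < 2) next
      for (ii in seq_len(length(present) - 1)) {
        a <- present[ii]
        bs <- present[(ii + 1):length(present)]
        inc <- if (pair_counting == "product") counts[a] * counts[bs] else 1
        A[a, bs] <- A[a, bs] + inc
        A[bs, a] <- A[bs, a] + inc
      }
    }
  }
  structure(list(services = services, adjacency = A, window_T = T_window),
            class = "cooccurrence_graph")
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat(sprintf("cooccurrence_graph: %d services, %d edges, T=%d, density=%.3f\n",
              length(x$services), sum(x$adjacency[upper.tri(x$adjacency)] > 0),
              x$window_T, graph_density(x)))
  invisible(x)
}

#' Fraction of realized service pairs
#'
#' @param graph a `cooccurrence_graph`.
#' @return Fraction of off-diagonal upper-triangle entries that are nonzero,
#'   in \[0,1\] (0 for graphs with < 2 vertices).
#' @export
graph_density <- function(graph) {
  stopifnot(inherits(graph, "cooccurrence_graph"))
  M <- length(graph$services)
  if (M < 2) return(0)
  ut <- graph$adjacency[upper.tri(graph$adjacency)]
  mean(ut > 0)
}

#' Serialize a co-occurrence graph as an edge list
#'
#' Writes a TSV (`service_a`, `service_b`, `weight`) of the upper triangle,
#' plus a vocabulary file (one service per line) fixing vertex order so
#' isolated services survive the round trip.
#'
#' @param graph a `cooccurrence_graph`.
#' @param path edge-list TSV path; the vocabulary goes to `<path>.vocab`.
#' @export
write_cooccurrence <- function(graph, path) {
  stopifnot(inherits(graph, "cooccurrence_graph"))
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency > 0, arr.ind = TRUE)
  df <- data.frame(service_a = graph$services[idx[, 1]],
                   service_b = graph$services[idx[, 2]],
                   weight = graph$adjacency[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(graph$services, paste0(path, ".vocab"))
  invisible(path)
}

#' @rdname write_cooccurrence
#' @param window_T window size to record on the reconstructed graph.
#' @return `read_cooccurrence` returns a `cooccurrence_graph`.
#' @export
read_cooccurrence <- function(path, window_T = 8L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  vocab_path <- paste0(path, ".vocab")
  services <- if (file.exists(vocab_path)) {
    readLines(vocab_path)
  } else {
    sort(unique(c(df$service_a, df$service_b)))
  }
  M <- length(services)
  A <- matrix(0, M, M, dimnames = list(services, services))
  if (nrow(df) > 0) {
    ia <- match(df$service_a, services)
    ib <- match(df$service_b, services)
    if (anyNA(ia) || anyNA(ib)) stop("edge list references services outside vocabulary")
    A[cbind(ia, ib)] <- df$weight
    A[cbind(ib, ia)] <- df$weight
  }
  structure(list(services = services, adjacency = A,
                 window_T = as.integer(window_T)),
            class = "cooccurrence_graph")
}
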