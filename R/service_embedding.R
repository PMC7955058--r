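#' Biased random-walk configuration
#'
#' Second-order (node2vec-style) walk parameters. `p` (return) and `q`
#' (in-out) bias the walk towards or away from the previous node's
#' neighborhood; `p = q = 1` recovers a first-order weighted walk.
#'
#' @param p return parameter, > 0.
#' @param q in-out parameter, > 0.
#' @param num_walks walks started per node.
#' @param walk_length maximum nodes per walk.
#' @param seed integer RNG seed.
#' @export
walk_config <- function(p = 1, q = 1, num_walks = 10L, walk_length = 80L,
                        seed = 1L) {
  if (p <= 0 || q <= 0) stop("p and q must be > 0")
  if (num_walks < 1 || walk_length < 1) stop("num_walks and walk_length must be >= 1")
  structure(list(p = p, q = q, num_walks = as.integer(num_walks),
                 walk_length = as.integer(walk_length), seed = as.integer(seed)),
            class = "walk_config")
}

#' Skip-gram training configuration
#'
#' @param dim embedding dimension (default 128).
#' @param window context radius in walk positions.
#' @param negatives negative samples per positive pair (default 10).
#' @param epochs passes over the walk corpus (default 20; synthetic corpora
#'   are small, so low-frequency services need more passes to converge than
#'   web-scale word2vec defaults assume).
#' @param learning_rate initial SGD step size (linearly decayed when
#'   `decay = TRUE`).
#' @param decay linear learning-rate decay toward `1e-4 * learning_rate`.
#' @param subsample frequent-token subsampling threshold (word2vec `sample`;
#'   default `1e-3`, 0 disables). Curbs the over-training of hub services so
#'   routine services aggregate while rare ones stay peripheral.
#' @param seed integer RNG seed (initialization and negative sampling).
#' @export
skipgram_config <- function(dim = 128L, window = 5L, negatives = 10L,
                            epochs = 20L, learning_rate = 0.025, decay = TRUE,
                            subsample = 1e-3, seed = 1L) {
  if (dim < 1) stop("dim must be >= 1")
  if (negatives < 0) stop("negatives must be >= 0")
  if (epochs < 0) stop("epochs must be >= 0")
  if (window < 1) stop("window must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (subsample < 0) stop("subsample must be >= 0")
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negatives = as.integer(negatives), epochs = as.integer(epochs),
                 learning_rate = learning_rate, decay = isTRUE(decay),
                 subsample = subsample, seed = as.integer(seed)),
            class = "skipgram_config")
}

#' Second-order transition distribution of a biased walk
#'
#' Given the previous and current node of a walk on the co-occurrence graph,
#' the unnormalized probability of moving to neighbor `x` of `curr` is
#' `w(curr, x) * alpha` with `alpha = 1/p` if `x == prev`, `1` if `x` is
#' adjacent to `prev`, and `1/q` otherwise. With `prev = NULL` (walk start)
#' the distribution is first-order, proportional to edge weights.
#'
#' @param graph a `cooccurrence_graph`.
#' @param prev previous service code, or `NULL`/`NA` at the walk start.
#' @param curr current service code.
#' @param config a [walk_config] (only `p` and `q` are used).
#' @return named probability vector over the neighbors of `curr` (sums to 1);
#'   length zero if `curr` is isolated.
#' @export
transition_distribution <- function(graph, prev, curr, config = walk_config()) {
  stopifnot(inherits(graph, "cooccurrence_graph"))
  ci <- match(curr, graph$services)
  if (is.na(ci)) stop("unknown service: ", curr)
  w <- graph$adjacency[ci, ]
  nbr <- which(w > 0)
  if (length(nbr) == 0) return(stats::setNames(numeric(0), character(0)))
  at_start <- is.null(prev) || (length(prev) == 1 && is.na(prev))
  if (at_start) {
    probs <- w[nbr] / sum(w[nbr])
    return(stats::setNames(probs, graph$services[nbr]))
  }
  pi <- match(prev, graph$services)
  if (is.na(pi)) stop("unknown service: ", prev)
  if (graph$adjacency[pi, ci] <= 0) {
    stop("contract error: prev '", prev, "' is not adjacent to curr '", curr, "'")
  }
  alpha <- ifelse(nbr == pi, 1 / config$p,
                  ifelse(graph$adjacency[pi, nbr] > 0, 1, 1 / config$q))
  un <- w[nbr] * alpha
  stats::setNames(un / sum(un), graph$services[nbr])
}

#' Simulate biased random walks over the co-occurrence graph
#'
#' Starts `num_walks` walks from every node, in a seed-determined shuffled
#' order (reshuffled each round). Walks extend to `walk_length` nodes; a walk
#' reaching an isolated node stops there (walks from isolated nodes are
#' singletons). Transition distributions are cached per `(prev, curr)` pair.
#'
#' @param graph a `cooccurrence_graph`.
#' @param config a [walk_config].
#' @return list of character vectors of service codes (the walk corpus).
#' @export
simulate_walks <- function(graph, config = walk_config()) {
  stopifnot(inherits(graph, "cooccurrence_graph"))
  M <- length(graph$services)
  A <- graph$adjacency
  nbrs <- lapply(seq_len(M), function(i) which(A[i, ] > 0))
  first_probs <- lapply(seq_len(M), function(i) {
    nb <- nbrs[[i]]
    if (length(nb) == 0) numeric(0) else A[i, nb] / sum(A[i, nb])
  })
  cache <- new.env(parent = emptyenv(), size = 4096L)
  second_probs <- function(prev, curr) {
    key <- paste0(prev, "|", curr)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    nb <- nbrs[[curr]]
    alpha <- ifelse(nb == prev, 1 / config$p,
                    ifelse(A[prev, nb] > 0, 1, 1 / config$q))
    pr <- A[curr, nb] * alpha
    pr <- pr / sum(pr)
    cache[[key]] <- pr
    pr
  }
  set.seed(config$seed)
  walks <- vector("list", config$num_walks * M)
  k <- 0L
  for (round in seq_len(config$num_walks)) {
    for (start in sample.int(M)) {
      walk <- integer(config$walk_length)
      walk[1] <- start
      len <- 1L
      while (len < config$walk_length) {
        curr <- walk[len]
        nb <- nbrs[[curr]]
        if (length(nb) == 0) break
        pr <- if (len == 1L) first_probs[[curr]] else second_probs(walk[len - 1L], curr)
        walk[len + 1L] <- nb[sample.int(length(nb), 1L, prob = pr)]
        len <- len + 1L
      }
      k <- k + 1L
      walks[[k]] <- graph$services[walk[seq_len(len)]]
    }
  }
  walks
}

#' Train service embeddings by skip-gram with negative sampling
#'
#' Runs canonical word2vec-style SGD over the walk corpus (noise distribution
#' unigram^0.75 over the corpus), single-threaded and deterministic given the
#' seed. Every service in the vocabulary receives a vector; services absent
#' from all walks keep their seeded random initialization (with a warning).
#'
#' @param walks list of character vectors (from [simulate_walks]).
#' @param config a [skipgram_config].
#' @param services optional vocabulary fixing id order; defaults to the sorted
#'   set of codes appearing in the walks.
#' @return An [embedding_table] over services (input vectors). The context
#'   (output) matrix is attached as attribute `"context_vectors"`.
#' @export
train_skipgram <- function(walks, config = skipgram_config(), services = NULL) {
  stopifnot(inherits(config, "skipgram_config"))
  tokens <- unlist(walks, use.names = FALSE)
  if (length(tokens) == 0) stop("walk corpus is empty")
  if (is.null(services)) services <- sort(unique(tokens))
  missing <- setdiff(services, unique(tokens))
  if (length(missing) > 0) {
    warning("service(s) absent from all walks keep random initialization: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  walk_ids <- lapply(walks, function(w) {
    ids <- match(w, services)
    if (anyNA(ids)) stop("walk contains service codes outside the vocabulary")
    ids
  })
  fit <- sgns_train(walk_ids, length(services), config$dim, config$window,
                    config$negatives, config$epochs, config$learning_rate,
                    config$decay, config$subsample, config$seed)
  out <- embedding_table(services, fit$input)
  attr(out, "context_vectors") <- fit$output
  out
}

#' End-to-end service embedding
#'
#' Convenience wrapper: walks + skip-gram on a co-occurrence graph.
#'
#' @param graph a `cooccurrence_graph`.
#' @param walk a [walk_config].
#' @param sgns a [skipgram_config].
#' @return An [embedding_table] over all services of the graph.
#' @export
embed_services <- function(graph, walk = walk_config(), sgns = skipgram_config()) {
  walks <- simulate_walks(graph, walk)
  train_skipgram(walks, sgns, services = graph$services)
}
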