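#' Build the attributed patient-service-doctor multigraph
#'
#' One quadruple `(patient, service, doctor, weight)` per distinct
#' combination, with weight the number of journey rows carrying it — the
#' bipartite patient-service multigraph whose parallel edges are
#' doctor-attributed.
#'
#' @param journeys a [journey_table].
#' @return Object of class `patient_multigraph`: `patients` and `edges`
#'   (data.frame patient/service/doctor/weight).
#' @export
build_patient_multigraph <- function(journeys) {
  stopifnot(inherits(journeys, "journey_table"))
  rec <- journeys$records
  if (nrow(rec) == 0) {
    edges <- data.frame(patient = character(0), service = character(0),
                        doctor = character(0), weight = integer(0))
    return(structure(list(patients = character(0), edges = edges),
                     class = "patient_multigraph"))
  }
  agg <- stats::aggregate(list(weight = rep(1L, nrow(rec))),
                          by = list(patient = rec$patient_id,
                                    service = rec$service_code,
                                    doctor = rec$doctor_id), FUN = sum)
  agg <- agg[order(agg$patient, agg$service, agg$doctor), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(patients = sort(unique(agg$patient)), edges = agg),
            class = "patient_multigraph")
}

hybrid_id <- function(service, doctor) paste(service, doctor, sep = "|")

#' Duplication & annotation: multigraph to simple patient-hybrid graph
#'
#' Each service node is duplicated once per distinct doctor attribute on its
#' edges and annotated with that doctor, producing "hybrid" `(service,
#' doctor)` nodes; edges lose their attributes and keep their weights. The
#' result is a simple weighted bipartite graph with total edge weight
#' conserved and exactly one hybrid per distinct `(service, doctor)` pair in
#' the multigraph.
#'
#' @param mg a `patient_multigraph`.
#' @return Object of class `hybrid_graph`: `patients`, `hybrids` (data.frame
#'   `id`/`service`/`doctor`), `edges` (data.frame `patient`/`hybrid` index
#'   into `hybrids`/`weight`).
#' @export
duplicate_annotate <- function(mg) {
  stopifnot(inherits(mg, "patient_multigraph"))
  e <- mg$edges
  hid <- hybrid_id(e$service, e$doctor)
  hybrids <- unique(data.frame(id = hid, service = e$service, doctor = e$doctor))
  hybrids <- hybrids[order(hybrids$id), , drop = FALSE]
  rownames(hybrids) <- NULL
  edges <- data.frame(patient = e$patient,
                      hybrid = match(hid, hybrids$id),
                      weight = e$weight)
  edges <- edges[order(edges$patient, edges$hybrid), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(patients = mg$patients, hybrids = hybrids, edges = edges),
            class = "hybrid_graph")
}

#' @export
print.hybrid_graph <- function(x, ...) {
  cat(sprintf("hybrid_graph: %d patients, %d hybrids, %d edges (total weight %d)\n",
              length(x$patients), nrow(x$hybrids), nrow(x$edges),
              sum(x$edges$weight)))
  invisible(x)
}

#' Write the hybrid vocabulary
#'
#' TSV with columns `hybrid_id`, `service`, `doctor`.
#' @param hg a `hybrid_graph`.
#' @param path output path.
#' @export
write_hybrid_vocab <- function(hg, path) {
  utils::write.table(data.frame(hybrid_id = hg$hybrids$id,
                                service = hg$hybrids$service,
                                doctor = hg$hybrids$doctor),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annotation parameters (hybrid linear map)
#'
#' The hybrid vector is `h = W_a [s || d] + b_a`, a trainable linear map of
#' the concatenated frozen service and doctor vectors.
#'
#' @param p_service service embedding dimension.
#' @param p_doctor doctor embedding dimension.
#' @param p_out hybrid/patient dimension (default 128).
#' @param seed RNG seed for the Gaussian initialization of `W_a`.
#' @return Object of class `annotation_params` with `W_a`
#'   (`p_out x (p_service + p_doctor)`) and `b_a` (length `p_out`).
#' @export
annotation_params <- function(p_service, p_doctor, p_out = 128L, seed = 1L) {
  set.seed(seed)
  p_in <- p_service + p_doctor
  structure(list(W_a = matrix(stats::rnorm(p_out * p_in, sd = 1 / sqrt(p_in)),
                              nrow = p_out),
                 b_a = numeric(p_out)),
            class = "annotation_params")
}

# concatenated [s || d] design matrix, one row per hybrid
hybrid_inputs <- function(hybrids, service_emb, doctor_emb) {
  miss_s <- setdiff(hybrids$service, service_emb$ids)
  miss_d <- setdiff(hybrids$doctor, doctor_emb$ids)
  if (length(miss_s) > 0) stop("missing service vector(s): ",
                               paste(utils::head(miss_s, 5), collapse = ", "))
  if (length(miss_d) > 0) stop("missing doctor vector(s): ",
                               paste(utils::head(miss_d, 5), collapse = ", "))
  cbind(embedding_lookup(service_emb, hybrids$service),
        embedding_lookup(doctor_emb, hybrids$doctor))
}

#' Compute hybrid vectors through the annotation map
#'
#' @param hybrids data.frame with columns `id`, `service`, `doctor` (as in a
#'   `hybrid_graph`).
#' @param service_emb,doctor_emb frozen [embedding_table]s.
#' @param params an [annotation_params].
#' @return An [embedding_table] over hybrid ids.
#' @export
hybrid_vectors <- function(hybrids, service_emb, doctor_emb, params) {
  X <- hybrid_inputs(hybrids, service_emb, doctor_emb)
  H <- X %*% t(params$W_a)
  H <- sweep(H, 2, params$b_a, `+`)
  embedding_table(hybrids$id, H)
}

#' Empirical context distribution of a patient
#'
#' The edge-weight-normalized distribution over the patient's hybrid
#' neighbors: `p_hat(h | patient) = w(patient, h) / sum_l w(patient, l)`.
#'
#' @param graph a `hybrid_graph`.
#' @param patient patient id with >= 1 edge.
#' @return named probability vector over the patient's hybrid ids (sums to 1).
#' @export
empirical_context <- function(graph, patient) {
  sel <- graph$edges$patient == patient
  if (!any(sel)) stop("contract error: patient has no hybrid edges: ", patient)
  w <- graph$edges$weight[sel]
  stats::setNames(w / sum(w), graph$hybrids$id[graph$edges$hybrid[sel]])
}

# empirical distribution matrix (patients x hybrids), rows sum to 1
empirical_matrix <- function(graph) {
  n_p <- length(graph$patients)
  n_h <- nrow(graph$hybrids)
  W <- matrix(0, n_p, n_h, dimnames = list(graph$patients, graph$hybrids$id))
  pi <- match(graph$edges$patient, graph$patients)
  W[cbind(pi, graph$edges$hybrid)] <- graph$edges$weight
  rs <- rowSums(W)
  if (any(rs == 0)) {
    stop("contract error: patient(s) with no hybrid edges: ",
         paste(utils::head(graph$patients[rs == 0], 5), collapse = ", "))
  }
  W / rs
}

#' Exact second-order-proximity loss (full softmax)
#'
#' The weighted sum over edges of the KL divergence between each patient's
#' empirical context distribution and the softmax context probability
#' `p2(h | p) = exp(h . p) / sum_l exp(h_l . p)` over ALL hybrid nodes,
#' reduced to the cross-entropy form
#' `L = -sum_edges p_hat(h|p) log p2(h|p)`. Serves as the brute-force oracle
#' for the sampled trainer.
#'
#' @param graph a `hybrid_graph` (every patient with >= 1 edge).
#' @param patient_emb [embedding_table] over the graph's patients.
#' @param hybrid_emb [embedding_table] over the graph's hybrids (aligned ids).
#' @return non-negative scalar loss.
#' @export
exact_patient_loss <- function(graph, patient_emb, hybrid_emb) {
  P <- embedding_lookup(patient_emb, graph$patients)
  H <- embedding_lookup(hybrid_emb, graph$hybrids$id)
  scores <- P %*% t(H)
  if (!all(is.finite(scores))) stop("non-finite patient-hybrid dot products")
  mx <- apply(scores, 1, max)
  logZ <- mx + log(rowSums(exp(scores - mx)))
  logp <- scores - logZ
  What <- empirical_matrix(graph)
  -sum(What * logp)
}

# loss + full-batch gradients of the exact objective w.r.t. P, W_a, b_a
exact_patient_gradient <- function(graph, P, X, params) {
  H <- X %*% t(params$W_a)
  H <- sweep(H, 2, params$b_a, `+`)
  scores <- P %*% t(H)
  mx <- apply(scores, 1, max)
  logZ <- mx + log(rowSums(exp(scores - mx)))
  Q <- exp(scores - logZ)
  What <- empirical_matrix(graph)
  loss <- -sum(What * (scores - logZ))
  R <- Q - What
  dP <- R %*% H
  dH <- crossprod(R, P)
  list(loss = loss, dP = dP, dW_a = crossprod(dH, X), db_a = colSums(dH))
}

#' Patient-embedding training configuration
#'
#' @param dim patient/hybrid dimension (default 128).
#' @param negatives noise hybrids per positive edge sample (default 10; must
#'   be >= 1 in `"sampled"` mode).
#' @param epochs passes over the edge multiset.
#' @param lr learning rate (Adam in sampled mode; plain gradient descent in
#'   exact mode).
#' @param batch_size edges per sampled mini-batch.
#' @param mode `"sampled"` (negative-sampling approximation of the softmax) or
#'   `"exact"` (full-softmax gradient descent; small graphs only).
#' @param seed integer RNG seed.
#' @export
patient_config <- function(dim = 128L, negatives = 10L, epochs = 5L, lr = 0.01,
                           batch_size = 2048L, mode = c("sampled", "exact"),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "sampled" && negatives < 1) {
    stop("negatives must be >= 1 in sampled mode (objective degenerate)")
  }
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(dim = as.integer(dim), negatives = as.integer(negatives),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), mode = mode,
                 seed = as.integer(seed)),
            class = "patient_config")
}

#' Train patient embeddings on the hybrid bipartite graph
#'
#' Jointly optimizes the patient vectors and the annotation map `(W_a, b_a)`;
#' hybrid vectors are always re-derived from the frozen service and doctor
#' embeddings through the current annotation map, never free parameters. In
#' `"sampled"` mode, edges are sampled proportional to weight and each
#' positive pair is contrasted with `negatives` noise hybrids drawn with
#' probability proportional to weighted degree^0.75
#' (`log sigma(h.p) + sum log sigma(-h_n.p)`), optimized with Adam. In
#' `"exact"` mode, plain full-batch gradient descent on the exact softmax/KL
#' objective is used (the oracle path; small graphs only).
#'
#' @param graph a `hybrid_graph`.
#' @param service_emb,doctor_emb frozen [embedding_table]s covering the
#'   graph's services and doctors.
#' @param config a [patient_config].
#' @param init optional [annotation_params] to start from.
#' @return list of class `patient_fit`: `embeddings` ([embedding_table] over
#'   patients), `params` (trained [annotation_params]), `hybrids`
#'   ([embedding_table] of final hybrid vectors), `loss_history` (exact loss
#'   per epoch in exact mode; mean sampled batch loss per epoch otherwise).
#' @export
train_patient_embeddings <- function(graph, service_emb, doctor_emb,
                                     config = patient_config(), init = NULL) {
  stopifnot(inherits(graph, "hybrid_graph"), inherits(config, "patient_config"))
  n_p <- length(graph$patients)
  n_h <- nrow(graph$hybrids)
  if (n_p == 0 || n_h == 0) stop("empty hybrid graph")
  d <- config$dim
  X <- hybrid_inputs(graph$hybrids, service_emb, doctor_emb)

  set.seed(config$seed)
  P <- matrix(stats::rnorm(n_p * d, sd = 1 / sqrt(d)), nrow = n_p)
  params <- if (is.null(init)) {
    annotation_params(service_emb$dim, doctor_emb$dim, d, seed = config$seed + 1L)
  } else {
    init
  }
  if (nrow(params$W_a) != d || ncol(params$W_a) != ncol(X)) {
    stop("annotation map dimensions do not match embeddings")
  }

  finalize <- function(P, params, history) {
    H <- sweep(X %*% t(params$W_a), 2, params$b_a, `+`)
    structure(list(embeddings = embedding_table(graph$patients, P),
                   params = params,
                   hybrids = embedding_table(graph$hybrids$id, H),
                   loss_history = history),
              class = "patient_fit")
  }
  if (config$epochs == 0) return(finalize(P, params, numeric(0)))

  history <- numeric(config$epochs)
  if (config$mode == "exact") {
    for (ep in seq_len(config$epochs)) {
      g <- exact_patient_gradient(graph, P, X, params)
      history[ep] <- g$loss
      P <- P - config$lr * g$dP
      params$W_a <- params$W_a - config$lr * g$dW_a
      params$b_a <- params$b_a - config$lr * g$db_a
    }
    return(finalize(P, params, history))
  }

  # sampled mode: edge sampling proportional to the patient-NORMALIZED weight
  # (each patient's empirical context distribution carries total mass 1 in the
  # KL objective, so every patient receives equal expected sampling mass)
  pat_tot <- tapply(graph$edges$weight, graph$edges$patient, sum)
  edge_p <- graph$edges$weight / pat_tot[graph$edges$patient]
  edge_p <- edge_p / sum(edge_p)
  deg <- tapply(graph$edges$weight, graph$edges$hybrid, sum)
  noise <- numeric(n_h)
  noise[as.integer(names(deg))] <- as.numeric(deg)^0.75
  noise <- noise / sum(noise)
  pat_idx_all <- match(graph$edges$patient, graph$patients)

  opt_state <- adam_init(list(P = P, W_a = params$W_a, b_a = params$b_a))
  pars <- list(P = P, W_a = params$W_a, b_a = params$b_a)
  n_edges <- nrow(graph$edges)
  sigmoid <- stats::plogis

  for (ep in seq_len(config$epochs)) {
    remaining <- n_edges
    ep_loss <- 0
    n_batches <- 0L
    while (remaining > 0) {
      bs <- min(config$batch_size, remaining)
      remaining <- remaining - bs
      e_idx <- sample.int(n_edges, bs, replace = TRUE, prob = edge_p)
      pk <- pat_idx_all[e_idx]
      hp <- graph$edges$hybrid[e_idx]
      hn <- matrix(sample.int(n_h, bs * config$negatives, replace = TRUE,
                              prob = noise), nrow = bs)

      H <- sweep(X %*% t(pars$W_a), 2, pars$b_a, `+`)
      Pm <- pars$P[pk, , drop = FALSE]
      Hp <- H[hp, , drop = FALSE]
      s_pos <- sigmoid(rowSums(Pm * Hp))
      pk_rep <- rep(pk, times = config$negatives)
      hn_vec <- as.vector(hn)
      Pn <- pars$P[pk_rep, , drop = FALSE]
      Hn <- H[hn_vec, , drop = FALSE]
      s_neg <- sigmoid(rowSums(Pn * Hn))

      ep_loss <- ep_loss +
        (-sum(log(pmax(s_pos, 1e-12))) - sum(log(pmax(1 - s_neg, 1e-12)))) / bs
      n_batches <- n_batches + 1L

      gp <- -(1 - s_pos)       # d/d(score) of -log sigma(score)
      gn <- s_neg              # d/d(score) of -log sigma(-score)
      dP_rows <- rowsum(rbind(gp * Hp, gn * Hn), group = c(pk, pk_rep))
      dP <- matrix(0, n_p, d)
      dP[as.integer(rownames(dP_rows)), ] <- as.matrix(dP_rows) / bs
      dH_rows <- rowsum(rbind(gp * Pm, gn * Pn), group = c(hp, hn_vec))
      hid_u <- as.integer(rownames(dH_rows))
      dW_a <- crossprod(as.matrix(dH_rows), X[hid_u, , drop = FALSE]) / bs
      db_a <- colSums(dH_rows) / bs

      step <- adam_step(pars, list(P = dP, W_a = dW_a, b_a = db_a),
                        opt_state, config$lr)
      pars <- step$params
      opt_state <- step$state
    }
    history[ep] <- ep_loss / max(n_batches, 1L)
  }
  params$W_a <- pars$W_a
  params$b_a <- pars$b_a
  finalize(pars$P, params, history)
}
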