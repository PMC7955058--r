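# shared fixtures, built in code

# quick journey table from parallel vectors
jt <- function(patient, doctor, service, date, specialty = "SPX") {
  n <- max(length(patient), length(doctor), length(service), length(date))
  journey_table(data.frame(
    patient_id = rep_len(patient, n), doctor_id = rep_len(doctor, n),
    specialty = rep_len(specialty, n), service_code = rep_len(service, n),
    date = rep_len(date, n)))
}

# random small patient-service-doctor multigraph (as a journey table)
random_multigraph_journeys <- function(seed, n_pat = 6, n_svc = 8, n_doc = 4,
                                       n_rows = 40) {
  set.seed(seed)
  journey_table(data.frame(
    patient_id = sprintf("p%d", sample.int(n_pat, n_rows, TRUE)),
    doctor_id = sprintf("d%d", sample.int(n_doc, n_rows, TRUE)),
    specialty = "SPX",
    service_code = sprintf("s%d", sample.int(n_svc, n_rows, TRUE)),
    date = sample.int(30, n_rows, TRUE) - 1L))
}

# co-occurrence graph directly from a symmetric adjacency matrix
cg <- function(A, T_window = 8L) {
  stopifnot(identical(A, t(A)))
  structure(list(services = rownames(A), adjacency = A,
                 window_T = as.integer(T_window)),
            class = "cooccurrence_graph")
}

adj <- function(names, edges) {
  # edges: list of c(a, b, w)
  A <- matrix(0, length(names), length(names), dimnames = list(names, names))
  for (e in edges) {
    A[e[1], e[2]] <- as.numeric(e[3])
    A[e[2], e[1]] <- as.numeric(e[3])
  }
  A
}

# independently coded double-loop oracle for the exact patient loss:
# plain loops and scalar exp, no shared code with the package internals
oracle_patient_loss <- function(graph, patient_emb, hybrid_emb) {
  total <- 0
  for (pk in graph$patients) {
    sel <- which(graph$edges$patient == pk)
    p_vec <- patient_emb$vectors[match(pk, patient_emb$ids), ]
    denom <- 0
    for (l in seq_len(nrow(graph$hybrids))) {
      h_vec <- hybrid_emb$vectors[match(graph$hybrids$id[l], hybrid_emb$ids), ]
      denom <- denom + exp(sum(h_vec * p_vec))
    }
    w_tot <- sum(graph$edges$weight[sel])
    for (e in sel) {
      h_id <- graph$hybrids$id[graph$edges$hybrid[e]]
      h_vec <- hybrid_emb$vectors[match(h_id, hybrid_emb$ids), ]
      p2 <- exp(sum(h_vec * p_vec)) / denom
      total <- total - (graph$edges$weight[e] / w_tot) * log(p2)
    }
  }
  total
}

# hybrid graph with random embeddings of dimension d, for loss oracles
random_hybrid_setup <- function(seed, n_pat = 3, n_svc = 4, n_doc = 3, d = 5,
                                n_rows = 15) {
  journeys <- random_multigraph_journeys(seed, n_pat, n_svc, n_doc, n_rows)
  hg <- duplicate_annotate(build_patient_multigraph(journeys))
  set.seed(seed + 1000)
  pe <- embedding_table(hg$patients,
                        matrix(rnorm(length(hg$patients) * d, sd = 0.5),
                               ncol = d))
  he <- embedding_table(hg$hybrids$id,
                        matrix(rnorm(nrow(hg$hybrids) * d, sd = 0.5), ncol = d))
  list(graph = hg, patient_emb = pe, hybrid_emb = he)
}

# block-structured one-hot-ish service embedding: services in block g point
# along axis g (plus small noise), mimicking a trained, well-separated
# service embedding without running SGNS
block_service_embedding <- function(services, block, dim = 16, seed = 1) {
  set.seed(seed)
  V <- matrix(rnorm(length(services) * dim, sd = 0.05), ncol = dim)
  for (i in seq_along(services)) V[i, block[i]] <- V[i, block[i]] + 1
  embedding_table(services, V)
}

# planted doctor-service world: doctors draw services from their specialty's
# block; returns journeys plus the specialty truth
planted_doctor_world <- function(n_doc = 60, n_spec = 5, svc_per_block = 8,
                                 rows_per_doc = 40, seed = 1) {
  set.seed(seed)
  services <- sprintf("s%02d", seq_len(n_spec * svc_per_block))
  block <- rep(seq_len(n_spec), each = svc_per_block)
  specialty <- sprintf("SP%d", rep_len(seq_len(n_spec), n_doc))
  rows <- lapply(seq_len(n_doc), function(j) {
    own <- services[block == as.integer(sub("SP", "", specialty[j]))]
    svc <- ifelse(runif(rows_per_doc) < 0.85,
                  sample(own, rows_per_doc, TRUE),
                  sample(services, rows_per_doc, TRUE))
    data.frame(patient_id = sprintf("p%d", sample.int(50, rows_per_doc, TRUE)),
               doctor_id = sprintf("d%02d", j), specialty = specialty[j],
               service_code = svc, date = sample.int(60, rows_per_doc, TRUE) - 1L)
  })
  list(journeys = journey_table(do.call(rbind, rows)),
       services = services, block = block,
       specialty = stats::setNames(specialty, sprintf("d%02d", seq_len(n_doc))))
}

# multinomial goodness-of-fit p-value with sparse tail binned (expected < 5)
gof_pvalue <- function(obs, p) {
  n <- sum(obs)
  keep <- n * p >= 5
  if (any(!keep)) {
    x <- c(as.numeric(obs[keep]), sum(obs[!keep]))
    pp <- c(p[keep], sum(p[!keep]))
  } else {
    x <- as.numeric(obs)
    pp <- as.numeric(p)
  }
  stats::chisq.test(x, p = pp, rescale.p = TRUE)$p.value
}

mean_cosine_split <- function(vectors, groups) {
  V <- vectors / sqrt(rowSums(vectors^2))
  S <- V %*% t(V)
  same <- outer(groups, groups, "==")
  diag(S) <- NA
  c(within = mean(S[same], na.rm = TRUE), between = mean(S[!same], na.rm = TRUE))
}
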