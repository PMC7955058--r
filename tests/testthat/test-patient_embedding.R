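test_that("patient multigraph counts (patient, service, doctor) rows", {
  j <- journey_table(data.frame(
    patient_id = "p1", doctor_id = c("d1", "d1", "d2"),
    specialty = "x", service_code = "sA", date = 0:2))
  mg <- build_patient_multigraph(j)
  expect_equal(nrow(mg$edges), 2L)
  expect_equal(mg$edges$weight[mg$edges$doctor == "d1"], 2L)
  expect_equal(mg$edges$weight[mg$edges$doctor == "d2"], 1L)
  expect_equal(sum(mg$edges$weight), nrow(j$records))

  one <- build_patient_multigraph(jt("p1", "d1", "sA", 0))
  expect_equal(one$edges$weight, 1L)
})

test_that("duplication & annotation reproduces the worked toy example", {
  # ECG administered to two patients by two different doctors -> two ECG
  # hybrids; the gene service twice via the same doctor -> one hybrid
  j <- journey_table(data.frame(
    patient_id = c("p1", "p2", "p1", "p2"),
    doctor_id = c("dA", "dB", "dC", "dC"),
    specialty = "x",
    service_code = c("ECG", "ECG", "gene", "gene"),
    date = c(0L, 0L, 1L, 1L)))
  hg <- duplicate_annotate(build_patient_multigraph(j))
  expect_equal(sum(hg$hybrids$service == "ECG"), 2L)
  expect_equal(sum(hg$hybrids$service == "gene"), 1L)
  expect_equal(sum(hg$edges$weight), 4L)  # weight conserved

  # a service always administered by one doctor is never duplicated
  j2 <- random_multigraph_journeys(5, n_doc = 1)
  hg2 <- duplicate_annotate(build_patient_multigraph(j2))
  expect_equal(nrow(hg2$hybrids), length(j2$services))
})

test_that("duplicate_annotate matches brute force on random multigraphs", {
  for (seed in 1:10) {
    j <- random_multigraph_journeys(seed, n_pat = 10, n_svc = 8, n_doc = 4,
                                    n_rows = 60)
    mg <- build_patient_multigraph(j)
    hg <- duplicate_annotate(mg)
    # brute force over raw journey rows
    rec <- j$records
    expect_equal(nrow(hg$hybrids),
                 nrow(unique(rec[c("service_code", "doctor_id")])))
    expect_equal(sum(hg$edges$weight), nrow(rec))
    # simplicity: at most one edge per (patient, hybrid)
    expect_false(anyDuplicated(hg$edges[c("patient", "hybrid")]) > 0)
  }
})

test_that("hybrid vectors are the linear map of concatenated embeddings", {
  semb <- embedding_table(c("s1", "s2"), rbind(c(1, 2), c(3, 4)))
  demb <- embedding_table(c("d1", "d2"), rbind(c(5, 6), c(7, 8)))
  hybrids <- data.frame(id = c("s1|d2", "s2|d1"),
                        service = c("s1", "s2"), doctor = c("d2", "d1"))

  # projection [I | 0] with zero offset recovers the service vector
  proj <- structure(list(W_a = cbind(diag(2), matrix(0, 2, 2)),
                         b_a = c(0, 0)), class = "annotation_params")
  h <- hybrid_vectors(hybrids, semb, demb, proj)
  expect_equal(unname(h$vectors), rbind(c(1, 2), c(3, 4)))

  # zero map: every hybrid equals the offset
  off <- structure(list(W_a = matrix(0, 3, 4), b_a = c(9, -1, 2)),
                   class = "annotation_params")
  h0 <- hybrid_vectors(hybrids, semb, demb, off)
  expect_equal(unname(h0$vectors), rbind(c(9, -1, 2), c(9, -1, 2)))

  # random map matches independent matrix arithmetic
  set.seed(4)
  ap <- annotation_params(2, 2, p_out = 3, seed = 11)
  hr <- hybrid_vectors(hybrids, semb, demb, ap)
  x1 <- c(1, 2, 7, 8)  # [s1 || d2]
  expect_equal(unname(hr$vectors[1, ]), drop(ap$W_a %*% x1 + ap$b_a))

  expect_error(hybrid_vectors(hybrids, embedding_table("s1", matrix(0, 1, 2)),
                              demb, ap), "s2")
})

test_that("empirical context distributions follow the edge weights", {
  j <- journey_table(data.frame(
    patient_id = "p1", doctor_id = "d1", specialty = "x",
    service_code = c("a", "b", "b", "c", "c", "c"), date = 0L))
  hg <- duplicate_annotate(build_patient_multigraph(j))
  pr <- empirical_context(hg, "p1")
  expect_equal(sort(unname(pr)), c(1 / 6, 1 / 3, 1 / 2), tolerance = 1e-12)
  expect_lt(abs(sum(pr) - 1), 1e-12)

  single <- duplicate_annotate(build_patient_multigraph(jt("p1", "d1", "a", 0)))
  expect_equal(unname(empirical_context(single, "p1")), 1)
  expect_error(empirical_context(hg, "ghost"), "no hybrid edges")

  even <- duplicate_annotate(build_patient_multigraph(
    jt("p1", c("d1", "d2"), c("a", "a"), c(0, 0))))
  expect_equal(unname(empirical_context(even, "p1")), c(0.5, 0.5))
})

test_that("exact loss matches closed forms and the double-loop oracle", {
  # all-zero embeddings: uniform softmax, loss = n_patients * log n_hybrids
  s <- random_hybrid_setup(1)
  zero_p <- embedding_table(s$graph$patients,
                            matrix(0, length(s$graph$patients), 5))
  zero_h <- embedding_table(s$graph$hybrids$id,
                            matrix(0, nrow(s$graph$hybrids), 5))
  expect_equal(exact_patient_loss(s$graph, zero_p, zero_h),
               length(s$graph$patients) * log(nrow(s$graph$hybrids)),
               tolerance = 1e-12)

  # one patient, one hybrid: p2 = 1, loss = 0
  one <- duplicate_annotate(build_patient_multigraph(jt("p1", "d1", "a", 0)))
  expect_equal(exact_patient_loss(
    one, embedding_table("p1", matrix(2, 1, 1)),
    embedding_table(one$hybrids$id, matrix(3, 1, 1))), 0)

  for (seed in 1:6) {
    s <- random_hybrid_setup(seed)
    expect_equal(exact_patient_loss(s$graph, s$patient_emb, s$hybrid_emb),
                 oracle_patient_loss(s$graph, s$patient_emb, s$hybrid_emb),
                 tolerance = 1e-9)
  }
})

test_that("exact loss respects the entropy lower bound", {
  for (seed in 1:5) {
    s <- random_hybrid_setup(seed, n_pat = 4, n_svc = 5, d = 6, n_rows = 20)
    ent <- sum(vapply(s$graph$patients, function(pk) {
      w <- empirical_context(s$graph, pk)
      -sum(w * log(w))
    }, numeric(1)))
    expect_gte(exact_patient_loss(s$graph, s$patient_emb, s$hybrid_emb),
               ent - 1e-9)
  }
})

test_that("exact-mode full-batch descent decreases the loss monotonically", {
  s <- random_hybrid_setup(3, n_pat = 3, n_svc = 3, n_doc = 2, d = 4, n_rows = 12)
  semb <- embedding_table(sprintf("s%d", 1:3), matrix(rnorm(3 * 4), 3) * 0.3)
  demb <- embedding_table(sprintf("d%d", 1:2), matrix(rnorm(2 * 4), 2) * 0.3)
  fit <- train_patient_embeddings(s$graph, semb, demb,
                                  patient_config(dim = 4, epochs = 25,
                                                 lr = 0.02, mode = "exact",
                                                 negatives = 1, seed = 5))
  expect_true(all(diff(fit$loss_history) <= 1e-10))
})

test_that("sampled training recovers planted two-block structure", {
  # patients split over disjoint doctor/service blocks
  set.seed(20)
  rows <- do.call(rbind, lapply(1:20, function(i) {
    blk <- if (i <= 10) 1 else 2
    svc <- sprintf("s%d", (blk - 1) * 4 + sample.int(4, 12, TRUE))
    doc <- sprintf("d%d", (blk - 1) * 2 + sample.int(2, 12, TRUE))
    data.frame(patient_id = sprintf("p%02d", i), doctor_id = doc,
               specialty = "x", service_code = svc, date = 0:11)
  }))
  j <- journey_table(rows)
  hg <- duplicate_annotate(build_patient_multigraph(j))
  semb <- block_service_embedding(sprintf("s%d", 1:8), rep(1:2, each = 4),
                                  dim = 8, seed = 1)
  demb <- block_service_embedding(sprintf("d%d", 1:4), rep(1:2, each = 2),
                                  dim = 8, seed = 2)
  fit <- train_patient_embeddings(hg, semb, demb,
                                  patient_config(dim = 8, epochs = 40,
                                                 batch_size = 64, seed = 9))
  cs <- mean_cosine_split(fit$embeddings$vectors,
                          rep(1:2, each = 10))
  expect_gt(cs["within"], cs["between"])
})

test_that("patients sharing doctor+service are most similar, sharing nothing least", {
  # three patient pairs: same service + same doctor (a); same service via
  # different doctors (b); nothing shared (c). Doctor embeddings are derived
  # from their administered services (weighted-average initialization), as in
  # the hierarchy, so the two mri doctors are similar but not identical.
  rows <- data.frame(
    patient_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    doctor_id  = c("dS", "dS", "dX", "dY", "dZ", "dW"),
    specialty = "x",
    service_code = c("ecg", "ecg", "mri", "mri", "lab", "gene"),
    date = 0L)
  # each doctor also administers a distinguishing filler service
  filler <- data.frame(
    patient_id = sprintf("f%d", 1:5),
    doctor_id = c("dS", "dX", "dY", "dZ", "dW"),
    specialty = "x",
    service_code = c("f_s", "f_x", "f_y", "f_z", "f_w"),
    date = 1L)
  j <- journey_table(rbind(rows, filler))
  hg <- duplicate_annotate(build_patient_multigraph(j))
  svc <- sort(unique(j$records$service_code))
  set.seed(3)
  semb <- embedding_table(svc, matrix(rnorm(length(svc) * 8), ncol = 8))
  demb <- init_doctor_vectors(build_doctor_service_graph(j), semb)
  fit <- train_patient_embeddings(hg, semb, demb,
                                  patient_config(dim = 8, epochs = 150,
                                                 lr = 0.05, mode = "exact",
                                                 negatives = 1, seed = 8))
  V <- fit$embeddings$vectors
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  id <- fit$embeddings$ids
  sim <- function(a, b) cosine(V[match(a, id), ], V[match(b, id), ])
  expect_gt(sim("a1", "a2"), sim("b1", "b2"))
  expect_gt(sim("b1", "b2"), sim("c1", "c2"))
})

test_that("zero epochs returns the seeded initialization; config validates", {
  s <- random_hybrid_setup(2)
  semb <- embedding_table(sprintf("s%d", 1:4), matrix(rnorm(4 * 5), 4))
  demb <- embedding_table(sprintf("d%d", 1:3), matrix(rnorm(3 * 5), 3))
  a <- train_patient_embeddings(s$graph, semb, demb,
                                patient_config(dim = 5, epochs = 0, seed = 7))
  b <- train_patient_embeddings(s$graph, semb, demb,
                                patient_config(dim = 5, epochs = 0, seed = 7))
  expect_identical(a$embeddings$vectors, b$embeddings$vectors)
  trained <- train_patient_embeddings(s$graph, semb, demb,
                                      patient_config(dim = 5, epochs = 2,
                                                     batch_size = 8, seed = 7))
  expect_false(identical(a$embeddings$vectors, trained$embeddings$vectors))

  expect_error(patient_config(negatives = 0), "degenerate")
  expect_error(patient_config(negatives = 0, mode = "exact"), NA)
})

test_that("mean sampled gradient aligns with the exact KL gradient", {
  # Monte-Carlo consistency in the estimator's valid regime: small scores and
  # degree-balanced noise with one negative per positive, where the expected
  # contrastive gradient is proportional to the exact softmax/KL gradient
  set.seed(15)
  rows <- data.frame(patient_id = rep(sprintf("p%d", 1:3), each = 4),
                     doctor_id = "d1", specialty = "x",
                     service_code = sprintf("s%d", c(1, 2, 3, 4, 2, 3, 4, 5,
                                                     3, 4, 5, 6)),
                     date = 0L)
  hg <- duplicate_annotate(build_patient_multigraph(journey_table(rows)))
  n_h <- nrow(hg$hybrids)
  d <- 6
  P <- matrix(rnorm(3 * d, sd = 0.15), 3)
  H <- matrix(rnorm(n_h * d, sd = 0.15), n_h)
  X <- H  # identity annotation for the check
  params <- structure(list(W_a = diag(d), b_a = numeric(d)),
                      class = "annotation_params")
  exact <- me2vec:::exact_patient_gradient(hg, P, X, params)

  # expected sampled gradient, computed analytically over edge and noise draws
  sig <- stats::plogis
  W_hat <- me2vec:::empirical_matrix(hg)
  S <- P %*% t(H)
  dP_mc <- matrix(0, 3, d)
  for (k in 1:3) {
    for (h in seq_len(n_h)) {
      if (W_hat[k, h] > 0) {
        dP_mc[k, ] <- dP_mc[k, ] - W_hat[k, h] * (1 - sig(S[k, h])) * H[h, ]
      }
    }
    # one negative per positive, uniform over hybrids
    dP_mc[k, ] <- dP_mc[k, ] + colSums((1 / n_h) * sig(S[k, ]) * H)
  }
  angle <- function(a, b) {
    acos(min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
  }
  expect_lt(angle(as.vector(dP_mc), as.vector(exact$dP)), 15)
})
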