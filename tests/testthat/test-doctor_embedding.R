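test_that("doctor-service graph counts edges and resolves specialties", {
  j <- journey_table(data.frame(
    patient_id = "p1", doctor_id = c("d1", "d1", "d1"),
    specialty = c("onc", "onc", "card"),
    service_code = c("sA", "sA", "sB"), date = 0:2))
  g <- build_doctor_service_graph(j)
  expect_equal(g$edges$weight[g$edges$service == "sA"], 2L)
  expect_equal(g$edges$weight[g$edges$service == "sB"], 1L)
  expect_equal(unname(g$specialty["d1"]), "onc")  # 2:1 majority

  # specialty tie broken lexicographically
  j2 <- journey_table(data.frame(
    patient_id = "p1", doctor_id = "d9", specialty = c("zed", "abc"),
    service_code = c("s1", "s2"), date = 0:1))
  expect_equal(unname(build_doctor_service_graph(j2)$specialty["d9"]), "abc")

  empty <- build_doctor_service_graph(journey_table(data.frame(
    patient_id = character(0), doctor_id = character(0),
    specialty = character(0), service_code = character(0), date = integer(0))))
  expect_length(empty$doctors, 0)
})

test_that("doctor initialization is the weighted service average", {
  semb <- embedding_table(c("s1", "s2"), rbind(c(1, 0, 2), c(3, 4, 0)))
  g1 <- build_doctor_service_graph(jt("p", "d1", "s1", 0, specialty = "onc"))
  expect_equal(unname(init_doctor_vectors(g1, semb)$vectors[1, ]), c(1, 0, 2))

  j <- journey_table(data.frame(
    patient_id = "p", doctor_id = "d1", specialty = "onc",
    service_code = c("s1", "s2", "s2", "s2"), date = 0:3))
  g <- build_doctor_service_graph(j)  # weights (1, 3)
  expect_equal(unname(init_doctor_vectors(g, semb)$vectors[1, ]),
               (c(1, 0, 2) + 3 * c(3, 4, 0)) / 4)

  jeq <- journey_table(data.frame(
    patient_id = "p", doctor_id = "d1", specialty = "onc",
    service_code = c("s1", "s2"), date = 0:1))
  expect_equal(unname(init_doctor_vectors(build_doctor_service_graph(jeq),
                                          semb)$vectors[1, ]),
               (c(1, 0, 2) + c(3, 4, 0)) / 2)

  # init invariant under weight rescaling (duplicate every row)
  jx2 <- journey_table(rbind(j$records, j$records))
  expect_equal(init_doctor_vectors(build_doctor_service_graph(jx2), semb)$vectors,
               init_doctor_vectors(g, semb)$vectors)

  expect_error(init_doctor_vectors(g, embedding_table("s1", matrix(0, 1, 3))),
               "s2")
})

test_that("attention matches the hand-evaluated logit/softmax rule", {
  # p = p' = 1, K = 1, W = [1], a = [1, 1], d = 0, s = (1, -1):
  # e = LeakyReLU(1) = 1 and LeakyReLU(-1) = -0.2; alpha = softmax(1, -0.2)
  params <- me2vec:::gat_init_params(1, 1, 1, 2, 0.2, "elu", seed = 1)
  params$W[[1]] <- matrix(1, 1, 1)
  params$a1[[1]] <- 1
  params$a2[[1]] <- 1
  fwd <- attention_forward(0, matrix(c(1, -1), ncol = 1), params)
  expect_equal(unname(fwd$alpha[1, ]),
               exp(c(1, -0.2)) / sum(exp(c(1, -0.2))), tolerance = 1e-12)

  # single neighbor: alpha = 1 for every head, any params
  params4 <- me2vec:::gat_init_params(8, 2, 4, 3, 0.2, "elu", seed = 2)
  fwd1 <- attention_forward(rnorm(8), matrix(rnorm(8), 1), params4)
  expect_equal(unname(fwd1$alpha), matrix(1, 4, 1))

  # n identical neighbors: alpha = 1/n each
  s <- matrix(rep(rnorm(8), 5), nrow = 5, byrow = TRUE)
  fwd5 <- attention_forward(rnorm(8), s, params4)
  expect_equal(unname(fwd5$alpha), matrix(0.2, 4, 5), tolerance = 1e-12)
})

test_that("attention rows always normalize to one", {
  set.seed(31)
  params <- me2vec:::gat_init_params(12, 3, 4, 5, 0.2, "elu", seed = 3)
  for (i in 1:25) {
    n <- sample(1:10, 1)
    fwd <- attention_forward(rnorm(12), matrix(rnorm(n * 12), n), params)
    expect_true(all(abs(rowSums(fwd$alpha) - 1) <= 1e-6))
    expect_length(fwd$dprime, 12)
  }
})

test_that("GAT backprop gradients match numerical differentiation", {
  set.seed(8)
  p <- 6; K <- 2
  S <- matrix(rnorm(3 * p), 3)
  d_vec <- rnorm(p)
  params <- me2vec:::gat_init_params(p, p / K, K, 3, 0.2, "elu", seed = 4)
  grads <- me2vec:::gat_zero_grads(params)
  fb <- me2vec:::gat_forward_backward(d_vec, S, 2L, params, grads)
  loss_at <- function(pars) me2vec:::gat_forward_backward(d_vec, S, 2L, pars)$loss
  eps <- 1e-5
  central <- function(bump) {
    (loss_at(bump(params, eps)) - loss_at(bump(params, -eps))) / (2 * eps)
  }
  check <- function(analytic, numeric) {
    expect_lt(abs(analytic - numeric), 1e-6 + 1e-4 * abs(numeric))
  }
  # spot-check a handful of coordinates in each parameter block
  for (k in 1:K) {
    for (idx in list(c(1, 1), c(2, 3))) {
      num <- central(function(p_, e) {
        p_$W[[k]][idx[1], idx[2]] <- p_$W[[k]][idx[1], idx[2]] + e; p_
      })
      check(fb$grads$W[[k]][idx[1], idx[2]], num)
    }
    check(fb$grads$a1[[k]][1],
          central(function(p_, e) { p_$a1[[k]][1] <- p_$a1[[k]][1] + e; p_ }))
    check(fb$grads$a2[[k]][2],
          central(function(p_, e) { p_$a2[[k]][2] <- p_$a2[[k]][2] + e; p_ }))
  }
  check(fb$grads$C[2, 3],
        central(function(p_, e) { p_$C[2, 3] <- p_$C[2, 3] + e; p_ }))
  check(fb$grads$b[1],
        central(function(p_, e) { p_$b[1] <- p_$b[1] + e; p_ }))
})

test_that("planted specialties are recovered with held-out accuracy >= 0.9", {
  world <- planted_doctor_world(n_doc = 60, n_spec = 5, seed = 10)
  semb <- block_service_embedding(world$services, world$block, dim = 20, seed = 2)
  g <- build_doctor_service_graph(world$journeys)
  fit <- train_gat(g, semb, gat_config(K = 4, epochs = 80, seed = 6))
  expect_gte(fit$report$val_accuracy, 0.9)

  # trained embeddings cluster by specialty
  cs <- mean_cosine_split(fit$embeddings$vectors,
                          world$specialty[fit$embeddings$ids])
  expect_gt(cs["within"], cs["between"])
})

test_that("zero-epoch training returns the forward pass at init params", {
  world <- planted_doctor_world(n_doc = 12, n_spec = 3, seed = 3)
  semb <- block_service_embedding(world$services, world$block, dim = 12, seed = 5)
  g <- build_doctor_service_graph(world$journeys)
  cfg <- gat_config(K = 4, epochs = 0, seed = 9)
  fit <- train_gat(g, semb, cfg)

  init <- init_doctor_vectors(g, semb)
  params <- me2vec:::gat_init_params(12, 3, 4, 3, cfg$leaky_slope,
                                     cfg$activation, cfg$seed)
  manual <- t(vapply(g$doctors, function(d) {
    nb <- g$edges$service[g$edges$doctor == d]
    attention_forward(init$vectors[match(d, init$ids), ],
                      embedding_lookup(semb, nb), params)$dprime
  }, numeric(12)))
  expect_equal(unname(fit$embeddings$vectors), unname(manual), tolerance = 1e-12)
})

test_that("training preconditions: single class and unknown specialties", {
  j <- jt(c("p1", "p2"), c("d1", "d2"), c("s1", "s2"), c(0, 0), specialty = "onc")
  semb <- embedding_table(c("s1", "s2"), matrix(rnorm(8), 2))
  expect_error(train_gat(build_doctor_service_graph(j), semb,
                         gat_config(K = 2, epochs = 1)),
               "degenerate")

  # UNKNOWN doctors embedded but excluded from the task
  world <- planted_doctor_world(n_doc = 12, n_spec = 3, seed = 3)
  rec <- world$journeys$records
  rec$specialty[rec$doctor_id == "d01"] <- "UNKNOWN"
  semb <- block_service_embedding(world$services, world$block, dim = 12, seed = 5)
  fit <- train_gat(build_doctor_service_graph(journey_table(rec)), semb,
                   gat_config(K = 4, epochs = 5, seed = 2, val_fraction = 0))
  expect_true("d01" %in% fit$embeddings$ids)
  expect_false("UNKNOWN" %in% fit$params$classes)
})

test_that("specialty imputation is scale-invariant and normalized", {
  world <- planted_doctor_world(n_doc = 30, n_spec = 3, seed = 12)
  semb <- block_service_embedding(world$services, world$block, dim = 12, seed = 7)
  fit <- train_gat(build_doctor_service_graph(world$journeys), semb,
                   gat_config(K = 4, epochs = 60, seed = 8))
  # a doctor drawing purely from block 2's services
  edges <- data.frame(service = world$services[world$block == 2][1:4],
                      weight = c(3, 1, 2, 5))
  out <- impute_specialty(edges, semb, fit$params)
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
  expect_equal(out$specialty, "SP2")
  expect_gt(max(out$probabilities), 0.5)

  edges2 <- edges; edges2$weight <- edges$weight * 2
  out2 <- impute_specialty(edges2, semb, fit$params)
  expect_equal(out$probabilities, out2$probabilities, tolerance = 1e-12)

  expect_error(impute_specialty(data.frame(service = "nope", weight = 1),
                                semb, fit$params), "nope")
})
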