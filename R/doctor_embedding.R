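#' Build the weighted doctor-service bipartite graph
#'
#' Edge weight is the number of journey rows pairing the doctor with the
#' service. Each doctor's primary specialty is the majority specialty over the
#' doctor's rows (ties broken lexicographically); the sentinel `"UNKNOWN"`
#' marks doctors with no recorded specialty.
#'
#' @param journeys a [journey_table].
#' @return Object of class `doctor_service_graph`: `doctors`, `services`,
#'   `edges` (data.frame doctor/service/weight), `specialty` (named map).
#' @export
build_doctor_service_graph <- function(journeys) {
  stopifnot(inherits(journeys, "journey_table"))
  rec <- journeys$records
  if (nrow(rec) == 0) {
    return(structure(list(doctors = character(0), services = character(0),
                          edges = data.frame(doctor = character(0),
                                             service = character(0),
                                             weight = integer(0)),
                          specialty = stats::setNames(character(0), character(0))),
                     class = "doctor_service_graph"))
  }
  agg <- stats::aggregate(list(weight = rep(1L, nrow(rec))),
                          by = list(doctor = rec$doctor_id,
                                    service = rec$service_code), FUN = sum)
  agg <- agg[order(agg$doctor, agg$service), , drop = FALSE]
  rownames(agg) <- NULL
  specialty <- vapply(split(rec$specialty, rec$doctor_id), function(sp) {
    tab <- sort(table(sp), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1]
  }, character(1))
  structure(list(doctors = sort(unique(agg$doctor)),
                 services = sort(unique(agg$service)),
                 edges = agg, specialty = specialty),
            class = "doctor_service_graph")
}

#' Initialize doctor vectors as weighted averages of service vectors
#'
#' `d_j = sum_i w_ij s_i / sum_i w_ij` over the services doctor `j`
#' administered, so the initialization is invariant to rescaling all weights.
#'
#' @param graph a `doctor_service_graph`.
#' @param service_emb an [embedding_table] covering every service in `graph`.
#' @return An [embedding_table] over doctors.
#' @export
init_doctor_vectors <- function(graph, service_emb) {
  stopifnot(inherits(graph, "doctor_service_graph"),
            inherits(service_emb, "embedding_table"))
  missing <- setdiff(graph$services, service_emb$ids)
  if (length(missing) > 0) {
    stop("service(s) missing from embedding table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  vec <- matrix(0, nrow = length(graph$doctors), ncol = service_emb$dim)
  by_doc <- split(graph$edges[c("service", "weight")], graph$edges$doctor)
  for (j in seq_along(graph$doctors)) {
    e <- by_doc[[graph$doctors[j]]]
    S <- embedding_lookup(service_emb, e$service)
    vec[j, ] <- colSums(e$weight * S) / sum(e$weight)
  }
  embedding_table(graph$doctors, vec)
}

#' GAT training configuration
#'
#' @param K number of attention heads (default 4). The per-head dimension is
#'   `p / K` so the concatenated output keeps the input dimension `p`.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param val_fraction fraction of labeled doctors held out (stratified) for
#'   early stopping and reporting.
#' @param patience epochs without validation improvement before stopping.
#' @param leaky_slope negative slope of the LeakyReLU in the attention logit
#'   (0.2).
#' @param activation head output nonlinearity, `"elu"` (default) or
#'   `"sigmoid"`.
#' @param seed integer RNG seed.
#' @export
gat_config <- function(K = 4L, epochs = 150L, lr = 0.01, val_fraction = 0.1,
                       patience = 10L, leaky_slope = 0.2,
                       activation = c("elu", "sigmoid"), seed = 1L) {
  activation <- match.arg(activation)
  if (K < 1) stop("K must be >= 1")
  structure(list(K = as.integer(K), epochs = as.integer(epochs), lr = lr,
                 val_fraction = val_fraction, patience = as.integer(patience),
                 leaky_slope = leaky_slope, activation = activation,
                 seed = as.integer(seed)),
            class = "gat_config")
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

gat_init_params <- function(p, p_prime, K, n_classes, leaky_slope, activation,
                            seed) {
  set.seed(seed)
  W <- lapply(seq_len(K), function(k) {
    matrix(stats::rnorm(p_prime * p, sd = 1 / sqrt(p)), nrow = p_prime)
  })
  a1 <- lapply(seq_len(K), function(k) stats::rnorm(p_prime, sd = 0.1))
  a2 <- lapply(seq_len(K), function(k) stats::rnorm(p_prime, sd = 0.1))
  C <- matrix(stats::rnorm(n_classes * K * p_prime, sd = 1 / sqrt(K * p_prime)),
              nrow = n_classes)
  b <- numeric(n_classes)
  structure(list(W = W, a1 = a1, a2 = a2, C = C, b = b, K = K, p = p,
                 p_prime = p_prime, leaky_slope = leaky_slope,
                 activation = activation, classes = NULL),
            class = "gat_params")
}

#' Single-layer multi-head graph-attention forward pass
#'
#' For head `k`, the attention logit of neighbor service `i` is
#' `e_i = LeakyReLU(a1' W d + a2' W s_i)` (the concatenation form
#' `a' [W d || W s_i]` with `a = [a1; a2]`), normalized by a softmax over the
#' doctor's service neighborhood; the head output is
#' `sigma(sum_i alpha_i W s_i)` and the updated doctor vector is the
#' concatenation over heads.
#'
#' @param d_vec doctor query vector of length `p`.
#' @param neighbors numeric matrix (n x p) of neighbor service vectors, n >= 1.
#' @param params a `gat_params` (from [train_gat] or internal init).
#' @return list with `dprime` (length `K * p_prime`) and `alpha`
#'   (K x n matrix; each row sums to 1).
#' @export
attention_forward <- function(d_vec, neighbors, params) {
  neighbors <- as.matrix(neighbors)
  n <- nrow(neighbors)
  if (n < 1) stop("contract error: attention requires >= 1 neighbor")
  K <- params$K
  pp <- params$p_prime
  act <- if (params$activation == "elu") elu else stats::plogis
  dprime <- numeric(K * pp)
  alpha <- matrix(0, nrow = K, ncol = n)
  for (k in seq_len(K)) {
    Zs <- neighbors %*% t(params$W[[k]])          # n x p'
    zj <- drop(params$W[[k]] %*% d_vec)           # p'
    pre <- drop(Zs %*% params$a2[[k]]) + sum(params$a1[[k]] * zj)
    al <- softmax_vec(leaky_relu(pre, params$leaky_slope))
    u <- drop(crossprod(Zs, al))                  # p'
    dprime[((k - 1) * pp + 1):(k * pp)] <- act(u)
    alpha[k, ] <- al
  }
  list(dprime = dprime, alpha = alpha)
}

# forward + gradient accumulation for one labeled doctor.
# Returns loss, correctness, and gradient contributions.
gat_forward_backward <- function(d_vec, S, y_idx, params, grads = NULL) {
  n <- nrow(S)
  K <- params$K
  pp <- params$p_prime
  heads <- vector("list", K)
  dprime <- numeric(K * pp)
  for (k in seq_len(K)) {
    Zs <- S %*% t(params$W[[k]])
    zj <- drop(params$W[[k]] %*% d_vec)
    pre_raw <- drop(Zs %*% params$a2[[k]]) + sum(params$a1[[k]] * zj)
    al <- softmax_vec(leaky_relu(pre_raw, params$leaky_slope))
    u <- drop(crossprod(Zs, al))
    o <- if (params$activation == "elu") elu(u) else stats::plogis(u)
    heads[[k]] <- list(Zs = Zs, zj = zj, pre = pre_raw, al = al, u = u)
    dprime[((k - 1) * pp + 1):(k * pp)] <- o
  }
  logits <- drop(params$C %*% dprime) + params$b
  probs <- softmax_vec(logits)
  loss <- -log(max(probs[y_idx], 1e-12))
  pred <- which.max(probs)
  if (is.null(grads)) {
    return(list(loss = loss, pred = pred, dprime = dprime))
  }
  dlogit <- probs
  dlogit[y_idx] <- dlogit[y_idx] - 1
  grads$C <- grads$C + outer(dlogit, dprime)
  grads$b <- grads$b + dlogit
  ddprime <- drop(crossprod(params$C, dlogit))
  for (k in seq_len(K)) {
    h <- heads[[k]]
    go <- ddprime[((k - 1) * pp + 1):(k * pp)]
    du <- if (params$activation == "elu") {
      go * elu_grad(h$u)
    } else {
      go * stats::plogis(h$u) * (1 - stats::plogis(h$u))
    }
    dal <- drop(h$Zs %*% du)                       # n
    dZs <- outer(h$al, du)                          # n x p'
    de <- h$al * (dal - sum(h$al * dal))
    g <- de * leaky_relu_grad(h$pre, params$leaky_slope)
    grads$a2[[k]] <- grads$a2[[k]] + drop(crossprod(h$Zs, g))
    grads$a1[[k]] <- grads$a1[[k]] + sum(g) * h$zj
    dzj <- sum(g) * params$a1[[k]]
    dZs <- dZs + outer(g, params$a2[[k]])
    grads$W[[k]] <- grads$W[[k]] + outer(dzj, d_vec) + crossprod(dZs, S)
  }
  list(loss = loss, pred = pred, dprime = dprime, grads = grads)
}

gat_zero_grads <- function(params) {
  list(W = lapply(params$W, function(w) w * 0),
       a1 = lapply(params$a1, function(a) a * 0),
       a2 = lapply(params$a2, function(a) a * 0),
       C = params$C * 0, b = params$b * 0)
}

flatten_gat <- function(x) {
  out <- list(C = x$C, b = x$b)
  for (k in seq_along(x$W)) {
    out[[paste0("W", k)]] <- x$W[[k]]
    out[[paste0("a1_", k)]] <- x$a1[[k]]
    out[[paste0("a2_", k)]] <- x$a2[[k]]
  }
  out
}

unflatten_gat <- function(flat, params) {
  params$C <- flat$C
  params$b <- flat$b
  for (k in seq_along(params$W)) {
    params$W[[k]] <- flat[[paste0("W", k)]]
    params$a1[[k]] <- flat[[paste0("a1_", k)]]
    params$a2[[k]] <- flat[[paste0("a2_", k)]]
  }
  params
}

#' Train doctor embeddings via the auxiliary specialty-prediction task
#'
#' A single graph-attention layer aggregates each doctor's administered
#' service vectors (frozen inputs from the service embedding); a linear
#' softmax head predicts the doctor's primary specialty, and cross-entropy is
#' minimized with Adam. Doctor query vectors start as the weighted-average
#' initialization and are re-fed from the previous epoch's attention output
#' (the per-head dimension is `p/K`, so the concatenated output keeps
#' dimension `p`). Doctors with `"UNKNOWN"` specialty are embedded by the
#' forward pass but excluded from the loss and the validation split.
#'
#' @param graph a `doctor_service_graph` with >= 2 known specialty classes.
#' @param service_emb frozen service [embedding_table].
#' @param config a [gat_config].
#' @return Object of class `gat_fit`: `embeddings` ([embedding_table] over all
#'   doctors, at the best validation epoch), `params` (trained `gat_params`
#'   including class labels), and `report` (validation/train accuracy,
#'   confusion table, epochs run).
#' @export
train_gat <- function(graph, service_emb, config = gat_config()) {
  stopifnot(inherits(graph, "doctor_service_graph"),
            inherits(config, "gat_config"))
  p <- service_emb$dim
  if (p %% config$K != 0) {
    stop(sprintf("embedding dim %d is not divisible by K = %d heads", p, config$K))
  }
  doctors <- graph$doctors
  spec <- graph$specialty[doctors]
  known <- which(spec != SPECIALTY_UNKNOWN)
  classes <- sort(unique(spec[known]))
  if (length(classes) < 2) {
    stop("degenerate auxiliary task: need >= 2 known specialty classes")
  }
  y <- match(spec, classes)  # NA for UNKNOWN

  init <- init_doctor_vectors(graph, service_emb)
  by_doc <- split(graph$edges$service, graph$edges$doctor)
  Smats <- lapply(doctors, function(d) embedding_lookup(service_emb, by_doc[[d]]))

  params <- gat_init_params(p, p %/% config$K, config$K, length(classes),
                            config$leaky_slope, config$activation,
                            config$seed)
  params$classes <- classes

  # stratified validation split over labeled doctors
  set.seed(config$seed + 1L)
  val <- integer(0)
  if (config$val_fraction > 0) {
    for (cl in seq_along(classes)) {
      pool <- known[y[known] == cl]
      n_val <- max(1L, round(config$val_fraction * length(pool)))
      if (length(pool) > n_val) {
        val <- c(val, sample(pool, n_val))
      }
    }
  }
  train <- setdiff(known, val)

  forward_all <- function(pars, D_in) {
    t(vapply(seq_along(doctors), function(j) {
      attention_forward(D_in[j, ], Smats[[j]], pars)$dprime
    }, numeric(pars$K * pars$p_prime)))
  }
  accuracy_on <- function(pars, D_in, idx) {
    if (length(idx) == 0) return(NA_real_)
    preds <- vapply(idx, function(j) {
      fb <- gat_forward_backward(D_in[j, ], Smats[[j]], 1L, pars)
      fb$pred
    }, integer(1))
    mean(preds == y[idx])
  }
  loss_on <- function(pars, D_in, idx) {
    if (length(idx) == 0) return(NA_real_)
    mean(vapply(idx, function(j) {
      gat_forward_backward(D_in[j, ], Smats[[j]], y[j], pars)$loss
    }, numeric(1)))
  }

  D_in <- init$vectors
  if (config$epochs == 0) {
    emb <- forward_all(params, D_in)
    report <- list(classes = classes,
                   val_accuracy = accuracy_on(params, D_in, val),
                   train_accuracy = accuracy_on(params, D_in, train),
                   epochs_run = 0L, val_doctors = doctors[val])
    return(structure(list(embeddings = embedding_table(doctors, emb),
                          params = params, report = report),
                     class = "gat_fit"))
  }

  flat <- flatten_gat(params)
  opt <- adam_init(flat)
  # early stopping on validation cross-entropy (train loss when no val split)
  best <- list(loss = Inf, params = params, emb = NULL, D_in = D_in, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    grads <- gat_zero_grads(params)
    for (j in train) {
      fb <- gat_forward_backward(D_in[j, ], Smats[[j]], y[j], params, grads)
      grads <- fb$grads
    }
    gflat <- flatten_gat(grads)
    gflat <- lapply(gflat, function(g) g / length(train))
    step <- adam_step(flat, gflat, opt, config$lr)
    flat <- step$params
    opt <- step$state
    params <- unflatten_gat(flat, params)

    emb <- forward_all(params, D_in)
    val_loss <- loss_on(params, D_in, val)
    score <- if (is.na(val_loss)) loss_on(params, D_in, train) else val_loss
    if (score < best$loss - 1e-12) {
      best <- list(loss = score, params = params, emb = emb, D_in = D_in,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
    D_in <- emb  # re-feed: next epoch's queries are this epoch's outputs
  }
  params <- best$params
  emb <- if (is.null(best$emb)) forward_all(params, D_in) else best$emb

  # accuracy and confusion on the validation doctors under selected params
  conf <- NULL
  val_acc <- NA_real_
  if (length(val) > 0) {
    preds <- vapply(val, function(j) {
      gat_forward_backward(best$D_in[j, ], Smats[[j]], 1L, params)$pred
    }, integer(1))
    val_acc <- mean(preds == y[val])
    conf <- table(truth = classes[y[val]], predicted = classes[preds])
  }
  report <- list(classes = classes,
                 val_accuracy = val_acc,
                 train_accuracy = accuracy_on(params, best$D_in, train),
                 confusion = conf, epochs_run = best$epoch,
                 val_doctors = doctors[val])
  structure(list(embeddings = embedding_table(doctors, emb), params = params,
                 report = report),
            class = "gat_fit")
}

#' @export
print.gat_fit <- function(x, ...) {
  cat(sprintf("gat_fit: %d doctors, %d classes, val accuracy %.3f (%d epochs)\n",
              length(x$embeddings$ids), length(x$params$classes),
              x$report$val_accuracy, x$report$epochs_run))
  invisible(x)
}

#' Impute a doctor's primary specialty from administered services
#'
#' Reuses the trained attention layer and classifier head: forms the
#' weighted-average init vector from the doctor's (service, weight) profile,
#' runs the forward pass, and returns the argmax class with softmax
#' probabilities. Scale-invariant in the weights.
#'
#' @param doctor_edges data.frame with columns `service` and `weight`.
#' @param service_emb the service [embedding_table] used in training.
#' @param params trained `gat_params` (from [train_gat]).
#' @return list with `specialty` (predicted label) and `probabilities`
#'   (named, sums to 1).
#' @export
impute_specialty <- function(doctor_edges, service_emb, params) {
  if (is.null(params$classes)) stop("params carry no class labels; train first")
  missing <- setdiff(doctor_edges$service, service_emb$ids)
  if (length(missing) > 0) {
    stop("unseen service code(s): ", paste(missing, collapse = ", "))
  }
  S <- embedding_lookup(service_emb, doctor_edges$service)
  w <- doctor_edges$weight
  d_vec <- colSums(w * S) / sum(w)
  fwd <- attention_forward(d_vec, S, params)
  logits <- drop(params$C %*% fwd$dprime) + params$b
  probs <- softmax_vec(logits)
  names(probs) <- params$classes
  list(specialty = params$classes[which.max(probs)], probabilities = probs)
}
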