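# L2-regularized logistic regression via glmnet (ridge, single lambda).
# C is the inverse regularization strength; lambda = 1 / (n * C) matches the
# usual 'sum of losses + ||w||^2 / (2C)' parameterization up to the 1/n
# scaling glmnet applies to the loss.
fit_lr <- function(x, y, C = 1) {
  x <- as.matrix(x)
  if (ncol(x) == 1) x <- cbind(x, 0)  # glmnet needs >= 2 columns
  y <- factor(y)
  family <- if (nlevels(y) == 2) "binomial" else "multinomial"
  # glmnet warns about classes with < 8 observations; small folds are expected
  # in the protocols, so the advisory warning is muffled
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = family, alpha = 0,
                   lambda = 1 / (nrow(x) * C), standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8|one multinomial or binomial class",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(fit = fit, levels = levels(y), ncol = ncol(x))
}

predict_lr <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) == 1) x <- cbind(x, 0)
  if (type == "class") {
    as.character(stats::predict(model$fit, newx = x, type = "class")[, 1])
  } else if (length(model$levels) == 2) {
    # probability of the second factor level
    as.numeric(stats::predict(model$fit, newx = x, type = "response")[, 1])
  } else {
    p <- stats::predict(model$fit, newx = x, type = "response")
    matrix(p, nrow = nrow(x), dimnames = list(NULL, model$levels))
  }
}

#' ROC AUC of a score vector
#'
#' Rank statistic (Mann-Whitney) with average ranks for ties.
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 (or logical) labels.
#' @return AUC in \[0,1\].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(as.integer(labels)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC (average precision)
#'
#' @inheritParams auc_roc
#' @return average precision in \[0,1\].
#' @export
auc_pr <- function(scores, labels) {
  labels <- as.integer(as.logical(as.integer(labels)))
  if (sum(labels) == 0) stop("average precision needs positive labels")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  precision_at <- cumsum(y) / seq_along(y)
  mean(precision_at[y == 1])
}

f1_scores <- function(truth, pred, classes) {
  micro_tp <- sum(truth == pred)
  micro <- micro_tp / length(truth)  # single-label micro-F1 == accuracy
  per_class <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  c(micro_f1 = micro, macro_f1 = mean(per_class))
}

stratified_split <- function(y, ratio) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(ratio * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Node classification protocol
#'
#' For each training ratio and repeat: stratified random split, fit an
#' L2-regularized logistic regression on the training embeddings, score
#' micro-/macro-F1 on the held-out embeddings; means over repeats are
#' reported.
#'
#' @param emb an [embedding_table] (e.g. over patients).
#' @param labels named vector mapping id to class; every labeled id must have
#'   an embedding and >= 2 classes must be present.
#' @param ratios training ratios, each in (0,1); default 20\% to 80\%.
#' @param repeats randomized splits per ratio (default 10).
#' @param seed integer RNG seed.
#' @param C inverse L2 regularization strength (default 1).
#' @return data.frame with columns `ratio`, `micro_f1`, `macro_f1` (class
#'   `classification_report`, with `repeats` and `seed` attributes).
#' @export
node_classification_eval <- function(emb, labels, ratios = c(0.2, 0.4, 0.6, 0.8),
                                     repeats = 10L, seed = 1L, C = 1) {
  if (any(ratios <= 0 | ratios >= 1)) stop("ratios must be in (0,1)")
  ids <- names(labels)
  X <- embedding_lookup(emb, ids)
  y <- as.character(labels)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 classes")
  set.seed(seed)
  rows <- lapply(ratios, function(r) {
    f1 <- vapply(seq_len(repeats), function(rep_i) {
      tr <- stratified_split(y, r)
      te <- setdiff(seq_along(y), tr)
      model <- fit_lr(X[tr, , drop = FALSE], y[tr], C = C)
      pred <- predict_lr(model, X[te, , drop = FALSE], type = "class")
      f1_scores(y[te], pred, classes)
    }, numeric(2))
    data.frame(ratio = r, micro_f1 = mean(f1["micro_f1", ]),
               macro_f1 = mean(f1["macro_f1", ]))
  })
  out <- do.call(rbind, rows)
  attr(out, "repeats") <- repeats
  attr(out, "seed") <- seed
  class(out) <- c("classification_report", class(out))
  out
}

#' Remove patient-doctor edges for link prediction
#'
#' Randomly removes `fraction` of the edges as positive test edges while
#' keeping the residual graph connected (per connected component of the
#' original graph): candidate removals are rejected whenever the edge is a
#' bridge of the current residual graph. An equal number of negative test
#' pairs is sampled uniformly without replacement from patient-doctor pairs
#' that have no edge in the original graph.
#'
#' @param edges data.frame with columns `patient`, `doctor` (duplicates
#'   collapsed).
#' @param fraction fraction of edges to remove, in (0, 0.5\].
#' @param seed integer RNG seed.
#' @return Object of class `link_split` with `residual_edges`,
#'   `positive_test_edges`, `negative_test_edges` (data.frames with `patient`,
#'   `doctor`) and `removal_fraction`.
#' @export
link_prediction_split <- function(edges, fraction = 0.10, seed = 1L) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  edges <- unique(edges[c("patient", "doctor")])
  n_e <- nrow(edges)
  if (n_e < 10) stop("need >= 10 edges")
  quota <- round(fraction * n_e)
  pat_v <- paste0("P::", edges$patient)
  doc_v <- paste0("D::", edges$doctor)
  g <- igraph::graph_from_edgelist(cbind(pat_v, doc_v), directed = FALSE)
  igraph::E(g)$orig_idx <- seq_len(n_e)
  set.seed(seed)
  removed <- integer(0)
  if (quota > 0) {
    while (length(removed) < quota) {
      br <- igraph::bridges(g)
      candidates <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
      if (length(candidates) == 0) {
        stop(sprintf(paste0("cannot remove %d edges while keeping the residual ",
                            "graph connected; achieved %d"),
                     quota, length(removed)))
      }
      pick <- candidates[sample.int(length(candidates), 1L)]
      removed <- c(removed, igraph::edge_attr(g, "orig_idx", pick))
      g <- igraph::delete_edges(g, pick)
    }
  }
  positive <- edges[removed, , drop = FALSE]
  residual <- edges[setdiff(seq_len(n_e), removed), , drop = FALSE]
  rownames(positive) <- rownames(residual) <- NULL

  patients <- sort(unique(edges$patient))
  doctors <- sort(unique(edges$doctor))
  key <- function(p, d) paste(p, d, sep = "\r")
  existing <- key(edges$patient, edges$doctor)
  n_possible <- length(patients) * length(doctors) - n_e
  if (n_possible < quota) {
    stop("not enough non-edges to sample negatives")
  }
  neg_p <- character(0); neg_d <- character(0)
  seen <- character(0)
  while (length(neg_p) < quota) {
    p <- patients[sample.int(length(patients), 1L)]
    d <- doctors[sample.int(length(doctors), 1L)]
    k <- key(p, d)
    if (k %in% existing || k %in% seen) next
    seen <- c(seen, k)
    neg_p <- c(neg_p, p); neg_d <- c(neg_d, d)
  }
  structure(list(residual_edges = residual,
                 positive_test_edges = positive,
                 negative_test_edges = data.frame(patient = neg_p, doctor = neg_d),
                 removal_fraction = fraction),
            class = "link_split")
}

#' Score link prediction from embeddings
#'
#' Features are the concatenation of the patient and doctor vectors for each
#' positive and negative test pair. An L2 logistic regression is scored by
#' stratified k-fold cross-validation over the pair set (pooled held-out
#' probabilities), and ROC AUC is returned. Embeddings must have been trained
#' on the residual graph only.
#'
#' @param split a `link_split`.
#' @param patient_emb,doctor_emb [embedding_table]s covering the test pairs.
#' @param seed integer RNG seed for fold assignment.
#' @param folds cross-validation folds (default 5).
#' @param C inverse L2 regularization strength.
#' @return ROC AUC in \[0,1\].
#' @export
link_prediction_eval <- function(split, patient_emb, doctor_emb, seed = 1L,
                                 folds = 5L, C = 1) {
  stopifnot(inherits(split, "link_split"))
  pos <- split$positive_test_edges
  neg <- split$negative_test_edges
  keyp <- paste(pos$patient, pos$doctor, sep = "\r")
  keyn <- paste(neg$patient, neg$doctor, sep = "\r")
  if (length(intersect(keyp, keyn)) > 0) {
    stop("contract error: positive and negative test pairs overlap")
  }
  pairs <- rbind(pos, neg)
  y <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  X <- cbind(embedding_lookup(patient_emb, pairs$patient),
             embedding_lookup(doctor_emb, pairs$doctor))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in c(0L, 1L)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- fit_lr(X[tr, , drop = FALSE], y[tr], C = C)
    scores[!tr] <- predict_lr(model, X[!tr, , drop = FALSE], type = "prob")
  }
  auc_roc(scores, y)
}

#' Cross-validated binary-outcome evaluation
#'
#' Stratified k-fold cross-validation of an L2 logistic regression on the
#' embeddings; mean PR-AUC and ROC-AUC over the fold-wise test results.
#'
#' @param emb an [embedding_table].
#' @param labels named binary (0/1) vector; both classes must be present.
#' @param folds number of folds (default 10).
#' @param seed integer RNG seed.
#' @param C inverse L2 regularization strength.
#' @return named numeric vector `c(pr_auc = ..., roc_auc = ...)`.
#' @export
binary_outcome_eval <- function(emb, labels, folds = 10L, seed = 1L, C = 1) {
  ids <- names(labels)
  y <- as.integer(as.character(labels))
  if (length(unique(y)) < 2) stop("need both outcome classes")
  X <- embedding_lookup(emb, ids)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pr <- roc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- fit_lr(X[tr, , drop = FALSE], y[tr], C = C)
    s <- predict_lr(model, X[!tr, , drop = FALSE], type = "prob")
    pr[f] <- auc_pr(s, y[!tr])
    roc[f] <- auc_roc(s, y[!tr])
  }
  c(pr_auc = mean(pr), roc_auc = mean(roc))
}

#' PCA projection of an embedding table
#'
#' Mean-centered projection onto the top-k principal components; component
#' variances are non-increasing.
#'
#' @param emb an [embedding_table] with >= k vectors.
#' @param k output dimension (default 2), <= embedding dimension.
#' @return An [embedding_table] of the projected coordinates, with the
#'   per-component variances attached as attribute `"variances"`.
#' @export
pca_project <- function(emb, k = 2L) {
  if (k > emb$dim) stop("k must be <= embedding dimension")
  if (length(emb$ids) < k) stop("need at least k vectors")
  pc <- stats::prcomp(emb$vectors, center = TRUE, scale. = FALSE, rank. = k)
  out <- embedding_table(emb$ids, pc$x[, seq_len(k), drop = FALSE])
  attr(out, "variances") <- pc$sdev[seq_len(k)]^2
  out
}
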