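#' Pipeline configuration
#'
#' Bundles every stage's hyperparameters with the defaults used throughout:
#' context window `T = 8` days, embedding dimension 128 for all entities, 10
#' negative samples, `K = 4` attention heads, first-order-neutral walk biases
#' `p = q = 1`. Every random stage draws its own seed deterministically from
#' the master seed and the stage name, so reruns with the same configuration
#' and seed reproduce all embedding files bitwise.
#'
#' @param sim a [sim_config] (used by the `simulate` stage).
#' @param T_window co-occurrence context window in days.
#' @param pair_counting within-window pair weighting, `"product"` or
#'   `"binary"`.
#' @param walk a [walk_config].
#' @param sgns a [skipgram_config].
#' @param gat a [gat_config].
#' @param patient a [patient_config].
#' @param eval_ratios training ratios for node classification.
#' @param eval_repeats repeats per ratio.
#' @param eval_folds folds for the binary-outcome evaluation.
#' @param seed master seed.
#' @param stages character vector of stages to run, in hierarchical order
#'   among `"simulate"`, `"service_graph"`, `"service_embedding"`,
#'   `"doctor_embedding"`, `"patient_embedding"`, `"evaluate"`.
#' @export
pipeline_config <- function(sim = sim_config(), T_window = 8L,
                            pair_counting = "product",
                            walk = walk_config(), sgns = skipgram_config(),
                            gat = gat_config(), patient = patient_config(),
                            eval_ratios = c(0.2, 0.4, 0.6, 0.8),
                            eval_repeats = 10L, eval_folds = 10L, seed = 1L,
                            stages = c("simulate", "service_graph",
                                       "service_embedding", "doctor_embedding",
                                       "patient_embedding", "evaluate")) {
  structure(list(sim = sim, T_window = as.integer(T_window),
                 pair_counting = pair_counting, walk = walk, sgns = sgns,
                 gat = gat, patient = patient, eval_ratios = eval_ratios,
                 eval_repeats = as.integer(eval_repeats),
                 eval_folds = as.integer(eval_folds), seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

# deterministic 31-bit stage seed from master seed and stage name
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1014741823
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

#' Run the embedding pipeline
#'
#' Executes the requested stages in the hierarchical order services then
#' doctors then patients, reading and writing plain-text artifacts under
#' `out_dir`: `journeys.csv`, `ground_truth.csv`, `service_graph.tsv` (+
#' `.vocab`), `service.vec`, `doctor.vec`, `specialty_report.csv`,
#' `patient.vec`, `hybrids.tsv`, `eval_nodes.csv`, `eval_binary.csv`, and a
#' `manifest.json` recording per stage the seed, input hashes, outputs, and
#' wall time. A stage whose input artifact is missing fails with an error
#' naming the artifact.
#'
#' @param out_dir artifact directory (created if absent).
#' @param config a [pipeline_config].
#' @return Invisibly, the manifest (named list, one entry per executed stage).
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(path(f))) {
      stop(sprintf("stage '%s' requires missing artifact: %s", stage, path(f)))
    }
    path(f)
  }
  manifest <- list()
  note <- function(stage, inputs, outputs, seed, t0) {
    manifest[[stage]] <<- list(
      stage = stage, seed = seed,
      inputs = as.list(tools::md5sum(vapply(inputs, path, character(1)))),
      outputs = vapply(outputs, path, character(1)),
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3))
  }

  if ("simulate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    cohort <- generate_cohort(sim)
    write_journeys(cohort$journeys, path("journeys.csv"))
    write_ground_truth(cohort$ground_truth, path("ground_truth.csv"))
    note("simulate", character(0), c("journeys.csv", "ground_truth.csv"),
         sim$seed, t0)
  }

  if ("service_graph" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    journeys <- read_journeys(need("journeys.csv", "service_graph"))
    graph <- build_cooccurrence(journeys, config$T_window,
                                pair_counting = config$pair_counting)
    write_cooccurrence(graph, path("service_graph.tsv"))
    note("service_graph", "journeys.csv",
         c("service_graph.tsv", "service_graph.tsv.vocab"), NA, t0)
  }

  if ("service_embedding" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    graph <- read_cooccurrence(need("service_graph.tsv", "service_embedding"),
                               window_T = config$T_window)
    wcfg <- config$walk
    wcfg$seed <- stage_seed(config$seed, "service_embedding_walks")
    scfg <- config$sgns
    scfg$seed <- stage_seed(config$seed, "service_embedding_sgns")
    emb <- embed_services(graph, wcfg, scfg)
    write_embeddings(emb, path("service.vec"))
    note("service_embedding", "service_graph.tsv", "service.vec", scfg$seed, t0)
  }

  if ("doctor_embedding" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    journeys <- read_journeys(need("journeys.csv", "doctor_embedding"))
    service_emb <- read_embeddings(need("service.vec", "doctor_embedding"))
    gcfg <- config$gat
    gcfg$seed <- stage_seed(config$seed, "doctor_embedding")
    dgraph <- build_doctor_service_graph(journeys)
    fit <- train_gat(dgraph, service_emb, gcfg)
    write_embeddings(fit$embeddings, path("doctor.vec"))
    utils::write.csv(
      data.frame(metric = c("val_accuracy", "train_accuracy", "epochs_run"),
                 value = c(fit$report$val_accuracy, fit$report$train_accuracy,
                           fit$report$epochs_run)),
      path("specialty_report.csv"), row.names = FALSE)
    note("doctor_embedding", c("journeys.csv", "service.vec"),
         c("doctor.vec", "specialty_report.csv"), gcfg$seed, t0)
  }

  if ("patient_embedding" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    journeys <- read_journeys(need("journeys.csv", "patient_embedding"))
    service_emb <- read_embeddings(need("service.vec", "patient_embedding"))
    doctor_emb <- read_embeddings(need("doctor.vec", "patient_embedding"))
    pcfg <- config$patient
    pcfg$seed <- stage_seed(config$seed, "patient_embedding")
    hg <- duplicate_annotate(build_patient_multigraph(journeys))
    fit <- train_patient_embeddings(hg, service_emb, doctor_emb, pcfg)
    write_embeddings(fit$embeddings, path("patient.vec"))
    write_hybrid_vocab(hg, path("hybrids.tsv"))
    note("patient_embedding", c("journeys.csv", "service.vec", "doctor.vec"),
         c("patient.vec", "hybrids.tsv"), pcfg$seed, t0)
  }

  if ("evaluate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    patient_emb <- read_embeddings(need("patient.vec", "evaluate"))
    gt <- read_ground_truth(need("ground_truth.csv", "evaluate"))
    labels <- gt$label[names(gt$label) %in% patient_emb$ids]
    eseed <- stage_seed(config$seed, "evaluate")
    report <- node_classification_eval(patient_emb, labels,
                                       ratios = config$eval_ratios,
                                       repeats = config$eval_repeats,
                                       seed = eseed)
    utils::write.csv(as.data.frame(report), path("eval_nodes.csv"),
                     row.names = FALSE)
    bin <- binary_outcome_eval(patient_emb, labels, folds = config$eval_folds,
                               seed = eseed)
    utils::write.csv(data.frame(metric = names(bin), value = as.numeric(bin)),
                     path("eval_binary.csv"), row.names = FALSE)
    note("evaluate", c("patient.vec", "ground_truth.csv"),
         c("eval_nodes.csv", "eval_binary.csv"), eseed, t0)
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' End-to-end link prediction on a journey table
#'
#' Implements the protocol: remove a fraction of the distinct patient-doctor
#' edges (keeping the residual graph connected), drop the corresponding
#' journey rows, re-run the full embedding hierarchy on the residual journeys
#' only, and score edge existence by cross-validated logistic regression on
#' concatenated patient and doctor embeddings.
#'
#' @param journeys a [journey_table].
#' @param fraction edge-removal fraction (default 0.10).
#' @param seed master seed for the split and all embedding stages.
#' @param T_window co-occurrence window.
#' @param walk,sgns,gat,patient stage configurations.
#' @return list with `auc` and the `link_split` used.
#' @export
link_prediction_pipeline <- function(journeys, fraction = 0.10, seed = 1L,
                                     T_window = 8L, walk = walk_config(),
                                     sgns = skipgram_config(),
                                     gat = gat_config(),
                                     patient = patient_config()) {
  rec <- journeys$records
  edges <- unique(data.frame(patient = rec$patient_id, doctor = rec$doctor_id))
  split <- link_prediction_split(edges, fraction, seed = stage_seed(seed, "split"))
  res_key <- paste(split$residual_edges$patient, split$residual_edges$doctor,
                   sep = "\r")
  keep <- paste(rec$patient_id, rec$doctor_id, sep = "\r") %in% res_key
  residual <- journey_table(rec[keep, , drop = FALSE])

  graph <- build_cooccurrence(residual, T_window)
  walk$seed <- stage_seed(seed, "walks")
  sgns$seed <- stage_seed(seed, "sgns")
  service_emb <- embed_services(graph, walk, sgns)
  gat$seed <- stage_seed(seed, "gat")
  dfit <- train_gat(build_doctor_service_graph(residual), service_emb, gat)
  patient$seed <- stage_seed(seed, "patient")
  hg <- duplicate_annotate(build_patient_multigraph(residual))
  pfit <- train_patient_embeddings(hg, service_emb, dfit$embeddings, patient)
  auc <- link_prediction_eval(split, pfit$embeddings, dfit$embeddings,
                              seed = stage_seed(seed, "lp_eval"))
  list(auc = auc, split = split)
}
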