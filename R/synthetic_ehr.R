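#' Simulation configuration for synthetic patient journeys
#'
#' The generator plants the structure every downstream stage is designed to
#' recover: doctors have specialty-specific service-usage profiles that
#' concentrate most of their mass on disjoint service blocks; the global
#' service vocabulary is frequency-skewed (Zipf) with a designated fraction of
#' rare services reachable only through low-probability tail mass; journeys
#' advance by irregular inter-service gaps (geometric days, occasional same-day
#' bursts); and a latent per-patient condition drives both the specialties the
#' patient visits and a binary outcome label.
#'
#' @param n_patients number of patients (>= 0).
#' @param n_doctors number of doctors (>= 1); assigned to specialties
#'   round-robin, so every specialty is staffed when `n_doctors >=
#'   n_specialties`.
#' @param n_services size of the service vocabulary.
#' @param n_specialties number of doctor primary specialties.
#' @param n_conditions number of latent patient conditions; condition 1 is the
#'   designated "case" condition that sets the positive outcome label.
#' @param services_per_patient_mean Poisson mean of journey length (services
#'   per patient).
#' @param gap_param geometric parameter in (0,1) for inter-service day gaps
#'   (support >= 1 day).
#' @param same_day_prob probability that a step stays on the same day
#'   (same-day burst), default 0.2.
#' @param rare_service_fraction fraction of services designated rare: they
#'   belong to no specialty block and are reachable only via tail mass.
#' @param zipf_exponent exponent of the rank-frequency law used for service
#'   base weights.
#' @param label_noise probability that a patient's outcome label is flipped.
#' @param case_prevalence probability a patient draws the case condition.
#' @param seed integer master seed; journeys are reproducible from it and
#'   hierarchically split per patient, so enlarging the cohort does not
#'   perturb earlier patients.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 500, n_doctors = 50, n_services = 100,
                       n_specialties = 5, n_conditions = 5,
                       services_per_patient_mean = 30, gap_param = 0.5,
                       same_day_prob = 0.2, rare_service_fraction = 0.2,
                       zipf_exponent = 1.1, label_noise = 0.1,
                       case_prevalence = 0.2, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_doctors = as.integer(n_doctors),
              n_services = as.integer(n_services),
              n_specialties = as.integer(n_specialties),
              n_conditions = as.integer(n_conditions),
              services_per_patient_mean = services_per_patient_mean,
              gap_param = gap_param, same_day_prob = same_day_prob,
              rare_service_fraction = rare_service_fraction,
              zipf_exponent = zipf_exponent, label_noise = label_noise,
              case_prevalence = case_prevalence, seed = as.integer(seed))
  if (cfg$n_patients < 0) stop("n_patients must be >= 0")
  for (f in c("n_doctors", "n_services", "n_specialties", "n_conditions")) {
    if (cfg[[f]] < 1) stop(f, " must be >= 1")
  }
  for (f in c("rare_service_fraction", "label_noise", "case_prevalence",
              "same_day_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  }
  if (cfg$gap_param <= 0 || cfg$gap_param >= 1) stop("gap_param must be in (0,1)")
  if (cfg$services_per_patient_mean <= 0) stop("services_per_patient_mean must be > 0")
  if (cfg$zipf_exponent <= 0) stop("zipf_exponent must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic 31-bit sub-seed for patient i under master seed
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919 + 12345) %%
               2147483647)
}

#' Generate planted ground truth (profiles, affinities, doctor specialties)
#'
#' Services are ranked by a Zipf law `weight(r) ~ r^-zipf_exponent` (smaller
#' ids = more frequent). The last `rare_service_fraction` of ranks are rare
#' and belong to no block. Remaining services are split round-robin by rank
#' into `n_specialties` disjoint blocks; specialty g's profile puts 0.8 of its
#' mass (Zipf-proportional) on block g and 0.2 on everything outside it, so
#' profiles are pairwise separated by total-variation distance >= 0.3 by
#' construction. Each condition concentrates 0.7 of its specialty affinity on
#' its home specialty.
#'
#' @param config a [sim_config].
#' @return Object of class `ground_truth`: `doctor_specialty`,
#'   `patient_condition`, `patient_label` (patient maps empty until
#'   [generate_cohort] fills them), `specialty_service_profile` (matrix
#'   specialties x services, rows sum to 1), `condition_specialty_affinity`
#'   (matrix conditions x specialties, rows sum to 1), plus the vocabularies
#'   and the rare-service flag.
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  M <- config$n_services
  G <- config$n_specialties
  n_rare <- ceiling(config$rare_service_fraction * M)
  n_common <- M - n_rare
  if (n_common < G) {
    stop(sprintf(paste0("cannot allocate disjoint specialty blocks: %d ",
                        "non-rare services for %d specialties"), n_common, G))
  }
  services <- sprintf("S%03d", seq_len(M))
  base_w <- seq_len(M)^(-config$zipf_exponent)
  rare <- c(rep(FALSE, n_common), rep(TRUE, n_rare))
  # round-robin by rank: blocks have (near-)equal size and each spans the
  # frequency spectrum
  block <- rep(NA_integer_, M)
  block[seq_len(n_common)] <- ((seq_len(n_common) - 1) %% G) + 1
  specialties <- sprintf("SP%02d", seq_len(G))

  # Profiles are chosen so that (i) each specialty puts ~0.8 mass on its own
  # disjoint block, and (ii) the specialty-averaged marginal stays exactly
  # proportional to the Zipf law m(s) — so the cohort-level rank-frequency
  # slope matches zipf_exponent. With per-rank marginal m, a common service in
  # its own block gets a*m, in a foreign profile b*m, and a rare service t*m
  # everywhere; a, b, t solve the own-mass, row-sum and marginal constraints.
  m <- base_w / sum(base_w)
  Mc <- sum(m[!rare])
  Mr <- sum(m[rare])
  profile <- matrix(0, nrow = G, ncol = M,
                    dimnames = list(specialties, services))
  if (G == 1) {
    profile[1, ] <- m
  } else {
    a_bar <- 0.8 * G / Mc
    b <- max(G * (0.2 - 0.8 * Mr / Mc) / (G - 1), 1e-8)
    t_rare <- (a_bar + (G - 1) * b) / G
    for (g in seq_len(G)) {
      own <- !is.na(block) & block == g
      # per-row boost puts exactly 0.8 pre-normalization mass on the own block
      profile[g, own] <- (0.8 / sum(m[own])) * m[own]
      profile[g, !own & !rare] <- b * m[!own & !rare]
      profile[g, rare] <- t_rare * m[rare]
    }
    profile <- profile / rowSums(profile)
  }

  C <- config$n_conditions
  affinity <- matrix(0, nrow = C, ncol = G,
                     dimnames = list(as.character(seq_len(C)), specialties))
  for (cc in seq_len(C)) {
    home <- ((cc - 1) %% G) + 1
    if (G == 1) {
      affinity[cc, ] <- 1
    } else {
      affinity[cc, ] <- 0.3 / (G - 1)
      affinity[cc, home] <- 0.7
    }
  }

  doctors <- sprintf("D%03d", seq_len(config$n_doctors))
  doctor_specialty <- specialties[((seq_len(config$n_doctors) - 1) %% G) + 1]
  names(doctor_specialty) <- doctors

  structure(
    list(doctor_specialty = doctor_specialty,
         patient_condition = integer(0),
         patient_label = integer(0),
         specialty_service_profile = profile,
         condition_specialty_affinity = affinity,
         services = services, specialties = specialties, doctors = doctors,
         rare_service = stats::setNames(rare, services),
         service_block = stats::setNames(block, services)),
    class = "ground_truth"
  )
}

#' Generate a synthetic cohort of patient journeys
#'
#' Each patient draws a latent condition, then a journey: the number of
#' services is Poisson, each step picks a specialty from the condition's
#' affinity, a doctor uniformly within that specialty, a service from the
#' specialty's profile, and advances time by a same-day burst (probability
#' `same_day_prob`) or a geometric gap of >= 1 day. The binary outcome label
#' is 1 for the case condition, flipped independently with probability
#' `label_noise`. Fully reproducible from `config$seed`; per-patient RNG
#' streams mean earlier patients are unchanged when the cohort grows.
#'
#' @param config a [sim_config].
#' @return list with elements `journeys` (a [journey_table]) and
#'   `ground_truth` (a `ground_truth` with patient maps filled).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gt <- generate_profiles(config)
  docs_by_spec <- split(gt$doctors, gt$doctor_specialty[gt$doctors])
  empty <- setdiff(gt$specialties, names(docs_by_spec))
  if (length(empty) > 0) {
    stop("specialty with zero doctors: ", paste(empty, collapse = ", "))
  }

  n <- config$n_patients
  patients <- sprintf("P%05d", seq_len(n))
  condition <- integer(n)
  label <- integer(n)
  parts <- vector("list", n)
  G <- config$n_specialties

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    cond <- if (stats::runif(1) < config$case_prevalence || config$n_conditions == 1) {
      1L
    } else {
      1L + sample.int(config$n_conditions - 1L, 1L)
    }
    condition[i] <- cond
    lab <- as.integer(cond == 1L)
    if (stats::runif(1) < config$label_noise) lab <- 1L - lab
    label[i] <- lab

    k <- stats::rpois(1, config$services_per_patient_mean)
    if (k == 0) next
    spec_idx <- sample.int(G, k, replace = TRUE,
                           prob = gt$condition_specialty_affinity[cond, ])
    doctor <- vapply(spec_idx, function(g) {
      pool <- docs_by_spec[[gt$specialties[g]]]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    service <- character(k)
    for (g in unique(spec_idx)) {
      sel <- spec_idx == g
      service[sel] <- sample(gt$services, sum(sel), replace = TRUE,
                             prob = gt$specialty_service_profile[g, ])
    }
    same_day <- stats::runif(k) < config$same_day_prob
    gaps <- ifelse(same_day, 0L, stats::rgeom(k, config$gap_param) + 1L)
    gaps[1] <- 0L
    dates <- cumsum(gaps)
    parts[[i]] <- data.frame(patient_id = patients[i], doctor_id = doctor,
                             specialty = gt$doctor_specialty[doctor],
                             service_code = service, date = dates,
                             stringsAsFactors = FALSE)
  }

  records <- if (n == 0 || all(vapply(parts, is.null, logical(1)))) {
    data.frame(patient_id = character(0), doctor_id = character(0),
               specialty = character(0), service_code = character(0),
               date = integer(0))
  } else {
    do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  }

  gt$patient_condition <- stats::setNames(condition, patients)
  gt$patient_label <- stats::setNames(label, patients)
  list(journeys = journey_table(records), ground_truth = gt)
}

#' Write / read the ground-truth sidecar
#'
#' Long-format CSV with columns `entity_id`, `attribute`, `value` carrying
#' doctor specialties and patient conditions/labels.
#'
#' @param gt a `ground_truth`.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  df <- rbind(
    data.frame(entity_id = names(gt$doctor_specialty), attribute = "specialty",
               value = unname(gt$doctor_specialty)),
    data.frame(entity_id = names(gt$patient_condition), attribute = "condition",
               value = as.character(unname(gt$patient_condition))),
    data.frame(entity_id = names(gt$patient_label), attribute = "label",
               value = as.character(unname(gt$patient_label)))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @return `read_ground_truth` returns a named list of attribute maps.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  out <- list()
  for (attr in unique(df$attribute)) {
    sel <- df$attribute == attr
    out[[attr]] <- stats::setNames(df$value[sel], df$entity_id[sel])
  }
  out
}
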