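# Synthetic study generator: knowledge bases with planted structure,
# specificity-stratified vignette studies with internally consistent gold
# differentials, and noisy simulated raters. Everything is deterministic
# under the config seed, with per-vignette sub-streams so single vignettes
# can be regenerated stably.

#' Generator configuration for a synthetic study
#'
#' Defaults emulate a 15-disease febrile-illness domain evaluated over a
#' 15 diseases x 3 strata x 2 vignettes-per-cell design (90 vignettes, 30
#' per stratum). Stratum policies are threshold-based: a symptom is
#' pathognomonic for a disease when its weight for it is at least
#' `pathognomonic_threshold`, disease-leaning when at least
#' `leaning_threshold` (but pathognomonic for none), and shared-pool when
#' below `leaning_threshold` for every disease.
#'
#' @param n_diseases number of diseases.
#' @param n_symptoms number of symptoms.
#' @param pathognomonic_per_disease pathognomonic symptoms planted per disease.
#' @param shared_symptom_fraction fraction of symptoms in the shared pool
#'   (nonspecific complaints such as fever or malaise).
#' @param vignettes_per_cell vignettes per (disease, stratum) cell.
#' @param pathognomonic_threshold,leaning_threshold stratum policy cuts.
#' @param seed integer seed; fixes every downstream draw.
#' @return a `ddx_generator_config`.
#' @export
generator_config <- function(n_diseases = 15L, n_symptoms = 60L,
                             pathognomonic_per_disease = 2L,
                             shared_symptom_fraction = 0.25,
                             vignettes_per_cell = 2L,
                             pathognomonic_threshold = 0.85,
                             leaning_threshold = 0.5,
                             seed = 1L) {
  cfg <- list(n_diseases = as.integer(n_diseases),
              n_symptoms = as.integer(n_symptoms),
              pathognomonic_per_disease = as.integer(pathognomonic_per_disease),
              shared_symptom_fraction = shared_symptom_fraction,
              vignettes_per_cell = as.integer(vignettes_per_cell),
              pathognomonic_threshold = pathognomonic_threshold,
              leaning_threshold = leaning_threshold,
              seed = as.integer(seed))
  .stop_if(cfg$n_diseases < 1 || cfg$n_symptoms < 1 ||
             cfg$pathognomonic_per_disease < 1 || cfg$vignettes_per_cell < 1,
           "counts must be positive")
  .stop_if(shared_symptom_fraction < 0 || shared_symptom_fraction > 1,
           "shared_symptom_fraction must be in [0, 1]")
  structure(cfg, class = "ddx_generator_config")
}

#' Simulated-rater configuration
#'
#' Stands in for a human rater of imperfect accuracy: starting from the
#' engine's own differential, the primary is swapped for a random other
#' disease with probability `primary_error_rate`, and each secondary slot
#' is perturbed with probability `differential_error_rate`.
#'
#' @param label source label for emitted predictions.
#' @param primary_error_rate,differential_error_rate probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return a `ddx_rater_config`.
#' @export
rater_config <- function(label = "rater-1", primary_error_rate = 0.3,
                         differential_error_rate = 0.3, seed = 1L) {
  .stop_if(primary_error_rate < 0 || primary_error_rate > 1 ||
             differential_error_rate < 0 || differential_error_rate > 1,
           "error rates must be in [0, 1]")
  structure(list(label = label, primary_error_rate = primary_error_rate,
                 differential_error_rate = differential_error_rate,
                 seed = as.integer(seed)),
            class = "ddx_rater_config")
}

# Stable 32-bit sub-seed for item i of stream `seed` (parallel-safe
# regeneration of single vignettes).
.sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483629)
}

# sample() without the length-1 "1:x" surprise
.pick <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

#' Generate a synthetic knowledge base with planted structure
#'
#' Plants, per disease, `pathognomonic_per_disease` high-weight symptoms
#' (weight in (0.85, 0.99] for the owner, near zero elsewhere) and one or
#' more disease-leaning symptoms (weight in [0.5, 0.8]); the remaining
#' symptoms form a shared pool of nonspecific complaints with moderate
#' weights (below 0.5) for every disease. Priors are drawn from a
#' symmetric Dirichlet. Deterministic under `config$seed`.
#'
#' @param config a [generator_config()].
#' @return a valid `ddx_kb`.
#' @export
generate_kb <- function(config = generator_config()) {
  nd <- config$n_diseases; ns <- config$n_symptoms
  ppd <- config$pathognomonic_per_disease
  n_path <- nd * ppd
  n_shared <- max(1L, as.integer(round(config$shared_symptom_fraction * ns)))
  n_lean_total <- ns - n_path - n_shared
  if (n_lean_total < 0)
    stop(ddx_error(sprintf(
      "infeasible config: %d symptoms cannot host %d pathognomonic + %d shared",
      ns, n_path, n_shared)))
  n_lean_per <- n_lean_total %/% nd
  n_shared <- n_shared + n_lean_total %% nd

  set.seed(config$seed)
  did <- sprintf("d%02d", seq_len(nd))
  diseases <- data.frame(id = did, name = sprintf("Disease %02d", seq_len(nd)),
                         prior = stats::rgamma(nd, shape = 2, rate = 1),
                         stringsAsFactors = FALSE)

  sid <- sprintf("s%02d", seq_len(ns))
  W <- matrix(0, ns, nd, dimnames = list(sid, did))
  role <- character(ns); cat_ <- character(ns)
  k <- 0L
  lo <- config$pathognomonic_threshold       # plant strictly above the cut
  for (d in seq_len(nd)) {
    for (j in seq_len(ppd)) {
      k <- k + 1L
      W[k, ] <- stats::runif(nd, 0, 0.02)
      W[k, d] <- stats::runif(1, lo + 0.01, 0.99)
      role[k] <- "pathognomonic"; cat_[k] <- "present_illness"
    }
  }
  for (d in seq_len(nd)) {
    for (j in seq_len(n_lean_per)) {
      k <- k + 1L
      W[k, ] <- stats::runif(nd, 0, 0.3)
      W[k, d] <- stats::runif(1, config$leaning_threshold, 0.8)
      role[k] <- "leaning"; cat_[k] <- "medical_history"
    }
  }
  while (k < ns) {
    k <- k + 1L
    W[k, ] <- stats::runif(nd, 0.15, 0.45)
    role[k] <- "shared"; cat_[k] <- "presenting_complaint"
  }
  symptoms <- data.frame(
    id = sid,
    name = sprintf("Symptom %02d (%s)", seq_len(ns), role),
    category = cat_, stringsAsFactors = FALSE)
  knowledge_base(diseases, symptoms, W)
}

# Classify each symptom's role with respect to a disease, from the weight
# matrix alone (no reliance on generator bookkeeping).
.symptom_roles <- function(kb, disease_id, path_thr = 0.85, lean_thr = 0.5) {
  W <- kb$weights
  maxw <- apply(W, 1, max)
  list(
    pathognomonic = rownames(W)[W[, disease_id] >= path_thr],
    leaning = rownames(W)[W[, disease_id] >= lean_thr & maxw < path_thr],
    shared = rownames(W)[maxw < lean_thr]
  )
}

# Direct-product posterior (no logs): the generator's own small reference
# used to derive internally consistent gold differentials.
.direct_posterior <- function(kb, symptom_ids) {
  p <- kb$diseases$prior
  for (s in symptom_ids) {
    w <- pmin(pmax(kb$weights[s, ], .ddx_eps), 1 - .ddx_eps)
    p <- p * w
  }
  p / sum(p)
}

#' Generate one synthetic vignette
#'
#' Samples present-findings for `disease_id` under the stratum policy —
#' `high`: at least one pathognomonic symptom plus nonspecific complaints;
#' `moderate`: disease-leaning symptoms only (no pathognomonic) plus
#' nonspecific complaints; `low`: shared-pool symptoms only, drawn with
#' probability proportional to their weight for the disease. The gold
#' primary is the generating disease; the two gold secondaries are the
#' next-best diseases under a direct-product posterior on the sampled
#' findings, with sureties from the engine's largest-remainder rounding —
#' so the gold is internally consistent with the planted model.
#'
#' @param kb the generating `ddx_kb`.
#' @param disease_id the planted true disease.
#' @param stratum `"high"`, `"moderate"` or `"low"`.
#' @param id vignette id.
#' @param config a [generator_config()] (for the policy thresholds).
#' @param seed optional integer; when given, the vignette is regenerated
#'   reproducibly regardless of RNG state.
#' @return a `ddx_vignette`.
#' @export
generate_vignette <- function(kb, disease_id, stratum,
                              id = sprintf("v-%s-%s", disease_id, stratum),
                              config = generator_config(), seed = NULL) {
  .stop_if(!disease_id %in% kb$diseases$id,
           sprintf("undeclared disease id '%s'", disease_id))
  .stop_if(!stratum %in% .strata, sprintf("unknown stratum '%s'", stratum))
  if (!is.null(seed)) set.seed(seed)
  roles <- .symptom_roles(kb, disease_id,
                          path_thr = config$pathognomonic_threshold,
                          lean_thr = config$leaning_threshold)
  wfor <- function(ids) kb$weights[ids, disease_id] + 1e-9

  syms <- switch(stratum,
    high = {
      if (length(roles$pathognomonic) == 0)
        stop(ddx_error(sprintf("stratum 'high' unsatisfiable: %s has no pathognomonic symptom",
                               disease_id)))
      np <- sample.int(min(2L, length(roles$pathognomonic)), 1)
      c(.pick(roles$pathognomonic, np),
        if (length(roles$shared))
          .pick(roles$shared, min(length(roles$shared), sample.int(3L, 1)),
                prob = wfor(roles$shared)))
    },
    moderate = {
      if (length(roles$leaning) == 0)
        stop(ddx_error(sprintf("stratum 'moderate' unsatisfiable: %s has no disease-leaning symptom",
                               disease_id)))
      nl <- sample.int(min(2L, length(roles$leaning)), 1)
      c(.pick(roles$leaning, nl),
        if (length(roles$shared))
          .pick(roles$shared, min(length(roles$shared), 1L + sample.int(2L, 1)),
                prob = wfor(roles$shared)))
    },
    low = {
      if (length(roles$shared) == 0)
        stop(ddx_error(sprintf("stratum 'low' unsatisfiable: no shared-pool symptoms for %s",
                               disease_id)))
      .pick(roles$shared, min(length(roles$shared), 1L + sample.int(3L, 1)),
            prob = wfor(roles$shared))
    })
  syms <- unique(syms)

  post <- .direct_posterior(kb, syms)
  others <- setdiff(kb$diseases$id, disease_id)
  others <- others[.radix_order(-post[match(others, kb$diseases$id)], others)]
  gold_ids <- c(disease_id, utils::head(others, 2))
  gold <- differential(gold_ids,
                       surety_percentages(post[match(gold_ids, kb$diseases$id)]))

  demo <- list(age = sample.int(90L, 1),
               sex = .pick(c("female", "male"), 1),
               presentation_date = format(as.Date("2019-01-01") +
                                            sample.int(365L, 1) - 1L, "%Y-%m-%d"))
  clinical_vignette(id = id,
                    findings = lapply(syms, finding),
                    stratum = stratum, gold = gold, demographics = demo)
}

#' Generate a balanced, specificity-stratified vignette study
#'
#' Emits `n_diseases x 3 x vignettes_per_cell` vignettes, balanced over
#' every (disease, stratum) cell — with the default configuration, the
#' classic 90-vignette (15 x 3 x 2) design with 30 vignettes per stratum.
#' Fully deterministic under `config$seed`; each vignette is drawn from
#' its own sub-stream keyed by its cell index.
#'
#' @param kb the generating `ddx_kb` (typically from [generate_kb()]).
#' @param config a [generator_config()].
#' @return a `ddx_vignette_set`.
#' @export
generate_study <- function(kb, config = generator_config()) {
  .assert_valid_kb(kb)
  vigs <- list(); i <- 0L
  for (did in kb$diseases$id) {
    for (st in .strata) {
      for (rep in seq_len(config$vignettes_per_cell)) {
        i <- i + 1L
        vigs[[i]] <- generate_vignette(
          kb, did, st, id = sprintf("v-%s-%s-%02d", did, st, rep),
          config = config, seed = .sub_seed(config$seed, i))
      }
    }
  }
  vignette_set(vigs, label = sprintf("synthetic study (seed %d)", config$seed))
}

#' Simulate a noisy rater over a vignette study
#'
#' Starts from the engine's own differential on each vignette (the
#' noiseless oracle), then injects rater error: with probability
#' `primary_error_rate` the primary is swapped with a uniformly chosen
#' other disease (swapping slots if that disease is already a secondary),
#' and each secondary slot is replaced by a random out-of-list disease
#' with probability `differential_error_rate`. Slot sureties are kept, so
#' every emitted differential still sums to 100. Deterministic under the
#' rater seed.
#'
#' @param kb the `ddx_kb` the oracle runs on.
#' @param vs the `ddx_vignette_set` to answer.
#' @param rater a [rater_config()].
#' @return list of [prediction_record()]s, one per vignette.
#' @export
simulate_rater <- function(kb, vs, rater = rater_config()) {
  .assert_valid_kb(kb)
  .stop_if(!inherits(vs, "ddx_vignette_set"), "expected a ddx_vignette_set")
  all_d <- kb$diseases$id
  lapply(seq_along(vs$vignettes), function(i) {
    v <- vs$vignettes[[i]]
    set.seed(.sub_seed(rater$seed, i))
    d <- suppressWarnings(diagnose(kb, v, k = 3L))
    ids <- d$disease_id; sur <- d$surety
    if (stats::runif(1) < rater$primary_error_rate) {
      cand <- setdiff(all_d, ids[1])
      newd <- .pick(cand, 1)
      j <- match(newd, ids)
      if (!is.na(j)) { ids[j] <- ids[1]; ids[1] <- newd } else ids[1] <- newd
    }
    for (slot in 2:3) {
      if (stats::runif(1) < rater$differential_error_rate) {
        cand <- setdiff(all_d, ids)
        if (length(cand)) ids[slot] <- .pick(cand, 1)
      }
    }
    prediction_record(v$id, rater$label, differential(ids, sur))
  })
}

#' Run the engine over a whole vignette set
#'
#' Convenience wrapper producing one [prediction_record()] per vignette
#' under the source label `"model"`.
#'
#' @param kb a valid `ddx_kb`.
#' @param vs a `ddx_vignette_set`.
#' @param k differential depth.
#' @param source source label.
#' @return list of `ddx_prediction`s.
#' @export
diagnose_set <- function(kb, vs, k = 3L, source = "model") {
  .stop_if(!inherits(vs, "ddx_vignette_set"), "expected a ddx_vignette_set")
  lapply(vs$vignettes, function(v)
    prediction_record(v$id, source, suppressWarnings(diagnose(kb, v, k = k))))
}
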