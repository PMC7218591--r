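# Independent oracles and fixture builders. These deliberately avoid the
# package's computational paths: the posterior oracle multiplies raw
# probabilities with no logs, and the Welch oracle spells out the textbook
# formulas.

# Direct-product Bayes posterior over the closed disease set.
brute_posterior <- function(kb, findings) {
  eps <- 1e-6
  p <- kb$diseases$prior
  for (f in findings) {
    if (!f$symptom_id %in% kb$symptoms$id) next
    w <- kb$weights[f$symptom_id, ]
    w <- pmin(pmax(w, eps), 1 - eps)
    p <- p * if (f$polarity == "present") w else 1 - w
  }
  stats::setNames(p / sum(p), kb$diseases$id)
}

# Welch two-sample upper-tailed t test, written out from the
# Welch-Satterthwaite formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p_value = pt(t, df, lower.tail = FALSE))
}

# Small random KB for property tests (independent of the synthetic module).
random_kb <- function(n_d, n_s) {
  knowledge_base(
    diseases = data.frame(id = sprintf("d%d", seq_len(n_d)),
                          name = sprintf("disease %d", seq_len(n_d)),
                          prior = runif(n_d, 0.05, 1)),
    symptoms = data.frame(id = sprintf("s%d", seq_len(n_s)),
                          name = sprintf("symptom %d", seq_len(n_s)),
                          category = sample(symptom_categories, n_s, replace = TRUE)),
    weights = matrix(runif(n_s * n_d), n_s, n_d,
                     dimnames = list(sprintf("s%d", seq_len(n_s)),
                                     sprintf("d%d", seq_len(n_d))))
  )
}

random_findings <- function(kb, n) {
  ids <- sample(kb$symptoms$id, min(n, nrow(kb$symptoms)))
  lapply(ids, function(s)
    finding(s, sample(c("present", "absent"), 1)))
}

# A gold vignette whose content only matters through its gold differential;
# findings are a single dummy code.
gold_vignette <- function(id, gold_ids, surety = c(60, 25, 15),
                          stratum = "high") {
  clinical_vignette(id = id, findings = list(finding("sx")),
                    stratum = stratum,
                    gold = differential(gold_ids, surety))
}

pred_of <- function(id, ids, surety = c(60, 25, 15), source = "model") {
  prediction_record(id, source, differential(ids, surety))
}
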