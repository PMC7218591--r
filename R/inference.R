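# Inference engine: naive-Bayes posterior over the closed disease set and
# conversion to a ranked differential with integer percentage sureties.

#' Construct a finding
#'
#' One unit of evidence: a symptom code with a polarity. Symptoms a case
#' never mentions are unobserved, not absent — record `polarity = "absent"`
#' only for findings explicitly elicited as negative.
#'
#' @param symptom_id non-empty symptom code.
#' @param polarity `"present"` or `"absent"`.
#' @return a `ddx_finding`.
#' @export
finding <- function(symptom_id, polarity = c("present", "absent")) {
  polarity <- match.arg(polarity)
  .stop_if(!is.character(symptom_id) || length(symptom_id) != 1 || !nzchar(symptom_id),
           "symptom_id must be a non-empty string")
  structure(list(symptom_id = symptom_id, polarity = polarity),
            class = "ddx_finding")
}

#' Posterior disease distribution given a set of findings
#'
#' Applies Bayes' rule under the model's assumptions: the disease set is
#' closed and exhaustive, exactly one disease generates the findings, and
#' findings are conditionally independent given the disease (naive Bayes).
#' The posterior is
#' \deqn{P(d \mid f_1, \dots, f_n) \propto \pi_d \prod_i P(f_i \mid d)}
#' with each likelihood taken from the clamped association weight (see
#' [likelihood()]). Accumulation is done in log space with max-subtraction
#' before exponentiation, so long finding lists cannot underflow.
#'
#' Findings whose symptom code is not declared in the knowledge base are
#' skipped (with a warning) and counted in the result's provenance, so a
#' KB covering a limited disease domain can still consume vignettes that
#' mention out-of-scope findings. Identical duplicate findings count once;
#' the same symptom reported both present and absent is an error.
#'
#' @param kb a valid `ddx_kb`.
#' @param findings list of [finding()] objects (may be empty, in which case
#'   the posterior equals the priors).
#' @return a `ddx_posterior`: data.frame of `(disease_id, probability)` in
#'   descending probability (ties broken by disease id), with a
#'   `provenance` attribute counting findings used and skipped.
#' @examples
#' kb <- example_kb()
#' posterior(kb, list(finding("s1"), finding("s2", "absent")))
#' @export
posterior <- function(kb, findings = list()) {
  .assert_valid_kb(kb)
  if (inherits(findings, "ddx_finding")) findings <- list(findings)
  .stop_if(!is.list(findings), "findings must be a list of finding() objects")
  if (length(findings)) {
    ok <- vapply(findings, inherits, TRUE, what = "ddx_finding")
    .stop_if(!all(ok), "findings must be a list of finding() objects")
  }

  sid <- vapply(findings, `[[`, "", "symptom_id")
  pol <- vapply(findings, `[[`, "", "polarity")
  keydup <- duplicated(paste(sid, pol))
  findings <- findings[!keydup]; sid <- sid[!keydup]; pol <- pol[!keydup]
  if (anyDuplicated(sid))
    stop(ddx_error(sprintf(
      "contradictory findings: symptom(s) %s reported both present and absent",
      paste(unique(sid[duplicated(sid)]), collapse = ", "))))

  known <- sid %in% kb$symptoms$id
  if (any(!known))
    warning(sprintf("skipping %d finding(s) with symptom ids unknown to the KB: %s",
                    sum(!known), paste(sid[!known], collapse = ", ")),
            call. = FALSE)

  logp <- log(kb$diseases$prior)
  for (f in findings[known]) logp <- logp + log(.likelihood_row(kb, f))
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)

  ord <- .radix_order(-p, kb$diseases$id)
  res <- data.frame(disease_id = kb$diseases$id[ord], probability = p[ord],
                    stringsAsFactors = FALSE)
  structure(res,
            provenance = list(n_findings = length(sid),
                              n_used = sum(known),
                              n_skipped = sum(!known),
                              skipped = sid[!known]),
            class = c("ddx_posterior", "data.frame"))
}

#' @export
print.ddx_posterior <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<ddx_posterior> %d diseases (%d finding(s) used, %d skipped)\n",
              nrow(x), prov$n_used, prov$n_skipped))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}

#' Construct a differential diagnosis
#'
#' A ranked list of `(disease_id, surety)` pairs whose integer percentage
#' sureties sum to exactly 100; the first item is the primary diagnosis.
#'
#' @param disease_id character vector of distinct disease ids, best first.
#' @param surety integer percentages, same length, summing to 100.
#' @return a `ddx_differential` data.frame with columns
#'   `disease_id`, `rank`, `surety`.
#' @export
differential <- function(disease_id, surety) {
  .stop_if(length(disease_id) < 1, "differential must be non-empty")
  .stop_if(length(disease_id) != length(surety),
           "disease_id and surety lengths differ")
  .stop_if(anyDuplicated(disease_id) > 0, "duplicate disease in differential")
  s <- as.integer(round(surety))
  .stop_if(any(is.na(s)) || any(abs(surety - s) > 1e-9) || any(s < 0),
           "surety values must be non-negative integers")
  .stop_if(sum(s) != 100L,
           sprintf("surety values sum to %d, expected 100", sum(s)))
  structure(data.frame(disease_id = as.character(disease_id),
                       rank = seq_along(disease_id),
                       surety = s, stringsAsFactors = FALSE),
            class = c("ddx_differential", "data.frame"))
}

#' @export
print.ddx_differential <- function(x, ...) {
  cat(sprintf("<ddx_differential> k = %d\n", nrow(x)))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Rank a posterior into a k-item differential
#'
#' Takes the top-`k` posterior entries (ties already resolved by disease id
#' in the posterior ordering), renormalizes their probabilities, and
#' converts them to integer percentage sureties by largest-remainder
#' rounding so they sum to exactly 100.
#'
#' @param post a `ddx_posterior`.
#' @param k number of diagnoses to keep, `1 <= k <=` number of diseases.
#' @return a `ddx_differential` of length `k`.
#' @examples
#' rank_differential(posterior(example_kb(), list(finding("s1"))), k = 2)
#' @export
rank_differential <- function(post, k = 3L) {
  .stop_if(!inherits(post, "ddx_posterior"), "expected a ddx_posterior")
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > nrow(post))
    stop(ddx_error(sprintf("k must be in [1, %d], got %s", nrow(post), k)))
  top <- post[seq_len(k), ]
  differential(top$disease_id, surety_percentages(top$probability))
}

#' Diagnose a coded vignette
#'
#' Runs the full pipeline: posterior over the knowledge base's disease set
#' given the vignette's findings, then ranking into a `k`-item differential
#' with percentage sureties. Deterministic for fixed inputs. `k` defaults
#' to 3, matching the one-primary-plus-two-differentials reporting
#' convention of vignette studies.
#'
#' @param kb a valid `ddx_kb`.
#' @param vignette a `ddx_vignette` (see [clinical_vignette()]).
#' @param k differential length.
#' @return a `ddx_differential`.
#' @export
diagnose <- function(kb, vignette, k = 3L) {
  .stop_if(!inherits(vignette, "ddx_vignette"), "expected a ddx_vignette")
  rank_differential(posterior(kb, vignette$findings), k = k)
}
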