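# Knowledge base: closed disease set with priors + symptom-disease association
# weights in [0,1]. w(s,d) is read as P(symptom s present | disease d).

#' @keywords internal
.ddx_eps <- 1e-6

#' Symptom categories recognised in a knowledge base
#'
#' The closed set of history sections a coded symptom may belong to,
#' mirroring the standard medical-history format (presenting complaints,
#' present illness, medical/family/personal history) plus a `demographic`
#' category so age bands or sex can carry association weights.
#'
#' @export
symptom_categories <- c(
  "presenting_complaint", "present_illness", "medical_history",
  "family_history", "personal_history", "demographic"
)

#' Construct a symptom-disease knowledge base
#'
#' A knowledge base is the sole parameterization of the diagnostic model:
#' an ordered closed set of diseases with prior prevalence weights, an
#' ordered set of symptoms, and a dense association matrix with entries
#' `w(s, d)` in `[0, 1]` interpreted as the probability that symptom `s`
#' is present given disease `d`.
#'
#' @param diseases data.frame with columns `id`, `name` and optionally
#'   `prior`. Ids must be unique non-empty tokens without whitespace.
#'   Missing priors default to uniform.
#' @param symptoms data.frame with columns `id`, `name` and optionally
#'   `category` (one of [symptom_categories]; defaults to
#'   `"present_illness"`).
#' @param weights numeric matrix with one row per symptom and one column
#'   per disease, dimnames matching the declared ids. Rows/columns may be
#'   given in any order; missing cells (symptoms or diseases absent from
#'   the dimnames) are filled with 0, meaning "no curated association".
#' @param normalize_priors if `TRUE` (default) and all priors are
#'   non-negative with a positive sum, priors are rescaled to sum to 1.
#' @return An object of class `ddx_kb`.
#' @examples
#' kb <- knowledge_base(
#'   diseases = data.frame(id = c("flu", "cold"), name = c("Influenza", "Common cold")),
#'   symptoms = data.frame(id = "fever", name = "Fever", category = "presenting_complaint"),
#'   weights  = matrix(c(0.9, 0.4), 1, 2, dimnames = list("fever", c("flu", "cold")))
#' )
#' kb
#' @export
knowledge_base <- function(diseases, symptoms, weights = NULL,
                           normalize_priors = TRUE) {
  diseases <- as.data.frame(diseases, stringsAsFactors = FALSE)
  symptoms <- as.data.frame(symptoms, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(diseases)))
    stop("`diseases` needs columns id, name", call. = FALSE)
  if (!all(c("id", "name") %in% names(symptoms)))
    stop("`symptoms` needs columns id, name", call. = FALSE)
  diseases$id <- as.character(diseases$id)
  symptoms$id <- as.character(symptoms$id)
  if (is.null(diseases$prior) || all(is.na(diseases$prior)))
    diseases$prior <- rep(1 / nrow(diseases), nrow(diseases))
  diseases$prior <- as.numeric(diseases$prior)
  if (is.null(symptoms$category)) symptoms$category <- "present_illness"
  symptoms$category <- as.character(symptoms$category)

  W <- matrix(0, nrow(symptoms), nrow(diseases),
              dimnames = list(symptoms$id, diseases$id))
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    srows <- intersect(rownames(weights), symptoms$id)
    dcols <- intersect(colnames(weights), diseases$id)
    W[srows, dcols] <- weights[srows, dcols]
  }

  if (normalize_priors) {
    s <- sum(diseases$prior)
    if (all(!is.na(diseases$prior)) && all(diseases$prior >= 0) && s > 0)
      diseases$prior <- diseases$prior / s
  }

  structure(
    list(diseases = diseases[, c("id", "name", "prior")],
         symptoms = symptoms[, c("id", "name", "category")],
         weights  = W),
    class = "ddx_kb"
  )
}

#' @export
print.ddx_kb <- function(x, ...) {
  cat(sprintf("<ddx_kb> %d diseases x %d symptoms\n",
              nrow(x$diseases), nrow(x$symptoms)))
  cat("diseases:", paste(utils::head(x$diseases$id, 8), collapse = ", "),
      if (nrow(x$diseases) > 8) "..." else "", "\n")
  cat("symptoms:", paste(utils::head(x$symptoms$id, 8), collapse = ", "),
      if (nrow(x$symptoms) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.ddx_kb <- function(object, ...) {
  v <- validate_knowledge_base(object)
  cat(sprintf("Knowledge base: %d diseases, %d symptoms\n",
              nrow(object$diseases), nrow(object$symptoms)))
  cat(sprintf("Prior sum: %.6f | weight range: [%.3f, %.3f]\n",
              sum(object$diseases$prior),
              min(object$weights), max(object$weights)))
  cat(sprintf("Validation: %d violation(s)\n", nrow(v)))
  invisible(v)
}

.violation <- function(code, location, message) {
  data.frame(code = code, location = location, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a knowledge base
#'
#' Checks every structural invariant: unique whitespace-free ids, priors
#' non-negative and summing to 1 (within 1e-9, unless `normalized = FALSE`),
#' symptom categories from the closed set, and all weights inside `[0, 1]`
#' with dimnames matching the declared entities. Violations are returned,
#' never raised, so the function can drive both interactive checking and
#' the `validate` CLI subcommand.
#'
#' @param kb a `ddx_kb` object.
#' @param normalized if `FALSE`, skip the prior-sum check (useful for a KB
#'   deliberately held in unnormalized form).
#' @return data.frame with columns `code`, `location`, `message`, ordered
#'   by location; zero rows iff the KB is valid.
#' @export
validate_knowledge_base <- function(kb, normalized = TRUE) {
  out <- list()
  add <- function(v) out[[length(out) + 1]] <<- v

  chk_ids <- function(ids, kind) {
    bad <- which(!nzchar(ids) | grepl("\\s", ids))
    for (i in bad)
      add(.violation("bad_id", sprintf("/%s/%d/id", kind, i - 1L),
                     sprintf("%s id %d is empty or contains whitespace", kind, i)))
    dup <- which(duplicated(ids))
    for (i in dup)
      add(.violation("duplicate_id", sprintf("/%s/%d/id", kind, i - 1L),
                     sprintf("duplicate %s id '%s'", kind, ids[i])))
  }
  chk_ids(kb$diseases$id, "diseases")
  chk_ids(kb$symptoms$id, "symptoms")

  neg <- which(is.na(kb$diseases$prior) | kb$diseases$prior < 0)
  for (i in neg)
    add(.violation("prior_negative", sprintf("/diseases/%d/prior", i - 1L),
                   sprintf("prior of '%s' is missing or negative", kb$diseases$id[i])))
  if (normalized && length(neg) == 0 &&
      abs(sum(kb$diseases$prior) - 1) > 1e-9)
    add(.violation("prior_sum", "/diseases",
                   sprintf("disease priors sum to %.12g, expected 1", sum(kb$diseases$prior))))

  badcat <- which(!(kb$symptoms$category %in% symptom_categories))
  for (i in badcat)
    add(.violation("bad_category", sprintf("/symptoms/%d/category", i - 1L),
                   sprintf("symptom '%s' has unknown category '%s'",
                           kb$symptoms$id[i], kb$symptoms$category[i])))

  W <- kb$weights
  if (!identical(rownames(W), kb$symptoms$id) ||
      !identical(colnames(W), kb$diseases$id)) {
    add(.violation("weight_names", "/weights",
                   "weight matrix dimnames do not match declared symptoms x diseases"))
  } else {
    bad <- which(is.na(W) | W < 0 | W > 1, arr.ind = TRUE)
    if (nrow(bad)) {
      bad <- bad[order(bad[, 1], bad[, 2]), , drop = FALSE]
      for (r in seq_len(nrow(bad))) {
        s <- rownames(W)[bad[r, 1]]; d <- colnames(W)[bad[r, 2]]
        add(.violation("weight_range", sprintf("/weights/%s/%s", s, d),
                       sprintf("w(%s, %s) = %.12g outside [0, 1]", s, d, W[bad[r, 1], bad[r, 2]])))
      }
    }
  }

  if (length(out) == 0)
    return(.violation(character(), character(), character()))
  res <- do.call(rbind, out)
  res[order(res$location, res$code), , drop = FALSE]
}

.assert_valid_kb <- function(kb) {
  if (!inherits(kb, "ddx_kb"))
    stop(ddx_error("expected a ddx_kb object"))
  v <- validate_knowledge_base(kb)
  if (nrow(v) > 0)
    stop(ddx_error(sprintf(
      "invalid knowledge base: %d violation(s), first: [%s] %s at %s",
      nrow(v), v$code[1], v$message[1], v$location[1])))
  invisible(kb)
}

#' Likelihood of one finding under one disease
#'
#' Returns `P(finding | disease)` under the association-weight model:
#' the weight `w(s, d)`, clamped to `[eps, 1 - eps]` with `eps = 1e-6`,
#' for a present finding, and its complement for an absent finding. The
#' clamp guarantees no single finding can zero out a disease, preserving
#' a strictly positive posterior over the closed disease set.
#'
#' @param kb a `ddx_kb`.
#' @param finding a [finding()] (symptom id + polarity).
#' @param disease_id a disease id declared in `kb`.
#' @return a probability strictly inside (0, 1).
#' @examples
#' kb <- example_kb()
#' likelihood(kb, finding("s1", "present"), "d1")
#' @export
likelihood <- function(kb, finding, disease_id) {
  if (!finding$symptom_id %in% kb$symptoms$id)
    stop(ddx_error(sprintf("undeclared symptom id '%s'", finding$symptom_id)))
  if (!disease_id %in% kb$diseases$id)
    stop(ddx_error(sprintf("undeclared disease id '%s'", disease_id)))
  w <- kb$weights[finding$symptom_id, disease_id]
  w <- min(max(w, .ddx_eps), 1 - .ddx_eps)
  if (identical(finding$polarity, "present")) w else 1 - w
}

# Vectorised likelihood over all diseases, used by the inference engine.
.likelihood_row <- function(kb, finding) {
  w <- kb$weights[finding$symptom_id, ]
  w <- pmin(pmax(w, .ddx_eps), 1 - .ddx_eps)
  if (identical(finding$polarity, "present")) w else 1 - w
}

#' A small worked-example knowledge base
#'
#' Two diseases and three symptoms with round weights; handy for examples
#' and interactive exploration.
#' @return a `ddx_kb`.
#' @export
example_kb <- function() {
  knowledge_base(
    diseases = data.frame(id = c("d1", "d2"),
                          name = c("Disease one", "Disease two"),
                          prior = c(0.5, 0.5)),
    symptoms = data.frame(id = c("s1", "s2", "s3"),
                          name = c("Symptom one", "Symptom two", "Symptom three"),
                          category = c("presenting_complaint", "present_illness",
                                       "medical_history")),
    weights = matrix(c(0.9, 0.1,
                       0.7, 0.3,
                       0.2, 0.2), 3, 2, byrow = TRUE,
                     dimnames = list(c("s1", "s2", "s3"), c("d1", "d2")))
  )
}
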