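# Accuracy-analysis battery: top-k accuracy, per-disease and
# frequency-weighted precision/recall, Jaccard and cosine similarity of
# differentials, upper-tailed Welch t tests, and the stratified study report.

#' Construct a prediction record
#'
#' One source's differential for one vignette; the common output form of
#' the engine, of simulated raters, and of human raters transcribed into
#' the package's formats.
#'
#' @param vignette_id id of the vignette the prediction answers.
#' @param source label of the predicting source (e.g. `"model"`, `"rater-1"`).
#' @param differential a `ddx_differential`.
#' @return a `ddx_prediction`.
#' @export
prediction_record <- function(vignette_id, source, differential) {
  .stop_if(!is.character(vignette_id) || !nzchar(vignette_id),
           "vignette_id must be a non-empty string")
  .stop_if(!inherits(differential, "ddx_differential"),
           "differential must be a ddx_differential")
  structure(list(vignette_id = vignette_id, source = source,
                 differential = differential),
            class = "ddx_prediction")
}

# Index predictions by vignette id against a gold set; enforces one
# prediction per vignette and that every prediction resolves.
.pred_index <- function(predictions, gold) {
  .stop_if(!inherits(gold, "ddx_vignette_set"), "gold must be a ddx_vignette_set")
  ok <- vapply(predictions, inherits, TRUE, what = "ddx_prediction")
  .stop_if(!all(ok), "predictions must be ddx_prediction objects")
  pid <- vapply(predictions, `[[`, "", "vignette_id")
  if (anyDuplicated(pid))
    stop(ddx_error(sprintf("duplicate prediction(s) for vignette(s): %s",
                           paste(unique(pid[duplicated(pid)]), collapse = ", "))))
  gid <- vapply(gold$vignettes, `[[`, "", "id")
  if (!all(pid %in% gid))
    stop(ddx_error(sprintf("prediction(s) for unknown vignette id(s): %s",
                           paste(setdiff(pid, gid), collapse = ", "))))
  stats::setNames(predictions, pid)
}

#' Top-k accuracy against gold primaries
#'
#' Fraction of vignettes whose gold primary diagnosis appears anywhere in
#' the top `k` items of the prediction's differential. With the usual
#' `k = 3` this is the study's headline safety-oriented accuracy.
#'
#' @param predictions list of [prediction_record()]s, one per vignette.
#' @param gold the gold `ddx_vignette_set`.
#' @param k how deep to look into each predicted differential.
#' @return a proportion in `[0, 1]`.
#' @export
top_k_accuracy <- function(predictions, gold, k = 3L) {
  idx <- .pred_index(predictions, gold)
  covered <- gold$vignettes[vapply(gold$vignettes, `[[`, "", "id") %in% names(idx)]
  .stop_if(length(covered) == 0, "no gold vignettes covered by predictions")
  hits <- vapply(covered, function(v) {
    pred <- idx[[v$id]]$differential
    v$gold$disease_id[1] %in% utils::head(pred$disease_id, k)
  }, TRUE)
  mean(hits)
}

#' Per-disease precision and recall on primary diagnoses
#'
#' Confusion counts on the primary diagnosis only (the top item of each
#' differential): for disease `d`, TP = cases where predicted and gold
#' primary are both `d`; FP = predicted primary `d` with a different gold
#' primary; FN = gold primary `d` missed. `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`; a 0/0 ratio is reported as `NaN` and handled by
#' the aggregation policy. Diseases appearing neither as gold nor as
#' predicted primary are excluded.
#'
#' @inheritParams top_k_accuracy
#' @return data.frame with columns `disease_id`, `tp`, `fp`, `fn`,
#'   `gold_count`, `predicted_count`, `precision`, `recall`.
#' @export
per_disease_precision_recall <- function(predictions, gold) {
  idx <- .pred_index(predictions, gold)
  covered <- gold$vignettes[vapply(gold$vignettes, `[[`, "", "id") %in% names(idx)]
  gold_primary <- vapply(covered, function(v) v$gold$disease_id[1], "")
  pred_primary <- vapply(covered, function(v) idx[[v$id]]$differential$disease_id[1], "")
  diseases <- sort(unique(c(gold_primary, pred_primary)), method = "radix")
  rows <- lapply(diseases, function(d) {
    tp <- sum(gold_primary == d & pred_primary == d)
    fp <- sum(pred_primary == d & gold_primary != d)
    fn <- sum(gold_primary == d & pred_primary != d)
    data.frame(disease_id = d, tp = tp, fp = fp, fn = fn,
               gold_count = tp + fn, predicted_count = tp + fp,
               precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
               recall = if (tp + fn > 0) tp / (tp + fn) else NaN,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.aggregate_metric <- function(tab, col, undefined) {
  .stop_if(nrow(tab) == 0 || sum(tab$gold_count) == 0,
           "empty gold set: no disease frequencies to weight by")
  w <- tab$gold_count
  v <- tab[[col]]
  if (undefined == "zero") {
    v[is.nan(v)] <- 0
  } else {
    keep <- !is.nan(v)
    w <- w[keep]; v <- v[keep]
    .stop_if(sum(w) == 0, "all defined values have zero gold frequency")
  }
  sum(w * v) / sum(w)
}

#' Frequency-weighted aggregate precision
#'
#' Weighted mean of per-disease precision with weights equal to each
#' disease's gold-primary frequency. The `undefined` policy governs 0/0
#' precisions (diseases never predicted as primary): `"zero"` (default)
#' counts them as 0 with their full gold weight — conservative, it
#' penalizes never predicting a disease — while `"exclude"` drops them and
#' renormalizes the weights.
#'
#' @param per_disease table from [per_disease_precision_recall()].
#' @param undefined `"zero"` or `"exclude"`.
#' @return a proportion in `[0, 1]`.
#' @export
aggregate_precision <- function(per_disease, undefined = c("zero", "exclude")) {
  .aggregate_metric(per_disease, "precision", match.arg(undefined))
}

#' Frequency-weighted aggregate recall
#' @inheritParams aggregate_precision
#' @return a proportion in `[0, 1]`.
#' @export
aggregate_recall <- function(per_disease, undefined = c("zero", "exclude")) {
  .aggregate_metric(per_disease, "recall", match.arg(undefined))
}

.diff_ids <- function(x) {
  if (inherits(x, "ddx_differential")) x$disease_id else as.character(x)
}

#' Jaccard similarity of two differentials
#'
#' Intersection-over-union of the unordered disease-id sets of the two
#' differentials (primary included, sureties ignored) — the rank-agnostic
#' overlap of the two shortlists.
#'
#' @param pred,gold `ddx_differential`s (or character vectors of ids).
#' @return a proportion in `[0, 1]`.
#' @export
jaccard_similarity <- function(pred, gold) {
  a <- unique(.diff_ids(pred)); b <- unique(.diff_ids(gold))
  .stop_if(length(a) == 0 || length(b) == 0, "empty differential")
  length(intersect(a, b)) / length(union(a, b))
}

#' Cosine similarity of two surety-weighted differentials
#'
#' Embeds each differential as a vector over the disease universe with its
#' surety percentages as coordinates (zero for diseases not listed) and
#' returns the normalized dot product. Because coordinates are
#' non-negative the value lies in `[0, 1]`; it reaches 1 exactly when the
#' two differentials name the same diseases with proportional sureties.
#'
#' @param pred,gold `ddx_differential`s.
#' @param universe optional character vector of disease ids covering both
#'   differentials; defaults to their union (additional all-zero
#'   coordinates cannot change the value).
#' @return a proportion in `[0, 1]`.
#' @export
cosine_similarity <- function(pred, gold, universe = NULL) {
  .stop_if(!inherits(pred, "ddx_differential") || !inherits(gold, "ddx_differential"),
           "pred and gold must be ddx_differential objects")
  if (is.null(universe)) universe <- union(pred$disease_id, gold$disease_id)
  .stop_if(!all(c(pred$disease_id, gold$disease_id) %in% universe),
           "universe does not cover both differentials")
  u <- stats::setNames(numeric(length(universe)), universe)
  v <- u
  u[pred$disease_id] <- pred$surety
  v[gold$disease_id] <- gold$surety
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  .stop_if(nu == 0 || nv == 0, "zero surety vector")
  sum(u * v) / (nu * nv)
}

# Per-vignette scores for one source: the sampling units of the t tests.
.vignette_scores <- function(predictions, gold, k = 3L) {
  idx <- .pred_index(predictions, gold)
  covered <- gold$vignettes[vapply(gold$vignettes, `[[`, "", "id") %in% names(idx)]
  do.call(rbind, lapply(covered, function(v) {
    pred <- idx[[v$id]]$differential
    data.frame(
      vignette_id = v$id, stratum = v$stratum,
      hit = as.numeric(v$gold$disease_id[1] %in% utils::head(pred$disease_id, k)),
      jaccard = jaccard_similarity(pred, v$gold),
      cosine = cosine_similarity(pred, v$gold),
      stringsAsFactors = FALSE)
  }))
}

#' Study mean of per-vignette Jaccard similarities
#' @inheritParams top_k_accuracy
#' @return mean Jaccard similarity over covered vignettes.
#' @export
jaccard_mean <- function(predictions, gold) {
  mean(.vignette_scores(predictions, gold)$jaccard)
}

#' Study mean of per-vignette cosine similarities
#' @inheritParams top_k_accuracy
#' @return mean cosine similarity over covered vignettes.
#' @export
cosine_mean <- function(predictions, gold) {
  mean(.vignette_scores(predictions, gold)$cosine)
}

#' Upper-tailed Welch two-sample t test
#'
#' Tests whether `mean(scores_a)` exceeds `mean(scores_b)` using the
#' unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees
#' of freedom and an upper-tail p value. If both samples are constant the
#' statistic degenerates; by convention equal constants give `p = 0.5`
#' (and the result is flagged), separated constants give `p` of 0 or 1.
#'
#' @param scores_a,scores_b numeric vectors of length >= 2.
#' @param metric optional label carried into the result.
#' @return a `ddx_ttest` list: `statistic`, `df`, `p_value`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `degenerate`.
#' @export
upper_tailed_t_test <- function(scores_a, scores_b, metric = NA_character_) {
  .stop_if(length(scores_a) < 2 || length(scores_b) < 2,
           "each sample needs at least 2 observations")
  ma <- mean(scores_a); mb <- mean(scores_b)
  va <- stats::var(scores_a); vb <- stats::var(scores_b)
  if (va == 0 && vb == 0) {
    res <- list(statistic = if (ma == mb) 0 else sign(ma - mb) * Inf,
                df = NA_real_,
                p_value = if (ma == mb) 0.5 else if (ma > mb) 0 else 1,
                degenerate = TRUE)
  } else {
    tt <- stats::t.test(scores_a, scores_b, alternative = "greater",
                        var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, degenerate = FALSE)
  }
  structure(c(list(metric = metric), res,
              list(n_a = length(scores_a), n_b = length(scores_b),
                   mean_a = ma, mean_b = mb)),
            class = "ddx_ttest")
}

#' @export
print.ddx_ttest <- function(x, ...) {
  cat(sprintf(
    "Upper-tailed Welch t test%s: t = %.4g (df = %.4g), p = %.4g\n  mean_a = %.4g (n = %d) vs mean_b = %.4g (n = %d)%s\n",
    if (!is.na(x$metric)) paste0(" [", x$metric, "]") else "",
    x$statistic, x$df, x$p_value, x$mean_a, x$n_a, x$mean_b, x$n_b,
    if (isTRUE(x$degenerate)) "  (degenerate)" else ""))
  invisible(x)
}

#' Evaluate one or more prediction sources against a gold vignette study
#'
#' Computes the full metric battery for every source, per specificity
#' stratum and overall (the full set, not an average of strata), and —
#' when a source labelled `model_source` is present alongside others —
#' upper-tailed Welch t tests comparing the model's per-vignette scores
#' (top-k hit indicators, Jaccard, cosine) against the pooled non-model
#' sources' scores.
#'
#' @param gold the gold `ddx_vignette_set`.
#' @param predictions_by_source named list: source label -> list of
#'   [prediction_record()]s covering every vignette in `gold`.
#' @param model_source which source plays the model in comparisons.
#' @param k differential depth for top-k accuracy.
#' @param undefined_precision policy passed to the aggregates.
#' @return a `ddx_eval` with elements `metrics` (data.frame: one row per
#'   source x stratum), `per_disease` (nested list of confusion tables),
#'   `comparisons` (data.frame of t-test results) and `scores`
#'   (per-vignette score table used by the tests).
#' @export
evaluate_study <- function(gold, predictions_by_source,
                           model_source = "model", k = 3L,
                           undefined_precision = c("zero", "exclude")) {
  undefined_precision <- match.arg(undefined_precision)
  .stop_if(is.null(names(predictions_by_source)) ||
             any(!nzchar(names(predictions_by_source))),
           "predictions_by_source must be a named list")
  gid <- vapply(gold$vignettes, `[[`, "", "id")
  for (src in names(predictions_by_source)) {
    pid <- vapply(predictions_by_source[[src]], `[[`, "", "vignette_id")
    miss <- setdiff(gid, pid)
    if (length(miss))
      stop(ddx_error(sprintf("source '%s' missing prediction(s) for: %s",
                             src, paste(miss, collapse = ", "))))
  }

  strata_sets <- c(stratify(gold), list(overall = gold))
  metrics <- list(); per_disease <- list(); scores <- list()
  for (src in names(predictions_by_source)) {
    preds <- predictions_by_source[[src]]
    sc <- .vignette_scores(preds, gold, k = k)
    sc$source <- src
    scores[[src]] <- sc
    per_disease[[src]] <- list()
    for (st in names(strata_sets)) {
      gsub <- strata_sets[[st]]
      if (length(gsub) == 0) next
      ids <- vapply(gsub$vignettes, `[[`, "", "id")
      psub <- preds[vapply(preds, `[[`, "", "vignette_id") %in% ids]
      tab <- per_disease_precision_recall(psub, gsub)
      per_disease[[src]][[st]] <- tab
      metrics[[length(metrics) + 1]] <- data.frame(
        source = src, stratum = st, n = length(gsub),
        top3_accuracy = top_k_accuracy(psub, gsub, k = k),
        precision_aggregate = aggregate_precision(tab, undefined_precision),
        recall_aggregate = aggregate_recall(tab, undefined_precision),
        jaccard_mean = jaccard_mean(psub, gsub),
        cosine_mean = cosine_mean(psub, gsub),
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, metrics)
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL

  comparisons <- NULL
  others <- setdiff(names(predictions_by_source), model_source)
  if (model_source %in% names(predictions_by_source) && length(others)) {
    msc <- scores[scores$source == model_source, ]
    osc <- scores[scores$source %in% others, ]
    comparisons <- do.call(rbind, lapply(
      c(top3_accuracy = "hit", jaccard_mean = "jaccard", cosine_mean = "cosine"),
      function(col) {
        tt <- upper_tailed_t_test(msc[[col]], osc[[col]], metric = col)
        data.frame(metric = col, source_a = model_source,
                   source_b = paste(others, collapse = "+"),
                   statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
                   n_a = tt$n_a, n_b = tt$n_b, stringsAsFactors = FALSE)
      }))
    comparisons$metric <- c("top3_accuracy", "jaccard_mean", "cosine_mean")
    rownames(comparisons) <- NULL
  }

  structure(list(metrics = metrics, per_disease = per_disease,
                 comparisons = comparisons, scores = scores, k = k),
            class = "ddx_eval")
}

#' @export
print.ddx_eval <- function(x, digits = 3, ...) {
  cat(sprintf("<ddx_eval> %d source(s), k = %d\n", length(x$per_disease), x$k))
  m <- x$metrics
  num <- vapply(m, is.numeric, TRUE)
  m[num] <- lapply(m[num], round, digits = digits)
  print.data.frame(m, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\nModel vs pooled raters (upper-tailed Welch t):\n")
    cmp <- x$comparisons
    cmp$statistic <- round(cmp$statistic, digits)
    cmp$df <- round(cmp$df, 1)
    cmp$p_value <- signif(cmp$p_value, 3)
    print.data.frame(cmp, row.names = FALSE)
  }
  invisible(x)
}

#' Read prediction records from a JSON-lines file
#' @param path JSON-lines file, one prediction object per line.
#' @return list of `ddx_prediction`s.
#' @export
read_predictions <- function(path) {
  .stop_if(!file.exists(path), sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) stop(ddx_error(
                      sprintf("line %d: malformed JSON: %s", i, conditionMessage(e)))))
    items <- .need(.need(obj, "differential", sprintf("line %d", i)), "items",
                   sprintf("line %d/differential", i))
    prediction_record(
      vignette_id = .as_scalar_chr(.need(obj, "vignette_id", sprintf("line %d", i)), "vignette_id"),
      source = .as_scalar_chr(.need(obj, "source", sprintf("line %d", i)), "source"),
      differential = differential(
        vapply(items, function(it) as.character(it$disease_id), ""),
        vapply(items, function(it) as.numeric(it$surety), 0)))
  })
}

#' Write prediction records to a JSON-lines file
#' @param predictions list of `ddx_prediction`s.
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  lines <- vapply(predictions, function(p) {
    d <- p$differential
    obj <- list(vignette_id = p$vignette_id, source = p$source,
                differential = list(
                  items = lapply(seq_len(nrow(d)), function(i)
                    list(disease_id = d$disease_id[i], rank = d$rank[i],
                         surety = d$surety[i])),
                  k = nrow(d)))
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write an evaluation report
#'
#' @param ev a `ddx_eval`.
#' @param path output path.
#' @param format `"json"` (machine-readable bundle) or `"tsv"`
#'   (aligned long-format table, one row per source x stratum x metric).
#' @export
write_report <- function(ev, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  .stop_if(!inherits(ev, "ddx_eval"), "expected a ddx_eval")
  if (format == "json") {
    doc <- list(metrics = ev$metrics,
                comparisons = ev$comparisons,
                per_disease = ev$per_disease)
    writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE, na = "null")),
               path, useBytes = TRUE)
  } else {
    m <- ev$metrics
    long <- do.call(rbind, lapply(
      c("top3_accuracy", "precision_aggregate", "recall_aggregate",
        "jaccard_mean", "cosine_mean"),
      function(col) data.frame(source = m$source, stratum = m$stratum,
                               metric = col, value = sprintf("%.6f", m[[col]]),
                               stringsAsFactors = FALSE)))
    long <- long[order(long$source, long$stratum, long$metric, method = "radix"), ]
    utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
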