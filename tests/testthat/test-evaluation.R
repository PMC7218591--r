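# Metric fixtures are small constructed studies with hand-countable
# confusion tables; helpers gold_vignette()/pred_of() live in helper-oracles.R.

test_that("top-k accuracy counts gold primaries found in the top k", {
  # 10 vignettes, gold primary in the predicted 3-list for exactly 7
  gold <- vignette_set(lapply(1:10, function(i)
    gold_vignette(sprintf("v%02d", i), c("A", "B", "C"))))
  preds <- c(
    lapply(1:4, function(i) pred_of(sprintf("v%02d", i), c("A", "X", "Y"))),  # rank 1
    lapply(5:7, function(i) pred_of(sprintf("v%02d", i), c("X", "Y", "A"))),  # rank 3
    lapply(8:10, function(i) pred_of(sprintf("v%02d", i), c("X", "Y", "Z"))))  # miss
  expect_equal(top_k_accuracy(preds, gold, k = 3), 0.7)
  expect_equal(top_k_accuracy(preds, gold, k = 1), 0.4)

  # rank-3-only predictions: 1.0 at k = 3, 0.0 at k = 1
  p3 <- lapply(1:10, function(i) pred_of(sprintf("v%02d", i), c("X", "Y", "A")))
  expect_equal(top_k_accuracy(p3, gold, k = 3), 1.0)
  expect_equal(top_k_accuracy(p3, gold, k = 1), 0.0)

  # non-decreasing in k
  accs <- vapply(1:3, function(k) top_k_accuracy(preds, gold, k = k), 1)
  expect_true(all(diff(accs) >= 0))

  expect_error(top_k_accuracy(c(preds, preds[1]), gold), "duplicate")
  expect_error(top_k_accuracy(list(pred_of("zz", c("A", "B", "C"))), gold),
               "unknown vignette")
})

test_that("per-disease precision/recall match hand confusion counts", {
  # A predicted primary 4x, correct 3x; B gold 3x, predicted 1x correct
  gold <- vignette_set(list(
    gold_vignette("v1", c("A", "B", "C")), gold_vignette("v2", c("A", "X", "Y")),
    gold_vignette("v3", c("A", "B", "C")), gold_vignette("v4", c("B", "A", "C")),
    gold_vignette("v5", c("B", "C", "X")), gold_vignette("v6", c("B", "C", "Y"))))
  preds <- list(
    pred_of("v1", c("A", "B", "C")), pred_of("v2", c("A", "X", "Y")),
    pred_of("v3", c("A", "B", "C")), pred_of("v4", c("A", "B", "C")),
    pred_of("v5", c("B", "C", "X")), pred_of("v6", c("X", "B", "Y")))
  tab <- per_disease_precision_recall(preds, gold)

  expect_equal(tab$precision[tab$disease_id == "A"], 3 / 4)
  expect_equal(tab$recall[tab$disease_id == "A"], 1)
  expect_equal(tab$precision[tab$disease_id == "B"], 1)
  expect_equal(tab$recall[tab$disease_id == "B"], 1 / 3)
  # X: predicted once, never gold primary
  expect_equal(tab$precision[tab$disease_id == "X"], 0)
  expect_equal(tab$gold_count[tab$disease_id == "X"], 0)
  # diseases never gold and never predicted are excluded
  expect_false("C" %in% tab$disease_id)

  # all-correct limit
  perfect <- lapply(gold$vignettes, function(v)
    pred_of(v$id, v$gold$disease_id, v$gold$surety))
  tp <- per_disease_precision_recall(perfect, gold)
  expect_true(all(tp$precision[tp$gold_count > 0] == 1))
  expect_true(all(tp$recall[tp$gold_count > 0] == 1))
})

test_that("aggregates are gold-frequency-weighted means with a 0/0 policy", {
  tab <- data.frame(disease_id = c("A", "B"), tp = c(3, 2), fp = c(0, 2),
                    fn = c(3, 0), gold_count = c(6, 4), predicted_count = c(3, 4),
                    precision = c(1.0, 0.5), recall = c(0.5, 1.0))
  expect_equal(aggregate_precision(tab), 0.6 * 1.0 + 0.4 * 0.5)  # 0.8
  expect_equal(aggregate_recall(tab), 0.6 * 0.5 + 0.4 * 1.0)

  # equal gold frequencies reduce to the unweighted mean
  tab$gold_count <- c(5, 5)
  expect_equal(aggregate_precision(tab), mean(tab$precision))

  # a never-predicted disease (0/0) counts as zero, or is excluded on request
  tab2 <- data.frame(disease_id = c("A", "B"), tp = c(4, 0), fp = c(0, 0),
                     fn = c(0, 4), gold_count = c(4, 4), predicted_count = c(4, 0),
                     precision = c(1.0, NaN), recall = c(1.0, 0))
  expect_equal(aggregate_precision(tab2, undefined = "zero"), 0.5)
  expect_equal(aggregate_precision(tab2, undefined = "exclude"), 1.0)

  # single disease in gold: aggregate equals its value
  tab3 <- tab2[1, ]
  expect_equal(aggregate_precision(tab3), 1.0)
})

test_that("Jaccard works on unordered 3-sets", {
  d1 <- differential(c("a", "b", "c"), c(60, 25, 15))
  d2 <- differential(c("c", "a", "b"), c(98, 1, 1))
  d3 <- differential(c("a", "b", "d"), c(40, 30, 30))
  d4 <- differential(c("x", "y", "z"), c(40, 30, 30))
  expect_equal(jaccard_similarity(d1, d2), 1.0)   # order and surety ignored
  expect_equal(jaccard_similarity(d1, d3), 0.5)   # 2 shared / 4 in union
  expect_equal(jaccard_similarity(d1, d4), 0.0)
})

test_that("cosine similarity reproduces the worked dot-product example", {
  u <- differential(c("a", "b", "c"), c(50, 30, 20))
  v <- differential(c("a", "b", "c"), c(20, 30, 50))
  expect_equal(cosine_similarity(u, v), 2900 / 3800, tolerance = 1e-9)
  expect_equal(cosine_similarity(u, u), 1.0, tolerance = 1e-12)
  w <- differential(c("x", "y", "z"), c(50, 30, 20))
  expect_equal(cosine_similarity(u, w), 0.0)
  # proportional sureties also reach 1
  v2 <- differential(c("a", "b", "c"), c(25, 15, 10) * 2)
  expect_equal(cosine_similarity(u, v2), 1.0, tolerance = 1e-12)
  # a larger universe with zero coordinates changes nothing
  expect_equal(cosine_similarity(u, v, universe = letters), 2900 / 3800,
               tolerance = 1e-12)
})

test_that("the upper-tailed Welch t test matches the textbook formulas", {
  a <- c(0.9, 0.8, 1.0, 0.7); b <- c(0.5, 0.6, 0.4, 0.7)
  got <- upper_tailed_t_test(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$df, want$df, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)

  # identical samples: symmetric null
  same <- upper_tailed_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)

  # near-separation drives p toward 0
  sep <- upper_tailed_t_test(1 + 1e-6 * rnorm(20), 0 + 1e-6 * rnorm(20))
  expect_lt(sep$p_value, 1e-10)

  # degenerate constants
  expect_true(upper_tailed_t_test(c(1, 1), c(1, 1))$degenerate)
  expect_equal(upper_tailed_t_test(c(1, 1), c(1, 1))$p_value, 0.5)
  expect_equal(upper_tailed_t_test(c(2, 2), c(1, 1))$p_value, 0)
  expect_equal(upper_tailed_t_test(c(1, 1), c(2, 2))$p_value, 1)
  expect_error(upper_tailed_t_test(1, c(1, 2)), "at least 2")
})

test_that("evaluate_study reports per-stratum metrics and recomputable aggregates", {
  gold <- vignette_set(c(
    lapply(1:4, function(i) gold_vignette(sprintf("h%d", i), c("A", "B", "C"),
                                          stratum = "high")),
    lapply(1:4, function(i) gold_vignette(sprintf("m%d", i), c("B", "A", "C"),
                                          stratum = "moderate")),
    lapply(1:4, function(i) gold_vignette(sprintf("l%d", i), c("C", "A", "B"),
                                          stratum = "low"))))
  perfect <- lapply(gold$vignettes, function(v)
    pred_of(v$id, v$gold$disease_id, v$gold$surety))
  ev <- evaluate_study(gold, list(model = perfect))
  expect_equal(nrow(ev$metrics), 4)  # 3 strata + overall
  for (col in c("top3_accuracy", "precision_aggregate", "recall_aggregate",
                "jaccard_mean", "cosine_mean"))
    expect_true(all(ev$metrics[[col]] == 1))

  # a flawed rater: primary wrong on every moderate vignette
  noisy <- lapply(gold$vignettes, function(v) {
    ids <- if (v$stratum == "moderate") c("Z", v$gold$disease_id[2:3])
           else v$gold$disease_id
    pred_of(v$id, ids, v$gold$surety, source = "rater-1")
  })
  ev2 <- evaluate_study(gold, list(model = perfect, `rater-1` = noisy))
  m <- ev2$metrics
  expect_equal(m$top3_accuracy[m$source == "rater-1" & m$stratum == "moderate"], 0)
  expect_equal(m$top3_accuracy[m$source == "rater-1" & m$stratum == "overall"], 2 / 3)

  # aggregates recompute from the stored per-disease tables
  for (src in names(ev2$per_disease)) for (st in names(ev2$per_disease[[src]])) {
    tab <- ev2$per_disease[[src]][[st]]
    row <- m[m$source == src & m$stratum == st, ]
    expect_equal(row$precision_aggregate, aggregate_precision(tab))
    expect_equal(row$recall_aggregate, aggregate_recall(tab))
  }

  # comparisons cover the three per-vignette metrics
  expect_equal(ev2$comparisons$metric,
               c("top3_accuracy", "jaccard_mean", "cosine_mean"))
  expect_true(all(ev2$comparisons$p_value >= 0 & ev2$comparisons$p_value <= 1))

  # coverage gaps are named
  expect_error(evaluate_study(gold, list(model = perfect[-1])),
               "missing prediction.*h1")
})

test_that("the metric battery is invariant to vignette ordering", {
  set.seed(61)
  kb <- generate_kb(generator_config(seed = 61))
  vs <- generate_study(kb, generator_config(seed = 61))
  preds <- diagnose_set(kb, vs)
  perm <- sample(length(vs))
  vs2 <- vignette_set(vs$vignettes[perm], label = vs$label)
  ev1 <- evaluate_study(vs, list(model = preds))
  ev2 <- evaluate_study(vs2, list(model = rev(preds)))
  expect_equal(ev1$metrics[ev1$metrics$stratum == "overall", -(1:2)],
               ev2$metrics[ev2$metrics$stratum == "overall", -(1:2)],
               tolerance = 1e-12)
})

test_that("prediction records round-trip through JSON lines", {
  preds <- list(pred_of("v1", c("a", "b", "c")),
                pred_of("v2", c("c", "a", "b"), c(98, 1, 1)))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_predictions(preds, path)
  back <- read_predictions(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$vignette_id, "v1")
  expect_equal(as.data.frame(back[[2]]$differential),
               as.data.frame(preds[[2]]$differential))
})
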