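test_that("priors are normalized on construction and default to uniform", {
  kb <- knowledge_base(
    diseases = data.frame(id = c("a", "b"), name = c("A", "B"), prior = c(1, 1)),
    symptoms = data.frame(id = "s", name = "S"))
  expect_equal(kb$diseases$prior, c(0.5, 0.5))

  kb2 <- knowledge_base(
    diseases = data.frame(id = c("a", "b", "c"), name = c("A", "B", "C")),
    symptoms = data.frame(id = "s", name = "S"))
  expect_equal(kb2$diseases$prior, rep(1 / 3, 3))

  # missing weight cells fill as zero
  kb3 <- knowledge_base(
    diseases = data.frame(id = c("a", "b"), name = c("A", "B")),
    symptoms = data.frame(id = c("s1", "s2"), name = c("S1", "S2")),
    weights = matrix(0.4, 1, 1, dimnames = list("s1", "a")))
  expect_equal(kb3$weights["s2", "b"], 0)
  expect_equal(kb3$weights["s1", "a"], 0.4)
})

test_that("likelihood clamps into (0,1) and respects the complement identity", {
  kb <- knowledge_base(
    diseases = data.frame(id = c("a", "b"), name = c("A", "B")),
    symptoms = data.frame(id = c("s0", "s1", "s7"), name = c("z", "o", "m")),
    weights = matrix(c(0, 0, 1, 1, 0.7, 0.7), 3, 2, byrow = TRUE,
                     dimnames = list(c("s0", "s1", "s7"), c("a", "b"))))
  expect_equal(likelihood(kb, finding("s0", "present"), "a"), 1e-6)
  expect_equal(likelihood(kb, finding("s1", "absent"), "a"), 1e-6)
  expect_equal(likelihood(kb, finding("s7", "absent"), "a"), 0.3, tolerance = 1e-9)

  # present + absent = 1 and strict interiority, across random KBs
  set.seed(11)
  for (rep in 1:5) {
    rkb <- random_kb(4, 6)
    for (s in rkb$symptoms$id) for (d in rkb$diseases$id) {
      lp <- likelihood(rkb, finding(s, "present"), d)
      la <- likelihood(rkb, finding(s, "absent"), d)
      expect_lt(abs(lp + la - 1), 1e-12)
      expect_gt(lp, 0); expect_lt(lp, 1)
    }
  }
  expect_error(likelihood(kb, finding("nope"), "a"), "undeclared symptom")
  expect_error(likelihood(kb, finding("s0"), "nope"), "undeclared disease")
})

test_that("validate_knowledge_base flags each single-field corruption", {
  kb <- example_kb()
  expect_equal(nrow(validate_knowledge_base(kb)), 0)

  dup <- kb; dup$diseases$id[2] <- "d1"
  dup$weights <- kb$weights; colnames(dup$weights) <- dup$diseases$id
  expect_true("duplicate_id" %in% validate_knowledge_base(dup)$code)

  off <- kb; off$diseases$prior <- c(0.5, 0.4)
  v <- validate_knowledge_base(off)
  expect_true("prior_sum" %in% v$code)
  expect_equal(nrow(validate_knowledge_base(off, normalized = FALSE)), 0)

  neg <- kb; neg$diseases$prior <- c(1.2, -0.2)
  expect_true("prior_negative" %in% validate_knowledge_base(neg)$code)

  cat_ <- kb; cat_$symptoms$category[1] <- "vibes"
  expect_true("bad_category" %in% validate_knowledge_base(cat_)$code)

  big <- kb; big$weights["s2", "d1"] <- 1.2
  v <- validate_knowledge_base(big)
  expect_true("weight_range" %in% v$code)
  expect_match(v$location[v$code == "weight_range"], "s2/d1")

  ws <- kb; ws$symptoms$id[1] <- "s 1"
  expect_true("bad_id" %in% validate_knowledge_base(ws)$code)

  mis <- kb; rownames(mis$weights)[1] <- "zzz"
  expect_true("weight_names" %in% validate_knowledge_base(mis)$code)

  # violations come back ordered by location, deterministically
  both <- kb; both$weights["s1", "d1"] <- 2; both$weights["s3", "d2"] <- -1
  v <- validate_knowledge_base(both)
  expect_equal(v$location, sort(v$location))
})

test_that("JSON and CSV round-trips reproduce the knowledge base", {
  kb <- example_kb()
  jpath <- withr::local_tempfile(fileext = ".json")
  save_knowledge_base(kb, jpath)
  kb2 <- load_knowledge_base(jpath)
  expect_equal(kb2$diseases, kb$diseases, tolerance = 1e-12)
  expect_equal(kb2$symptoms, kb$symptoms)
  expect_equal(kb2$weights, kb$weights, tolerance = 1e-12)

  cdir <- withr::local_tempdir()
  save_knowledge_base(kb, cdir, format = "csv")
  expect_true(file.exists(file.path(cdir, "entities.csv")))
  kb3 <- load_knowledge_base(cdir, format = "csv")
  expect_equal(kb3$diseases, kb$diseases, tolerance = 1e-12)
  expect_equal(kb3$weights, kb$weights, tolerance = 1e-12)

  # randomized round-trip at full precision
  set.seed(5)
  rkb <- random_kb(5, 7)
  save_knowledge_base(rkb, jpath)
  expect_equal(load_knowledge_base(jpath)$weights, rkb$weights, tolerance = 1e-12)
})

test_that("loading rejects malformed knowledge bases with located errors", {
  expect_error(load_knowledge_base("no/such/file.json"), "no such file")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"diseases":[{"id":"a","name":"A"}],"symptoms":[{"id":"s","name":"S"}],
              "weights":{"s":{"a":1.2}}}', bad)
  expect_error(load_knowledge_base(bad), "/weights/s/a")

  writeLines('{"diseases":[{"id":"a","name":"A"},{"id":"a","name":"B"}],
              "symptoms":[]}', bad)
  expect_error(load_knowledge_base(bad), "duplicate")

  writeLines('{"symptoms":[]}', bad)
  expect_error(load_knowledge_base(bad), "missing key 'diseases'")

  # an invalid KB is refused by save and nothing is written
  kb <- example_kb(); kb$weights["s1", "d1"] <- 7
  out <- file.path(withr::local_tempdir(), "kb.json")
  expect_error(save_knowledge_base(kb, out), "invalid knowledge base")
  expect_false(file.exists(out))
})

test_that("the packaged 15-disease synthetic fixture is valid and complete", {
  path <- system.file("extdata", "fever15_synthetic_kb.json", package = "ddxbayes")
  kb <- load_knowledge_base(path)
  expect_equal(nrow(kb$diseases), 15)
  expect_equal(nrow(kb$symptoms), 60)
  expect_equal(sum(kb$diseases$prior), 1, tolerance = 1e-9)
  expect_equal(nrow(validate_knowledge_base(kb)), 0)
})
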