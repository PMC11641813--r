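test_that("weight derivation matches a brute-force evaluation of the formula", {
  set.seed(101)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    m <- runif(k, 1, 5)
    s <- runif(k, 0.2, 1.5)
    w <- derive_weights(m, s)
    # independent re-evaluation, element by element
    denom <- 0
    for (j in seq_len(k)) denom <- denom + m[j] / s[j]
    for (j in seq_len(k)) expect_equal(w[j], 100 * (m[j] / s[j]) / denom)
    expect_equal(sum(w), 100, tolerance = 1e-12)
    expect_true(all(w > 0))
    # pairwise ratios equal the mean-over-sd ratios
    expect_equal(w[1] / w[2], (m[1] / s[1]) / (m[2] / s[2]))
  }
})

test_that("weight derivation handles degenerate and trivial inputs", {
  expect_equal(derive_weights(4.0, 1.0), 100)
  expect_equal(derive_weights(rep(3.2, 4), rep(0.7, 4)), rep(25, 4))
  expect_error(derive_weights(numeric(), numeric()), "empty")
  expect_error(derive_weights(c(4, 3), c(0.5, 0)), "degenerate")
  # opt-in floor fallback replaces the zero sd
  w <- derive_weights(c(4, 3), c(0.5, 0), sd_floor = 0.1)
  expect_equal(w, 100 * c(4 / 0.5, 3 / 0.1) / (4 / 0.5 + 3 / 0.1))
})

test_that("weights are invariant to a common positive rescaling of ratings", {
  set.seed(7)
  m <- runif(6, 1, 4.5); s <- runif(6, 0.3, 1.2)
  for (c0 in c(0.5, 2, 10))
    expect_equal(derive_weights(m, s), derive_weights(pmin(c0 * m, 5 * c0) , c0 * s))
})

test_that("importance threshold selection retains high-mean and overridden items", {
  # the six published pattern candidates all clear the 3.00 cutoff
  pats <- c("LSDH", "FRDO", "SSDC", "SDQS", "TACH", "DHSS")
  means <- c(4.21, 4.00, 3.86, 3.50, 3.14, 3.07)
  expect_equal(select_by_importance(pats, means, 3), pats)
  expect_equal(select_by_importance(character(), numeric(), 3), character())
  # the below-threshold item survives only through the override
  expect_equal(select_by_importance("Q8", 2.82, 3), character())
  expect_equal(select_by_importance("Q8", 2.82, 3, overrides = "Q8"), "Q8")
  # order preserved with mixed retention
  expect_equal(select_by_importance(c("a", "b", "c"), c(3.5, 2.1, 4.0), 3), c("a", "c"))
})

test_that("item removal re-normalizes the surviving weights", {
  instr <- toy_instrument()
  expect_identical(remove_items_and_reweight(instr, character()), instr)
  rev <- remove_items_and_reweight(instr, "I4")
  expect_false("I4" %in% rev$items$item_id)
  ms <- rev$memberships
  b <- ms[ms$pattern_id == "B", ]
  # survivors re-normalize to 100 in the ratio of their mean/sd (brute force)
  r <- b$importance_mean / b$importance_sd
  expect_equal(b$weight, 100 * r / sum(r))
  expect_equal(sum(b$weight), 100, tolerance = 1e-9)
  # disjoint drops commute
  ab <- remove_items_and_reweight(remove_items_and_reweight(instr, "I1"), "I5")
  ba <- remove_items_and_reweight(remove_items_and_reweight(instr, "I5"), "I1")
  expect_equal(ab$memberships, ba$memberships)
  # emptying a pattern is refused
  expect_error(remove_items_and_reweight(instr, c("I3", "I4", "I5")),
               "empty pattern")
  expect_error(remove_items_and_reweight(instr, "nope"), "unknown item")
})

test_that("instrument JSON round-trips field for field", {
  instr <- toy_instrument()
  path <- withr::local_tempfile(fileext = ".json")
  write_instrument(instr, path)
  back <- read_instrument(path)
  expect_equal(back$instrument_id, instr$instrument_id)
  expect_equal(back$version, instr$version)
  expect_equal(back$patterns, instr$patterns)
  expect_equal(back$items, instr$items)
  expect_equal(back$memberships, instr$memberships, tolerance = 1e-12)
})

test_that("loading a malformed instrument names the offending record", {
  instr <- toy_instrument()
  path <- withr::local_tempfile(fileext = ".json")
  write_instrument(instr, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$memberships$item_id[1] <- "GHOST"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_instrument(path), "GHOST")
  # duplicate item ids are refused too
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$memberships$item_id[1] <- "I1"
  obj$items$item_id[2] <- "I1"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_instrument(path), "duplicate")
})

test_that("packaged draft fixture has the published structure", {
  d <- stpi_draft38()
  expect_s3_class(d, "stpi_instrument")
  expect_equal(d$version, "draft38")
  expect_equal(nrow(d$patterns), 6)
  expect_equal(d$patterns$pattern_id,
               c("SSDC", "SDQS", "LSDH", "TACH", "DHSS", "FRDO"))
  expect_equal(sum(d$items$rater == "patient"), 38)
  expect_equal(sum(d$items$rater == "evaluator_tongue"), 6)
  expect_equal(sum(d$items$rater == "evaluator_pulse"), 5)
  cnt <- table(factor(d$memberships$pattern_id, levels = d$patterns$pattern_id))
  expect_equal(as.integer(cnt), c(10, 10, 13, 12, 12, 9))
  # shared items carry membership-specific ratings
  q26 <- d$memberships[d$memberships$item_id == "Q26", ]
  expect_equal(nrow(q26), 2)
  expect_true(length(unique(q26$importance_mean)) == 2)
})

test_that("packaged final fixture is the pruned draft, reweighted", {
  d <- stpi_draft38()
  f <- stpi_final36()
  expect_equal(nrow(f$items), 36)
  expect_true(all(f$items$rater == "patient"))
  cnt <- table(factor(f$memberships$pattern_id, levels = f$patterns$pattern_id))
  expect_equal(as.integer(cnt), c(8, 8, 11, 9, 9, 7))
  ev <- d$items$item_id[d$items$rater != "patient"]
  redo <- remove_items_and_reweight(d, c("Q32", "Q33", ev), version = "final36")
  expect_equal(f$items, redo$items)
  expect_equal(f$memberships, redo$memberships, tolerance = 1e-9)
})

test_that("per-pattern weights always sum to 100 in the packaged fixtures", {
  for (instr in list(stpi_draft38(), stpi_final36())) {
    ws <- tapply(instr$memberships$weight, instr$memberships$pattern_id, sum)
    expect_true(all(abs(ws - 100) < 1e-6))
  }
})
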