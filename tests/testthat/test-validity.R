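# Published pattern-by-subtype cross-table (rows SSDC..FRDO, cols
# PDS/EPS/overlapping) and its reported exact p.
subtype_counts <- matrix(c(19, 13, 17,
                          5, 3, 1,
                          2, 4, 1,
                          3, 5, 5,
                          3, 4, 7,
                          3, 0, 0), nrow = 6, byrow = TRUE,
                        dimnames = list(c("SSDC", "SDQS", "LSDH", "TACH",
                                          "DHSS", "FRDO"),
                                        c("PDS", "EPS", "overlapping")))

test_that("the exact test reproduces the published 6x3 p-value", {
  ct <- contingency_test(subtype_counts)
  expect_equal(ct$test, "fisher_freeman_halton")  # expected counts < 5
  expect_false(ct$monte_carlo)
  expect_equal(round(ct$p_value, 3), 0.289)
})

test_that("exact p-values are invariant under row/column permutation", {
  p0 <- contingency_test(subtype_counts)$p_value
  set.seed(4)
  for (rep in 1:3) {
    perm <- subtype_counts[sample(6), sample(3)]
    expect_equal(contingency_test(perm)$p_value, p0, tolerance = 1e-9)
  }
})

test_that("exact 2x2 p equals brute-force hypergeometric on all small tables", {
  checked <- 0
  for (R1 in 1:6) for (R2 in 1:6) for (C1 in 1:6) {
    N <- R1 + R2
    C2 <- N - C1
    if (C2 < 1 || C2 > 6) next
    for (a in max(0, C1 - R2):min(R1, C1)) {
      tab <- matrix(c(a, R1 - a, C1 - a, R2 - C1 + a), 2, byrow = TRUE)
      expect_equal(contingency_test(tab, policy = "exact")$p_value,
                   fisher_2x2_brute(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                   tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 400)
})

test_that("degenerate tables are reduced or refused", {
  tab <- rbind(c(3, 1), c(0, 0), c(2, 5))
  expect_message(ct <- contingency_test(tab), "all-zero row")
  expect_equal(ct$p_value, contingency_test(rbind(c(3, 1), c(2, 5)))$p_value)
  expect_error(suppressMessages(contingency_test(rbind(c(3, 0), c(2, 0)))),
               "degenerate")
  expect_error(contingency_test(rbind(c(1.5, 2), c(1, 1))), "integer")
  # policy auto: large balanced table -> Pearson chi-square
  big <- matrix(c(30, 20, 25, 35), 2)
  ct2 <- contingency_test(big)
  expect_equal(ct2$test, "pearson_chi2")
  expect_equal(ct2$statistic,
               unname(suppressWarnings(chisq.test(big, correct = FALSE))$statistic))
})

test_that("Kruskal-Wallis matches hand computation and handles degeneracy", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4)
  expect_equal(kw$H_uncorrected, 2.4)   # no ties, no correction
  expect_equal(kw$tie_correction, 1)
  expect_equal(unname(kw$mean_ranks), c(1.5, 3.5))
  # defined degenerate case: everything tied
  kw0 <- kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Kruskal-Wallis agrees with the stats oracle and grand-rank identity", {
  set.seed(17)
  for (rep in 1:20) {
    x <- sample(0:4, 60, TRUE)
    g <- sample(c("a", "b", "c"), 60, TRUE)
    kw <- kruskal_wallis(x, g)
    orc <- kruskal.test(x, factor(g))
    expect_equal(kw$H, unname(orc$statistic), tolerance = 1e-10)
    expect_equal(kw$p_value, orc$p.value, tolerance = 1e-10)
    # grand mean rank identity
    N <- length(x)
    expect_equal(sum(kw$n * kw$mean_ranks) / N, (N + 1) / 2, tolerance = 1e-9)
    # tie correction never shrinks H
    expect_gte(kw$H, kw$H_uncorrected - 1e-12)
  }
  # equality holds exactly when there are no ties
  set.seed(18)
  x <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  kw <- kruskal_wallis(x, g)
  expect_equal(kw$H, kw$H_uncorrected)
  expect_equal(kw$tie_correction, 1)
})

test_that("uncorrected H reconstructed from mean ranks is a lower bound", {
  # published spot row: Q1 mean ranks and group sizes
  H <- kw_from_mean_ranks(c(51.06, 56.44, 31.43, 37.08, 52.00, 40.00),
                          c(49, 9, 7, 13, 14, 3))
  expect_equal(round(H, 2), 6.56)
  expect_lte(H, 7.683)
  # all groups at the grand mean rank
  expect_equal(kw_from_mean_ranks(rep(5.5, 2), c(5, 5)), 0)
  # internal consistency on tie-free data
  set.seed(19)
  x <- rnorm(50)
  g <- sample(c("a", "b", "c"), 50, TRUE)
  kw <- kruskal_wallis(x, g)
  expect_equal(kw_from_mean_ranks(kw$mean_ranks, kw$n), kw$H, tolerance = 1e-9)
  # rounded/mislabelled printed values warn but still return
  expect_warning(kw_from_mean_ranks(c(10, 20), c(5, 5)), "inconsistent")
})

test_that("Dunn-Bonferroni post-hoc flags only the shifted group", {
  # two groups: the single pair keeps its raw p
  set.seed(23)
  x <- rnorm(30); g <- rep(c("a", "b"), 15)
  ph <- posthoc_pairwise(x, g)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$p_adj, ph$p_raw)
  # three groups, one strongly shifted
  x <- c(rnorm(30), rnorm(30), rnorm(30, mean = 2.5))
  g <- rep(c("a", "b", "c"), each = 30)
  ph <- posthoc_pairwise(x, g)
  expect_equal(nrow(ph), 3)
  sig <- ph$p_adj < 0.05
  expect_true(all(sig[ph$group1 == "c" | ph$group2 == "c"]))
  expect_false(any(sig[ph$group1 != "c" & ph$group2 != "c"]))
  # Bonferroni: adjusted = min(1, m * raw), monotone, never below raw
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p_raw))
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_true(all(ph$p_adj <= 1))
  o <- order(ph$p_raw)
  expect_true(all(diff(ph$p_adj[o]) >= -1e-12))
  # the Mann-Whitney alternative returns the same pair structure
  ph2 <- posthoc_pairwise(x, g, method = "mw_bonferroni")
  expect_equal(ph2[c("group1", "group2")], ph[c("group1", "group2")])
  expect_true(all(ph2$p_adj[ph2$group1 == "c" | ph2$group2 == "c"] < 0.05))
})

test_that("correlation screen matches hand values and the stats oracle", {
  x <- data.frame(a = c(0, 1, 2, 3))
  expect_equal(correlation_screen(x, data.frame(b = 2 * x$a + 3))$r[1, 1], 1)
  cs <- correlation_screen(x, data.frame(b = c(1, 0, 3, 2)))
  expect_equal(cs$r[1, 1], 0.6)
  set.seed(29)
  X <- data.frame(u = rnorm(40), v = rnorm(40))
  Y <- data.frame(w = rnorm(40))
  cs <- correlation_screen(X, Y)
  for (i in 1:2) {
    orc <- cor.test(X[[i]], Y$w)
    expect_equal(cs$r[i, 1], unname(orc$estimate), tolerance = 1e-12)
    expect_equal(cs$p[i, 1], orc$p.value, tolerance = 1e-10)
  }
})

test_that("correlation screen applies tier stars and strength bands", {
  set.seed(30)
  n <- 95
  g <- rnorm(n)
  X <- data.frame(s = g + 0.8 * rnorm(n))
  Y <- data.frame(strong = g + 0.45 * rnorm(n), none = rnorm(n),
                  flat = rep(1, n))
  cs <- correlation_screen(X, Y)
  expect_equal(cs$band[1, "strong"], "strong")
  expect_equal(cs$sig[1, "strong"], "***")   # p below both Bonferroni tiers
  expect_equal(cs$band[1, "flat"], "undefined")
  expect_true(is.na(cs$r[1, "flat"]))
  expect_equal(cs$sig[1, "none"], "")
})
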