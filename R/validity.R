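#' Contingency analysis of pattern by subtype
#'
#' Tests association in an r x c count table. Under the \code{"auto"}
#' policy the test follows the expected-frequency rule: the exact
#' Fisher-Freeman-Halton test when any expected cell count falls below 5
#' (Cochran's rule), the Pearson chi-square test otherwise. The exact p is
#' the probability-ordering two-sided definition (total probability of
#' tables with fixed margins no more probable than the observed one),
#' evaluated by the network enumeration algorithm; when enumeration exceeds
#' the workspace budget a seeded Monte-Carlo estimate over \code{B} sampled
#' tables is used instead.
#'
#' All-zero rows are dropped (with a message) before testing; an all-zero
#' column margin is an error.
#'
#' @param counts matrix of non-negative integer counts, at least 2 x 2.
#' @param policy \code{"auto"}, \code{"exact"}, or \code{"chisq"}.
#' @param B number of Monte-Carlo tables for the fallback.
#' @param workspace workspace for the exact network algorithm.
#' @return list of class \code{stpi_contingency}: \code{counts},
#'   \code{expected}, \code{test} (\code{"pearson_chi2"} or
#'   \code{"fisher_freeman_halton"}), \code{statistic} (chi-square, NA for
#'   the exact test), \code{df}, \code{p_value}, \code{monte_carlo} flag.
#' @export
contingency_test <- function(counts, policy = c("auto", "exact", "chisq"),
                             B = 1e6, workspace = 2e7) {
  policy <- match.arg(policy)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts))
    stop("counts must be non-negative integers")
  zr <- rowSums(counts) == 0
  if (any(zr)) {
    message("dropping ", sum(zr), " all-zero row(s)")
    counts <- counts[!zr, , drop = FALSE]
  }
  if (any(colSums(counts) == 0))
    stop("degenerate margins: all-zero column")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2 x 2 table after dropping empty rows")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  use_exact <- switch(policy, exact = TRUE, chisq = FALSE,
                      auto = any(expected < 5))
  mc <- FALSE
  if (use_exact) {
    ft <- tryCatch(
      stats::fisher.test(counts, workspace = workspace),
      error = function(e) {
        mc <<- TRUE
        stats::fisher.test(counts, simulate.p.value = TRUE, B = B)
      })
    res <- list(test = "fisher_freeman_halton", statistic = NA_real_,
                df = NA_integer_, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    res <- list(test = "pearson_chi2",
                statistic = unname(ct$statistic),
                df = unname(ct$parameter), p_value = ct$p.value)
  }
  structure(c(list(counts = counts, expected = expected), res,
              list(monte_carlo = mc)),
            class = "stpi_contingency")
}

#' @export
print.stpi_contingency <- function(x, ...) {
  cat("Contingency test (", x$test,
      if (x$monte_carlo) ", Monte-Carlo", "):\n", sep = "")
  if (!is.na(x$statistic))
    cat("  chi-square =", round(x$statistic, 3), "df =", x$df, "\n")
  cat("  p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}

# midranks, tie counts and the tie-correction divisor for a value vector
rank_info <- function(values) {
  r <- rank(values)
  t <- table(values)
  N <- length(values)
  list(ranks = r,
       tie_term = sum(t^3 - t),
       correction = 1 - sum(t^3 - t) / (N^3 - N))
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Tie-corrected Kruskal-Wallis H with mid-ranks,
#' \deqn{H = \frac{12/(N(N+1)) \sum_i n_i (\bar R_i - (N+1)/2)^2}
#'   {1 - \sum_t (t^3 - t)/(N^3 - N)},}
#' compared to a chi-square distribution on g-1 degrees of freedom. With
#' ordinal 0--4 responses ties are the norm, so the correction matters: the
#' corrected H is never smaller than the uncorrected one. A fully tied
#' sample is the defined degenerate case H = 0, p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length (at least 2 non-empty groups).
#' @return list of class \code{stpi_kw}: \code{n} (per-group sizes),
#'   \code{mean_ranks}, \code{H} (tie-corrected), \code{H_uncorrected},
#'   \code{df}, \code{p_value}, \code{tie_correction}.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (anyNA(values) || anyNA(groups)) stop("missing values not supported")
  ri <- rank_info(values)
  N <- length(values)
  n <- tabulate(groups)
  names(n) <- levels(groups)
  mr <- tapply(ri$ranks, groups, mean)
  mr <- stats::setNames(as.numeric(mr), names(mr))
  H0 <- 12 / (N * (N + 1)) * sum(n * (mr - (N + 1) / 2)^2)
  if (ri$correction <= 0) {        # every observation identical
    H <- 0; p <- 1
  } else {
    H <- H0 / ri$correction
    p <- stats::pchisq(H, nlevels(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(n = n, mean_ranks = mr, H = H, H_uncorrected = H0,
                 df = nlevels(groups) - 1L, p_value = p,
                 tie_correction = ri$correction),
            class = "stpi_kw")
}

#' @export
print.stpi_kw <- function(x, ...) {
  cat("Kruskal-Wallis: H =", round(x$H, 3), "df =", x$df,
      "p =", format.pval(x$p_value, digits = 3), "\n")
  cat("  mean ranks:\n"); print(round(x$mean_ranks, 2))
  invisible(x)
}

#' Uncorrected H from published mean ranks
#'
#' Reconstructs the uncorrected Kruskal-Wallis statistic
#' \eqn{12/(N(N+1)) \sum n_i (\bar R_i - (N+1)/2)^2} from per-group mean
#' ranks and sizes, as printed in a results table. Because the printed
#' chi-square is tie-corrected, the reconstruction is a lower bound on it —
#' a consistency check available even when the raw data are not. A rank sum
#' inconsistent with N(N+1)/2 beyond \code{tol} (printed values are
#' rounded) raises a warning, not an error.
#'
#' @param mean_ranks numeric vector of per-group mean ranks.
#' @param n integer vector of group sizes, same length.
#' @param tol tolerance on the total rank-sum identity.
#' @return scalar uncorrected H.
#' @export
kw_from_mean_ranks <- function(mean_ranks, n, tol = 0.01) {
  stopifnot(length(mean_ranks) == length(n), all(n >= 1))
  N <- sum(n)
  if (abs(sum(n * mean_ranks) - N * (N + 1) / 2) > tol * N * (N + 1) / 2)
    warning("rank sums inconsistent with N(N+1)/2 beyond tolerance ",
            "(printed mean ranks may be rounded or mislabelled)")
  12 / (N * (N + 1)) * sum(n * (mean_ranks - (N + 1) / 2)^2)
}

#' Post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Dunn's rank-based z test on mean-rank differences with tie-corrected
#' variance (default), or pairwise Mann-Whitney tests, with Bonferroni
#' adjustment over all g(g-1)/2 pairs: adjusted p = min(1, m * raw p).
#' Significance tiers are flagged at 0.05 / 0.01 / 0.001.
#'
#' @inheritParams kruskal_wallis
#' @param method \code{"dunn_bonferroni"} or \code{"mw_bonferroni"}.
#' @return data.frame with columns \code{group1}, \code{group2}, \code{z}
#'   (NA for Mann-Whitney), \code{p_raw}, \code{p_adj}, \code{sig}
#'   (\code{""}, \code{"*"}, \code{"**"}, \code{"***"}).
#' @export
posthoc_pairwise <- function(values, groups,
                             method = c("dunn_bonferroni", "mw_bonferroni")) {
  method <- match.arg(method)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  N <- length(values)
  if (method == "dunn_bonferroni") {
    ri <- rank_info(values)
    mr <- tapply(ri$ranks, groups, mean)
    n <- tabulate(groups); names(n) <- lev
    v0 <- N * (N + 1) / 12 - ri$tie_term / (12 * (N - 1))
    z <- apply(pairs, 2L, function(pr) {
      (mr[pr[1]] - mr[pr[2]]) / sqrt(v0 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    })
    p_raw <- 2 * stats::pnorm(-abs(z))
  } else {
    z <- rep(NA_real_, ncol(pairs))
    p_raw <- apply(pairs, 2L, function(pr) {
      suppressWarnings(stats::wilcox.test(
        values[groups == pr[1]], values[groups == pr[2]],
        exact = FALSE, correct = TRUE)$p.value)
    })
  }
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  sig <- cut(p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
             labels = c("***", "**", "*", ""))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             z = unname(z), p_raw = unname(p_raw), p_adj = unname(p_adj),
             sig = as.character(sig), stringsAsFactors = FALSE)
}

#' Pearson correlation screen with Bonferroni tiers
#'
#' Correlates every column of \code{x_table} (e.g. pattern scores) with
#' every column of \code{y_table} (e.g. companion scale scores): Pearson r,
#' two-sided p from the t distribution, significance stars at the
#' configured Bonferroni thresholds, and descriptive strength bands on |r|
#' (0.4--0.6 moderate, 0.6--0.8 strong). Zero-variance columns yield
#' undefined (NA) cells rather than an error.
#'
#' @param x_table,y_table data.frames or matrices with equal row counts
#'   (same respondents), at least 3 rows.
#' @param alpha_tiers decreasing numeric vector of p thresholds; the i-th
#'   threshold met earns i+1 stars (defaults follow a Bonferroni family:
#'   0.05/40 and 0.05/400).
#' @return list of class \code{stpi_correlation}: matrices \code{r} and
#'   \code{p} (x columns in rows), character matrices \code{sig} and
#'   \code{band}, and \code{alpha_tiers}.
#' @export
correlation_screen <- function(x_table, y_table,
                               alpha_tiers = c(0.00125, 0.000125)) {
  X <- as.matrix(x_table); Y <- as.matrix(y_table)
  if (nrow(X) != nrow(Y)) stop("x_table and y_table must have equal row counts")
  n <- nrow(X)
  if (n < 3L) stop("correlation screen needs at least 3 respondents")
  stopifnot(all(diff(alpha_tiers) < 0))
  r <- matrix(NA_real_, ncol(X), ncol(Y),
              dimnames = list(colnames(X), colnames(Y)))
  p <- r
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Y))) {
    if (stats::var(X[, i]) == 0 || stats::var(Y[, j]) == 0) next
    rij <- stats::cor(X[, i], Y[, j])
    r[i, j] <- rij
    p[i, j] <- if (abs(rij) >= 1) 0 else
      2 * stats::pt(-abs(rij * sqrt((n - 2) / (1 - rij^2))), n - 2)
  }
  stars <- function(pv) {
    if (is.na(pv)) return("NA")
    k <- sum(pv < alpha_tiers)
    if (k == 0L) "" else strrep("*", k + 1L)
  }
  band <- function(rv) {
    if (is.na(rv)) return("undefined")
    a <- abs(rv)
    if (a < 0.4) "weak" else if (a < 0.6) "moderate"
    else if (a < 0.8) "strong" else "very strong"
  }
  structure(list(r = r, p = p,
                 sig = apply(p, c(1, 2), stars),
                 band = apply(r, c(1, 2), band),
                 alpha_tiers = alpha_tiers, n = n),
            class = "stpi_correlation")
}

#' @export
print.stpi_correlation <- function(x, ...) {
  cat("Pearson correlation screen (n = ", x$n, "), stars at p < ",
      paste(signif(x$alpha_tiers, 3), collapse = " / "), "\n", sep = "")
  disp <- matrix(paste0(formatC(x$r, digits = 3, format = "f"), x$sig),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}
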