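# Small instruments and cohorts built in code for the unit tests.

# two patterns, five patient items (I3 shared with different ratings)
toy_instrument <- function() {
  new_instrument(
    "toy", "custom",
    patterns = data.frame(pattern_id = c("A", "B"), label = c("a", "b")),
    items = data.frame(item_id = paste0("I", 1:5),
                       text = paste("item", 1:5),
                       rater = "patient", scale_max = 4L),
    memberships = data.frame(
      item_id = c("I1", "I2", "I3", "I3", "I4", "I5"),
      pattern_id = c("A", "A", "A", "B", "B", "B"),
      importance_mean = c(4.0, 3.5, 3.0, 4.5, 3.8, 3.2),
      importance_sd = c(0.8, 0.6, 1.0, 0.5, 0.9, 0.7)))
}

# valid random responses for an instrument's items
toy_cohort <- function(instr, n = 10, seed = 1) {
  set.seed(seed)
  ids <- instr$items$item_id
  df <- as.data.frame(matrix(sample(0:4, n * length(ids), replace = TRUE),
                             n, length(ids)))
  names(df) <- ids
  cbind(data.frame(respondent_id = sprintf("S%02d", seq_len(n))), df)
}

# response vector: 'value' on the given items, 'fill' elsewhere
response_vec <- function(instr, ids, value = 4, fill = 0) {
  x <- stats::setNames(rep(fill, nrow(instr$items)), instr$items$item_id)
  x[ids] <- value
  x
}

# brute-force two-sided Fisher p for a 2x2 table (probability ordering),
# by direct hypergeometric enumeration -- independent of fisher.test
fisher_2x2_brute <- function(a, b, c, d) {
  R1 <- a + b; R2 <- c + d; C1 <- a + c
  ks <- max(0, C1 - R2):min(R1, C1)
  pr <- stats::dhyper(ks, R1, R2, C1)
  p_obs <- stats::dhyper(a, R1, R2, C1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
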