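#' Cronbach's alpha
#'
#' Internal-consistency reliability of a respondent-by-item score matrix,
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i \sigma^2_i}
#'   {\sigma^2_{total}}\right)}
#' with sample variances (n-1 denominator, the SPSS convention).
#'
#' @param M numeric matrix or data.frame, respondents in rows, items in
#'   columns; at least 2 items and 3 respondents, no missing entries.
#' @return scalar alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(M) {
  M <- as.matrix(M)
  if (anyNA(M)) stop("item matrix contains missing entries")
  k <- ncol(M)
  if (k < 2L) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(M) < 3L) stop("Cronbach's alpha needs at least 3 respondents")
  vt <- stats::var(rowSums(M))
  if (vt <= .Machine$double.eps * max(1, mean(abs(M)))^2)
    stop("degenerate matrix: total-score variance is zero")
  k / (k - 1) * (1 - sum(apply(M, 2L, stats::var)) / vt)
}

#' Item-total correlation
#'
#' Pearson correlation between one item and the total score. The corrected
#' form (default, as reported by SPSS) excludes the item itself from the
#' total, so an item is not correlated with its own contribution.
#'
#' @param M respondent-by-item matrix or data.frame with column names.
#' @param item_id column name (or index) of the item.
#' @param corrected exclude the item from the total (default TRUE).
#' @return scalar Pearson correlation in [-1, 1].
#' @export
item_total_correlation <- function(M, item_id, corrected = TRUE) {
  M <- as.matrix(M)
  if (anyNA(M)) stop("item matrix contains missing entries")
  if (nrow(M) < 3L) stop("item-total correlation needs at least 3 respondents")
  j <- if (is.character(item_id)) match(item_id, colnames(M)) else item_id
  if (is.na(j) || j < 1L || j > ncol(M)) stop("unknown item: ", item_id)
  x <- M[, j]
  tot <- if (corrected) rowSums(M[, -j, drop = FALSE]) else rowSums(M)
  if (stats::var(x) == 0 || stats::var(tot) == 0)
    stop("zero variance: item-total correlation undefined for item ",
         if (is.character(item_id)) item_id else colnames(M)[j] %||% j)
  stats::cor(x, tot)
}

#' Alpha if item deleted
#'
#' For each item, Cronbach's alpha of the matrix with that column removed —
#' the standard column of a reliability table. Each value is a full
#' recomputation, not an incremental update.
#'
#' @param M respondent-by-item matrix or data.frame (at least 3 items).
#' @return named numeric vector, one alpha per deleted item.
#' @export
alpha_if_deleted <- function(M) {
  M <- as.matrix(M)
  if (ncol(M) < 3L) stop("alpha-if-deleted needs at least 3 items")
  out <- vapply(seq_len(ncol(M)),
                function(j) cronbach_alpha(M[, -j, drop = FALSE]), numeric(1))
  names(out) <- colnames(M)
  out
}

#' Extract a respondent-by-item matrix from a cohort
#'
#' Pulls the patient-rated item columns of an instrument out of a cohort
#' table, either all of them (\code{scope = "overall"}, the scoping used
#' for the overall reliability table, which excludes evaluator items) or
#' the items of one pattern.
#'
#' @param instr an \code{stpi_instrument}.
#' @param cohort data.frame with one column per item.
#' @param scope \code{"overall"} or a pattern id.
#' @return integer matrix with item ids as column names.
#' @export
item_matrix <- function(instr, cohort, scope = "overall") {
  ids <- if (identical(scope, "overall")) patient_items(instr)
  else {
    if (!scope %in% instr$patterns$pattern_id) stop("unknown scope: ", scope)
    ms <- instr$memberships
    intersect(patient_items(instr), ms$item_id[ms$pattern_id == scope])
  }
  absent <- setdiff(ids, names(cohort))
  if (length(absent))
    stop("cohort lacks item column(s): ", paste(absent, collapse = ", "))
  M <- as.matrix(cohort[ids])
  rownames(M) <- cohort$respondent_id
  M
}

#' Reliability report for an instrument on a cohort
#'
#' Computes the full internal-consistency battery over the patient items:
#' overall alpha, per-pattern alphas, and per item the mean, SD,
#' symptomatic count (respondents answering at least 1), corrected
#' item-total correlation against the overall total, and overall
#' alpha-if-deleted.
#'
#' @param instr an \code{stpi_instrument}.
#' @param cohort data.frame with one column per patient item.
#' @return list of class \code{stpi_reliability}: \code{alpha_overall},
#'   \code{alpha_pattern} (named vector), \code{items} (data.frame with
#'   columns \code{item_id}, \code{mean}, \code{sd}, \code{symptomatic},
#'   \code{asymptomatic}, \code{item_total_correlation},
#'   \code{alpha_if_deleted}), \code{n}.
#' @export
reliability_report <- function(instr, cohort) {
  M <- item_matrix(instr, cohort, "overall")
  aid <- alpha_if_deleted(M)
  items <- data.frame(
    item_id = colnames(M),
    mean = colMeans(M),
    sd = apply(M, 2L, stats::sd),
    symptomatic = colSums(M >= 1),
    asymptomatic = colSums(M < 1),
    item_total_correlation = vapply(colnames(M), function(id)
      item_total_correlation(M, id, corrected = TRUE), numeric(1)),
    alpha_if_deleted = aid,
    row.names = NULL, stringsAsFactors = FALSE)
  ap <- vapply(instr$patterns$pattern_id, function(p)
    cronbach_alpha(item_matrix(instr, cohort, p)), numeric(1))
  structure(list(alpha_overall = cronbach_alpha(M), alpha_pattern = ap,
                 items = items, n = nrow(M)),
            class = "stpi_reliability")
}

#' @export
print.stpi_reliability <- function(x, digits = 3, ...) {
  cat("Reliability report (n = ", x$n, ")\n", sep = "")
  cat("  overall alpha:", round(x$alpha_overall, digits), "\n")
  cat("  per-pattern alpha:\n")
  print(round(x$alpha_pattern, digits))
  it <- x$items
  it$mean <- round(it$mean, 2); it$sd <- round(it$sd, 2)
  it$item_total_correlation <- round(it$item_total_correlation, digits)
  it$alpha_if_deleted <- round(it$alpha_if_deleted, digits)
  print(utils::head(it, 10), row.names = FALSE)
  if (nrow(it) > 10) cat("  ... (", nrow(it) - 10, " more items)\n", sep = "")
  invisible(x)
}

#' Reliability-driven item pruning
#'
#' Flags removal candidates by the published rule — corrected item-total
#' correlation at or below the cutoff, or any increase of Cronbach's alpha
#' on deletion, screened both overall and within each pattern — then
#' removes the confirmed items via \code{\link{remove_items_and_reweight}}
#' and recomputes the report on the revised instrument. Item pruning on a
#' draft instrument is expert-in-the-loop: the statistics nominate
#' candidates, the panel confirms. \code{confirm} carries that decision; by
#' default all candidates are accepted. A single pass is performed
#' (matching the published procedure); set \code{iterative = TRUE} to
#' repeat until no candidate remains.
#'
#' @param instr an \code{stpi_instrument} (evaluator items are ignored by
#'   the statistics; only patient items are ever flagged).
#' @param cohort data.frame with one column per patient item.
#' @param r_it_cutoff item-total correlation cutoff (default 0.3).
#' @param confirm character vector of item ids to actually remove. Default
#'   \code{NULL} removes every candidate. May include expert-chosen items
#'   that were not statistical candidates; the log records the distinction.
#' @param iterative repeat flag-and-remove passes until stable.
#' @return list of class \code{stpi_pruning}: \code{candidates} (data.frame
#'   \code{item_id}, \code{scope}, \code{reason}, \code{statistic}),
#'   \code{log} (candidates plus \code{action}), \code{instrument} (the
#'   revised instrument), \code{report_before}, \code{report_after}.
#' @export
prune_items <- function(instr, cohort, r_it_cutoff = 0.3, confirm = NULL,
                        iterative = FALSE) {
  stopifnot(r_it_cutoff >= -1, r_it_cutoff <= 1)
  flag_pass <- function(ins) {
    rep <- reliability_report(ins, cohort)
    low <- rep$items[rep$items$item_total_correlation <= r_it_cutoff,
                     c("item_id", "item_total_correlation")]
    cand <- data.frame(item_id = low$item_id,
                       scope = rep("overall", nrow(low)),
                       reason = rep("low_item_total_correlation", nrow(low)),
                       statistic = low$item_total_correlation,
                       stringsAsFactors = FALSE)
    gain <- rep$items[rep$items$alpha_if_deleted > rep$alpha_overall,
                      c("item_id", "alpha_if_deleted")]
    cand <- rbind(cand, data.frame(item_id = gain$item_id,
                                   scope = rep("overall", nrow(gain)),
                                   reason = rep("alpha_gain", nrow(gain)),
                                   statistic = gain$alpha_if_deleted,
                                   stringsAsFactors = FALSE))
    for (p in ins$patterns$pattern_id) {
      Mp <- item_matrix(ins, cohort, p)
      if (ncol(Mp) < 3L) next
      ap <- cronbach_alpha(Mp)
      aidp <- alpha_if_deleted(Mp)
      up <- names(aidp)[aidp > ap]
      if (length(up))
        cand <- rbind(cand, data.frame(item_id = up, scope = p,
                                       reason = "alpha_gain",
                                       statistic = aidp[up],
                                       stringsAsFactors = FALSE))
    }
    rownames(cand) <- NULL
    list(report = rep, candidates = cand)
  }

  first <- flag_pass(instr)
  candidates <- first$candidates
  report_before <- first$report
  logs <- list()
  revised <- instr
  pass_cand <- candidates
  repeat {
    chosen <- if (is.null(confirm)) unique(pass_cand$item_id)
              else intersect(as.character(confirm), revised$items$item_id)
    log <- pass_cand
    log$action <- ifelse(log$item_id %in% chosen, "removed", "kept")
    extra <- setdiff(chosen, pass_cand$item_id)
    if (length(extra))
      log <- rbind(log, data.frame(item_id = extra, scope = "expert",
                                   reason = "expert_decision",
                                   statistic = NA_real_, action = "removed",
                                   stringsAsFactors = FALSE))
    logs[[length(logs) + 1L]] <- log
    if (length(chosen) == 0L) break
    revised <- remove_items_and_reweight(revised, chosen)
    if (!iterative || !is.null(confirm)) break
    pass_cand <- flag_pass(revised)$candidates
    if (nrow(pass_cand) == 0L) break
  }
  structure(list(candidates = candidates, log = do.call(rbind, logs),
                 instrument = revised, report_before = report_before,
                 report_after = reliability_report(revised, cohort)),
            class = "stpi_pruning")
}

#' @export
print.stpi_pruning <- function(x, ...) {
  removed <- unique(x$log$item_id[x$log$action == "removed"])
  cat("Pruning: ", nrow(x$candidates), " candidate flag(s), removed ",
      length(removed), " item(s)",
      if (length(removed)) paste0(" (", paste(removed, collapse = ", "), ")"),
      "\n", sep = "")
  cat("  overall alpha: ", round(x$report_before$alpha_overall, 3), " -> ",
      round(x$report_after$alpha_overall, 3), "\n", sep = "")
  invisible(x)
}
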