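#' Score one respondent on a weighted instrument
#'
#' The score of pattern p is the weighted sum of the respondent's item
#' responses over the items belonging to p,
#' \eqn{S_p = \sum_{i \in p} x_i w_{i,p}}, and the diagnosed pattern is the
#' one attaining the maximum score. Because every pattern's weights sum to
#' 100 and responses run 0--\code{scale_max}, scores are directly comparable
#' across patterns and bounded by \code{100 * scale_max} (400 on the 0--4
#' scale).
#'
#' @param instr an \code{stpi_instrument}.
#' @param responses named numeric vector (or one-row data.frame) of integer
#'   responses, names being item ids. All instrument items must be present
#'   unless imputation was applied upstream.
#' @param tie how to resolve several patterns sharing the maximum:
#'   \code{"report"} (default) assigns the label \code{"tie"} and lists the
#'   tied patterns; \code{"order"} deterministically picks the first tied
#'   pattern in the instrument's canonical pattern order.
#' @return list of class \code{stpi_score}: \code{scores} (named numeric per
#'   pattern), \code{assigned_pattern}, \code{tied_patterns}.
#' @export
score_respondent <- function(instr, responses, tie = c("report", "order")) {
  tie <- match.arg(tie)
  if (is.data.frame(responses)) {
    stopifnot(nrow(responses) == 1L)
    responses <- unlist(responses)
  }
  ids <- instr$items$item_id
  missing_ids <- setdiff(ids, names(responses))
  if (length(missing_ids))
    stop("missing response for item(s): ", paste(missing_ids, collapse = ", "))
  x <- as.numeric(responses[ids])
  if (anyNA(x))
    stop("missing (NA) response for item(s): ",
         paste(ids[is.na(x)], collapse = ", "))
  smax <- instr$items$scale_max
  bad <- x < 0 | x > smax | x != round(x)
  if (any(bad))
    stop("response out of range 0..scale_max for item(s): ",
         paste(ids[bad], collapse = ", "))
  s <- drop(x %*% weight_matrix(instr))
  top <- names(s)[abs(s - max(s)) < 1e-9]
  assigned <- if (length(top) == 1L) top
              else if (tie == "order") top[1L] else "tie"
  structure(list(scores = s, assigned_pattern = assigned,
                 tied_patterns = if (length(top) > 1L) top else character()),
            class = "stpi_score")
}

#' @export
print.stpi_score <- function(x, ...) {
  cat("Pattern scores:\n")
  print(round(x$scores, 2))
  cat("assigned:", x$assigned_pattern,
      if (length(x$tied_patterns))
        paste0("(tied: ", paste(x$tied_patterns, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Score a cohort of respondents
#'
#' Vectorized weighted scoring over a respondent-by-item table. Missing
#' cells can optionally be filled with the cohort item mean (rounded to the
#' nearest integer response); imputed cells are flagged in the result.
#'
#' @param instr an \code{stpi_instrument}.
#' @param cohort data.frame with a \code{respondent_id} column and one
#'   column per instrument item (extra columns are ignored).
#' @param tie tie policy, see \code{\link{score_respondent}}.
#' @param impute if \code{TRUE}, NA cells are replaced by the rounded
#'   cohort mean of the item before scoring; default is strict (error).
#' @return data.frame with \code{respondent_id}, one \code{score_<pattern>}
#'   column per pattern, \code{assigned_pattern}, \code{tied}
#'   (semicolon-separated tied patterns, empty if none), and \code{imputed}
#'   (semicolon-separated item ids whose response was imputed).
#' @export
score_cohort <- function(instr, cohort, tie = c("report", "order"),
                         impute = FALSE) {
  tie <- match.arg(tie)
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L)
  if (is.null(cohort$respondent_id))
    stop("cohort must carry a 'respondent_id' column")
  ids <- instr$items$item_id
  absent <- setdiff(ids, names(cohort))
  if (length(absent))
    stop("cohort lacks item column(s): ", paste(absent, collapse = ", "))
  X <- as.matrix(cohort[ids])
  storage.mode(X) <- "double"
  imputed <- rep("", nrow(X))
  if (anyNA(X)) {
    if (!impute) {
      r <- which(rowSums(is.na(X)) > 0)[1L]
      stop("respondent ", cohort$respondent_id[r],
           ": missing response for item(s): ",
           paste(ids[is.na(X[r, ])], collapse = ", "),
           " (set impute = TRUE for cohort-mean imputation)")
    }
    fill <- round(colMeans(X, na.rm = TRUE))
    if (anyNA(fill))
      stop("cannot impute item(s) with no observed responses: ",
           paste(ids[is.na(fill)], collapse = ", "))
    for (j in which(colSums(is.na(X)) > 0)) {
      rows <- is.na(X[, j])
      X[rows, j] <- fill[j]
      imputed[rows] <- sub("^;", "", paste(imputed[rows], ids[j], sep = ";"))
    }
  }
  smax <- rep(instr$items$scale_max, each = nrow(X))
  if (any(X < 0 | X > smax | X != round(X))) {
    bad <- which(X < 0 | X > smax | X != round(X), arr.ind = TRUE)[1L, ]
    stop("respondent ", cohort$respondent_id[bad[1L]],
         ": response out of range for item ", ids[bad[2L]])
  }
  S <- X %*% weight_matrix(instr)
  mx <- apply(S, 1L, max)
  is_top <- abs(S - mx) < 1e-9
  ntop <- rowSums(is_top)
  pats <- colnames(S)
  first_top <- pats[apply(is_top, 1L, which.max)]
  assigned <- ifelse(ntop == 1L, first_top,
                     if (tie == "order") first_top else "tie")
  tied <- vapply(seq_len(nrow(S)), function(r)
    if (ntop[r] > 1L) paste(pats[is_top[r, ]], collapse = ";") else "",
    character(1))
  out <- data.frame(respondent_id = cohort$respondent_id, S,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1L] <- paste0("score_", pats)
  out$assigned_pattern <- assigned
  out$tied <- tied
  out$imputed <- imputed
  out
}

#' Classify a cohort and tabulate pattern frequencies
#'
#' Convenience wrapper around \code{\link{score_cohort}} that adds the
#' frequency distribution of assigned patterns (counts and percentages to
#' one decimal), in the instrument's canonical pattern order with a
#' trailing \code{"tie"} row when ties were reported.
#'
#' @inheritParams score_cohort
#' @return list of class \code{stpi_classification}: \code{results} (the
#'   per-respondent score table) and \code{frequencies} (data.frame
#'   \code{pattern}, \code{n}, \code{pct}).
#' @export
classify_cohort <- function(instr, cohort, tie = c("report", "order"),
                            impute = FALSE) {
  res <- score_cohort(instr, cohort, tie = tie, impute = impute)
  lev <- instr$patterns$pattern_id
  if (any(res$assigned_pattern == "tie")) lev <- c(lev, "tie")
  cnt <- table(factor(res$assigned_pattern, levels = lev))
  freq <- data.frame(pattern = names(cnt), n = as.integer(cnt),
                     pct = round(100 * as.integer(cnt) / nrow(res), 1),
                     stringsAsFactors = FALSE)
  structure(list(results = res, frequencies = freq),
            class = "stpi_classification")
}

#' @export
print.stpi_classification <- function(x, ...) {
  cat("Cohort classification (n = ", nrow(x$results), ")\n", sep = "")
  print(x$frequencies, row.names = FALSE)
  invisible(x)
}
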