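#' Derive item weights from Delphi importance ratings
#'
#' Converts expert importance ratings (mean and standard deviation on the
#' 1--5 Delphi scale) for the items of one pattern into weights that sum to
#' 100. Each item's weight is proportional to its mean-over-SD ratio, so an
#' item the panel rated both important (high mean) and consensually (low SD)
#' receives a large share of the pattern's scoring budget:
#' \deqn{w_i = 100 \cdot \frac{m_i / s_i}{\sum_j m_j / s_j}}
#'
#' @param mean numeric vector of importance means (1--5).
#' @param sd numeric vector of importance standard deviations, same length.
#' @param sd_floor optional positive scalar. By default an SD of zero (all
#'   experts gave the identical rating) is an error because the ratio
#'   degenerates; supplying a floor substitutes \code{max(sd, sd_floor)}
#'   instead. No published rating table needs this, hence the opt-in.
#' @return numeric vector of weights, positive, summing to 100.
#' @examples
#' derive_weights(c(4.09, 4.45), c(0.70, 0.69))
#' @export
derive_weights <- function(mean, sd, sd_floor = NULL) {
  if (length(mean) == 0L) stop("cannot derive weights from an empty rating list")
  if (length(mean) != length(sd)) stop("'mean' and 'sd' must have equal length")
  if (any(!is.finite(mean)) || any(!is.finite(sd)))
    stop("importance ratings must be finite")
  if (any(mean <= 0)) stop("importance means must be positive")
  if (any(sd < 0)) stop("importance standard deviations must be non-negative")
  if (any(sd == 0)) {
    if (is.null(sd_floor))
      stop("degenerate rating: sd = 0 at position ",
           paste(which(sd == 0), collapse = ", "),
           " (set 'sd_floor' to enable the floor fallback)")
    stopifnot(is.numeric(sd_floor), length(sd_floor) == 1L, sd_floor > 0)
    sd <- pmax(sd, sd_floor)
  }
  ratio <- mean / sd
  100 * ratio / sum(ratio)
}

#' Select candidates by importance threshold
#'
#' Applies the Delphi retention rule: a candidate survives when its mean
#' importance reaches the threshold (3.00 in the published procedure, the
#' midpoint of the 1--5 scale), or when the expert panel explicitly
#' overrides the rule for it. Input order is preserved.
#'
#' @param ids character vector of candidate identifiers.
#' @param mean numeric vector of importance means, parallel to \code{ids}.
#' @param threshold retention cutoff on the importance scale, in [1, 5].
#' @param overrides character vector of ids retained regardless of mean.
#' @return character vector of retained ids, in input order.
#' @export
select_by_importance <- function(ids, mean, threshold = 3, overrides = character()) {
  stopifnot(length(ids) == length(mean))
  if (length(ids) == 0L) return(character())
  if (threshold < 1 || threshold > 5) stop("'threshold' must lie in [1, 5]")
  keep <- mean >= threshold | ids %in% overrides
  as.character(ids[keep])
}

#' Construct a pattern-identification instrument
#'
#' An instrument bundles the patterns, items, and pattern memberships of a
#' weighted diagnostic questionnaire. An item may belong to several patterns
#' with a different importance rating (and hence weight) per membership.
#'
#' @param instrument_id short identifier string.
#' @param version version tag, e.g. \code{"draft38"}, \code{"final36"},
#'   or \code{"custom"}.
#' @param patterns data.frame with columns \code{pattern_id}, \code{label};
#'   row order fixes the canonical pattern order (used for deterministic
#'   tie-breaking downstream).
#' @param items data.frame with columns \code{item_id}, \code{text},
#'   \code{rater} (one of \code{"patient"}, \code{"evaluator_tongue"},
#'   \code{"evaluator_pulse"}), \code{scale_max}.
#' @param memberships data.frame with columns \code{item_id},
#'   \code{pattern_id}, \code{importance_mean}, \code{importance_sd}, and
#'   optionally \code{weight}. When \code{weight} is absent it is derived
#'   with \code{\link{derive_weights}} per pattern.
#' @param overrides character vector of item ids exempt from the
#'   importance-threshold exclusion.
#' @return object of class \code{stpi_instrument}.
#' @export
new_instrument <- function(instrument_id, version, patterns, items,
                           memberships, overrides = character()) {
  patterns <- as.data.frame(patterns, stringsAsFactors = FALSE)
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  memberships <- as.data.frame(memberships, stringsAsFactors = FALSE)
  if (is.null(memberships$weight)) memberships$weight <- NA_real_
  instr <- structure(
    list(instrument_id = as.character(instrument_id),
         version = as.character(version),
         patterns = patterns, items = items,
         memberships = memberships,
         overrides = as.character(overrides)),
    class = "stpi_instrument")
  if (anyNA(instr$memberships$weight)) instr <- reweight(instr)
  validate_instrument(instr)
  instr
}

#' Validate instrument invariants
#'
#' Checks identifier uniqueness, referential integrity of memberships,
#' rating ranges, and that the weights of every pattern sum to 100.
#'
#' @param instr an \code{stpi_instrument}.
#' @param tol tolerance on the per-pattern weight sum.
#' @return \code{instr}, invisibly; errors describe the offending record.
#' @export
validate_instrument <- function(instr, tol = 1e-6) {
  stopifnot(inherits(instr, "stpi_instrument"))
  it <- instr$items; ms <- instr$memberships; pt <- instr$patterns
  if (anyDuplicated(it$item_id))
    stop("duplicate item_id: ",
         paste(unique(it$item_id[duplicated(it$item_id)]), collapse = ", "))
  if (anyDuplicated(pt$pattern_id))
    stop("duplicate pattern_id: ",
         paste(unique(pt$pattern_id[duplicated(pt$pattern_id)]), collapse = ", "))
  bad <- setdiff(ms$item_id, it$item_id)
  if (length(bad))
    stop("membership references missing item: ", paste(bad, collapse = ", "))
  bad <- setdiff(ms$pattern_id, pt$pattern_id)
  if (length(bad))
    stop("membership references missing pattern: ", paste(bad, collapse = ", "))
  if (anyDuplicated(ms[c("item_id", "pattern_id")]))
    stop("duplicate membership (item, pattern) pair")
  if (any(it$scale_max < 1)) stop("scale_max must be >= 1")
  if (!all(it$rater %in% c("patient", "evaluator_tongue", "evaluator_pulse")))
    stop("unknown rater category")
  if (any(ms$importance_mean < 1 | ms$importance_mean > 5))
    stop("importance_mean outside [1, 5] for item ",
         paste(ms$item_id[ms$importance_mean < 1 | ms$importance_mean > 5],
               collapse = ", "))
  if (any(ms$importance_sd < 0)) stop("importance_sd must be non-negative")
  wsum <- tapply(ms$weight, ms$pattern_id, sum)
  off <- names(wsum)[abs(wsum - 100) > tol]
  if (length(off))
    stop("weights do not sum to 100 in pattern ", paste(off, collapse = ", "))
  invisible(instr)
}

#' Re-derive all membership weights from importance ratings
#'
#' @param instr an \code{stpi_instrument}.
#' @param sd_floor passed to \code{\link{derive_weights}}.
#' @return the instrument with the \code{weight} column recomputed.
#' @export
reweight <- function(instr, sd_floor = NULL) {
  ms <- instr$memberships
  for (p in unique(ms$pattern_id)) {
    idx <- ms$pattern_id == p
    ms$weight[idx] <- derive_weights(ms$importance_mean[idx],
                                     ms$importance_sd[idx], sd_floor)
  }
  instr$memberships <- ms
  instr
}

#' Remove items from an instrument and re-derive weights
#'
#' Drops the given items and all their pattern memberships, then re-applies
#' the weight derivation to the surviving memberships of every pattern, as
#' done when the reliability analysis prunes items from a draft tool.
#'
#' @param instr an \code{stpi_instrument}.
#' @param drop character vector of item ids to remove (may be empty).
#' @param version version tag for the revised instrument; defaults to
#'   \code{"custom"} when items were dropped, unchanged otherwise.
#' @return revised \code{stpi_instrument}.
#' @export
remove_items_and_reweight <- function(instr, drop, version = NULL) {
  stopifnot(inherits(instr, "stpi_instrument"))
  drop <- as.character(drop)
  unknown <- setdiff(drop, instr$items$item_id)
  if (length(unknown))
    stop("cannot drop unknown item: ", paste(unknown, collapse = ", "))
  if (length(drop) == 0L) return(instr)
  ms <- instr$memberships
  emptied <- setdiff(unique(ms$pattern_id),
                     unique(ms$pattern_id[!(ms$item_id %in% drop)]))
  if (length(emptied))
    stop("empty pattern: dropping these items would leave no membership in ",
         paste(emptied, collapse = ", "))
  instr$items <- instr$items[!(instr$items$item_id %in% drop), , drop = FALSE]
  instr$memberships <- ms[!(ms$item_id %in% drop), , drop = FALSE]
  rownames(instr$items) <- rownames(instr$memberships) <- NULL
  instr$overrides <- setdiff(instr$overrides, drop)
  instr$version <- if (is.null(version)) "custom" else version
  instr <- reweight(instr)
  validate_instrument(instr)
  instr
}

#' Write an instrument to its JSON interchange form
#'
#' Weights are serialized at full precision; a rounded \code{weight_2dp}
#' convenience field mirrors the two-decimal presentation used in print.
#'
#' @param instr an \code{stpi_instrument}.
#' @param path file path to write (UTF-8 JSON).
#' @return \code{path}, invisibly.
#' @export
write_instrument <- function(instr, path) {
  validate_instrument(instr)
  ms <- instr$memberships
  ms$weight_2dp <- round(ms$weight, 2)
  obj <- list(instrument_id = instr$instrument_id,
              version = instr$version,
              patterns = instr$patterns,
              items = instr$items,
              memberships = ms,
              overrides = instr$overrides)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an instrument from its JSON interchange form
#'
#' Invariant validation runs on load; a malformed file fails with an error
#' naming the offending record.
#'
#' @param path path to an instrument JSON file.
#' @return an \code{stpi_instrument}.
#' @export
read_instrument <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("instrument_id", "version", "patterns", "items", "memberships")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("instrument file lacks field(s): ", paste(miss, collapse = ", "))
  ms <- obj$memberships
  ms$weight_2dp <- NULL
  new_instrument(obj$instrument_id, obj$version, obj$patterns, obj$items,
                 ms, overrides = unlist(obj$overrides) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged draft instrument (38 patient + 11 evaluator items)
#'
#' The draft STPI-FD: six patterns (SSDC, SDQS, LSDH, TACH, DHSS, FRDO),
#' 38 patient-rated symptom items plus 6 tongue and 5 pulse evaluator items,
#' with the published Delphi importance ratings and derived weights.
#'
#' @return an \code{stpi_instrument}, version \code{"draft38"}.
#' @export
stpi_draft38 <- function() {
  read_instrument(system.file("extdata", "stpi_fd_draft38.json",
                              package = "stpifd", mustWork = TRUE))
}

#' Packaged final instrument (36 patient items)
#'
#' The revised STPI-FD after reliability-driven pruning: the tongue and
#' pulse evaluator items and two low-consistency symptom items (Q32, Q33)
#' are removed and weights re-derived from the surviving importance
#' ratings. Per-pattern item counts are 8/8/11/9/9/7.
#'
#' @return an \code{stpi_instrument}, version \code{"final36"}.
#' @export
stpi_final36 <- function() {
  read_instrument(system.file("extdata", "stpi_fd_final36.json",
                              package = "stpifd", mustWork = TRUE))
}

#' @export
print.stpi_instrument <- function(x, ...) {
  cat("Pattern-identification instrument <", x$instrument_id, "> version ",
      x$version, "\n", sep = "")
  n_by_rater <- table(x$items$rater)
  cat("  items: ", nrow(x$items), " (",
      paste(names(n_by_rater), n_by_rater, sep = ": ", collapse = ", "),
      ")\n", sep = "")
  cnt <- table(factor(x$memberships$pattern_id, levels = x$patterns$pattern_id))
  cat("  patterns:", paste(sprintf("%s[%d]", names(cnt), cnt), collapse = " "),
      "\n")
  if (length(x$overrides))
    cat("  overrides:", paste(x$overrides, collapse = ", "), "\n")
  invisible(x)
}

# items of an instrument restricted to patient (self-rated) items
patient_items <- function(instr) {
  instr$items$item_id[instr$items$rater == "patient"]
}

# item_id x pattern_id weight matrix (0 where no membership)
weight_matrix <- function(instr) {
  ids <- instr$items$item_id
  pats <- instr$patterns$pattern_id
  W <- matrix(0, nrow = length(ids), ncol = length(pats),
              dimnames = list(ids, pats))
  ms <- instr$memberships
  W[cbind(match(ms$item_id, ids), match(ms$pattern_id, pats))] <- ms$weight
  W
}
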