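#' Companion dyspepsia scale definitions
#'
#' Definitions of the four concurrent-validity anchor scales:
#' \describe{
#'   \item{VAS}{overall dyspeptic severity on a 0--100 continuous line.}
#'   \item{TDS}{total dyspepsia symptoms: eight symptoms on a 0--3 severity
#'     scale, total 0--24.}
#'   \item{SDS}{single dyspepsia symptoms: four cardinal symptoms
#'     (epigastric pain, epigastric burning, postprandial fullness, early
#'     satiety), each rated for frequency, intensity and discomfort on
#'     0--3; per-symptom and per-dimension subtotals plus a 0--36 grand
#'     total.}
#'   \item{FDQOL}{dyspepsia-related quality of life: 21 items on 0--4
#'     across four domains (eating 5, vitality 4, emotions 6, social 6),
#'     total 0--84.}
#' }
#'
#' @param scale_id one of \code{"VAS"}, \code{"TDS"}, \code{"SDS"},
#'   \code{"FDQOL"}.
#' @return list of class \code{stpi_scale_def}: \code{scale_id},
#'   \code{items} (character vector of expected response names),
#'   \code{item_min}, \code{item_max}, \code{domains} (named list of item
#'   name subsets; empty for VAS/TDS).
#' @export
scale_definition <- function(scale_id = c("VAS", "TDS", "SDS", "FDQOL")) {
  scale_id <- match.arg(scale_id)
  def <- switch(scale_id,
    VAS = list(items = "vas", item_min = 0, item_max = 100,
               domains = list()),
    TDS = list(items = paste0("tds_", 1:8), item_min = 0, item_max = 3,
               domains = list()),
    SDS = {
      sym <- c("pain", "burning", "fullness", "satiety")
      dim <- c("frequency", "intensity", "discomfort")
      items <- as.vector(t(outer(sym, dim, paste, sep = "_")))
      items <- paste0("sds_", items)
      doms <- c(
        stats::setNames(lapply(sym, function(s)
          paste0("sds_", s, "_", dim)), sym),
        stats::setNames(lapply(dim, function(d)
          paste0("sds_", sym, "_", d)), dim))
      list(items = items, item_min = 0, item_max = 3, domains = doms)
    },
    FDQOL = list(
      items = paste0("fdqol_", 1:21), item_min = 0, item_max = 4,
      domains = list(eating = paste0("fdqol_", 1:5),
                     vitality = paste0("fdqol_", 6:9),
                     emotions = paste0("fdqol_", 10:15),
                     social = paste0("fdqol_", 16:21))))
  structure(c(list(scale_id = scale_id), def), class = "stpi_scale_def")
}

#' Score a companion scale
#'
#' Sums the item responses of a companion scale and, where the scale has a
#' domain partition, its domain subtotals as well. Responses must be
#' complete and in range; VAS is continuous, the item scales are integer.
#'
#' @param def an \code{stpi_scale_def} from \code{\link{scale_definition}},
#'   or a scale id string.
#' @param responses named numeric vector or one-row data.frame holding at
#'   least the scale's items (extra names are ignored).
#' @return list: \code{scale_id}, \code{total}, \code{domains} (named
#'   numeric vector of subtotals; empty where the scale has no partition).
#' @export
score_scale <- function(def, responses) {
  if (is.character(def)) def <- scale_definition(def)
  stopifnot(inherits(def, "stpi_scale_def"))
  if (is.data.frame(responses)) {
    stopifnot(nrow(responses) == 1L)
    responses <- unlist(responses)
  }
  miss <- setdiff(def$items, names(responses))
  if (length(miss))
    stop(def$scale_id, ": missing response for ",
         paste(miss, collapse = ", "))
  x <- as.numeric(responses[def$items])
  bad <- is.na(x) | x < def$item_min | x > def$item_max
  if (def$scale_id != "VAS") bad <- bad | (x != round(x) & !is.na(x))
  if (any(bad))
    stop(def$scale_id, ": response out of range for ",
         paste(def$items[bad], collapse = ", "))
  names(x) <- def$items
  doms <- vapply(def$domains, function(ids) sum(x[ids]), numeric(1))
  list(scale_id = def$scale_id, total = sum(x), domains = doms)
}

#' Cohort-level scale totals
#'
#' Applies \code{\link{score_scale}} across a cohort table, returning the
#' totals (and domain subtotals) as columns.
#'
#' @param def scale definition or id.
#' @param cohort data.frame holding the scale's item columns.
#' @return data.frame with \code{total} and one column per domain subtotal.
#' @export
score_scale_cohort <- function(def, cohort) {
  if (is.character(def)) def <- scale_definition(def)
  res <- lapply(seq_len(nrow(cohort)), function(r)
    score_scale(def, cohort[r, , drop = FALSE]))
  out <- data.frame(total = vapply(res, `[[`, numeric(1), "total"))
  for (d in names(def$domains))
    out[[d]] <- vapply(res, function(z) z$domains[[d]], numeric(1))
  out
}

#' Inclusion check on the severity VAS
#'
#' The study entry criterion: overall dyspeptic symptom severity of at
#' least 40 on the 0--100 VAS.
#'
#' @param vas numeric vector of VAS values in [0, 100].
#' @return logical vector, \code{TRUE} where the criterion is met.
#' @export
validate_inclusion <- function(vas) {
  if (any(is.na(vas) | vas < 0 | vas > 100))
    stop("VAS values must lie in [0, 100]")
  vas >= 40
}
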