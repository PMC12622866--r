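# Recovery credit: the area under the (meta)population-size curve, an
# integrative measure of recovery over the study horizon.

#' Recovery credit of one abundance series
#'
#' Trapezoidal area under the curve of population size against time, in
#' abundance-days. The credit is linear in the series, so the metapopulation
#' credit (of the summed series) equals the sum of per-patch credits.
#'
#' @param values Non-negative abundances.
#' @param times Strictly increasing observation days, same length.
#' @return The trapezoidal area over `[times[1], times[length(times)]]`.
#' @examples
#' recovery_credit(rep(1, 27), 0:26)   # 26
#' recovery_credit(c(0, 10, 10), c(0, 13, 26))  # 195
#' @export
recovery_credit <- function(values, times) {
  if (length(values) != length(times))
    stop("values and times must have equal length")
  if (length(values) < 2)
    stop("need at least 2 points to integrate")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(values < 0))
    stop("values must be non-negative")
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Recovery credits of a simulation at the three spatial scales
#'
#' For the focal species, computes (a) the mean per-patch credit over
#' initially empty patches, (b) the mean over initially populated patches and
#' (c) the metapopulation credit (credit of the across-patch summed series).
#' Class means are taken on raw credits and the `ln(1+x)` transform applied
#' afterwards (`transform_first = FALSE`, the default) or the other way
#' around.
#'
#' @param sim A `metacommunity_sim`, or a day x patch abundance matrix with
#'   `placement` supplied.
#' @param placement Required when `sim` is a matrix.
#' @param focal Species id (default `"Bb"`, the focal aphid).
#' @param transform_first Apply `ln(1+x)` per patch before averaging.
#' @return Data frame with one row per available scale: `scale`, `credit`,
#'   `credit_ln1p`.
#' @export
summarise_credits <- function(sim, placement = NULL, focal = "Bb",
                              transform_first = FALSE) {
  if (inherits(sim, "metacommunity_sim")) {
    placement <- sim$placement
    Y <- sim$abundance[, , focal]
  } else {
    Y <- as.matrix(sim)
    if (is.null(placement)) stop("placement required for a plain matrix")
  }
  days <- 0:(nrow(Y) - 1)
  np <- ncol(Y)
  pop <- placement$populated + 1L
  emp <- setdiff(seq_len(np), pop)
  per_patch <- apply(Y, 2, recovery_credit, times = days)
  agg <- function(x) {
    if (transform_first) mean(log1p(x)) else mean(x)
  }
  rows <- list()
  if (length(emp)) {
    cr <- agg(per_patch[emp])
    rows$empty_patches <- cr
  } else {
    warning("placement covers all patches: no empty-patch scale")
  }
  if (length(pop)) {
    rows$populated_patches <- agg(per_patch[pop])
  } else {
    warning("placement populates no patch: no populated-patch scale")
  }
  rows$metapopulation <- {
    m <- recovery_credit(rowSums(Y), days)
    if (transform_first) log1p(m) else m
  }
  out <- data.frame(scale = names(rows), credit = unlist(rows),
                    stringsAsFactors = FALSE)
  out$credit_ln1p <- if (transform_first) out$credit else log1p(out$credit)
  if (transform_first) out$credit <- expm1(out$credit)
  rownames(out) <- NULL
  out
}
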