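# Parameterisation regressions: re-estimate model parameters from time
# series, exactly as the model is parameterised from single-patch growth
# experiments, attack-count assays and emigration counts.

#' Estimate intrinsic growth rate and intraspecific competition
#'
#' Regresses the per-capita growth rate, as log-transformed differences
#' normalised by the census interval, `y_t = (ln N_{t+1} - ln N_t) / dt`, on
#' population size `N_t`. Under the Ricker-type growth model the relationship
#' is exactly linear: the intercept estimates `r` and the negative slope
#' estimates `alpha`. Division by `dt` makes 3- and 4-day census gaps
#' comparable.
#'
#' @param days Observation days (increasing, need not be unit-spaced).
#' @param counts Population sizes (positive within the fitted window).
#' @return A `growth_fit`: list with `r`, `alpha`, 95% CIs `ci_r`, `ci_alpha`,
#'   and the underlying `lm` fit.
#' @export
fit_growth <- function(days, counts) {
  if (length(days) != length(counts)) stop("days and counts must align")
  if (length(counts) < 3) stop("need at least 3 points")
  if (any(counts <= 0))
    stop("zero or negative count inside the fitted window; trim the series")
  dt <- diff(days)
  if (any(dt <= 0)) stop("days must be strictly increasing")
  y <- diff(log(counts)) / dt
  N <- utils::head(counts, -1)
  if (stats::sd(y) < 1e-12)
    stop("degenerate series: per-capita growth rate has zero variance ",
         "(population at equilibrium)")
  fit <- stats::lm(y ~ N)
  ci <- stats::confint(fit)
  structure(list(r = unname(stats::coef(fit)[1]),
                 alpha = -unname(stats::coef(fit)[2]),
                 ci_r = unname(ci[1, ]),
                 ci_alpha = unname(rev(-ci[2, ])),
                 fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> r = %.4f [%.4f, %.4f], alpha = %.5f [%.5f, %.5f]\n",
              x$r, x$ci_r[1], x$ci_r[2], x$alpha, x$ci_alpha[1], x$ci_alpha[2]))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) c(r = object$r, alpha = object$alpha)

# candidate grid: observed values plus midpoints, ties toward smaller values
.break_grid <- function(x) {
  xs <- sort(unique(x))
  sort(unique(c(xs, xs[-length(xs)] + diff(xs) / 2)))
}

#' Fit the piecewise-linear saturating functional response
#'
#' Least squares for `y = min(slope * x, cap)` over a grid of candidate
#' breakpoints (observed x values and their midpoints), continuous at the
#' breakpoint (`cap = slope * breakpoint`). For a fixed breakpoint b the
#' model is linear in the slope through `min(x, b)`, so each candidate is a
#' one-parameter regression; the breakpoint with the smallest SSE wins, ties
#' going to the smaller breakpoint. If no candidate beats the pure linear
#' model (cap never reached), the fit falls back to `y = slope * x` with an
#' infinite breakpoint and is flagged.
#'
#' @param x Host (or larval) densities, non-negative.
#' @param y Attacks per consumer per day.
#' @return A `saturating_fit`: `slope`, `cap`, `breakpoint`, `sse`,
#'   `linear_fallback` flag.
#' @export
fit_saturating <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must align")
  if (length(x) < 4) stop("need at least 4 points")
  if (any(x < 0)) stop("x must be non-negative")
  cands <- .break_grid(x)
  cands <- cands[cands > 0]
  best <- NULL
  for (b in c(cands, Inf)) {
    m <- pmin(x, b)
    if (sum(m^2) == 0) next
    s <- sum(y * m) / sum(m^2)
    sse <- sum((y - s * m)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(slope = s, breakpoint = b, sse = sse)
    }
  }
  fallback <- !is.finite(best$breakpoint) || best$breakpoint >= max(x)
  structure(list(slope = best$slope,
                 cap = if (is.finite(best$breakpoint))
                   best$slope * best$breakpoint else Inf,
                 breakpoint = best$breakpoint, sse = best$sse,
                 linear_fallback = fallback),
            class = "saturating_fit")
}

#' @export
print.saturating_fit <- function(x, ...) {
  cat(sprintf("<saturating_fit> slope = %.4f, cap = %.4f, breakpoint = %.4f%s\n",
              x$slope, x$cap, x$breakpoint,
              if (x$linear_fallback) " (linear fallback: cap unreached)" else ""))
  invisible(x)
}

#' @export
coef.saturating_fit <- function(object, ...)
  c(slope = object$slope, cap = object$cap, breakpoint = object$breakpoint)

#' Fit the density-dependent emigration rule
#'
#' Least squares for `E = e * max(0, A - tau)` over a grid of candidate
#' thresholds (0, the observed abundances and their midpoints). For fixed
#' `tau` the model is linear in `e`; the threshold with smallest SSE wins,
#' ties toward the smaller threshold. All-zero emigrant counts return
#' `e = 0, tau = max(A)`, flagged.
#'
#' @param abundance Patch abundances.
#' @param emigrants Observed emigrant counts.
#' @return An `emigration_fit`: `e`, `tau`, `sse`, `all_zero` flag.
#' @export
fit_emigration <- function(abundance, emigrants) {
  if (length(abundance) != length(emigrants)) stop("inputs must align")
  if (length(abundance) < 4) stop("need at least 4 points")
  if (all(emigrants == 0)) {
    return(structure(list(e = 0, tau = max(abundance), sse = 0,
                          all_zero = TRUE), class = "emigration_fit"))
  }
  cands <- sort(unique(c(0, .break_grid(abundance))))
  best <- NULL
  for (tau in cands) {
    m <- pmax(0, abundance - tau)
    if (sum(m^2) == 0) next
    e <- sum(emigrants * m) / sum(m^2)
    sse <- sum((emigrants - e * m)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(e = e, tau = tau, sse = sse)
    }
  }
  structure(list(e = best$e, tau = best$tau, sse = best$sse, all_zero = FALSE),
            class = "emigration_fit")
}

#' @export
print.emigration_fit <- function(x, ...) {
  cat(sprintf("<emigration_fit> e = %.4f, tau = %.2f%s\n", x$e, x$tau,
              if (x$all_zero) " (no emigration observed)" else ""))
  invisible(x)
}

#' @export
coef.emigration_fit <- function(object, ...) c(e = object$e, tau = object$tau)
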