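# Synthetic-data generators with known ground truth. These emulate the kinds
# of observations the pipeline consumes (census-day count series for the
# growth regression; factorial credit tables for the ANOVA stage) so every
# analysis step is testable end to end without external data.

#' Twice-weekly census grid
#'
#' Observation days alternating 3- and 4-day gaps from day 0 up to `horizon`,
#' the twice-a-week counting schedule of a 26-day run (8 days: 0, 3, 7, 10,
#' 14, 17, 21, 24).
#'
#' @param horizon Last day of the study (default 26).
#' @return Integer vector of census days.
#' @export
census_days <- function(horizon = 26) {
  d <- 0L
  gaps <- c(3L, 4L)
  i <- 0L
  while (d[length(d)] + gaps[i %% 2L + 1L] <= horizon) {
    d <- c(d, d[length(d)] + gaps[i %% 2L + 1L])
    i <- i + 1L
  }
  d
}

#' Generate a synthetic single-patch count series
#'
#' Iterates the Ricker-type growth map `N <- N * exp(r - alpha * N)` daily
#' from `n0`, samples it on the census grid and optionally multiplies
#' lognormal observation noise `exp(rnorm(0, sigma))` (counts are positive
#' and their dispersion grows with the mean, hence multiplicative noise).
#'
#' @param r,alpha True growth and intraspecific competition parameters.
#' @param n0 Initial population size (default 10).
#' @param sigma Lognormal noise sd on the log scale (0 = deterministic).
#' @param days Observation days (default [census_days()]).
#' @param seed Optional seed; same seed, same series.
#' @return Data frame: `day`, `count`.
#' @export
make_observation_series <- function(r, alpha, n0 = 10, sigma = 0,
                                    days = census_days(), seed = NULL) {
  horizon <- max(days)
  N <- numeric(horizon + 1)
  N[1] <- n0
  for (t in seq_len(horizon)) N[t + 1] <- N[t] * exp(r - alpha * N[t])
  counts <- N[days + 1]
  if (sigma > 0) {
    counts <- with_seed(seed,
                        counts * exp(stats::rnorm(length(counts), 0, sigma)))
  }
  data.frame(day = days, count = counts)
}

#' Generate a synthetic factorial credit table with known effects
#'
#' Builds a balanced 2 (number) x 2 (location) x K (community) table on the
#' ln(1+credit) scale: response = grand mean + injected main effects
#' (+ optional number:location interaction) + Gaussian noise. Used to verify
#' that the ANOVA stage recovers injected effects and holds its type-I error.
#'
#' @param effects List with entries `number` (added at number = 4),
#'   `location` (added at location = peripheral), `community` (numeric vector,
#'   one offset per community level, first usually 0), and optionally
#'   `number_location` (added when number = 4 AND location = peripheral).
#' @param grand_mean Baseline ln(1+credit) (default 4).
#' @param sd Gaussian noise sd (0 allowed: degenerate, F becomes 0/Inf).
#' @param reps Replicates per cell.
#' @param communities Community level labels.
#' @param scale Scale label stamped on the rows.
#' @param seed Optional seed.
#' @return Credit table with the same columns [run_factorial()] produces.
#' @export
make_credit_table <- function(effects = list(), grand_mean = 4, sd = 0.3,
                              reps = 5,
                              communities = c("1A", "2A", "2A-1P"),
                              scale = "metapopulation", seed = NULL) {
  pick <- function(nm, default) {
    if (is.null(effects[[nm, exact = TRUE]])) default else effects[[nm]]
  }
  eff_n <- pick("number", 0)
  eff_l <- pick("location", 0)
  eff_c <- pick("community", rep(0, length(communities)))
  eff_nl <- pick("number_location", 0)
  if (length(eff_c) != length(communities))
    stop("effects$community must have one entry per community")
  grid <- expand.grid(replicate = seq_len(reps),
                      community = communities,
                      location = c("central", "peripheral"),
                      number = c(1L, 4L),
                      stringsAsFactors = FALSE)
  mu <- grand_mean +
    eff_n * (grid$number == 4L) +
    eff_l * (grid$location == "peripheral") +
    eff_c[match(grid$community, communities)] +
    eff_nl * (grid$number == 4L & grid$location == "peripheral")
  y <- with_seed(seed, mu + stats::rnorm(nrow(grid), 0, sd))
  data.frame(community = grid$community,
             config = paste0(grid$number,
                             ifelse(grid$location == "central", "C", "P")),
             number = grid$number, location = grid$location,
             replicate = grid$replicate, scale = rep(scale, nrow(grid)),
             credit = expm1(y), credit_ln1p = y,
             stringsAsFactors = FALSE)
}
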