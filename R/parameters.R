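# Built-in SYNTHETIC reference parameter set.
#
# The study system's fitted parameter values live in its supplementary
# material, which is not redistributed here. The values below are a synthetic
# reference set chosen once on biological grounds for the same six species
# (see the methods vignette for the reasoning) and shaped exactly like a
# user-supplied table, so they can be overridden with `read_parameter_priors()`.
#
# Units: rates per day, abundances in individuals, lags in days.
# Columns: species, parameter, target (interaction partner or NA),
#          estimate, lower, upper (95% confidence bounds used for the
#          per-replicate uniform draws).
.default_priors <- local({
  row <- function(sp, par, tg, est, lo, hi)
    data.frame(species = sp, parameter = par, target = tg,
               estimate = est, lower = lo, upper = hi,
               stringsAsFactors = FALSE)
  rbind(
    # aphid intrinsic growth (d^-1): ~4 generations in 26 days
    row("Bb", "r", NA, 0.28, 0.24, 0.32),
    row("Le", "r", NA, 0.30, 0.26, 0.34),
    row("Mp", "r", NA, 0.33, 0.29, 0.37),
    # competition coefficients alpha[i <- j] (per capita d^-1);
    # intraspecific ~ r/K with K 200-300 per patch; interspecific follow the
    # hierarchy Bb weakest, Mp strongest, with coexistence preserved
    row("Bb", "alpha", "Bb", 0.0014, 0.0011, 0.0017),
    row("Bb", "alpha", "Le", 0.0008, 0.0005, 0.0011),
    row("Bb", "alpha", "Mp", 0.0011, 0.0008, 0.0014),
    row("Le", "alpha", "Bb", 0.0005, 0.0003, 0.0007),
    row("Le", "alpha", "Le", 0.0012, 0.0009, 0.0015),
    row("Le", "alpha", "Mp", 0.0009, 0.0006, 0.0012),
    row("Mp", "alpha", "Bb", 0.0004, 0.0002, 0.0006),
    row("Mp", "alpha", "Le", 0.0005, 0.0003, 0.0007),
    row("Mp", "alpha", "Mp", 0.0011, 0.0008, 0.0014),
    # aphid density-dependent emigration: rate above threshold, threshold
    row("Bb", "e", NA, 0.10, 0.08, 0.12),
    row("Le", "e", NA, 0.10, 0.08, 0.12),
    row("Mp", "e", NA, 0.12, 0.10, 0.14),
    row("Bb", "tau", NA, 50, 40, 60),
    row("Le", "tau", NA, 50, 40, 60),
    row("Mp", "tau", NA, 45, 35, 55),
    # parasitoid attack-rate slopes a[p, i] (hosts per adult per day per host);
    # D. rapae prefers B. brassicae, A. colemani prefers M. persicae
    row("Dr", "a", "Bb", 0.10, 0.08, 0.12),
    row("Dr", "a", "Le", 0.05, 0.03, 0.07),
    row("Dr", "a", "Mp", 0.02, 0.01, 0.03),
    row("Ac", "a", "Bb", 0.03, 0.02, 0.04),
    row("Ac", "a", "Le", 0.04, 0.03, 0.05),
    row("Ac", "a", "Mp", 0.10, 0.08, 0.12),
    # egg-load cap (hosts per adult per day), conversion, adult mortality,
    # larval development lag, dispersal
    row("Dr", "h", NA, 8, 6, 10),
    row("Ac", "h", NA, 8, 6, 10),
    row("Dr", "c", NA, 0.5, 0.4, 0.6),
    row("Ac", "c", NA, 0.5, 0.4, 0.6),
    row("Dr", "d", NA, 0.15, 0.12, 0.18),
    row("Ac", "d", NA, 0.15, 0.12, 0.18),
    row("Dr", "L", NA, 10, 10, 10),
    row("Ac", "L", NA, 10, 10, 10),
    row("Dr", "e", NA, 0.30, 0.25, 0.35),
    row("Ac", "e", NA, 0.30, 0.25, 0.35),
    row("Dr", "tau", NA, 1, 1, 1),
    row("Ac", "tau", NA, 1, 1, 1),
    # hyperparasitoid: attacks D. rapae larvae at a higher rate than
    # A. colemani's
    row("Af", "g", "Dr", 0.04, 0.03, 0.05),
    row("Af", "g", "Ac", 0.02, 0.01, 0.03),
    row("Af", "k", NA, 6, 4, 8),
    row("Af", "c", NA, 0.5, 0.4, 0.6),
    row("Af", "d", NA, 0.15, 0.12, 0.18),
    row("Af", "L", NA, 10, 10, 10),
    row("Af", "e", NA, 0.30, 0.25, 0.35),
    row("Af", "tau", NA, 1, 1, 1)
  )
})

#' Default parameter priors
#'
#' Point estimates with lower/upper confidence bounds for every model
#' parameter of the six-species pool. This is a synthetic reference set (the
#' original fitted values are not redistributed); override any subset by
#' editing the returned table or loading one with [read_parameter_priors()].
#'
#' @return Data frame with columns `species`, `parameter`, `target`,
#'   `estimate`, `lower`, `upper`.
#' @export
default_parameter_priors <- function() .default_priors

#' Read / write parameter priors as CSV
#' @param path File path.
#' @export
read_parameter_priors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "parameter", "target", "estimate", "lower", "upper")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("priors table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$lower > df$estimate | df$estimate > df$upper))
    stop("priors must satisfy lower <= estimate <= upper")
  df[need]
}

#' @rdname read_parameter_priors
#' @param priors Priors data frame.
#' @export
write_parameter_priors <- function(priors, path) {
  utils::write.csv(priors, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Draw one replicate's parameter values
#'
#' Each parameter is drawn independently and uniformly between its lower and
#' upper confidence bound (degenerate bounds return the point estimate).
#' This is the replicate-level stochasticity of the simulation design:
#' dynamics are deterministic within a replicate.
#'
#' @param priors Priors data frame (see [default_parameter_priors()]).
#' @param seed Optional integer seed; same seed gives identical draws.
#' @return The priors data frame with an extra `value` column.
#' @export
draw_replicate_parameters <- function(priors, seed = NULL) {
  with_seed(seed, {
    v <- stats::runif(nrow(priors), priors$lower, priors$upper)
    v[priors$lower == priors$upper] <- priors$estimate[priors$lower == priors$upper]
    # guard type invariants: rates/fractions non-negative, mortality and
    # emigration fractions in [0, 1]
    v <- pmax(v, 0)
    frac <- priors$parameter %in% c("e", "d", "c")
    clipped <- frac & v > 1
    if (any(clipped)) {
      warning("clipped ", sum(clipped), " drawn fraction(s) to 1")
      v[clipped] <- 1
    }
    priors$value <- v
    priors
  })
}

# Assemble the matrix/vector form the simulator consumes, restricted to one
# food web. `draws` is a priors table with a `value` column (or the estimate
# column is used, giving the point parameterisation).
as_parameter_set <- function(draws, web) {
  if (!"value" %in% names(draws)) draws$value <- draws$estimate
  get1 <- function(sp, par, tg = NA) {
    hit <- draws$species == sp & draws$parameter == par &
      (if (is.na(tg)) is.na(draws$target) else !is.na(draws$target) & draws$target == tg)
    if (sum(hit) != 1)
      stop("parameter lookup failed for ", sp, "/", par,
           if (!is.na(tg)) paste0("/", tg), " (", sum(hit), " matches)")
    draws$value[hit]
  }
  sp <- web$species
  aph <- sp$id[sp$common_role == "aphid"]
  par <- sp$id[sp$common_role == "parasitoid"]
  hyp <- sp$id[sp$common_role == "hyperparasitoid"]
  ps <- list(
    aphids = aph, parasitoids = par, hyper = hyp,
    r = vapply(aph, get1, 0, par = "r"),
    alpha = {
      a <- matrix(0, length(aph), length(aph), dimnames = list(aph, aph))
      for (i in aph) for (j in aph) a[i, j] <- get1(i, "alpha", j)
      a
    },
    e_a = vapply(aph, get1, 0, par = "e"),
    tau_a = vapply(aph, get1, 0, par = "tau")
  )
  if (length(par)) {
    ps$a <- {
      m <- matrix(0, length(par), length(aph), dimnames = list(par, aph))
      for (p in par) for (i in aph) m[p, i] <- get1(p, "a", i)
      m
    }
    ps$h <- vapply(par, get1, 0, par = "h")
    ps$c_p <- vapply(par, get1, 0, par = "c")
    ps$d_p <- vapply(par, get1, 0, par = "d")
    ps$L_p <- stats::setNames(as.integer(round(vapply(par, get1, 0, par = "L"))), par)
    ps$e_p <- vapply(par, get1, 0, par = "e")
    ps$tau_p <- vapply(par, get1, 0, par = "tau")
  }
  if (length(hyp)) {
    ps$g <- vapply(par, function(p) get1(hyp, "g", p), 0)
    ps$k_h <- get1(hyp, "k")
    ps$c_h <- get1(hyp, "c")
    ps$d_h <- get1(hyp, "d")
    ps$L_h <- as.integer(round(get1(hyp, "L")))
    ps$e_h <- get1(hyp, "e")
    ps$tau_h <- get1(hyp, "tau")
  }
  ps
}
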