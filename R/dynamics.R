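# Core discrete-time metacommunity dynamics.
#
# Aphids follow a Ricker-type (exponential logistic) competition model; losses
# to parasitism and dispersal are applied outside the exponential:
#   A(t+1) = max(0, A exp(r - sum_j alpha_ij A_j) - M - E + I)
# Parasitoid and hyperparasitoid adults follow a birth/death balance with a
# larval development lag; attack rates use a piecewise-linear saturating
# function (ramp with a cap) mimicking a Type II functional response.
# All fluxes in one day are computed from the state at t (synchronous update).

.clamp_exp <- function(x, cap = 50) exp(pmin(pmax(x, -cap), cap))

#' Aphid growth and competition
#'
#' One day of density-dependent growth: `A_i * exp(r_i - sum_j alpha_ij A_j)`.
#' The exponent is capped at +/-50 to guard against overflow on adversarial
#' inputs.
#'
#' @param A Aphid abundances: vector (one patch) or patches x species matrix.
#' @param r Intrinsic growth rates (per day), one per aphid species.
#' @param alpha Competition matrix; `alpha[i, j]` is the per-capita effect of
#'   species j on species i.
#' @param exp_cap Cap on the exponent argument.
#' @return Grown abundances, same shape as `A`.
#' @export
growth_competition <- function(A, r, alpha, exp_cap = 50) {
  vec <- is.null(dim(A))
  A <- if (vec) matrix(A, nrow = 1) else A
  alpha <- if (is.null(dim(alpha))) matrix(alpha, length(r)) else alpha
  G <- A * .clamp_exp(sweep(-A %*% t(alpha), 2, r, "+"), exp_cap)
  if (vec) unname(drop(G)) else G
}

#' Parasitism mortality (piecewise-linear saturating attack)
#'
#' Per consumer adult of species p, total daily attacks are
#' `min(sum_i a[p,i] * A_i, h_p)`: linear in host density at low density,
#' capped by the egg load at high density. Attacks are allocated to host
#' species proportionally to `a[p,i] * A_i`, summed over consumer species, and
#' clipped so no host species loses more than its standing abundance
#' (proportional down-scaling across consumers).
#'
#' @param A Host abundances: vector or patches x hosts matrix.
#' @param P Consumer adult abundances: vector or patches x consumers matrix.
#' @param a Attack-rate slope matrix, consumers x hosts.
#' @param h Saturation caps (attacks per adult per day), one per consumer.
#' @return List: `M` (host losses, same shape as `A`) and `attacks`
#'   (patches x consumers x hosts array of realised attacks).
#' @export
parasitism_mortality <- function(A, P, a, h) {
  vec <- is.null(dim(A))
  A <- rbind(A); P <- rbind(P); a <- matrix(a, ncol = ncol(A))
  np <- nrow(A); ni <- ncol(A); nc <- nrow(a)
  load <- A %*% t(a)                               # patches x consumers
  Tp <- t(pmin(t(load), h))                        # attacks per adult
  tot <- P * Tp                                    # total attacks by species
  attacks <- array(0, c(np, nc, ni))
  for (p in seq_len(nc)) {
    num <- sweep(A, 2, a[p, ], "*")
    denom <- ifelse(load[, p] > 0, load[, p], 1)
    attacks[, p, ] <- (num / denom) * tot[, p]
  }
  M <- apply(attacks, c(1, 3), sum)
  dim(M) <- c(np, ni)
  sc <- ifelse(M > A & M > 0, A / M, 1)            # per-host clip factor
  if (any(sc < 1)) {
    M <- M * sc
    for (p in seq_len(nc)) attacks[, p, ] <- attacks[, p, ] * sc
  }
  list(M = if (vec) drop(M) else M, attacks = attacks)
}

#' Density-dependent dispersal flows
#'
#' Emigration from patch k is `e * max(0, Q_k - tau)` (capped at `Q_k`);
#' emigrants split equally among the patch's neighbours, so total emigration
#' equals total immigration exactly (no dispersal mortality, stepping-stone
#' movement along edges only).
#'
#' @param Q Abundances of one species across patches (vector), or a
#'   patches x species matrix with per-species `e`, `tau`.
#' @param landscape A `patch_landscape`.
#' @param e Emigration rate(s) above threshold.
#' @param tau Emigration threshold(s).
#' @return List of `E` and `I`, same shape as `Q`.
#' @export
dispersal_flows <- function(Q, landscape, e, tau) {
  vec <- is.null(dim(Q))
  Q <- cbind(Q)
  E <- pmin(Q, sweep(pmax(sweep(Q, 2, tau, "-"), 0), 2, e, "*"))
  deg <- landscape$degree
  if (any(deg == 0 & rowSums(E) > 0)) {
    warning("isolated patch above dispersal threshold: emigration forced to 0")
    E[deg == 0, ] <- 0
  }
  adj <- adjacency_matrix(landscape)
  I <- adj %*% (E / pmax(deg, 1))
  list(E = if (vec) drop(E) else E, I = if (vec) drop(I) else I)
}

# Initial state for a simulation: abundance matrix plus empty larval queues.
.init_state <- function(web, landscape, placement, params,
                        init_aphids = 10, init_consumers = 1) {
  np <- landscape$n_patches
  ids <- web$species$id
  N <- matrix(0, np, length(ids), dimnames = list(NULL, ids))
  pop <- placement$populated + 1L
  N[pop, params$aphids] <- init_aphids
  consumers <- c(params$parasitoids, params$hyper)
  if (length(consumers)) N[pop, consumers] <- init_consumers
  larvae <- lapply(params$parasitoids, function(p)
    matrix(0, params$L_p[p], np))
  names(larvae) <- params$parasitoids
  hlarvae <- if (length(params$hyper)) matrix(0, params$L_h, np) else NULL
  list(t = 0L, N = N, larvae = larvae, hlarvae = hlarvae)
}

#' Consumer (parasitoid / hyperparasitoid) update
#'
#' One day of consumer dynamics across all patches: (i) today's attacks join
#' the larval pool; (ii) hyperparasitoids attack the standing larval pool with
#' the same saturating rule, converting attacked larvae into future
#' hyperparasitoids (their development restarts at attack); (iii) cohorts
#' completing the development lag emerge as `c * count` adults of their
#' current identity; (iv) adults lose a mortality fraction `d`, gain the
#' emergences, and disperse with their own threshold-linear rule.
#'
#' @param state Simulator state (`N`, `larvae`, `hlarvae`).
#' @param landscape A `patch_landscape`.
#' @param params Parameter set (see `as_parameter_set`).
#' @param attacks Patches x parasitoids x aphids array of today's attacks.
#' @return Updated `N` columns, larval queues, and emergence bookkeeping.
#' @export
consumer_update <- function(state, landscape, params, attacks) {
  np <- landscape$n_patches
  pars <- params$parasitoids
  hyp <- params$hyper
  if (!length(pars))
    return(list(N = state$N, larvae = state$larvae, hlarvae = state$hlarvae))
  N <- state$N
  new_cohort <- matrix(0, np, length(pars))
  pool <- matrix(0, np, length(pars))
  for (p in seq_along(pars)) {
    new_cohort[, p] <- rowSums(matrix(attacks[, p, ], nrow = np))
    # standing larval pool (incl. today's cohort)
    pool[, p] <- new_cohort[, p] + colSums(state$larvae[[p]])
  }

  removed <- matrix(0, np, length(pars))
  if (length(hyp)) {
    H <- N[, hyp]
    att <- parasitism_mortality(pool, cbind(H), matrix(params$g, nrow = 1), params$k_h)
    removed <- cbind(att$M)
  }
  frac_left <- ifelse(pool > 0, 1 - removed / pool, 1)

  larvae <- state$larvae
  emerged <- matrix(0, np, length(pars))
  for (p in seq_along(pars)) {
    q <- larvae[[p]] * rep(frac_left[, p], each = nrow(larvae[[p]]))
    nc0 <- new_cohort[, p] * frac_left[, p]
    L <- nrow(q)
    emerged[, p] <- q[L, ]
    larvae[[p]] <- rbind(nc0, q[-L, , drop = FALSE], deparse.level = 0)
  }

  hlarvae <- state$hlarvae
  h_emerged <- numeric(np)
  if (length(hyp)) {
    Lh <- nrow(hlarvae)
    h_emerged <- hlarvae[Lh, ]
    hlarvae <- rbind(rowSums(removed), hlarvae[-Lh, , drop = FALSE],
                     deparse.level = 0)
  }

  # adult balance: survival + emergence - emigration + immigration
  Pad <- N[, pars, drop = FALSE]
  dp <- dispersal_flows(Pad, landscape, params$e_p, params$tau_p)
  births <- sweep(emerged, 2, params$c_p, "*")
  N[, pars] <- pmax(0, sweep(Pad, 2, 1 - params$d_p, "*") + births - dp$E + dp$I)
  if (length(hyp)) {
    Had <- N[, hyp]
    dh <- dispersal_flows(Had, landscape, params$e_h, params$tau_h)
    N[, hyp] <- pmax(0, Had * (1 - params$d_h) + params$c_h * h_emerged -
                       dh$E + dh$I)
  }
  list(N = N, larvae = larvae, hlarvae = hlarvae)
}

#' One synchronous day of metacommunity dynamics
#'
#' Computes growth, parasitism, emigration and immigration for every patch
#' from the state at `t`, then applies them:
#' `A(t+1) = max(0, G - M - E + I)` for aphids, and [consumer_update()] for
#' the wasps. The returned ledger records the pre-clip components
#' (`growth_net = G - A(t)`, `parasitism`, `emigration`, `immigration`), so
#' `A(t+1) - A(t)` equals `growth_net - parasitism - emigration + immigration`
#' up to the documented non-negativity clip.
#'
#' @param state Simulator state.
#' @param landscape A `patch_landscape`.
#' @param params Parameter set.
#' @param control List: `exp_cap` (default 50), `inside_exp` (default FALSE;
#'   if TRUE the growth factor multiplies the post-flux abundance instead).
#' @return List: `state` (advanced one day), `ledger` (list of
#'   patches x aphids matrices), `clipped` (count of patch/species cells hit
#'   by the non-negativity clip).
#' @export
step_metacommunity <- function(state, landscape, params, control = list()) {
  exp_cap <- if (is.null(control$exp_cap)) 50 else control$exp_cap
  inside <- isTRUE(control$inside_exp)
  aph <- params$aphids
  A <- state$N[, aph, drop = FALSE]
  G <- growth_competition(A, params$r, params$alpha, exp_cap)
  if (length(params$parasitoids)) {
    pm <- parasitism_mortality(A, state$N[, params$parasitoids, drop = FALSE],
                               params$a, params$h)
  } else {
    pm <- list(M = A * 0, attacks = array(0, c(nrow(A), 0, ncol(A))))
  }
  da <- dispersal_flows(A, landscape, params$e_a, params$tau_a)
  if (inside) {
    fac <- .clamp_exp(sweep(-A %*% t(params$alpha), 2, params$r, "+"), exp_cap)
    A1 <- pmax(0, (A - pm$M - da$E + da$I) * fac)
  } else {
    A1 <- G - pm$M - da$E + da$I
  }
  clipped <- sum(A1 < 0)
  A1 <- pmax(0, A1)

  st <- consumer_update(state, landscape, params, pm$attacks)
  st$N[, aph] <- A1
  st$t <- state$t + 1L
  list(state = st,
       ledger = list(growth_net = G - A, parasitism = pm$M,
                     emigration = da$E, immigration = da$I),
       clipped = clipped)
}

#' Simulate a metacommunity
#'
#' Runs the full model for one community on one landscape: initial abundances
#' are 10 per aphid species and 1 adult per (hyper)parasitoid species in each
#' initially populated patch and 0 elsewhere, followed by `days` synchronous
#' daily steps. Replicate-level stochasticity enters only through the uniform
#' parameter draws between confidence bounds; the dynamics themselves are
#' deterministic.
#'
#' @param web A `foodweb` (see [build_community()]).
#' @param landscape A `patch_landscape`; must be connected.
#' @param placement A `placement` on that landscape.
#' @param priors Parameter priors table (default [default_parameter_priors()]).
#' @param days Simulation horizon in days (default 26).
#' @param seed Optional integer seed for the parameter draw.
#' @param init_aphids,init_consumers Initial abundances in populated patches.
#' @param draw If `FALSE`, use point estimates instead of drawing.
#' @param control Passed to [step_metacommunity()].
#' @return A `metacommunity_sim` object: `abundance` (day x patch x species
#'   array, day 0 first), `ledger` (list of day x patch x aphid arrays),
#'   plus the inputs and the drawn parameter set.
#' @export
simulate_metacommunity <- function(web, landscape, placement,
                                   priors = default_parameter_priors(),
                                   days = 26, seed = NULL,
                                   init_aphids = 10, init_consumers = 1,
                                   draw = TRUE, control = list()) {
  if (any(placement$populated >= landscape$n_patches | placement$populated < 0))
    stop("placement references patches outside the landscape")
  if (!is_connected_landscape(landscape))
    stop("landscape must be connected")
  draws <- if (draw) draw_replicate_parameters(priors, seed) else priors
  params <- as_parameter_set(draws, web)
  st <- .init_state(web, landscape, placement, params, init_aphids, init_consumers)
  np <- landscape$n_patches
  ids <- web$species$id
  ab <- array(0, c(days + 1, np, length(ids)),
              dimnames = list(NULL, NULL, ids))
  ab[1, , ] <- st$N
  na <- length(params$aphids)
  led <- lapply(c("growth_net", "parasitism", "emigration", "immigration"),
                function(nm) array(0, c(days, np, na),
                                   dimnames = list(NULL, NULL, params$aphids)))
  names(led) <- c("growth_net", "parasitism", "emigration", "immigration")
  clipped <- 0L
  for (t in seq_len(days)) {
    out <- step_metacommunity(st, landscape, params, control)
    st <- out$state
    ab[t + 1, , ] <- st$N
    for (nm in names(led)) led[[nm]][t, , ] <- out$ledger[[nm]]
    clipped <- clipped + out$clipped
  }
  structure(list(web = web, landscape = landscape, placement = placement,
                 params = params, days = days, seed = seed,
                 abundance = ab, ledger = led, clip_events = clipped),
            class = "metacommunity_sim")
}

#' @export
print.metacommunity_sim <- function(x, ...) {
  cat("<metacommunity_sim>", x$web$label, "on", x$landscape$kind,
      paste0("(", x$landscape$n_patches, " patches),"),
      x$placement$config_label, "placement,", x$days, "days\n")
  cat("  final metapopulation sizes:",
      paste(sprintf("%s=%.1f", dimnames(x$abundance)[[3]],
                    apply(x$abundance[x$days + 1, , , drop = FALSE], 3, sum)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.metacommunity_sim <- function(object, focal = "Bb", ...) {
  cr <- summarise_credits(object, focal = focal)
  cat("Recovery credits for", focal, "over", object$days, "days:\n")
  print(cr, row.names = FALSE)
  invisible(cr)
}

#' @export
plot.metacommunity_sim <- function(x, species = "Bb", ...) {
  y <- x$abundance[, , species]
  graphics::matplot(0:x$days, y, type = "l", lty = 1,
                    xlab = "day", ylab = paste(species, "abundance"),
                    main = paste(x$web$label, x$placement$config_label), ...)
  graphics::legend("topleft", bty = "n", lty = 1, col = seq_len(ncol(y)),
                   legend = paste0("patch ", seq_len(ncol(y)) - 1,
                                   ifelse(seq_len(ncol(y)) - 1 %in%
                                            x$placement$populated,
                                          " (populated)", "")))
  invisible(x)
}

#' @export
as.data.frame.metacommunity_sim <- function(x, ...) {
  ab <- x$abundance
  dn <- dim(ab)
  data.frame(
    day = rep(0:(dn[1] - 1), times = dn[2] * dn[3]),
    patch = rep(rep(0:(dn[2] - 1), each = dn[1]), times = dn[3]),
    species = rep(dimnames(ab)[[3]], each = dn[1] * dn[2]),
    abundance = as.vector(ab),
    stringsAsFactors = FALSE
  )
}

#' Decompose population change into local and dispersal components
#'
#' Sums the per-day ledger over the run: cumulative net growth, parasitism
#' loss, emigration and immigration per patch and aphid species. A patch is a
#' `source` for a species when cumulative emigration exceeds immigration, a
#' `sink` when the reverse holds, `neutral` when the two balance exactly.
#'
#' @param sim A `metacommunity_sim`.
#' @return Data frame: patch, species, the four cumulative components,
#'   `net_emigration` and `role`.
#' @export
decompose_trajectory <- function(sim) {
  led <- sim$ledger
  aph <- dimnames(led$growth_net)[[3]]
  np <- dim(led$growth_net)[2]
  out <- expand.grid(patch = 0:(np - 1), species = aph,
                     stringsAsFactors = FALSE)
  for (nm in names(led)) {
    cum <- apply(led[[nm]], c(2, 3), sum)
    out[[nm]] <- as.vector(cum)
  }
  out$net_emigration <- out$emigration - out$immigration
  out$role <- ifelse(out$net_emigration > 0, "source",
                     ifelse(out$net_emigration < 0, "sink", "neutral"))
  out
}
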