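test_that("growth_competition matches hand-evaluated cases", {
  # equilibrium r/alpha is a fixed point
  expect_equal(growth_competition(10, r = 0.3, alpha = 0.03), 10)
  # extinction is absorbing
  expect_equal(growth_competition(0, r = 0.3, alpha = 0.03), 0)
  # two symmetric competitors
  out <- growth_competition(c(5, 5), r = c(0.4, 0.4),
                            alpha = matrix(c(0.04, 0.02, 0.02, 0.04), 2))
  expect_equal(out, rep(5 * exp(0.1), 2))
  # exponent cap guards overflow
  expect_true(is.finite(growth_competition(1, r = 1e6, alpha = 0)))
})

test_that("parasitism follows the saturating allocation rule", {
  # no parasitoids, no mortality
  out <- parasitism_mortality(c(10, 10), 0, a = matrix(c(0.2, 0.1), 1), h = 4)
  expect_equal(out$M, c(0, 0))
  # below the cap: attacks proportional to a_i * A_i
  out <- parasitism_mortality(c(10, 10), 1, a = matrix(c(0.2, 0.1), 1), h = 4)
  expect_equal(out$M, c(2, 1))
  # saturation: huge host density pins attacks per adult at h
  out <- parasitism_mortality(1e6, 1, a = matrix(0.2, 1), h = 4)
  expect_equal(out$M, 4)
  # attacks never exceed standing hosts (clip)
  out <- parasitism_mortality(c(3, 1), 10, a = matrix(c(0.2, 0.1), 1), h = 8)
  expect_true(all(out$M <= c(3, 1) + 1e-12))
})

test_that("dispersal conserves mass and follows the threshold rule", {
  ls <- star5()
  # below threshold: nothing moves
  out <- dispersal_flows(rep(10, 5), ls, e = 0.1, tau = 50)
  expect_equal(out$E, rep(0, 5))
  expect_equal(out$I, rep(0, 5))
  # hub 40 above threshold: E = 4 split equally over 4 leaves
  out <- dispersal_flows(c(90, 0, 0, 0, 0), ls, e = 0.1, tau = 50)
  expect_equal(out$E, c(4, 0, 0, 0, 0))
  expect_equal(out$I, c(0, 1, 1, 1, 1))
  # conservation on random instances
  set.seed(42)
  for (i in 1:20) {
    ls2 <- scale_free_landscape(15, 2, seed = i)
    Q <- matrix(runif(15 * 3, 0, 200), 15, 3)
    out <- dispersal_flows(Q, ls2, e = c(0.1, 0.2, 0.3), tau = c(30, 50, 70))
    expect_equal(colSums(out$E), colSums(out$I))
    expect_true(all(out$E <= Q + 1e-12))
  }
})

test_that("consumers decay geometrically without hosts and emerge via the queue", {
  ls <- star5()
  web <- build_community("1A-1P")
  pl <- placement_1c(ls)
  pr <- frozen_priors()
  # no aphids at all: parasitoid adults decay at (1 - d) per day
  sim <- simulate_metacommunity(web, ls, pl, priors = pr, days = 8,
                                init_aphids = 0, draw = FALSE)
  d <- sim$params$d_p[["Dr"]]
  expect_equal(sim$abundance[, 1, "Dr"], (1 - d)^(0:8))
  # with hosts and no hyperparasitoid, cohorts attacked on day t emerge as
  # c_p * cohort adults L days later
  sim <- simulate_metacommunity(web, ls, pl, priors = pr, days = 12,
                                draw = FALSE)
  ps <- sim$params
  att_day1 <- sum(parasitism_mortality(sim$abundance[1, 1, "Bb"],
                                       sim$abundance[1, 1, "Dr"],
                                       a = ps$a, h = ps$h)$M)
  L <- ps$L_p[["Dr"]]
  d <- ps$d_p[["Dr"]]
  # adults just before emergence vs just after: the jump is c_p * cohort
  P_before <- sim$abundance[L + 1, 1, "Dr"]
  P_after <- sim$abundance[L + 2, 1, "Dr"]
  dsp <- dispersal_flows(sim$abundance[L + 1, , "Dr"], ls,
                         e = ps$e_p[["Dr"]], tau = ps$tau_p[["Dr"]])
  expect_equal(P_after,
               P_before * (1 - d) + ps$c_p[["Dr"]] * att_day1 -
                 dsp$E[1] + dsp$I[1],
               tolerance = 1e-10)
})

test_that("a lone aphid population sits at and returns to r/alpha", {
  ls <- star5()
  pl <- placement_1c(ls)
  pr <- point_priors(r = 0.3, alpha = 0.0015, e = 0.1, tau = 1e9)
  web <- build_community("1A")
  Kstar <- 0.3 / 0.0015
  sim <- simulate_metacommunity(web, ls, pl, priors = pr, days = 10,
                                init_aphids = Kstar, draw = FALSE)
  expect_equal(sim$abundance[, 1, "Bb"], rep(Kstar, 11))
  # discrete-logistic stability: nearby states converge for 0 < r < 2
  sim2 <- simulate_metacommunity(web, ls, pl, priors = pr, days = 60,
                                 init_aphids = Kstar * 1.3, draw = FALSE)
  expect_equal(unname(sim2$abundance[61, 1, "Bb"]), Kstar, tolerance = 1e-6)
})

test_that("empty patches stay empty when no species can emigrate", {
  pr <- frozen_priors()
  pr$estimate[pr$parameter == "e"] <- 0
  pr$lower[pr$parameter == "e"] <- 0
  pr$upper[pr$parameter == "e"] <- 0
  ls <- star5()
  sim <- simulate_metacommunity(build_community("3A-2P-1H"), ls,
                                placement_1c(ls), priors = pr, days = 26,
                                draw = FALSE)
  empty <- setdiff(1:5, 1)
  expect_true(all(sim$abundance[, empty, ] == 0))
})

test_that("abundances stay non-negative under randomised parameters", {
  set.seed(7)
  for (i in 1:10) {
    pr <- default_parameter_priors()
    # stretch bounds to push the dynamics around
    pr$upper <- pr$upper * runif(nrow(pr), 1, 3)
    lab <- sample(community_labels(), 1)
    ls <- scale_free_landscape(12, 2, seed = i)
    pl <- select_placement(ls, sample(c(1, 4), 1),
                           sample(c("central", "peripheral"), 1), seed = i)
    # stretched bounds can push fractions past 1: the documented clip warns
    sim <- suppressWarnings(
      simulate_metacommunity(build_community(lab), ls, pl, priors = pr,
                             days = 26, seed = i))
    expect_true(all(sim$abundance >= 0), info = paste("case", i, lab))
  }
})

test_that("the ledger identity holds pre-clip, against independent recomputation", {
  set.seed(3)
  for (i in 1:5) {
    sim <- quick_sim("2A-1P", seed = i)
    ab <- sim$abundance
    led <- sim$ledger
    nd <- dim(ab)[1]
    for (spc in c("Bb", "Le")) {
      delta <- ab[2:nd, , spc] - ab[1:(nd - 1), , spc]
      recon <- led$growth_net[, , spc] - led$parasitism[, , spc] -
        led$emigration[, , spc] + led$immigration[, , spc]
      # identity exact wherever the non-negativity clip did not fire
      pre_clip <- ab[1:(nd - 1), , spc] + recon
      ok <- pre_clip >= 0
      expect_equal(delta[ok], recon[ok], tolerance = 1e-10)
      expect_true(all(ab[2:nd, , spc][!ok] == 0))
    }
  }
})

test_that("replicate parameter draws are uniform within bounds and reproducible", {
  pr <- default_parameter_priors()
  d1 <- draw_replicate_parameters(pr, seed = 99)
  d2 <- draw_replicate_parameters(pr, seed = 99)
  expect_identical(d1$value, d2$value)
  expect_true(all(d1$value >= pr$lower - 1e-12 & d1$value <= pr$upper + 1e-12))
  # degenerate bounds return the point estimate
  expect_equal(d1$value[pr$lower == pr$upper], pr$estimate[pr$lower == pr$upper])
  # uniform-mean check: mean of many draws of r in [0.24, 0.32] is the centre
  draws <- replicate(2000, draw_replicate_parameters(pr[1, ])$value)
  se <- (0.32 - 0.24) / sqrt(12) / sqrt(2000)
  expect_lt(abs(mean(draws) - 0.28), 3 * se)
})

test_that("simulate validates inputs and returns the full trajectory", {
  ls <- star5()
  sim <- quick_sim("1A")
  expect_equal(dim(sim$abundance), c(27, 5, 1))
  expect_equal(unname(sim$abundance[1, 1, "Bb"]), 10)
  expect_equal(sim$abundance[1, 2:5, "Bb"], rep(0, 4))
  # T = 0: initial state only
  sim0 <- quick_sim("1A", days = 0)
  expect_equal(dim(sim0$abundance)[1], 1)
  # placement outside the landscape
  pl_bad <- structure(list(config_label = "1C", populated = 7L,
                           number_factor = 1L, location_factor = "central"),
                      class = "placement")
  expect_error(simulate_metacommunity(build_community("1A"), ls, pl_bad),
               "outside")
  # disconnected landscapes are rejected
  disc <- structure(list(n_patches = 4L,
                         edges = matrix(c(0L, 1L, 2L, 3L), 2, byrow = TRUE),
                         degree = rep(1L, 4), kind = "custom"),
                    class = "patch_landscape")
  expect_error(simulate_metacommunity(build_community("1A"), disc,
                                      placement_1c(disc)), "connected")
})

test_that("decomposition labels populated patches sources and empty ones sinks", {
  sim <- quick_sim("1A", seed = 5)
  dec <- decompose_trajectory(sim)
  focal <- dec[dec$species == "Bb", ]
  expect_equal(focal$role[focal$patch == 0], "source")
  expect_equal(focal$role[focal$patch != 0], rep("sink", 4))
  # component sums equal the ledger totals
  expect_equal(focal$net_emigration, focal$emigration - focal$immigration)
  # no dispersal -> all neutral
  pr <- point_priors(e = 0, tau = 50)
  ls <- star5()
  sim2 <- simulate_metacommunity(build_community("1A"), ls, placement_1c(ls),
                                 priors = pr, days = 10, draw = FALSE)
  dec2 <- decompose_trajectory(sim2)
  expect_true(all(dec2$role == "neutral"))
})

test_that("removing the hyperparasitoid tends to lower focal credit with 2 parasitoids", {
  # Monte-Carlo trend, not a hard per-replicate assert
  ls <- star5()
  pl <- placement_1c(ls)
  diffs <- vapply(1:15, function(s) {
    with_h <- simulate_metacommunity(build_community("1A-2P-1H"), ls, pl,
                                     days = 26, seed = s)
    no_h <- simulate_metacommunity(build_community("1A-2P"), ls, pl,
                                   days = 26, seed = s)
    ch <- summarise_credits(with_h)
    cn <- summarise_credits(no_h)
    ch$credit_ln1p[ch$scale == "metapopulation"] -
      cn$credit_ln1p[cn$scale == "metapopulation"]
  }, 0)
  expect_gt(mean(diffs), 0)
})
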