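# Shared tiny fixtures, built in code at test time.

star5 <- function() star_landscape(4)

placement_1c <- function(ls = star5()) select_placement(ls, 1, "central")

# Minimal single-aphid parameter priors with degenerate bounds, so the point
# dynamics are fully under test control.
point_priors <- function(r = 0.3, alpha = 0.0015, e = 0.1, tau = 50) {
  pr <- default_parameter_priors()
  set1 <- function(sp, par, tg, val) {
    hit <- pr$species == sp & pr$parameter == par &
      (if (is.na(tg)) is.na(pr$target) else !is.na(pr$target) & pr$target == tg)
    pr$estimate[hit] <<- val; pr$lower[hit] <<- val; pr$upper[hit] <<- val
  }
  set1("Bb", "r", NA, r)
  set1("Bb", "alpha", "Bb", alpha)
  set1("Bb", "e", NA, e)
  set1("Bb", "tau", NA, tau)
  pr
}

# Priors table with every row degenerate at its point estimate.
frozen_priors <- function() {
  pr <- default_parameter_priors()
  pr$lower <- pr$estimate
  pr$upper <- pr$estimate
  pr
}

quick_sim <- function(label = "1A", days = 26, seed = 1, ...) {
  ls <- star5()
  simulate_metacommunity(build_community(label), ls, placement_1c(ls),
                         days = days, seed = seed, ...)
}
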