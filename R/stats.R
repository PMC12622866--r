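# Effect decomposition of recovery credits: three-way ANOVA on ln(1+credit),
# per-level marginal-mean predictions with 95% CIs, percent-change effects
# and simple-effect (post hoc) contrasts.

.as_effect_factors <- function(credits) {
  credits$number <- factor(credits$number)
  credits$location <- factor(credits$location)
  credits$community <- factor(credits$community,
                              levels = unique(credits$community))
  credits
}

#' Fit the three-way effects model to a credit table
#'
#' Fits `ln(1+credit) ~ number * location * community` (model `"full"`) or
#' the same model without the three-way interaction (`"no_threeway"`) to the
#' credits of one spatial scale, by ordinary least squares on a balanced
#' factorial. With a 2 x 2 x 3 design the residual df are `60R/12 - 1 - 9`
#' for `no_threeway` and `N - 12` for `full` (50 at 5 replicates, 1188 at
#' 100), matching the ANOVA denominator df of the study design.
#'
#' Per-level predictions are marginal means: the fitted cell means averaged
#' over a balanced grid of the other factors, with t-based 95% CIs.
#'
#' A constant response yields F = 0 for every term; a zero-residual fit with
#' non-zero term sums of squares yields F = Inf (degenerate noiseless input).
#'
#' @param credits Credit table (see [run_factorial()]): needs columns
#'   `number`, `location`, `community`, `scale`, and the response.
#' @param scale Which scale to analyse (default `"metapopulation"`).
#' @param model `"no_threeway"` or `"full"`.
#' @param response Response column (default `"credit_ln1p"`).
#' @param force Analyse an unbalanced table (Type-II sums of squares via
#'   \pkg{car}) instead of refusing.
#' @param anova_only Skip the marginal-mean predictions (faster when only the
#'   F table is needed, e.g. in large null simulations).
#' @return An `effects_fit`: list with `anova` (term, df, F, p), `predictions`
#'   (factor, level, fit, lwr, upr), the underlying `lm` fit and metadata.
#' @export
fit_effects_model <- function(credits, scale = "metapopulation",
                              model = c("no_threeway", "full"),
                              response = "credit_ln1p", force = FALSE,
                              anova_only = FALSE) {
  model <- match.arg(model)
  dat <- credits[credits$scale == scale, , drop = FALSE]
  if (!nrow(dat)) stop("no rows for scale '", scale, "'")
  dat <- .as_effect_factors(dat)
  counts <- table(dat$number, dat$location, dat$community)
  balanced <- length(unique(as.vector(counts))) == 1 && all(counts > 0)
  if (!balanced && !force)
    stop("unbalanced design (unequal cell counts); use force = TRUE for ",
         "Type-II sums of squares")
  dat$.y <- dat[[response]]
  form <- if (model == "full") .y ~ number * location * community
          else .y ~ (number + location + community)^2
  fit <- stats::lm(form, data = dat)
  if (balanced) {
    av <- stats::anova(fit)
    terms <- rownames(av)[rownames(av) != "Residuals"]
    an <- data.frame(term = terms,
                     df_num = av$Df[seq_along(terms)],
                     df_den = av$Df[nrow(av)],
                     ss = av$`Sum Sq`[seq_along(terms)],
                     F = av$`F value`[seq_along(terms)],
                     p = av$`Pr(>F)`[seq_along(terms)],
                     stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("car", quietly = TRUE))
      stop("package 'car' is required for unbalanced (Type-II) analysis")
    av <- car::Anova(fit, type = 2)
    terms <- rownames(av)[rownames(av) != "Residuals"]
    an <- data.frame(term = terms,
                     df_num = av$Df[seq_along(terms)],
                     df_den = av$Df[nrow(av)],
                     ss = av$`Sum Sq`[seq_along(terms)],
                     F = av$`F value`[seq_along(terms)],
                     p = av$`Pr(>F)`[seq_along(terms)],
                     stringsAsFactors = FALSE)
  }
  # degenerate inputs: constant response -> F 0; exact fit -> F Inf
  resid_ss <- sum(stats::residuals(fit)^2)
  if (resid_ss < 1e-12) {
    an$F <- ifelse(an$ss < 1e-12, 0, Inf)
    an$p <- ifelse(an$ss < 1e-12, 1, 0)
  }
  preds <- if (anova_only) NULL else .marginal_means(fit, dat)
  structure(list(anova = an, predictions = preds, fit = fit, model = model,
                 scale = scale, response = response,
                 n = nrow(dat), balanced = balanced),
            class = "effects_fit")
}

# Balanced grid of all factor-level combinations, preserving each factor's
# level order (a character grid would be re-levelled alphabetically by
# model.matrix, permuting the predictions).
.factor_grid <- function(dat, factors) {
  grid <- expand.grid(lapply(dat[factors], function(f)
    factor(levels(f), levels = levels(f))))
  names(grid) <- factors
  grid
}

# Marginal mean of each level of each factor: average of predicted cell means
# over the balanced grid of the remaining factors; CI from x' V x with the
# residual t distribution.
.marginal_means <- function(fit, dat) {
  factors <- c("number", "location", "community")
  grid <- .factor_grid(dat, factors)
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  V <- stats::vcov(fit)
  beta <- stats::coef(fit)
  dfres <- stats::df.residual(fit)
  tq <- stats::qt(0.975, dfres)
  out <- NULL
  for (f in factors) {
    for (lev in levels(dat[[f]])) {
      w <- as.numeric(grid[[f]] == lev)
      w <- w / sum(w)
      x <- drop(crossprod(X, w))          # averaged design row
      m <- sum(x * beta)
      se <- sqrt(drop(t(x) %*% V %*% x))
      out <- rbind(out, data.frame(factor = f, level = lev, fit = m,
                                   se = se, lwr = m - tq * se,
                                   upr = m + tq * se,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.effects_fit <- function(x, ...) {
  cat("<effects_fit>", x$model, "model on", x$scale, "scale,",
      x$n, "observations", if (!x$balanced) "(unbalanced, Type II)", "\n")
  an <- x$anova
  an$F <- signif(an$F, 4); an$p <- signif(an$p, 3); an$ss <- NULL
  print(an, row.names = FALSE)
  invisible(x)
}

#' @export
summary.effects_fit <- function(object, ...) {
  print(object)
  cat("\nMarginal-mean predictions (ln(1+credit) scale):\n")
  pr <- object$predictions
  pr[c("fit", "se", "lwr", "upr")] <- lapply(pr[c("fit", "se", "lwr", "upr")],
                                             signif, 4)
  print(pr, row.names = FALSE)
  invisible(object)
}

#' @export
coef.effects_fit <- function(object, ...) stats::coef(object$fit)

#' Percent change between two predicted factor levels
#'
#' `100 * (m_to - m_from) / m_from` computed on the prediction scale of the
#' fitted model (the ln(1+x) scale by default, matching how average effects
#' are reported); set `back_transform = TRUE` for the raw-credit scale.
#'
#' @param fit An `effects_fit`.
#' @param factor_name One of `"number"`, `"location"`, `"community"`.
#' @param from,to Level names.
#' @param back_transform Compare `expm1(m)` instead of `m`.
#' @return Percent change (negative for a decrease).
#' @export
percent_change <- function(fit, factor_name, from, to, back_transform = FALSE) {
  pr <- fit$predictions
  get <- function(lev) {
    hit <- pr$factor == factor_name & pr$level == lev
    if (!any(hit)) stop("no prediction for ", factor_name, " level '", lev, "'")
    pr$fit[hit]
  }
  m0 <- get(from); m1 <- get(to)
  if (back_transform) { m0 <- expm1(m0); m1 <- expm1(m1) }
  if (m0 == 0) stop("baseline prediction is zero; percent change undefined")
  100 * (m1 - m0) / m0
}

#' Post hoc simple-effect contrasts for a two-factor interaction
#'
#' Contrasts each pair of levels of `factor_a` within every level of
#' `factor_b` (cell means averaged over the remaining factor), with
#' Holm-adjusted p-values across the whole set.
#'
#' @param fit An `effects_fit`.
#' @param factor_a,factor_b Factor names.
#' @return Data frame: `within` (level of `factor_b`), `from`, `to`,
#'   `estimate` (difference on the response scale), `se`, `t`, `p`, `p_adj`.
#' @export
posthoc_interaction <- function(fit, factor_a, factor_b) {
  dat <- fit$fit$model
  factors <- intersect(c("number", "location", "community"), names(dat))
  grid <- .factor_grid(dat, factors)
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)), grid)
  V <- stats::vcov(fit$fit)
  beta <- stats::coef(fit$fit)
  dfres <- stats::df.residual(fit$fit)
  lev_a <- levels(dat[[factor_a]])
  lev_b <- levels(dat[[factor_b]])
  out <- NULL
  for (b in lev_b) {
    for (i in seq_len(length(lev_a) - 1)) for (j in (i + 1):length(lev_a)) {
      w <- as.numeric(grid[[factor_b]] == b & grid[[factor_a]] == lev_a[j]) -
           as.numeric(grid[[factor_b]] == b & grid[[factor_a]] == lev_a[i])
      w <- w / sum(grid[[factor_b]] == b & grid[[factor_a]] == lev_a[j])
      x <- drop(crossprod(X, w))
      est <- sum(x * beta)
      se <- sqrt(drop(t(x) %*% V %*% x))
      tval <- est / se
      out <- rbind(out, data.frame(
        within = b, from = lev_a[i], to = lev_a[j], estimate = est, se = se,
        t = tval, p = 2 * stats::pt(-abs(tval), dfres),
        stringsAsFactors = FALSE))
    }
  }
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Percent change from adding one species to each community
#'
#' For every community in the fitted effects model, finds the catalogue
#' community obtained by adding one aphid (`+A`), one parasitoid (`+P`) or
#' the hyperparasitoid (`+H`), and computes the percent change in the
#' predicted marginal mean between the two. This is the species-addition
#' comparison across the whole complexity lattice.
#'
#' @param fit An `effects_fit` whose `community` factor uses catalogue labels.
#' @return Data frame: `from`, `to`, `type` (`"A"`, `"P"` or `"H"`), `pc`
#'   (percent change from `from` to `to`).
#' @export
community_addition_changes <- function(fit) {
  labs <- fit$predictions$level[fit$predictions$factor == "community"]
  out <- NULL
  for (lab in labs) {
    k <- .parse_label(lab)
    steps <- list(A = k + c(1L, 0L, 0L), P = k + c(0L, 1L, 0L),
                  H = k + c(0L, 0L, 1L))
    for (type in names(steps)) {
      s <- steps[[type]]
      if (s[1] > 3L || s[2] > 2L || s[3] > 1L) next
      if (s[3] == 1L && s[2] == 0L) next
      to <- paste0(s[1], "A",
                   if (s[2] > 0) paste0("-", s[2], "P"),
                   if (s[3] > 0) "-1H")
      if (!to %in% labs) next
      out <- rbind(out, data.frame(
        from = lab, to = to, type = type,
        pc = percent_change(fit, "community", lab, to),
        stringsAsFactors = FALSE))
    }
  }
  out
}
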