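#' Asymptotic confidence interval of the subsample t-statistic
#'
#' Closed-form asymptotic level-`alpha` interval for the t-statistic
#' evaluated by subsamples of sizes `(a, b)`:
#' center `sqrt(a + b) * (mu1 - mu0) / sqrt(sigma1^2 / pi1 + sigma0^2 / pi0)`
#' and half-width `z_{alpha/2} * sqrt(a + b) / sqrt(n)`.  For a mixture
#' disease distribution, the mixture mean and variance are used.  Note the
#' half-width depends only on `(a, b, n, alpha)`, not on the model: two
#' models with equal standardized mean difference have identical intervals,
#' which is exactly why the t-statistic cannot separate calibrated homo and
#' hetero genes.
#'
#' @param model A [two_group_model()].
#' @param a,b Subset sizes.
#' @param n Total sample size.
#' @param alpha Level in (0, 1); default 0.05.
#' @return A one-row tibble (`statistic`, `center`, `half_width`, `lower`,
#'   `upper`, `alpha`, `n`).
#' @export
t_ci <- function(model, a, b, n, alpha = 0.05) {
  check_ci_args(n, alpha)
  mu1 <- dist_mean(model$f1)
  v1 <- dist_var(model$f1)
  mu0 <- dist_mean(model$f0)
  v0 <- dist_var(model$f0)
  center <- sqrt(a + b) * (mu1 - mu0) / sqrt(v1 / model$pi1 + v0 / model$pi0)
  hw <- qnorm(1 - alpha / 2) * sqrt(a + b) / sqrt(n)
  ci_row("subsample_t", center, hw, alpha, n)
}

check_ci_args <- function(n, alpha) {
  if (n < 1) abort("`n` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1).")
}

ci_row <- function(statistic, center, half_width, alpha, n) {
  tibble::tibble(statistic = statistic, center = center,
                 half_width = half_width,
                 lower = center - half_width, upper = center + half_width,
                 alpha = alpha, n = n)
}

# Distributions of V_y and W_y entering the sign-sum asymptotics:
#   V1 = X11 / a                   W1 = -(1/a) sum_{i=2..a} X1i + (1/b) sum_j X0j
#   V0 = -X01 / b                  W0 = -(1/a) sum_i X1i + (1/b) sum_{j=2..b} X0j
# G_y(v) = Pr(W_y <= v); E[U^S] = E[G1(V1)];
# sigma_tilde^2 = (a^2/pi1) Var[G1(V1)] + (b^2/pi0) Var[G0(V0)].
vw_dists <- function(model, a, b) {
  f1 <- model$f1
  f0 <- model$f0
  V1 <- dist_scale(f1, 1 / a)
  W1 <- dist_add(dist_scale(dist_sum(f1, a - 1), -1 / a),
                 dist_scale(dist_sum(f0, b), 1 / b))
  V0 <- dist_scale(f0, -1 / b)
  W0 <- dist_add(dist_scale(dist_sum(f1, a), -1 / a),
                 dist_scale(dist_sum(f0, b - 1), 1 / b))
  list(V1 = V1, W1 = W1, V0 = V0, W0 = W0)
}

# E[G(V)] and Var[G(V)] by adaptive quadrature of the density of V against
# the (normal-mixture) CDF G, over +-10 component standard deviations.
g_moments <- function(G, V, abs_tol = 1e-10) {
  lo <- min(V$mean - 10 * sqrt(V$var))
  hi <- max(V$mean + 10 * sqrt(V$var))
  quad <- function(f) {
    r <- tryCatch(
      integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = abs_tol,
                subdivisions = 400L),
      error = function(e) abort(sprintf(
        "Quadrature failed on [%.4g, %.4g]: %s", lo, hi, conditionMessage(e)))
    )
    if (r$message != "OK") {
      abort(sprintf("Quadrature did not converge on [%.4g, %.4g]: %s",
                    lo, hi, r$message))
    }
    r$value
  }
  e1 <- quad(function(v) dist_pdf(V, v) * dist_cdf(G, v))
  e2 <- quad(function(v) dist_pdf(V, v) * dist_cdf(G, v)^2)
  c(mean = e1, var = max(0, e2 - e1^2))
}

#' Asymptotic moments of the sign-sum statistic
#'
#' Numerically evaluates the limiting mean `E[U^S] = E[G1(V1)]` and the
#' asymptotic variance
#' `sigma_tilde^2 = (a^2 / pi1) Var[G1(V1)] + (b^2 / pi0) Var[G0(V0)]`
#' of the sign-sum statistic under a normal / normal-mixture two-group
#' model.  `G_y` is the CDF of `W_y` (a normal-mixture convolution,
#' available in closed form); the outer expectations are one-dimensional
#' adaptive quadratures with absolute tolerance below 1e-8.
#'
#' @inheritParams t_ci
#' @return Named numeric vector `c(e_us, sigma_tilde_sq)`.
#' @examples
#' m <- two_group_model(dist_normal(1, 1))
#' signsum_moments(m, 1, 1)[["e_us"]]  # pnorm(1 / sqrt(2))
#' @export
signsum_moments <- function(model, a, b) {
  stopifnot(inherits(model, "two_group_model"))
  d <- vw_dists(model, a, b)
  g1 <- g_moments(d$W1, d$V1)
  g0 <- g_moments(d$W0, d$V0)
  c(e_us = unname(g1["mean"]),
    sigma_tilde_sq = unname(a^2 / model$pi1 * g1["var"] +
                              b^2 / model$pi0 * g0["var"]))
}

#' Asymptotic confidence interval of the sign-sum statistic
#'
#' Level-`alpha` interval `E[U^S] +- z_{alpha/2} * sigma_tilde / sqrt(n)`,
#' composing [signsum_moments()].
#'
#' @inheritParams t_ci
#' @return A one-row tibble; see [t_ci()].
#' @export
signsum_ci <- function(model, a, b, n, alpha = 0.05) {
  check_ci_args(n, alpha)
  mom <- signsum_moments(model, a, b)
  hw <- qnorm(1 - alpha / 2) * sqrt(mom[["sigma_tilde_sq"]]) / sqrt(n)
  ci_row("sign_sum", mom[["e_us"]], hw, alpha, n)
}

#' Homo-minus-hetero difference in sign-sum upper confidence limits
#'
#' For two models calibrated to the same asymptotic t (so their subsample-t
#' intervals coincide), returns `UCL_homo - UCL_hetero` of the sign-sum
#' statistic at level `alpha`.  A positive value means the sign-sum
#' statistic separates homo from hetero genes where the t-statistic cannot;
#' the difference grows with `b` at fixed `a = 1` and shrinks as `a` grows.
#'
#' @param homo,hetero [two_group_model()]s for the homo and hetero gene.
#' @inheritParams t_ci
#' @return The scalar UCL difference.
#' @export
ucl_difference <- function(homo, hetero, a, b, n, alpha = 0.05) {
  ci_h <- signsum_ci(homo, a, b, n, alpha)
  ci_t <- signsum_ci(hetero, a, b, n, alpha)
  ci_h$upper - ci_t$upper
}

#' Grid evaluation of sign-sum asymptotics
#'
#' Convenience wrapper for exploring subset sizes: evaluates
#' [signsum_moments()], [signsum_ci()] and (when a calibrated hetero model
#' is supplied) [ucl_difference()] over a grid of `(a, b)`.
#'
#' @param homo A [two_group_model()] (homo gene).
#' @param hetero Optional calibrated hetero [two_group_model()].
#' @param a,b Integer vectors; the grid is their cross product.
#' @inheritParams t_ci
#' @return A tibble with one row per `(a, b)`, columns `e_us`,
#'   `sigma_tilde`, `lower`, `upper` and, if `hetero` is given,
#'   `e_us_hetero`, `upper_hetero`, `ucl_diff`.
#' @export
asymptotics_grid <- function(homo, hetero = NULL, a = 1L, b = c(1L, 5L, 10L),
                             n = 200, alpha = 0.05) {
  grid <- tidyr::expand_grid(a = as.integer(a), b = as.integer(b))
  purrr::pmap_dfr(grid, function(a, b) {
    ci <- signsum_ci(homo, a, b, n, alpha)
    row <- tibble::tibble(a = a, b = b, e_us = ci$center,
                          sigma_tilde = ci$half_width * sqrt(n) /
                            qnorm(1 - alpha / 2),
                          lower = ci$lower, upper = ci$upper)
    if (!is.null(hetero)) {
      ci2 <- signsum_ci(hetero, a, b, n, alpha)
      row$e_us_hetero <- ci2$center
      row$upper_hetero <- ci2$upper
      row$ucl_diff <- ci$upper - ci2$upper
    }
    row
  })
}

#' Plot UCL differences over subset sizes
#'
#' Line chart of the homo-minus-hetero upper-confidence-limit difference
#' against `b`, one line per `a` - the diagnostic that motivates small `a`
#' and larger `b`.
#'
#' @param grid Output of [asymptotics_grid()] including `ucl_diff`.
#' @return A ggplot object.
#' @export
plot_ucl_difference <- function(grid) {
  if (!"ucl_diff" %in% names(grid)) {
    abort("`grid` must come from asymptotics_grid() with a hetero model.")
  }
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$b, y = .data$ucl_diff,
                                     colour = factor(.data$a))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "b (normal subset size)", y = "UCL difference (homo - hetero)",
                  colour = "a") +
    ggplot2::theme_minimal()
}
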