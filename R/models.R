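#' Component distributions for two-group models
#'
#' `dist_normal()` is a normal distribution; `dist_mixture2()` is a
#' two-component normal mixture `tau1 * N(m1, v1_sq) + tau2 * N(m2, v2_sq)`
#' with `tau2 = 1 - tau1`.  These are the expression-level distributions the
#' asymptotic theory and the simulation study work with.
#'
#' @param mean,var Mean and variance (variance > 0).
#' @return A `ss_dist` list.
#' @export
dist_normal <- function(mean = 0, var = 1) {
  if (var <= 0) abort("Variance must be > 0.")
  structure(list(type = "normal", w = 1, mean = mean, var = var),
            class = "ss_dist")
}

#' @rdname dist_normal
#' @param tau1 Mixing proportion of the first component, in (0, 1).
#' @param m1,v1_sq First component mean and variance.
#' @param m2,v2_sq Second component mean and variance.
#' @export
dist_mixture2 <- function(tau1, m1, v1_sq, m2, v2_sq) {
  if (tau1 <= 0 || tau1 >= 1) abort("`tau1` must lie strictly in (0, 1).")
  if (v1_sq <= 0 || v2_sq <= 0) abort("Component variances must be > 0.")
  structure(list(type = "mixture", w = c(tau1, 1 - tau1),
                 mean = c(m1, m2), var = c(v1_sq, v2_sq)),
            class = "ss_dist")
}

#' @export
print.ss_dist <- function(x, ...) {
  if (x$type == "normal") {
    cat(sprintf("N(%.4g, %.4g)\n", x$mean, x$var))
  } else {
    cat(sprintf("%.3g N(%.4g, %.4g) + %.3g N(%.4g, %.4g)\n",
                x$w[1], x$mean[1], x$var[1], x$w[2], x$mean[2], x$var[2]))
  }
  invisible(x)
}

dist_mean <- function(f) sum(f$w * f$mean)

dist_var <- function(f) {
  mu <- dist_mean(f)
  sum(f$w * (f$var + f$mean^2)) - mu^2
}

dist_cdf <- function(f, x) {
  out <- 0
  for (i in seq_along(f$w)) {
    out <- out + f$w[i] * pnorm(x, f$mean[i], sqrt(f$var[i]))
  }
  out
}

dist_pdf <- function(f, x) {
  out <- 0
  for (i in seq_along(f$w)) {
    out <- out + f$w[i] * stats::dnorm(x, f$mean[i], sqrt(f$var[i]))
  }
  out
}

dist_rand <- function(f, n) {
  if (f$type == "normal") return(rnorm(n, f$mean, sqrt(f$var)))
  comp <- rbinom(n, 1, f$w[2]) + 1
  rnorm(n, f$mean[comp], sqrt(f$var[comp]))
}

# Distribution of the sum of k iid draws from f.  For a two-component
# mixture the number of component-2 draws is Binomial(k, tau2), giving an
# exact (k + 1)-component normal mixture - the collapsed form of the 2^k
# component-assignment expansion, valid for every k.
dist_sum <- function(f, k) {
  if (k == 0) return(structure(list(type = "normal", w = 1, mean = 0, var = 0),
                               class = "ss_dist"))
  if (f$type == "normal") return(dist_normal(k * f$mean, k * f$var))
  j <- 0:k
  w <- stats::dbinom(j, k, f$w[2])
  structure(list(type = "mixture",
                 w = w,
                 mean = (k - j) * f$mean[1] + j * f$mean[2],
                 var = (k - j) * f$var[1] + j * f$var[2]),
            class = "ss_dist")
}

# c * X for scalar c != 0
dist_scale <- function(f, c) {
  structure(list(type = f$type, w = f$w, mean = c * f$mean, var = c^2 * f$var),
            class = "ss_dist")
}

# X + Y for independent normal(-mixture) X, Y: cross the components
dist_add <- function(f, g) {
  w <- as.vector(outer(f$w, g$w))
  mean <- as.vector(outer(f$mean, g$mean, `+`))
  var <- as.vector(outer(f$var, g$var, `+`))
  keep <- w > 0
  structure(list(type = if (length(w[keep]) > 1) "mixture" else "normal",
                 w = w[keep], mean = mean[keep], var = var[keep]),
            class = "ss_dist")
}

#' Two-group parametric model
#'
#' Specifies the distributions of gene expression in the disease group
#' (`f1`, normal or two-component normal mixture) and the normal group
#' (`f0`, normal), together with the group sampling ratios `pi1 + pi0 = 1`.
#' Consumed by the asymptotic-interval functions and the simulation
#' calibration.
#'
#' @param f1 Disease-group distribution ([dist_normal()] or
#'   [dist_mixture2()]).
#' @param f0 Normal-group distribution ([dist_normal()]).
#' @param pi1 Disease sampling ratio, in (0, 1).
#' @return A `two_group_model` list with elements `f1`, `f0`, `pi1`, `pi0`.
#' @examples
#' two_group_model(dist_normal(1, 1))
#' @export
two_group_model <- function(f1, f0 = dist_normal(0, 1), pi1 = 0.5) {
  stopifnot(inherits(f1, "ss_dist"), inherits(f0, "ss_dist"))
  if (f0$type != "normal") abort("`f0` must be a plain normal distribution.")
  if (pi1 <= 0 || pi1 >= 1) abort("`pi1` must lie strictly in (0, 1).")
  structure(list(f1 = f1, f0 = f0, pi1 = pi1, pi0 = 1 - pi1),
            class = "two_group_model")
}

#' @export
print.two_group_model <- function(x, ...) {
  cat("<two_group_model>\n  F1 (disease): ")
  print(x$f1)
  cat("  F0 (normal):  ")
  print(x$f0)
  cat(sprintf("  pi1 = %.3g, pi0 = %.3g\n", x$pi1, x$pi0))
  invisible(x)
}

#' Moments of a two-component normal mixture
#'
#' Returns the mean `mu1* = tau1 m1 + tau2 m2` and variance
#' `sigma1*^2 = tau1 (v1^2 + m1^2) + tau2 (v2^2 + m2^2) - mu1*^2` of a
#' mixture distribution - the quantities entering the t-equalization
#' constraint between homo and hetero genes.
#'
#' @param f1 A [dist_mixture2()] (a plain [dist_normal()] returns its own
#'   moments).
#' @return Named numeric vector `c(mean, var)`.
#' @export
mixture_moments <- function(f1) {
  stopifnot(inherits(f1, "ss_dist"))
  c(mean = dist_mean(f1), var = dist_var(f1))
}
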