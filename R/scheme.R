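#' Subsampling scheme for subset-pair statistics
#'
#' Describes how the subset pairs behind [sign_sum()] and [subsample_t()]
#' are evaluated: subset sizes `a` (disease) and `b` (normal), exact
#' enumeration over all `choose(n1, a) * choose(n0, b)` pairs versus Monte
#' Carlo, the Monte-Carlo draw budget, and an optional top-k stability rule
#' that keeps adding draws until the top-k gene set settles.
#'
#' @param a Disease-group subset size (positive integer).
#' @param b Normal-group subset size (positive integer).
#' @param mode `"exact"` (all subset pairs; only allowed while
#'   `choose(n1, a) * choose(n0, b) <= exact_ceiling`) or `"monte_carlo"`.
#' @param n_draws Monte-Carlo subset-pair draws per gene (default 10000).
#'   With `a = 1` the draws are structured: every disease singleton is
#'   enumerated and `ceiling(n_draws / n1)` random normal subsets are drawn
#'   per singleton, which is cheaper and lower-variance than naive pair
#'   draws and unbiased for the same average.
#' @param seed Integer seed.  Per-gene Monte-Carlo streams are derived
#'   deterministically from `(seed, gene index)`, so each gene's score does
#'   not depend on how many genes are scored or in what order.
#' @param exact_ceiling Largest pair count admitted in exact mode
#'   (default 1e7).
#' @param convergence Optional list activating the top-k stability rule:
#'   `k` (top-k size, default 100), `tol` (maximum tolerated top-k
#'   membership changes between successive batches, default 0), `double`
#'   (if `TRUE`, each batch doubles the running draw total; if `FALSE`,
#'   batches of `n_draws / 10` are added), and `max_draws` (cap; default
#'   `10 * n_draws`, or `4 * n_draws` when doubling).
#' @return A `subsample_scheme` list.
#' @export
subsample_scheme <- function(a, b, mode = c("exact", "monte_carlo"),
                             n_draws = 10000L, seed = 1L,
                             exact_ceiling = 1e7, convergence = NULL) {
  mode <- match.arg(mode)
  a <- as.integer(a)
  b <- as.integer(b)
  if (is.na(a) || a < 1L) abort("`a` must be a positive integer.")
  if (is.na(b) || b < 1L) abort("`b` must be a positive integer.")
  if (mode == "monte_carlo" && n_draws < 1) abort("`n_draws` must be >= 1.")
  if (!is.null(convergence)) {
    defaults <- list(k = 100L, tol = 0L, double = FALSE, max_draws = NULL)
    unknown <- setdiff(names(convergence), names(defaults))
    if (length(unknown)) {
      abort(paste0("Unknown convergence field(s): ", paste(unknown, collapse = ", ")))
    }
    convergence <- utils::modifyList(defaults, convergence)
    if (is.null(convergence$max_draws)) {
      convergence$max_draws <- if (isTRUE(convergence$double)) 4 * n_draws else 10 * n_draws
    }
  }
  structure(
    list(a = a, b = b, mode = mode, n_draws = as.integer(n_draws),
         seed = as.integer(seed), exact_ceiling = exact_ceiling,
         convergence = convergence),
    class = "subsample_scheme"
  )
}

#' @export
print.subsample_scheme <- function(x, ...) {
  cat(sprintf("<subsample_scheme> a=%d b=%d mode=%s", x$a, x$b, x$mode))
  if (x$mode == "monte_carlo") cat(sprintf(" n_draws=%d seed=%d", x$n_draws, x$seed))
  if (!is.null(x$convergence)) {
    cat(sprintf(" [top-%d stability, tol=%d]", x$convergence$k, x$convergence$tol))
  }
  cat("\n")
  invisible(x)
}

validate_scheme <- function(scheme, es) {
  n1 <- n_disease(es)
  n0 <- n_normal(es)
  if (scheme$a > n1) {
    abort(sprintf("Subset size a=%d exceeds disease group size n1=%d.", scheme$a, n1))
  }
  if (scheme$b > n0) {
    abort(sprintf("Subset size b=%d exceeds normal group size n0=%d.", scheme$b, n0))
  }
  if (scheme$mode == "exact") {
    npairs <- choose(n1, scheme$a) * choose(n0, scheme$b)
    if (npairs > scheme$exact_ceiling) {
      abort(sprintf(
        paste0("Exact enumeration needs %.3g subset pairs (> ceiling %.3g); ",
               "use mode = \"monte_carlo\"."),
        npairs, scheme$exact_ceiling))
    }
  }
  invisible(scheme)
}
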