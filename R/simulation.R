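#' Solve the hetero-gene calibration constraint
#'
#' Finds the shifted-component mean `m2` of the hetero mixture
#' `tau1 N(mu0, sigma0^2) + tau2 N(m2, sigma0^2)` such that the asymptotic
#' Welch t of the hetero gene equals that of the homo gene
#' `N(mu1, sigma1^2)`:
#' `(mu1 - mu0) / sqrt(sigma1^2/pi1 + sigma0^2/pi0) =
#'  (mu1* - mu0) / sqrt(sigma1*^2/pi1 + sigma0^2/pi0)`.
#' This makes the t-statistic blind to the homo/hetero difference by
#' construction; the positive root is returned in closed form and verified
#' by back-substitution (residual <= 1e-10).
#'
#' @param sigma1_sq Homo-gene disease variance.
#' @param tau1 Mixing proportion of the normal-like component, in (0, 1).
#' @param pi1,pi0 Group sampling ratios (default 0.5 / 0.5).
#' @param mu1,mu0 Homo disease mean (default 1) and normal mean (default 0).
#' @param sigma0_sq Normal-group variance (default 1), also used for both
#'   mixture components.
#' @return The positive solution `m2`.
#' @examples
#' solve_hetero_mean(1, 0.5)   # 2 * sqrt(2)
#' solve_hetero_mean(4, 0.75)  # 4
#' @export
solve_hetero_mean <- function(sigma1_sq, tau1, pi1 = 0.5, pi0 = 0.5,
                              mu1 = 1, mu0 = 0, sigma0_sq = 1) {
  if (tau1 <= 0 || tau1 >= 1) abort("`tau1` must lie strictly in (0, 1).")
  if (sigma1_sq <= 0 || sigma0_sq <= 0) abort("Variances must be > 0.")
  tau2 <- 1 - tau1
  cc <- (mu1 - mu0) / sqrt(sigma1_sq / pi1 + sigma0_sq / pi0)
  num <- cc^2 * (sigma0_sq / pi1 + sigma0_sq / pi0)
  den <- tau2^2 - cc^2 * tau1 * tau2 / pi1
  if (den <= 0) {
    abort(sprintf(
      paste0("No positive m2 solves the calibration for sigma1_sq=%g, tau1=%g, ",
             "pi1=%g: the mixture cannot reach the homo gene's asymptotic t."),
      sigma1_sq, tau1, pi1))
  }
  m2 <- mu0 + sqrt(num / den)
  resid <- abs(cc - calibration_rhs(m2, tau1, pi1, pi0, mu0, sigma0_sq))
  stopifnot(resid <= 1e-10)
  m2
}

calibration_rhs <- function(m2, tau1, pi1, pi0, mu0, sigma0_sq) {
  f1 <- dist_mixture2(tau1, mu0, sigma0_sq, m2, sigma0_sq)
  (dist_mean(f1) - mu0) / sqrt(dist_var(f1) / pi1 + sigma0_sq / pi0)
}

#' Simulation situation parameters
#'
#' The three calibrated situations of the simulation study:
#' I `sigma1^2 = 1, tau1 = 0.5` (half the disease group normal-like);
#' II `sigma1^2 = 1, tau1 = 0.25` (small normal-like minority, weak shift
#' `m2 ~ 1.46`); III `sigma1^2 = 4, tau1 = 0.75` (large normal-like
#' majority, strong shift `m2 = 4`, homo variance inflated to match).
#'
#' @param situation `"I"`, `"II"` or `"III"`.
#' @return List with `sigma1_sq` and `tau1`.
#' @export
situation_params <- function(situation) {
  switch(as.character(situation),
         I = list(sigma1_sq = 1, tau1 = 0.5),
         II = list(sigma1_sq = 1, tau1 = 0.25),
         III = list(sigma1_sq = 4, tau1 = 0.75),
         abort(sprintf("Unknown situation '%s' (use I, II or III).", situation)))
}

#' Calibrated homo / hetero models for a situation
#'
#' Builds the homo model `N(1, sigma1^2)` vs `N(0, 1)` and the calibrated
#' hetero model `tau1 N(0,1) + tau2 N(m2, 1)` vs `N(0, 1)` sharing the same
#' asymptotic Welch t.
#'
#' @inheritParams situation_params
#' @param pi1 Disease sampling ratio.
#' @return List with [two_group_model()]s `homo` and `hetero` plus `m2`.
#' @export
situation_models <- function(situation, pi1 = 0.5) {
  par <- situation_params(situation)
  m2 <- solve_hetero_mean(par$sigma1_sq, par$tau1, pi1 = pi1, pi0 = 1 - pi1)
  list(
    homo = two_group_model(dist_normal(1, par$sigma1_sq), pi1 = pi1),
    hetero = two_group_model(dist_mixture2(par$tau1, 0, 1, m2, 1), pi1 = pi1),
    m2 = m2
  )
}

#' Configuration of the calibrated simulation study
#'
#' Defaults mirror the study conditions: 1000 genes (100 homo + 100 hetero +
#' 800 null), equal group sizes, 100 replicates, top-100 ranking depth, and
#' the statistic panel `t`, `t_1,1`, `s_1,1`, `s_1,5`, `s_1,10`.
#'
#' @param situation `"I"`, `"II"`, `"III"`, or `NULL` when `sigma1_sq` and
#'   `tau1` are given explicitly.
#' @param n Total sample size, split equally (`n0 = n1 = n / 2`).
#' @param p_homo,p_hetero,p_null Gene counts per class.
#' @param n_reps Number of replicates.
#' @param k_top Ranking depth for the homo-gene count.
#' @param statistics Character vector of statistic labels: `"t"` (full-data
#'   Welch t), `"t_a,b"` (subsample t), `"s_a,b"` (sign-sum).
#' @param master_seed Integer master seed; replicate `r` uses a
#'   deterministic substream so it is reproducible in isolation.
#' @param sigma1_sq,tau1 Explicit situation parameters (override
#'   `situation`).
#' @param mc_draws Total Monte-Carlo subset pairs per gene for subsampled
#'   statistics.  Default `max(50, ceiling(20000 / n1)) * n1`: about 20,000
#'   pairs spread over the enumerated disease singletons (200 per singleton
#'   at `n1 = 100`), with a floor of 50 per singleton for large groups.
#' @param stability Top-k stability rule for Monte-Carlo statistics: draws
#'   are doubled (up to 4x `mc_draws`) until top-`k_top` membership changes
#'   at most `stability` genes between doublings.  `NULL` disables.
#' @return A `simulation_config` list (includes the solved `m2`).
#' @export
simulation_config <- function(situation = "I", n = 200,
                              p_homo = 100, p_hetero = 100, p_null = 800,
                              n_reps = 100, k_top = 100,
                              statistics = c("t", "t_1,1", "s_1,1", "s_1,5", "s_1,10"),
                              master_seed = 1, sigma1_sq = NULL, tau1 = NULL,
                              mc_draws = NULL, stability = 2L) {
  if (is.null(sigma1_sq) || is.null(tau1)) {
    par <- situation_params(situation)
    sigma1_sq <- par$sigma1_sq
    tau1 <- par$tau1
  } else {
    situation <- "custom"
  }
  if (n %% 2 != 0) abort("`n` must be even (equal group sizes).")
  n1 <- n %/% 2
  n0 <- n - n1
  if (min(p_homo, p_hetero, p_null) < 0 || p_homo + p_hetero + p_null < 1) {
    abort("Gene counts must be nonnegative with at least one gene.")
  }
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  m2 <- if (p_hetero > 0) {
    solve_hetero_mean(sigma1_sq, tau1, pi1 = n1 / n, pi0 = n0 / n)
  } else NA_real_
  if (is.null(mc_draws)) mc_draws <- max(50, ceiling(20000 / n1)) * n1
  structure(
    list(situation = situation, sigma1_sq = sigma1_sq, tau1 = tau1, m2 = m2,
         n = n, n0 = n0, n1 = n1,
         p_homo = p_homo, p_hetero = p_hetero, p_null = p_null,
         n_reps = as.integer(n_reps), k_top = as.integer(k_top),
         statistics = statistics, master_seed = as.integer(master_seed),
         mc_draws = as.integer(mc_draws),
         stability = if (is.null(stability)) NULL else as.integer(stability)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> situation %s (sigma1^2=%g, tau1=%g, m2=%.5g)\n",
    x$situation, x$sigma1_sq, x$tau1, x$m2))
  cat(sprintf("  %d+%d+%d genes (homo+hetero+null), n=%d (n0=n1=%d), %d reps\n",
              x$p_homo, x$p_hetero, x$p_null, x$n, x$n1, x$n_reps))
  cat(sprintf("  statistics: %s; seed %d\n",
              paste(x$statistics, collapse = ", "), x$master_seed))
  invisible(x)
}

# Deterministic 31-bit substream seed for replicate r (and statistic s).
substream_seed <- function(master_seed, rep_index, stat_index = 0L) {
  s <- (as.double(master_seed) %% 2147483647) * 2654435761 +
    as.double(rep_index) * 97003 + as.double(stat_index) * 7919
  as.integer(s %% 2147483629) + 1L
}

#' Parse statistic labels
#'
#' Turns labels like `"t"`, `"t_1,1"`, `"s_1,10"` into a specification
#' table (`label`, `type`, `a`, `b`).
#'
#' @param labels Character vector.
#' @return A tibble.
#' @export
parse_statistics <- function(labels) {
  purrr::map_dfr(labels, function(lab) {
    if (lab == "t") {
      return(tibble::tibble(label = lab, type = "welch_t",
                            a = NA_integer_, b = NA_integer_))
    }
    m <- regmatches(lab, regexec("^([ts])_([0-9]+),([0-9]+)$", lab))[[1]]
    if (length(m) != 4) {
      abort(sprintf("Unknown statistic '%s' (expected 't', 't_a,b' or 's_a,b').", lab))
    }
    tibble::tibble(
      label = lab,
      type = if (m[2] == "t") "subsample_t" else "sign_sum",
      a = as.integer(m[3]), b = as.integer(m[4])
    )
  })
}

#' Generate one calibrated replicate dataset
#'
#' Normal-group entries are `N(0, 1)` for every gene; disease-group entries
#' are `N(1, sigma1^2)` for homo genes, `tau1 N(0,1) + tau2 N(m2, 1)` for
#' hetero genes (with `m2` solved from the calibration constraint) and
#' `N(0, 1)` for null genes.
#'
#' @param config A [simulation_config()].
#' @param rep_index Replicate number (1-based); seeds the substream.
#' @return A `labeled_dataset`: list with the [expr_set()] (`es`),
#'   `gene_class` (factor homo/hetero/null) and the realized `m2`.
#' @export
generate_dataset <- function(config, rep_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$master_seed, rep_index))
  p <- config$p_homo + config$p_hetero + config$p_null
  n0 <- config$n0
  n1 <- config$n1
  gene_class <- factor(
    rep(c("homo", "hetero", "null"),
        times = c(config$p_homo, config$p_hetero, config$p_null)),
    levels = c("homo", "hetero", "null"))
  gene_ids <- sprintf("g%0*d", nchar(p), seq_len(p))
  x0 <- matrix(rnorm(p * n0), p, n0)
  x1 <- matrix(rnorm(p * n1), p, n1)  # null baseline N(0, 1)
  if (config$p_homo > 0) {
    rows <- which(gene_class == "homo")
    x1[rows, ] <- matrix(rnorm(length(rows) * n1, mean = 1,
                               sd = sqrt(config$sigma1_sq)),
                         length(rows), n1)
  }
  if (config$p_hetero > 0) {
    rows <- which(gene_class == "hetero")
    k <- length(rows) * n1
    comp2 <- stats::runif(k) >= config$tau1
    x1[rows, ] <- matrix(rnorm(k, mean = ifelse(comp2, config$m2, 0), sd = 1),
                         length(rows), n1)
  }
  values <- cbind(x0, x1)
  colnames(values) <- c(paste0("n", seq_len(n0)), paste0("d", seq_len(n1)))
  es <- expr_set(values, group = rep(c(0L, 1L), c(n0, n1)), gene_ids = gene_ids)
  structure(list(es = es, gene_class = gene_class, m2 = config$m2),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %s; classes: %s\n",
              format(x$es)[1],
              paste(sprintf("%s=%d", levels(x$gene_class),
                            tabulate(x$gene_class)), collapse = ", ")))
  invisible(x)
}

# Score an expr_set with one parsed statistic row, choosing exact
# enumeration when the full pair set is small enough (sign-sum only;
# subsample t stays Monte Carlo so it reflects subset noise the way the
# study's t_{1,1} column does).
score_statistic <- function(es, spec, seed, mc_draws = 20000L,
                            stability = NULL, k_top = 100L) {
  if (spec$type == "welch_t") return(suppressWarnings(welch_t(es)))
  n1 <- n_disease(es)
  n0 <- n_normal(es)
  npairs <- choose(n1, spec$a) * choose(n0, spec$b)
  exact_ok <- spec$type == "sign_sum" && npairs <= 1e6
  conv <- if (!is.null(stability)) {
    list(k = k_top, tol = stability, double = TRUE)
  } else NULL
  scheme <- if (exact_ok) {
    subsample_scheme(spec$a, spec$b, mode = "exact")
  } else {
    subsample_scheme(spec$a, spec$b, mode = "monte_carlo",
                     n_draws = mc_draws, seed = seed, convergence = conv)
  }
  fn <- if (spec$type == "sign_sum") sign_sum else subsample_t
  suppressWarnings(fn(es, scheme))
}

#' Run the calibrated homo/hetero simulation study
#'
#' For each replicate: generate a calibrated dataset, score all genes with
#' every requested statistic, rank signed scores descending (the simulated
#' effects are nonnegative by construction) and count homo genes in the top
#' `k_top`.  Heterogeneity robustness is summarized as the mean (sd) of
#' that count over replicates.
#'
#' @param config A [simulation_config()].
#' @return A `signsum_sim` object: list with `summary` (per-statistic mean
#'   and sd), `counts` (per replicate x statistic), and `config`.  Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
run_simulation_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  specs <- parse_statistics(config$statistics)
  counts <- purrr::map_dfr(seq_len(config$n_reps), function(r) {
    ds <- generate_dataset(config, r)
    homo_ids <- ds$es$gene_ids[ds$gene_class == "homo"]
    purrr::map_dfr(seq_len(nrow(specs)), function(si) {
      spec <- specs[si, ]
      seed <- substream_seed(config$master_seed, r, si)
      st <- score_statistic(ds$es, spec, seed, mc_draws = config$mc_draws,
                            stability = config$stability,
                            k_top = config$k_top)
      ranked <- rank_genes(st, orientation = "signed")
      tibble::tibble(
        rep = r, statistic = spec$label,
        homo_in_top_k = sum(top_genes(ranked, config$k_top) %in% homo_ids))
    })
  })
  summary <- counts |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(mean = mean(.data$homo_in_top_k),
                     sd = sd(.data$homo_in_top_k), .groups = "drop") |>
    dplyr::arrange(match(.data$statistic, config$statistics))
  structure(list(summary = summary, counts = counts, config = config),
            class = "signsum_sim")
}

#' @export
print.signsum_sim <- function(x, ...) {
  cat(sprintf("<signsum_sim> situation %s, n=%d, %d reps; homo genes in top %d:\n",
              x$config$situation, x$config$n, x$config$n_reps, x$config$k_top))
  print(format_simulation_table(x))
  invisible(x)
}

#' @rdname run_simulation_study
#' @param x A `signsum_sim` object.
#' @param ... Unused.
#' @export
tidy.signsum_sim <- function(x, ...) x$summary

#' @rdname run_simulation_study
#' @export
glance.signsum_sim <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(situation = cfg$situation, sigma1_sq = cfg$sigma1_sq,
                 tau1 = cfg$tau1, m2 = cfg$m2, n = cfg$n,
                 p = cfg$p_homo + cfg$p_hetero + cfg$p_null,
                 n_reps = cfg$n_reps, k_top = cfg$k_top,
                 master_seed = cfg$master_seed)
}

#' One-row "mean (sd)" table of a simulation study
#'
#' @param result A `signsum_sim`.
#' @return A one-row tibble, one column per statistic, entries
#'   `"mean (sd)"`.
#' @export
format_simulation_table <- function(result) {
  s <- result$summary
  wide <- setNames(sprintf("%.1f (%.2f)", s$mean, s$sd), s$statistic)
  dplyr::bind_cols(tibble::tibble(situation = result$config$situation,
                                  n = result$config$n),
                   tibble::as_tibble(as.list(wide)))
}

#' @rdname run_simulation_study
#' @param object A `signsum_sim` object.
#' @export
autoplot.signsum_sim <- function(object, ...) {
  df <- object$counts
  df$statistic <- factor(df$statistic, levels = object$config$statistics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic,
                                   y = .data$homo_in_top_k)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL,
                  y = sprintf("homo genes in top %d", object$config$k_top)) +
    ggplot2::theme_minimal()
}
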