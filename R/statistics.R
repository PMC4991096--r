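#' Welch t-statistic per gene
#'
#' The two-sample t-statistic `T_j = sqrt(n) * (mean1_j - mean0_j) / s_j`
#' with the Welch (non-pooled) denominator
#' `s_j = sqrt(s1_j^2 / pihat1 + s0_j^2 / pihat0)`, `pihat_y = n_y / n`.
#' Scores are signed; no absolute value is taken.
#'
#' Genes whose denominator is zero (zero sample variance in both groups)
#' are flagged `degenerate = TRUE` with an `NA` score and a warning, rather
#' than silently returning infinities; [rank_genes()] places them last.
#'
#' @param es An [expr_set()] with at least two samples per group.
#' @return A tibble (`score_table`) with columns `gene_id`, `statistic`,
#'   `score`, `mc_stderr` (all `NA` here), `full_t` (equal to `score`) and
#'   `degenerate`.
#' @examples
#' es <- expr_set(rbind(g1 = c(0, 2, 3, 5)), group = c(0, 0, 1, 1))
#' welch_t(es)$score  # ~2.1213
#' @export
welch_t <- function(es) {
  n1 <- n_disease(es)
  n0 <- n_normal(es)
  if (n1 < 2L || n0 < 2L) {
    abort("Welch t needs at least 2 samples per group (sample variances).")
  }
  n <- n0 + n1
  x1 <- disease_values(es)
  x0 <- normal_values(es)
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  s <- sqrt(v1 / (n1 / n) + v0 / (n0 / n))
  degenerate <- s == 0
  score <- ifelse(degenerate, NA_real_, sqrt(n) * (m1 - m0) / s)
  if (any(degenerate)) {
    warn(sprintf("%d gene(s) have zero variance in both groups; Welch t flagged degenerate.",
                 sum(degenerate)))
  }
  new_score_table(es$gene_ids, "welch_t", score, mc_stderr = NA_real_,
                  full_t = score, degenerate = degenerate, scheme = NULL)
}

new_score_table <- function(gene_ids, statistic, score, mc_stderr, full_t,
                            degenerate, scheme) {
  out <- tibble::tibble(
    gene_id = gene_ids,
    statistic = statistic,
    score = unname(score),
    mc_stderr = unname(mc_stderr),
    full_t = unname(full_t),
    degenerate = unname(degenerate)
  )
  attr(out, "scheme") <- scheme
  class(out) <- c("score_table", class(out))
  out
}

welch_denominator <- function(es) {
  x1 <- disease_values(es)
  x0 <- normal_values(es)
  n1 <- ncol(x1)
  n0 <- ncol(x0)
  n <- n0 + n1
  v1 <- rowSums((x1 - rowMeans(x1))^2) / (n1 - 1)
  v0 <- rowSums((x0 - rowMeans(x0))^2) / (n0 - 1)
  sqrt(v1 / (n1 / n) + v0 / (n0 / n))
}

#' Sign-sum statistic per gene
#'
#' For subset sizes `a` (disease) and `b` (normal), the sign-sum statistic
#' of gene `j` is the average of `H(mean1_jl - mean0_jm)` over subset pairs
#' `(l, m)`, where `H` is the Heaviside step with `H(0) = 1`.  It counts how
#' stably the disease subset mean exceeds the normal subset mean, lies in
#' `[0, 1]`, and for `a = b = 1` reduces to the Mann-Whitney proportion of
#' (disease, normal) sample pairs with disease >= normal.
#'
#' Exact mode averages over all `choose(n1, a) * choose(n0, b)` pairs.
#' Monte-Carlo mode averages over random pairs (structured over disease
#' singletons when `a = 1`) and reports a per-gene Monte-Carlo standard
#' error, conditional on the data, in `mc_stderr`.
#'
#' @param es An [expr_set()].
#' @param scheme A [subsample_scheme()].
#' @return A `score_table` tibble; see [welch_t()] for columns.
#' @examples
#' es <- expr_set(rbind(g1 = c(0, 1, 2, 1, 3)), group = c(0, 0, 0, 1, 1))
#' sign_sum(es, subsample_scheme(a = 2, b = 2, mode = "exact"))$score  # 1
#' @export
sign_sum <- function(es, scheme) {
  score_subset_statistic(es, scheme, "sign_sum")
}

#' Subsample t-statistic per gene
#'
#' The t-statistic evaluated by subsamples: the average over subset pairs of
#' `sqrt(a + b) * (mean1_jl - mean0_jm) / s_j`, with `s_j` the full-sample
#' Welch denominator of [welch_t()].  In exact mode the average of all
#' subset means equals the full group mean, so the exact statistic is the
#' scalar multiple `sqrt((a + b) / n)` of Welch t and ranks genes
#' identically.
#'
#' @inheritParams sign_sum
#' @return A `score_table` tibble.
#' @export
subsample_t <- function(es, scheme) {
  score_subset_statistic(es, scheme, "subsample_t")
}

score_subset_statistic <- function(es, scheme, statistic) {
  stopifnot(inherits(scheme, "subsample_scheme"))
  validate_scheme(scheme, es)
  full_t <- NULL
  s_denom <- NULL
  if (statistic == "subsample_t") {
    tt <- suppressWarnings(welch_t(es))
    full_t <- tt$score
    s_denom <- welch_denominator(es)
  }
  if (scheme$mode == "exact") {
    res <- exact_subset_pairs(es, scheme)
  } else {
    res <- mc_subset_pairs(es, scheme, statistic, s_denom)
  }
  if (statistic == "sign_sum") {
    score <- res$prop
    mc_stderr <- res$prop_se
    degenerate <- rep(FALSE, length(score))
    if (is.null(full_t)) {
      full_t <- suppressWarnings(welch_t(es))$score
    }
  } else {
    degenerate <- s_denom == 0
    if (any(degenerate)) {
      warn(sprintf("%d gene(s) have zero Welch denominator; subsample t flagged degenerate.",
                   sum(degenerate)))
    }
    score <- ifelse(degenerate, NA_real_,
                    sqrt(scheme$a + scheme$b) * res$meandiff / s_denom)
    mc_stderr <- if (all(is.na(res$meandiff_se))) {
      rep(NA_real_, length(score))
    } else {
      ifelse(degenerate, NA_real_,
             sqrt(scheme$a + scheme$b) * res$meandiff_se / s_denom)
    }
  }
  new_score_table(es$gene_ids, statistic, score, mc_stderr, full_t,
                  degenerate, scheme)
}

subset_mean_matrix <- function(x, size) {
  n <- ncol(x)
  idx <- combn(n, size)
  k <- ncol(idx)
  ind <- matrix(0, n, k)
  ind[cbind(as.vector(idx), rep(seq_len(k), each = size))] <- 1
  x %*% ind / size
}

exact_subset_pairs <- function(es, scheme) {
  m1 <- subset_mean_matrix(disease_values(es), scheme$a)
  m0 <- subset_mean_matrix(normal_values(es), scheme$b)
  res <- cpp_exact_pairs(m1, m0)
  npairs <- ncol(m1) * ncol(m0)
  list(prop = res$counts / npairs,
       prop_se = rep(NA_real_, nrow(m1)),
       meandiff = res$meandiff,
       meandiff_se = rep(NA_real_, nrow(m1)),
       npairs = npairs)
}

# Monte-Carlo evaluation with optional top-k stability batching.  State is
# accumulated across batches; batch index feeds the per-gene RNG stream so
# every batch adds independent draws.  The stability rule ranks by the
# statistic actually being computed (sign-sum proportion, or mean subset
# difference over the Welch denominator for the subsample t).
mc_subset_pairs <- function(es, scheme, statistic = "sign_sum",
                            s_denom = NULL) {
  x1t <- t(disease_values(es))  # samples x genes: gene columns contiguous
  x0t <- t(normal_values(es))
  n1 <- nrow(x1t)
  p <- ncol(x1t)
  singleton <- scheme$a == 1L
  conv <- scheme$convergence

  state <- NULL
  draws_total <- 0L
  batch <- 0L
  add_batch <- function(ndraws) {
    if (singleton) {
      B <- max(1L, as.integer(ceiling(ndraws / n1)))
      res <- cpp_singleton_mc(x1t, x0t, scheme$b, B, scheme$seed, batch)
      got <- B * n1
    } else {
      res <- cpp_pair_mc(x1t, x0t, scheme$a, scheme$b, as.integer(ndraws),
                         scheme$seed, batch)
      got <- ndraws
    }
    if (is.null(state)) {
      state <<- res
    } else {
      state$counts <<- state$counts + res$counts
      state$sumdiff <<- state$sumdiff + res$sumdiff
      state$sumsq <<- state$sumsq + res$sumsq
    }
    draws_total <<- draws_total + got
    batch <<- batch + 1L
  }

  summarise_state <- function() {
    if (singleton) {
      B <- draws_total / n1
      prop_i <- state$counts / B
      prop <- rowMeans(prop_i)
      prop_se <- if (B > 1) {
        sqrt(rowSums(prop_i * (1 - prop_i)) / (B - 1)) / n1
      } else rep(NA_real_, p)
      md_i <- state$sumdiff / B
      meandiff <- rowMeans(md_i)
      md_se <- if (B > 1) {
        var_i <- (state$sumsq - state$sumdiff^2 / B) / (B - 1)
        sqrt(rowSums(var_i) / B) / n1
      } else rep(NA_real_, p)
    } else {
      nd <- draws_total
      prop <- state$counts / nd
      prop_se <- if (nd > 1) sqrt(prop * (1 - prop) / (nd - 1)) else rep(NA_real_, p)
      meandiff <- state$sumdiff / nd
      md_se <- if (nd > 1) {
        sqrt((state$sumsq / nd - meandiff^2) / (nd - 1))
      } else rep(NA_real_, p)
    }
    list(prop = prop, prop_se = prop_se, meandiff = meandiff,
         meandiff_se = md_se, npairs = draws_total)
  }

  add_batch(scheme$n_draws)
  if (!is.null(conv)) {
    k <- min(conv$k, p)
    topk <- function() {
      s <- summarise_state()
      key <- if (statistic == "sign_sum") {
        s$prop
      } else {
        ifelse(s_denom > 0, s$meandiff / s_denom, -Inf)
      }
      head(order(-key, es$gene_ids), k)
    }
    prev <- topk()
    repeat {
      step <- if (isTRUE(conv$double)) draws_total else max(1L, scheme$n_draws %/% 10L)
      if (draws_total + step > conv$max_draws) break
      add_batch(step)
      cur <- topk()
      changed <- length(setdiff(cur, prev))
      prev <- cur
      if (changed <= conv$tol) break
    }
  }
  summarise_state()
}

#' Rank genes by a score table
#'
#' Sorts genes by descending score.  With `orientation = "signed"` the raw
#' scores are used (appropriate when effect directions are known, as in the
#' calibrated simulations).  With `orientation = "oriented_by_full_t"` each
#' gene is first reflected so that its full-data Welch mean difference is
#' nonnegative: t-type scores of sign-negative genes are negated and
#' sign-sum scores are mapped to `1 - score`, which equals re-scoring the
#' negated gene row except on exact ties.
#'
#' Ties are broken deterministically: descending score, then descending
#' absolute full-data Welch t, then lexicographic gene id.  Degenerate genes
#' rank last.
#'
#' @param scores A `score_table` from [welch_t()], [sign_sum()] or
#'   [subsample_t()].
#' @param orientation `"signed"` or `"oriented_by_full_t"`.
#' @return The table sorted with a `rank` column prepended to the score
#'   columns; `score` holds the ranking key actually used.
#' @export
rank_genes <- function(scores, orientation = c("signed", "oriented_by_full_t")) {
  orientation <- match.arg(orientation)
  key <- scores$score
  if (orientation == "oriented_by_full_t") {
    flip <- !is.na(scores$full_t) & scores$full_t < 0
    key <- ifelse(flip,
                  if (scores$statistic[1] == "sign_sum") 1 - key else -key,
                  key)
  }
  tie <- abs(scores$full_t)
  tie[is.na(tie)] <- -Inf
  key_na <- key
  key_na[is.na(key_na)] <- -Inf
  ord <- order(-key_na, -tie, scores$gene_id)
  out <- scores[ord, ]
  out$score <- key[ord]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("gene_id", "statistic", "score", "mc_stderr", "full_t",
                 "degenerate", "rank")]
  attr(out, "scheme") <- attr(scores, "scheme")
  class(out) <- c("score_table", class(tibble::tibble()))
  out
}

#' Top-k gene ids of a ranking
#'
#' @param ranked A ranked `score_table` from [rank_genes()].
#' @param k Number of genes.
#' @return Character vector of the first `k` gene ids.
#' @export
top_genes <- function(ranked, k) {
  head(ranked$gene_id, k)
}

#' Plot the score profile of a ranking
#'
#' Scores against gene index (ranked order), the standard diagnostic for
#' how sharply a statistic separates informative from uninformative genes.
#'
#' @param object A `score_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_table <- function(object, ...) {
  df <- tibble::tibble(
    index = seq_len(nrow(object)),
    score = sort(object$score, decreasing = TRUE, na.last = TRUE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$score)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "gene (ranked)", y = unique(object$statistic)) +
    ggplot2::theme_minimal()
}
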