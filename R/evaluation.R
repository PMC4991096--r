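#' Stratified split of an expression set into halves
#'
#' Randomly divides the samples into two halves while maintaining the
#' disease/normal ratio: each group is permuted and cut in two, with the
#' extra sample of an odd-sized group going to the first half.  The halves
#' are disjoint and exhaustive.
#'
#' @param es An [expr_set()] with at least 4 samples per group (so Welch
#'   variances exist in each half).
#' @param trial_seed Integer seed; the same seed reproduces the same split.
#' @return List of two `expr_set`s, `half1` and `half2`.
#' @export
split_data <- function(es, trial_seed = 1L) {
  n1 <- n_disease(es)
  n0 <- n_normal(es)
  if (n1 < 4L || n0 < 4L) {
    abort("Each group needs >= 4 samples to split into Welch-scorable halves.")
  }
  set.seed(as.integer(trial_seed))
  idx1 <- sample(which(es$group == 1L))
  idx0 <- sample(which(es$group == 0L))
  take1 <- ceiling(n1 / 2)
  take0 <- ceiling(n0 / 2)
  h1 <- sort(c(idx1[seq_len(take1)], idx0[seq_len(take0)]))
  h2 <- sort(c(idx1[-seq_len(take1)], idx0[-seq_len(take0)]))
  list(half1 = subset_samples(es, h1), half2 = subset_samples(es, h2))
}

#' Top-k overlap between two rankings
#'
#' @param ranking1,ranking2 Ranked tables from [rank_genes()] (or plain
#'   character vectors of gene ids in rank order).
#' @param k Top-list size.
#' @return Number of genes shared by the two top-k sets.
#' @export
topk_overlap <- function(ranking1, ranking2, k) {
  ids1 <- if (is.character(ranking1)) ranking1 else ranking1$gene_id
  ids2 <- if (is.character(ranking2)) ranking2 else ranking2$gene_id
  length(intersect(head(ids1, k), head(ids2, k)))
}

#' Overlap ratio to random selection (ORRS)
#'
#' Mean top-k overlap across trials divided by the expected overlap of two
#' random k-selections out of p genes, `N_{p,k} = k^2 / p` (the mean of the
#' hypergeometric overlap count).  ORRS = 1 means no better than random;
#' identical rankings every trial give `p / k`.
#'
#' @param overlaps Integer vector of per-trial overlap counts.
#' @param p Total number of genes.
#' @param k Top-list size (`1 <= k <= p`).
#' @return The ORRS value.
#' @export
orrs <- function(overlaps, p, k) {
  if (k < 1 || k > p) abort("Need 1 <= k <= p.")
  mean(overlaps) / (k^2 / p)
}

#' Split-half reproducibility plan
#'
#' @param n_trials Number of random splits (default 100).
#' @param k_top Top-list size (default 100).
#' @param master_seed Integer master seed; trial `t` draws its split from a
#'   deterministic substream.
#' @return A `repro_plan` list.
#' @export
reproducibility_plan <- function(n_trials = 100L, k_top = 100L,
                                 master_seed = 1L) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  structure(list(n_trials = as.integer(n_trials), k_top = as.integer(k_top),
                 master_seed = as.integer(master_seed)),
            class = "repro_plan")
}

#' Split-half ranking reproducibility
#'
#' For each trial the data are split into stratified halves; each half is
#' oriented by its own full-half Welch t signs (so overlap compares gene
#' identities, not effect directions), scored with every requested
#' statistic, and ranked.  The top-`k_top` overlap between the halves is
#' recorded, and summarized as mean, sd, and ORRS.  Optionally, a DLDA
#' classifier built on half 1's top genes is scored on half 2 by AUC.
#'
#' @param es An [expr_set()].
#' @param statistics Character vector of statistic labels (see
#'   [parse_statistics()]).
#' @param plan A [reproducibility_plan()].
#' @param dlda_top Optional integer vector of top-gene counts (e.g.
#'   `c(10, 50, 100)`) activating the DLDA/AUC check.
#' @param mc_draws Monte-Carlo subset-pair budget per gene for subsampled
#'   statistics; default scales as in [simulation_config()] from the
#'   smaller half's disease-group size.
#' @return A `signsum_repro` object: list with `summary` (per statistic:
#'   `mean_overlap`, `sd_overlap`, `orrs_mean`, `orrs_sd`, `n_pk`),
#'   `overlaps` (per trial), `auc` (per trial, if requested) and the plan.
#'   `sd` columns are `NA` for a single-trial plan.
#' @export
run_reproducibility <- function(es, statistics, plan = reproducibility_plan(),
                                dlda_top = NULL, mc_draws = NULL) {
  stopifnot(inherits(plan, "repro_plan"))
  specs <- parse_statistics(statistics)
  p <- nrow(es$values)
  if (plan$k_top > p) abort("`k_top` exceeds the number of genes.")
  n1_half <- floor(n_disease(es) / 2)
  if (is.null(mc_draws)) mc_draws <- max(50, ceiling(20000 / n1_half)) * n1_half
  n_pk <- plan$k_top^2 / p

  one_trial <- function(tr) {
    halves <- split_data(es, substream_seed(plan$master_seed, tr))
    oriented <- lapply(halves, orient_by_full_t)
    rows <- list()
    auc_rows <- list()
    for (si in seq_len(nrow(specs))) {
      spec <- specs[si, ]
      seed1 <- substream_seed(plan$master_seed, tr, 2L * si)
      seed2 <- substream_seed(plan$master_seed, tr, 2L * si + 1L)
      r1 <- rank_genes(score_statistic(oriented$half1, spec, seed1,
                                       mc_draws = mc_draws,
                                       k_top = plan$k_top), "signed")
      r2 <- rank_genes(score_statistic(oriented$half2, spec, seed2,
                                       mc_draws = mc_draws,
                                       k_top = plan$k_top), "signed")
      rows[[si]] <- tibble::tibble(
        trial = tr, statistic = spec$label,
        overlap = topk_overlap(r1, r2, plan$k_top))
      if (!is.null(dlda_top)) {
        auc_rows[[si]] <- purrr::map_dfr(dlda_top, function(k) {
          genes <- top_genes(r1, k)
          fit <- dlda_fit(halves$half1, genes)
          scores <- predict(fit, halves$half2)
          tibble::tibble(trial = tr, statistic = spec$label, n_genes = k,
                         auc = auc(scores, halves$half2$group))
        })
      }
    }
    list(overlap = dplyr::bind_rows(rows), auc = dplyr::bind_rows(auc_rows))
  }

  trials <- purrr::map(seq_len(plan$n_trials), one_trial)
  overlaps <- purrr::map_dfr(trials, "overlap")
  auc_tbl <- purrr::map_dfr(trials, "auc")
  sd_or_na <- function(x) if (length(x) > 1) sd(x) else NA_real_
  summary <- overlaps |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      mean_overlap = mean(.data$overlap),
      sd_overlap = sd_or_na(.data$overlap),
      orrs_mean = mean(.data$overlap / n_pk),
      orrs_sd = sd_or_na(.data$overlap / n_pk),
      .groups = "drop") |>
    dplyr::mutate(n_pk = n_pk) |>
    dplyr::arrange(match(.data$statistic, statistics))
  structure(list(summary = summary, overlaps = overlaps,
                 auc = if (nrow(auc_tbl)) auc_tbl else NULL, plan = plan,
                 p = p),
            class = "signsum_repro")
}

#' @export
print.signsum_repro <- function(x, ...) {
  cat(sprintf("<signsum_repro> %d trials, top-%d (N_pk = %.3g):\n",
              x$plan$n_trials, x$plan$k_top, x$summary$n_pk[1]))
  print(x$summary)
  if (!is.null(x$auc)) {
    cat("DLDA test AUC (mean over trials):\n")
    print(tidy_auc(x))
  }
  invisible(x)
}

tidy_auc <- function(x) {
  x$auc |>
    dplyr::group_by(.data$statistic, .data$n_genes) |>
    dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
                     .groups = "drop")
}

#' @rdname run_reproducibility
#' @param x,object A `signsum_repro` object.
#' @param ... Unused.
#' @export
tidy.signsum_repro <- function(x, ...) x$summary

#' @rdname run_reproducibility
#' @export
glance.signsum_repro <- function(x, ...) {
  tibble::tibble(n_trials = x$plan$n_trials, k_top = x$plan$k_top,
                 p = x$p, n_pk = x$summary$n_pk[1],
                 master_seed = x$plan$master_seed)
}

#' @rdname run_reproducibility
#' @export
autoplot.signsum_repro <- function(object, ...) {
  df <- object$overlaps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$overlap)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = object$summary$n_pk[1],
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = sprintf("top-%d overlap", object$plan$k_top),
                  caption = "dashed line: expected overlap of random selection") +
    ggplot2::theme_minimal()
}

#' Diagonal linear discriminant analysis
#'
#' Fits the DLDA rule on a gene subset: per-gene group centroids with a
#' pooled (diagonal) within-group variance.  The discriminant score of a
#' sample `x` is `sum_j [(x_j - c0_j)^2 - (x_j - c1_j)^2] / s_j^2`; larger
#' scores favor the disease group.  Genes with zero pooled variance are
#' excluded with a warning.
#'
#' @param train An [expr_set()] containing both groups.
#' @param gene_subset Character vector of gene ids to use.
#' @return A `dlda` model object.
#' @export
dlda_fit <- function(train, gene_subset) {
  if (!length(gene_subset)) abort("`gene_subset` must be non-empty.")
  missing <- setdiff(gene_subset, train$gene_ids)
  if (length(missing)) {
    abort(paste0("Genes not in training set: ", paste(head(missing, 5), collapse = ", ")))
  }
  n1 <- n_disease(train)
  n0 <- n_normal(train)
  if (n1 < 2L || n0 < 2L) abort("DLDA needs >= 2 samples per group.")
  x1 <- disease_values(train)[gene_subset, , drop = FALSE]
  x0 <- normal_values(train)[gene_subset, , drop = FALSE]
  c1 <- rowMeans(x1)
  c0 <- rowMeans(x0)
  v1 <- rowSums((x1 - c1)^2)
  v0 <- rowSums((x0 - c0)^2)
  pooled <- (v1 + v0) / (n1 + n0 - 2)
  bad <- pooled == 0
  if (any(bad)) {
    warn(sprintf("%d gene(s) with zero pooled variance excluded from DLDA.", sum(bad)))
    if (all(bad)) abort("All genes have zero pooled variance.")
    c1 <- c1[!bad]; c0 <- c0[!bad]; pooled <- pooled[!bad]
    gene_subset <- gene_subset[!bad]
  }
  structure(list(genes = gene_subset, centroid1 = c1, centroid0 = c0,
                 pooled_var = pooled),
            class = "dlda")
}

#' @export
print.dlda <- function(x, ...) {
  cat(sprintf("<dlda> %d genes\n", length(x$genes)))
  invisible(x)
}

#' Predict DLDA discriminant scores
#'
#' @param object A `dlda` model.
#' @param newdata An [expr_set()] or a genes-by-samples matrix with the
#'   model's genes present in its rownames.
#' @param ... Unused.
#' @return Numeric vector of per-sample discriminant scores (larger =
#'   more disease-like).
#' @export
predict.dlda <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "expr_set")) newdata$values else newdata
  missing <- setdiff(object$genes, rownames(m))
  if (length(missing)) {
    abort(paste0("Genes missing from newdata: ", paste(head(missing, 5), collapse = ", ")))
  }
  x <- m[object$genes, , drop = FALSE]
  colSums(((x - object$centroid0)^2 - (x - object$centroid1)^2) /
            object$pooled_var)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the proportion of (disease, normal) score pairs in
#' which the disease sample scores higher, with tied pairs counted 0.5.
#'
#' @param scores Numeric scores (larger = more disease-like).
#' @param labels Binary labels (0 = normal, 1 = disease).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("Labels must be 0/1.")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("Both groups must be present.")
  r <- rank(scores)  # midranks handle ties as 0.5 per pair
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
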