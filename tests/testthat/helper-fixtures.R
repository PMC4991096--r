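# Seeded fixtures built in code; no data files.

random_es <- function(p = 20, n0 = 6, n1 = 6, seed = 1, effect = 0,
                      integer_valued = FALSE) {
  set.seed(seed)
  x0 <- matrix(rnorm(p * n0), p, n0)
  x1 <- matrix(rnorm(p * n1, mean = effect), p, n1)
  v <- cbind(x0, x1)
  if (integer_valued) v <- round(v)
  colnames(v) <- paste0("s", seq_len(n0 + n1))
  expr_set(v, rep(c(0L, 1L), c(n0, n1)))
}

one_gene_es <- function(normal, disease) {
  expr_set(rbind(g1 = c(normal, disease)),
           rep(c(0L, 1L), c(length(normal), length(disease))))
}

# Brute-force oracle for the a = b = 1 sign-sum: proportion of
# (disease, normal) sample pairs with disease >= normal.
pair_sign_proportion <- function(normal, disease) {
  mean(outer(disease, normal, `>=`))
}

# Brute-force oracle for the exact sign-sum at general (a, b):
# enumerate all subset pairs directly.
enum_sign_sum <- function(normal, disease, a, b) {
  m1 <- combn(disease, a, mean)
  m0 <- combn(normal, b, mean)
  mean(outer(m1, m0, `-`) >= 0)
}

# Draw from a two-group model's disease (y = 1) or normal (y = 0) side.
draw_group <- function(model, y, n) {
  f <- if (y == 1) model$f1 else model$f0
  if (f$type == "normal") return(rnorm(n, f$mean, sqrt(f$var)))
  comp <- rbinom(n, 1, f$w[2]) + 1
  rnorm(n, f$mean[comp], sqrt(f$var[comp]))
}

# Monte-Carlo oracle for E[U^S] under a model: H(mean of a disease draws -
# mean of b normal draws), n_draws independent replicates.  Returns the
# estimate and its standard error.
mc_signsum_mean <- function(model, a, b, n_draws) {
  x1 <- rowMeans(matrix(draw_group(model, 1, n_draws * a), n_draws, a))
  x0 <- rowMeans(matrix(draw_group(model, 0, n_draws * b), n_draws, b))
  h <- as.numeric(x1 - x0 >= 0)
  c(mean = mean(h), se = sd(h) / sqrt(n_draws))
}

write_expression_fixture <- function(dir = NULL, delim = "\t") {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  es <- random_es(p = 3, n0 = 2, n1 = 2, seed = 7, effect = 1)
  ext <- if (delim == "\t") "tsv" else "csv"
  path <- file.path(dir, paste0("expr.", ext))
  labels <- file.path(dir, "labels.tsv")
  write_expression(es, path, labels, delim = delim)
  list(es = es, path = path, labels = labels)
}
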