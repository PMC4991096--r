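#' Read a delimited expression matrix with group labels
#'
#' Expression input is delimited text (tab by default, comma accepted):
#' first column gene id, remaining columns samples, one header row of sample
#' names.  Labels are a two-column delimited file mapping `sample_id` to
#' 0 (normal) / 1 (disease); row order is irrelevant, matching is by name.
#'
#' @param path Path to the expression table.
#' @param labels_path Path to the label table.
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @return A validated [expr_set()].
#' @export
read_expression <- function(path, labels_path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("Expression file not found: ", path))
  if (!file.exists(labels_path)) abort(paste0("Label file not found: ", labels_path))
  if (is.null(delim)) delim <- sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(tbl) < 2) abort("Expression table needs a gene-id column plus sample columns.")
  gene_ids <- as.character(tbl[[1]])
  vals <- tbl[, -1, drop = FALSE]
  for (nm in names(vals)) {
    col <- vals[[nm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        abort(sprintf("Non-numeric expression value '%s' at gene '%s', sample '%s'.",
                      col[bad[1]], gene_ids[bad[1]], nm))
      }
      vals[[nm]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  labels <- read_labels(labels_path)
  expr_set(m, labels, gene_ids)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_labels <- function(path) {
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (ncol(raw) < 2) abort("Label file needs two columns: sample_id, label.")
  # drop a header row if the second field is not a 0/1 label
  if (!raw[[2]][1] %in% c("0", "1")) raw <- raw[-1, , drop = FALSE]
  lab <- suppressWarnings(as.integer(raw[[2]]))
  bad <- which(is.na(lab) | !lab %in% c(0L, 1L))
  if (length(bad)) {
    abort(sprintf("Label for sample '%s' is '%s'; must be 0 or 1.",
                  raw[[1]][bad[1]], raw[[2]][bad[1]]))
  }
  data.frame(sample_id = as.character(raw[[1]]), label = lab,
             stringsAsFactors = FALSE)
}

#' Write an expression set to delimited text
#'
#' Inverse of [read_expression()]: writes the expression table (gene_id
#' column + one column per sample) and the two-column label table.
#'
#' @param es An [expr_set()].
#' @param path,labels_path Output paths.
#' @param delim Field delimiter (default tab).
#' @return `es`, invisibly.
#' @export
write_expression <- function(es, path, labels_path, delim = "\t") {
  samples <- colnames(es$values)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(es$values)))
  tbl <- tibble::as_tibble(es$values, .name_repair = ~samples)
  tbl <- dplyr::bind_cols(tibble::tibble(gene_id = es$gene_ids), tbl)
  readr::write_delim(tbl, path, delim = delim)
  readr::write_delim(
    tibble::tibble(sample_id = samples, label = es$group),
    labels_path, delim = delim
  )
  invisible(es)
}

#' Write a score table as TSV
#'
#' Columns: gene_id, statistic, score, mc_stderr, rank (rank present only if
#' the table came from [rank_genes()]).
#'
#' @param scores A score table from [welch_t()], [sign_sum()],
#'   [subsample_t()] or [rank_genes()].
#' @param path Output path.
#' @return `scores`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  keep <- intersect(c("gene_id", "statistic", "score", "mc_stderr", "rank"),
                    names(scores))
  readr::write_tsv(scores[, keep], path)
  invisible(scores)
}

#' Read / write a run configuration
#'
#' Run configurations are plain YAML mappings mirroring the command-line
#' options (statistics with their subset sizes, Monte-Carlo settings, seeds,
#' paths).  `read_run_config()` and `write_run_config()` round-trip a config
#' losslessly.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config A named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(config)
}
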