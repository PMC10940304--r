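#' Construct an FPKM expression matrix
#'
#' @param values Numeric matrix (genes x samples), non-negative.
#' @param genes,samples Row/column identifiers (defaults to dimnames).
#' @param transformed Has log2(FPKM + 1) already been applied?
#' @return An `fpkm_matrix` object.
#' @export
fpkm_matrix <- function(values, genes = rownames(values),
                        samples = colnames(values), transformed = FALSE) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("FPKM values must be non-negative")
  if (is.null(genes) || is.null(samples)) stop("genes and samples required")
  stopifnot(nrow(values) == length(genes), ncol(values) == length(samples))
  dimnames(values) <- list(genes, samples)
  structure(list(genes = genes, samples = samples, values = values,
                 transformed = transformed), class = "fpkm_matrix")
}

#' Read an FPKM TSV (gene_id column + one column per sample)
#'
#' @param path TSV path.
#' @return An untransformed `fpkm_matrix`.
#' @export
read_fpkm <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (names(tab)[1L] != "gene_id") stop("first column must be gene_id")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vals) <- tab$gene_id
  fpkm_matrix(vals)
}

#' log2(FPKM + 1) transform
#'
#' @param m An untransformed `fpkm_matrix`.
#' @return The transformed matrix (flag set); transforming twice is an
#'   error.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "fpkm_matrix"))
  if (m$transformed) stop("matrix is already log2(FPKM + 1) transformed")
  m$values <- log2(m$values + 1)
  m$transformed <- TRUE
  m
}

#' Drop genes with low mean expression
#'
#' Genes whose arithmetic mean FPKM across all samples is strictly less
#' than `threshold` are discarded (a mean exactly at the threshold is
#' kept). Must run on raw FPKM, before [log_transform()].
#'
#' @param m An untransformed `fpkm_matrix`.
#' @param threshold Mean-FPKM cutoff (default 1, the "mean expression of
#'   less than 1 FPKM" rule).
#' @return `list(kept = fpkm_matrix, dropped_ids = character)`.
#' @export
filter_low_expression <- function(m, threshold = 1.0) {
  stopifnot(inherits(m, "fpkm_matrix"))
  if (m$transformed) stop("filter on raw FPKM, before the log transform")
  means <- rowMeans(m$values)
  drop <- means < threshold
  kept <- fpkm_matrix(m$values[!drop, , drop = FALSE],
                      genes = m$genes[!drop], samples = m$samples)
  list(kept = kept, dropped_ids = m$genes[drop])
}

#' Summarize a differential-expression table
#'
#' Significant rows (`fdr < fdr_cutoff`, strict) are split into up
#' (`log2fc > 0`) and down (`log2fc < 0`) per tissue/condition pair; a
#' significant row with log2fc exactly 0 counts in neither direction and
#' is reported in `attr(, "n_zero")`.
#'
#' @param det Data frame with columns `gene_id`, `tissue`,
#'   `condition_pair`, `log2fc`, `fdr`.
#' @param fdr_cutoff Significance cutoff on FDR (default 0.05).
#' @return Data frame `tissue`, `condition_pair`, `n_up`, `n_down`,
#'   `up_genes`, `down_genes` (comma-separated lists).
#' @export
de_summary <- function(det, fdr_cutoff = 0.05) {
  need <- c("gene_id", "tissue", "condition_pair", "log2fc", "fdr")
  stopifnot(all(need %in% names(det)))
  if (any(det$fdr < 0 | det$fdr > 1)) stop("fdr values must lie in [0, 1]")
  key <- unique(det[, c("tissue", "condition_pair"), drop = FALSE])
  n_zero <- 0L
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- det[det$tissue == key$tissue[i] &
                 det$condition_pair == key$condition_pair[i], , drop = FALSE]
    sig <- sel[sel$fdr < fdr_cutoff, , drop = FALSE]
    up <- sig$gene_id[sig$log2fc > 0]
    down <- sig$gene_id[sig$log2fc < 0]
    n_zero <<- n_zero + sum(sig$log2fc == 0)
    data.frame(tissue = key$tissue[i], condition_pair = key$condition_pair[i],
               n_up = length(up), n_down = length(down),
               up_genes = paste(sort(up), collapse = ","),
               down_genes = paste(sort(down), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tissue = character(0), condition_pair = character(0),
               n_up = integer(0), n_down = integer(0),
               up_genes = character(0), down_genes = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_zero") <- n_zero
  out
}

#' Stage/tissue specificity of expression
#'
#' Computed on raw FPKM (documented choice): for each gene, the score is
#' the largest group mean divided by the sum of group means, so a
#' uniformly expressed gene scores `1/n_groups` and a single-stage gene
#' scores 1. The argmax group is the first maximal group (deterministic).
#'
#' @param m An untransformed `fpkm_matrix`.
#' @param groups Factor/character of length `n_samples` mapping samples to
#'   groups; defaults to one group per sample.
#' @return Data frame `gene_id`, `top_group`, `specificity`; genes with
#'   zero total expression get `NA` score and are flagged in
#'   `attr(, "undefined_ids")`.
#' @export
stage_specificity <- function(m, groups = NULL) {
  stopifnot(inherits(m, "fpkm_matrix"))
  if (m$transformed) stop("specificity is computed on raw FPKM")
  if (is.null(groups)) groups <- m$samples
  stopifnot(length(groups) == length(m$samples))
  glev <- unique(as.character(groups))
  gm <- sapply(glev, function(g) {
    rowMeans(m$values[, groups == g, drop = FALSE])
  })
  gm <- matrix(gm, nrow = length(m$genes), dimnames = list(m$genes, glev))
  tot <- rowSums(gm)
  top <- glev[apply(gm, 1L, which.max)]
  score <- ifelse(tot > 0, apply(gm, 1L, max) / tot, NA_real_)
  out <- data.frame(gene_id = m$genes, top_group = top,
                    specificity = unname(score), stringsAsFactors = FALSE)
  attr(out, "undefined_ids") <- m$genes[tot == 0]
  out
}

#' Row order for an expression heatmap table
#'
#' Complete-linkage hierarchical clustering of the transformed rows under
#' correlation distance (1 - Pearson r); constant rows, for which the
#' correlation is undefined, are placed after the clustered rows in input
#' order.
#'
#' @param m A transformed `fpkm_matrix`.
#' @return Character vector of gene ids in display order.
#' @export
cluster_order <- function(m) {
  stopifnot(inherits(m, "fpkm_matrix"))
  if (!m$transformed) stop("cluster the log2(FPKM + 1) matrix")
  v <- m$values
  sds <- apply(v, 1L, stats::sd)
  variable <- sds > 0
  ordered <- m$genes[!variable]
  if (sum(variable) >= 2L) {
    cv <- v[variable, , drop = FALSE]
    d <- as.dist(1 - cor(t(cv)))
    hc <- hclust(d, method = "complete")
    ordered <- c(rownames(cv)[hc$order], ordered)
  } else {
    ordered <- c(m$genes[variable], ordered)
  }
  ordered
}
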