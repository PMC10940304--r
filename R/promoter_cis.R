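.IUPAC_CHARS <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Load a cis-regulatory motif table
#'
#' The package bundles a curated default table of IUPAC consensus strings
#' for the promoter elements commonly reported in plant stress/hormone
#' analyses (ABRE, AuxRR, TGA, CGTCA, GARE, P-box, TATC-box, TCA, SARE,
#' DRE, MBS, LTR, TC-rich repeats). The table is data, not code: scanning a
#' real genome with a different element definition simply means supplying a
#' different TSV, and counts are always relative to the table used.
#'
#' @param path TSV with columns `motif_id`, `consensus`, `stimulus`;
#'   `NULL` loads the bundled default.
#' @return Validated data frame of motifs.
#' @export
motif_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "plant_cis_motifs.tsv", package = "zfscan")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("motif_id", "consensus", "stimulus")
  if (!all(need %in% names(tab))) {
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$motif_id)) {
    stop("duplicate motif_id: ", tab$motif_id[duplicated(tab$motif_id)][1L])
  }
  tab$consensus <- toupper(tab$consensus)
  bad <- vapply(strsplit(tab$consensus, ""),
                function(ch) any(!ch %in% .IUPAC_CHARS), logical(1))
  if (any(bad)) stop("non-IUPAC consensus for motif ", tab$motif_id[bad][1L])
  if (any(!nzchar(tab$stimulus))) stop("empty stimulus in motif table")
  tab
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.is_palindromic <- function(consensus) identical(.revcomp(consensus), consensus)

#' Extract the upstream promoter region of a gene
#'
#' For a plus-strand gene, the `length` bases ending immediately before the
#' gene's 5'-most coordinate; for a minus-strand gene, the bases
#' immediately after its file-coordinate end, reverse-complemented. The
#' result is always 5' to 3' relative to transcription. Promoters are
#' truncated (flagged, not an error) at contig edges. This is the single
#' place where 1-based inclusive annotation coordinates are converted to
#' sequence slices.
#'
#' @param genome Nucleotide sequence table from [read_fasta()].
#' @param gene A `gene_model`.
#' @param length Promoter length in bp (default 2000, the 2-kb convention).
#' @return One-row sequence table; `attr(, "truncated")` flags a promoter
#'   shorter than requested and `attr(, "gene_id")` carries the gene.
#' @export
extract_upstream <- function(genome, gene, length = 2000L) {
  chrom <- genome$residues[match(gene$chromosome, genome$id)]
  if (is.na(chrom)) stop("chromosome ", gene$chromosome, " not in genome")
  clen <- nchar(chrom)
  if (gene$strand == "+") {
    from <- max(1L, gene$start - length)
    to <- gene$start - 1L
    seq <- if (to < from) "" else substr(chrom, from, to)
  } else {
    from <- gene$end + 1L
    to <- min(clen, gene$end + length)
    seq <- if (to < from) "" else .revcomp(substr(chrom, from, to))
  }
  out <- data.frame(id = paste0(gene$gene_id, "_promoter"),
                    description = "", residues = seq,
                    stringsAsFactors = FALSE)
  attr(out, "gene_id") <- gene$gene_id
  attr(out, "truncated") <- nchar(seq) < length
  out
}

.greedy_nonoverlap <- function(starts, ends) {
  keep <- logical(length(starts))
  ord <- order(starts)
  last_end <- -Inf
  for (i in ord) {
    if (starts[i] > last_end) { keep[i] <- TRUE; last_end <- ends[i] }
  }
  keep
}

#' Scan a promoter for cis-element motif occurrences
#'
#' IUPAC consensus matching on both strands via degenerate pattern
#' matching; occurrences are leftmost-greedy non-overlapping per motif and
#' strand (antisense occurrences are made non-overlapping in antisense
#' orientation). A palindromic consensus is scanned on the sense strand
#' only, so a site is never double-counted as its own reverse complement.
#'
#' @param promoter One-row sequence table from [extract_upstream()] or a
#'   nucleotide string.
#' @param motifs Motif table from [motif_table()].
#' @param gene_id Gene to report in the hits; defaults to the promoter's
#'   `gene_id` attribute.
#' @return Data frame `gene_id`, `motif_id`, `offset` (0-based from the
#'   promoter 5' end), `strand` (`sense`/`antisense`).
#' @export
scan_motifs <- function(promoter, motifs, gene_id = NULL) {
  if (is.data.frame(promoter)) {
    if (is.null(gene_id)) gene_id <- attr(promoter, "gene_id")
    promoter <- promoter$residues[1L]
  }
  if (is.null(gene_id)) gene_id <- "promoter"
  L <- nchar(promoter)
  empty <- data.frame(gene_id = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (L == 0L) return(empty)
  subj <- Biostrings::DNAString(promoter)
  rsubj <- Biostrings::reverseComplement(subj)
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[i]
    w <- nchar(cons)
    if (w > L) next
    pat <- Biostrings::DNAString(cons)
    m <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
    st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
    if (length(st)) {
      keep <- .greedy_nonoverlap(st, en)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, motif_id = motifs$motif_id[i],
        offset = st[keep] - 1L, strand = "sense", stringsAsFactors = FALSE)
    }
    if (!.is_palindromic(cons)) {
      mr <- Biostrings::matchPattern(pat, rsubj, fixed = FALSE)
      st <- BiocGenerics::start(mr); en <- BiocGenerics::end(mr)
      if (length(st)) {
        keep <- .greedy_nonoverlap(st, en)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, motif_id = motifs$motif_id[i],
          offset = L - en[keep],   # 0-based sense-strand start
          strand = "antisense", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$motif_id, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene, per-stimulus cis-element count matrix
#'
#' @param hits Hit table from [scan_motifs()] (rows for several genes may
#'   be concatenated).
#' @param motifs Motif table mapping motif ids to stimuli.
#' @param gene_ids Genes to report (keeps zero rows for genes without
#'   hits); defaults to the genes present in `hits`.
#' @return Data frame, one row per gene: `gene_id`, one count column per
#'   stimulus (in motif-table order), and `total`.
#' @export
element_count_matrix <- function(hits, motifs, gene_ids = NULL) {
  unknown <- setdiff(hits$motif_id, motifs$motif_id)
  if (length(unknown)) stop("unknown motif_id in hits: ", unknown[1L])
  if (is.null(gene_ids)) gene_ids <- sort(unique(hits$gene_id))
  stimuli <- unique(motifs$stimulus)
  mat <- matrix(0L, nrow = length(gene_ids), ncol = length(stimuli),
                dimnames = list(gene_ids, stimuli))
  if (nrow(hits)) {
    stim <- motifs$stimulus[match(hits$motif_id, motifs$motif_id)]
    tab <- table(factor(hits$gene_id, levels = gene_ids),
                 factor(stim, levels = stimuli))
    mat <- mat + unclass(tab)
  }
  out <- data.frame(gene_id = gene_ids, mat, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$total <- as.integer(rowSums(mat))
  out[order(out$gene_id), , drop = FALSE]
}
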