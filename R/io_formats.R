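#' Read a FASTA file into a sequence table
#'
#' Reads a (possibly multi-line) FASTA file and returns one row per record,
#' validated against the declared alphabet. Sequences are uppercased and
#' whitespace is stripped; record order follows the file.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param alphabet Either `"protein"` (ACDEFGHIKLMNPQRSTVWY + X) or
#'   `"nucleotide"` (ACGT + N).
#' @return A `data.frame` with columns `id`, `description`, `residues`, and
#'   the alphabet stored in `attr(, "alphabet")`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  residues <- toupper(gsub("\\s", "", as.character(set)))
  allowed <- if (alphabet == "protein") .PROTEIN_ALPHABET else .NUCLEOTIDE_ALPHABET
  for (i in seq_along(residues)) {
    if (!nzchar(residues[i])) stop("empty sequence for id ", ids[i])
    chars <- strsplit(residues[i], "")[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad)) {
      stop(sprintf("illegal %s character '%s' at position %d in record '%s'",
                   alphabet, chars[bad[1L]], bad[1L], ids[i]))
    }
  }
  out <- data.frame(id = ids, description = desc, residues = residues,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a sequence table to FASTA
#'
#' @param seqs A `data.frame` with columns `id`, `residues` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for the sequence body.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- seqs$id[i]
    if (!is.null(seqs$description) && nzchar(seqs$description[i])) {
      hdr <- paste(hdr, seqs$description[i])
    }
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", seqs$residues[i])
    cat(">", hdr, "\n", body, sep = "", file = con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features linked by ID/Parent attributes into a
#' list of gene models. Coordinates are kept 1-based inclusive as in GFF3;
#' conversion to 0-based half-open happens only at the sequence-slicing
#' boundary (see [extract_upstream()]).
#'
#' @param path Path to a GFF3 file.
#' @return A named list of `gene_model` objects, each a list with
#'   `gene_id`, `chromosome`, `strand`, `start`, `end`, and `transcripts`
#'   (a named list of `list(transcript_id, exons, cds)` with `exons`/`cds`
#'   data frames of `start`/`end`).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(gr$Parent, function(p) {
    if (length(p)) as.character(p[1L]) else NA_character_
  }, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss <- df[df$type == "CDS", , drop = FALSE]
  orphan <- mrnas$Parent[is.na(mrnas$Parent) | !mrnas$Parent %in% genes$ID]
  if (length(orphan)) {
    stop("orphan mRNA (Parent gene missing): ",
         mrnas$ID[is.na(mrnas$Parent) | !mrnas$Parent %in% genes$ID][1L])
  }
  out <- vector("list", nrow(genes))
  names(out) <- genes$ID
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gm <- mrnas[mrnas$Parent == g$ID, , drop = FALSE]
    transcripts <- vector("list", nrow(gm))
    names(transcripts) <- gm$ID
    for (j in seq_len(nrow(gm))) {
      tid <- gm$ID[j]
      ex <- exons[exons$Parent == tid, c("start", "end"), drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      rownames(ex) <- NULL
      if (nrow(ex) && (min(ex$start) < g$start || max(ex$end) > g$end)) {
        stop("exon outside gene span for transcript ", tid)
      }
      cd <- cdss[cdss$Parent == tid, c("start", "end"), drop = FALSE]
      cd <- cd[order(cd$start), , drop = FALSE]
      rownames(cd) <- NULL
      for (k in seq_len(nrow(cd))) {
        inside <- any(cd$start[k] >= ex$start & cd$end[k] <= ex$end)
        if (!inside) stop("CDS interval outside exons for transcript ", tid)
      }
      transcripts[[j]] <- list(transcript_id = tid, exons = ex, cds = cd)
    }
    out[[i]] <- structure(
      list(gene_id = g$ID, chromosome = as.character(g$seqnames),
           strand = as.character(g$strand), start = g$start, end = g$end,
           transcripts = transcripts),
      class = "gene_model")
  }
  out
}

#' Select the longest protein isoform of a gene
#'
#' Mirrors the family-identification convention that each gene is
#' represented by its longest encoded protein. Ties are broken by the
#' lexicographically smaller transcript id, so the choice is a pure function
#' of lengths and ids.
#'
#' @param gene A `gene_model` from [read_gff3()].
#' @param proteins A sequence table ([read_fasta()]) whose ids are
#'   transcript ids.
#' @return The selected one-row protein record, with the winning transcript
#'   id in `attr(, "transcript_id")`.
#' @export
select_longest_isoform <- function(gene, proteins) {
  tids <- names(gene$transcripts)
  missing <- setdiff(tids, proteins$id)
  if (length(missing)) {
    stop("no protein record for transcript ", missing[1L],
         " of gene ", gene$gene_id)
  }
  rows <- proteins[match(tids, proteins$id), , drop = FALSE]
  len <- nchar(rows$residues)
  ord <- order(-len, tids)
  pick <- rows[ord[1L], , drop = FALSE]
  rownames(pick) <- NULL
  attr(pick, "transcript_id") <- tids[ord[1L]]
  pick
}

# transcript used for gene-structure statistics: longest summed exon length,
# ties to the lexicographically smaller transcript id
.structure_transcript <- function(gene) {
  tids <- names(gene$transcripts)
  if (!length(tids)) stop("gene ", gene$gene_id, " has no transcripts")
  span <- vapply(gene$transcripts,
                 function(tr) sum(tr$exons$end - tr$exons$start + 1L),
                 numeric(1))
  gene$transcripts[[order(-span, tids)[1L]]]
}

#' Count introns of a gene
#'
#' Uses the gene's longest transcript (by summed exon length). An intron is
#' the gap between consecutive sorted exons: `start(next) - end(prev) - 1`.
#'
#' @param gene A `gene_model`.
#' @return `list(n_introns, intron_lengths)`.
#' @export
count_introns <- function(gene) {
  tr <- .structure_transcript(gene)
  ex <- tr$exons
  if (!nrow(ex)) stop("transcript ", tr$transcript_id, " has zero exons")
  ex <- ex[order(ex$start), , drop = FALSE]
  n <- nrow(ex)
  if (n == 1L) return(list(n_introns = 0L, intron_lengths = integer(0)))
  lens <- ex$start[-1L] - ex$end[-n] - 1L
  list(n_introns = n - 1L, intron_lengths = as.integer(lens))
}

.sanitize_newick_label <- function(x) gsub("[\\s()\\[\\]:;,']", "_", x, perl = TRUE)

#' Write a phylogenetic tree to newick
#'
#' Leaf and internal labels are sanitized (whitespace, parentheses, and
#' other newick metacharacters replaced by `_`) so the file round-trips
#' through [read_newick()].
#'
#' @param tree An [ape::phylo] tree; internal support values, if any, are
#'   expected in `tree$node.label`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label <- .sanitize_newick_label(tree$tip.label)
  if (!is.null(tree$node.label)) {
    tree$node.label <- .sanitize_newick_label(tree$node.label)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)
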