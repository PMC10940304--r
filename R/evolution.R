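.GENETIC_CODE <- Biostrings::GENETIC_CODE

.codons_of <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

.translate_cds <- function(cds) {
  aa <- unname(.GENETIC_CODE[.codons_of(cds)])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]  # trailing stop
  if (any(aa == "*")) stop("internal stop codon in CDS")
  paste(aa, collapse = "")
}

#' Find recently duplicated gene pairs
#'
#' Operationalizes "the gene pairs encoding the most similar proteins" as
#' mutual nearest neighbors on a protein distance matrix: a pair (a, b) is
#' reported when b is a's closest gene and a is b's closest gene. Ties are
#' broken by the lexicographically smaller label, so each gene appears in
#' at most one pair.
#'
#' @param dm Symmetric distance matrix with labelled dimnames.
#' @return Data frame `gene_a`, `gene_b`, `distance` (gene_a < gene_b),
#'   possibly with zero rows.
#' @export
find_duplicate_pairs <- function(dm) {
  labels <- rownames(dm)
  n <- length(labels)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  nn <- character(n)
  for (i in seq_len(n)) {
    d <- dm[i, ]; d[i] <- Inf
    cand <- labels[d == min(d)]
    nn[i] <- sort(cand)[1L]
  }
  rows <- list()
  for (i in seq_len(n)) {
    j <- match(nn[i], labels)
    if (j > i && nn[j] == labels[i]) {
      a <- sort(c(labels[i], labels[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a[1L], gene_b = a[2L], distance = dm[i, j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$gene_a), , drop = FALSE]
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue is replaced by its source codon and each gap by
#' `---`. The CDS must translate exactly to its (degapped) protein; a
#' trailing stop codon is tolerated and excluded.
#'
#' @param protein_aln Character vector of 2 aligned protein sequences
#'   (gaps as `-`).
#' @param cds Character vector of the 2 corresponding CDS.
#' @return Character vector of 2 aligned codon sequences (length
#'   `3 * alignment length`).
#' @export
codon_align <- function(protein_aln, cds) {
  stopifnot(length(protein_aln) == 2L, length(cds) == 2L)
  out <- character(2L)
  for (k in 1:2) {
    codons <- .codons_of(cds[k])
    if (.GENETIC_CODE[codons[length(codons)]] == "*") {
      codons <- codons[-length(codons)]
    }
    aa <- unname(.GENETIC_CODE[codons])
    res <- strsplit(toupper(protein_aln[k]), "")[[1]]
    plain <- res[res != "-"]
    if (length(plain) != length(codons)) {
      stop("CDS ", k, " encodes ", length(codons),
           " residues but the aligned protein has ", length(plain))
    }
    mismatch <- which(aa != plain)
    if (length(mismatch)) {
      stop(sprintf("codon %d of CDS %d translates to %s, protein has %s",
                   mismatch[1L], k, aa[mismatch[1L]], plain[mismatch[1L]]))
    }
    j <- 0L
    out[k] <- paste(vapply(res, function(r) {
      if (r == "-") "---" else { j <<- j + 1L; codons[j] }
    }, character(1)), collapse = "")
  }
  out
}

.BASES <- c("A", "C", "G", "T")

# fraction of the three possible changes at each codon position that are
# synonymous; changes to stop codons count as nonsynonymous, so each codon
# contributes exactly S + N = 3 sites
.codon_syn_sites <- function(codon) {
  aa <- .GENETIC_CODE[codon]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (.GENETIC_CODE[mut] != "*" && .GENETIC_CODE[mut] == aa) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways; pathways through stop codons are excluded
# (falling back to all pathways when every one is blocked)
.codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    idx <- if (k == 2L) list(c(1, 2), c(2, 1)) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(o) pos[o])
  }
  paths <- lapply(perms, function(order) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (.GENETIC_CODE[nxt] == "*") blocked <- TRUE
      if (.GENETIC_CODE[cur] == .GENETIC_CODE[nxt]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  })
  m <- do.call(rbind, paths)
  use <- m[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(sd = mean(m[use, "sd"]), nd = mean(m[use, "nd"]))
}

.jukes_cantor <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Nei-Gojobori (1986) Ka and Ks from a pairwise codon alignment
#'
#' Synonymous site fractions are computed per codon and averaged over the
#' two sequences; observed differences are partitioned by equal-weight
#' averaging over all minimal mutational pathways (pathways through stop
#' codons excluded); the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)` is applied to the proportions. `ks` or
#' `ka` is `NA` (undefined) when its proportion reaches 3/4. Codon columns
#' containing a gap, `N`, or a stop codon are skipped.
#'
#' @param codon_aln Character vector of 2 aligned codon sequences from
#'   [codon_align()].
#' @return List with `ka`, `ks`, and the intermediate quantities `pn`,
#'   `ps`, `N`, `S`, `nd`, `sd`, `n_codons`.
#' @export
kaks_ng86 <- function(codon_aln) {
  stopifnot(length(codon_aln) == 2L)
  co1 <- .codons_of(codon_aln[1L])
  co2 <- .codons_of(codon_aln[2L])
  if (length(co1) != length(co2)) stop("codon alignments differ in length")
  ok <- !grepl("[-N]", co1) & !grepl("[-N]", co2) &
    .GENETIC_CODE[co1] != "*" & .GENETIC_CODE[co2] != "*"
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) stop("no ungapped codon pair in alignment")
  S <- 0; Sd <- 0; Nd <- 0; n_used <- 0L
  for (i in which(ok)) {
    S <- S + (.codon_syn_sites(co1[i]) + .codon_syn_sites(co2[i])) / 2
    d <- .codon_path_diffs(co1[i], co2[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
    n_used <- n_used + 1L
  }
  N <- 3 * n_used - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  list(ka = .jukes_cantor(pn), ks = .jukes_cantor(ps), pn = pn, ps = ps,
       N = N, S = S, nd = unname(Nd), sd = unname(Sd), n_codons = n_used)
}

#' Divergence time from a synonymous substitution rate
#'
#' `T = Ks / (2 * lambda) * 1e-6` million years, with `lambda` the number
#' of synonymous substitutions per site per generation (default 6.5e-9,
#' the rate commonly used for asterid dating).
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda_ Synonymous substitution rate per site per generation.
#' @return Divergence time in million years (MYA).
#' @export
divergence_time <- function(ks, lambda_ = 6.5e-9) {
  if (is.na(ks)) return(NA_real_)
  if (ks < 0) stop("ks must be non-negative")
  stopifnot(lambda_ > 0)
  ks / (2 * lambda_) * 1e-6
}

#' Selection regime from Ka and Ks
#'
#' @param ka,ks Nonsynonymous and synonymous rates; `NA` allowed.
#' @return One of `"purifying"` (Ka/Ks < 1), `"neutral"` (= 1),
#'   `"positive"` (> 1), or `"undefined"` (Ks zero or undefined).
#' @export
selection_call <- function(ka, ks) {
  if (is.na(ks) || is.na(ka) || ks == 0) return("undefined")
  r <- ka / ks
  if (r < 1) "purifying" else if (r > 1) "positive" else "neutral"
}

#' Ka/Ks and divergence dating for a set of gene pairs
#'
#' @param pairs Data frame `gene_a`, `gene_b` (e.g. from
#'   [find_duplicate_pairs()] or a user table).
#' @param cds Sequence table of CDS keyed by gene id.
#' @param proteins Optional aligned protein table covering the pair members
#'   (e.g. MSA rows); when absent, the CDS translations are used directly
#'   and must have equal length.
#' @param lambda_ Synonymous rate for [divergence_time()].
#' @return Data frame: `gene_a`, `gene_b`, `ka`, `ks`, `ka_ks`, `t_mya`,
#'   `selection`.
#' @export
kaks_pairs <- function(pairs, cds, proteins = NULL, lambda_ = 6.5e-9) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    ca <- cds$residues[match(ga, cds$id)]
    cb <- cds$residues[match(gb, cds$id)]
    if (is.na(ca) || is.na(cb)) stop("missing CDS for pair ", ga, "/", gb)
    aln <- if (!is.null(proteins) && all(c(ga, gb) %in% proteins$id)) {
      c(proteins$residues[match(ga, proteins$id)],
        proteins$residues[match(gb, proteins$id)])
    } else {
      c(.translate_cds(ca), .translate_cds(cb))
    }
    res <- kaks_ng86(codon_align(aln, c(ca, cb)))
    ratio <- if (is.na(res$ks) || is.na(res$ka) || res$ks == 0) NA_real_ else
      res$ka / res$ks
    data.frame(gene_a = ga, gene_b = gb, ka = res$ka, ks = res$ks,
               ka_ks = ratio,
               t_mya = divergence_time(res$ks, lambda_),
               selection = selection_call(res$ka, res$ks),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
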