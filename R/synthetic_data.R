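#' @section Synthetic study design:
#' The generator emulates the inputs of a genome-wide C2H2-ZFP family
#' survey at desk scale, with full ground truth: a proteome with planted
#' fingers of known type and spacing, a genome + GFF3 with 2-kb promoters
#' carrying planted cis-elements and a half-intronless gene set, CDS pairs
#' mutated to target Ka/Ks values, and a 7-stage FPKM matrix with planted
#' low-expression and stage-specific genes. Protein filler sequence is
#' drawn from an alphabet without C, H, or any QALGGH letter, which
#' guarantees zero spurious fingers and unambiguous motif windows (a
#' documented, testable simplification). Promoter background uses only
#' A/T while every bundled motif has at least one C/G-obligate position,
#' so background can never produce a spurious element.
#' @name synthetic_data
NULL

# residues that can never take part in a finger skeleton or QALGGH window
.FILLER_AA <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      c("C", "H", "Q", "A", "L", "G"))

.DEFAULT_ARCH_MIX <- c("1i-Q" = 4, "1i-M" = 4, "2i-Q" = 4, "2i-M" = 4,
                       "2i-Mx" = 4, "3i-M" = 4, "3i-Mx" = 4, "4i-Mx" = 4,
                       "t1-M" = 4, "t2-Mx" = 4)

.STAGES <- c("RS", "SS", "LS", "LV", "LB", "LIF", "LPF")

#' Specification for one synthetic dataset
#'
#' The defaults define the package's reference study conditions: a
#' 40-gene family spread over 10 architecture subgroups (a 1/5-scale
#' echo of a ~200-gene plant family), 7 developmental-stage samples, and
#' a duplicate-pair plan of five pairs at Ks 0.1 / Ka 0.02 plus one
#' synonymous-only pair at Ks 0.2.
#'
#' @param n_genes Family size.
#' @param architecture_mix Named counts per subgroup label; must sum to
#'   `n_genes`.
#' @param kaks_pair_plan Data frame `ks_target`, `ka_target`, `n_codons`.
#' @param promoter_motif_plan Optional named list `gene_id -> named counts
#'   per motif_id`; `NULL` draws a random plan at generation time.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes = 40L,
                           architecture_mix = NULL,
                           kaks_pair_plan = NULL,
                           promoter_motif_plan = NULL,
                           seed = 17L) {
  if (is.null(architecture_mix)) {
    architecture_mix <- if (n_genes == 40L) .DEFAULT_ARCH_MIX else
      stop("architecture_mix required when n_genes != 40")
  }
  if (any(architecture_mix < 0)) stop("architecture counts must be >= 0")
  if (sum(architecture_mix) != n_genes) {
    stop("architecture_mix must sum to n_genes")
  }
  if (is.null(kaks_pair_plan)) {
    kaks_pair_plan <- data.frame(
      ks_target = c(rep(0.1, 5), 0.2),
      ka_target = c(rep(0.02, 5), 0.0),
      n_codons = 300L)
  }
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  structure(list(n_genes = as.integer(n_genes),
                 architecture_mix = architecture_mix,
                 kaks_pair_plan = kaks_pair_plan,
                 promoter_motif_plan = promoter_motif_plan,
                 gene_ids = gene_ids,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.filler <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.FILLER_AA, n, replace = TRUE), collapse = "")
}

# one planted finger; returns sequence and 1-based coordinating positions
.make_domain <- function(type) {
  iv <- sample(2:4, 1L)                      # C-X(2,4)-C
  qal <- strsplit("QALGGH", "")[[1]]
  deg <- 0L
  if (grepl("^M", type)) {
    deg <- as.integer(substr(type, 2L, 2L))
    at <- sample(1:5, deg)
    qal[at] <- sample(.FILLER_AA, deg, replace = TRUE)
  }
  core <- paste0(.filler(2), "C", .filler(iv), "C", .filler(7),
                 paste(qal, collapse = ""))
  c1 <- 3L
  c2 <- c1 + iv + 1L
  h1 <- c2 + 13L                             # the QALGGH H
  if (type == "D") {
    seq <- core                              # no second His; tail is linker
    h2 <- NA_integer_
    last <- h1
  } else {
    tail_x <- sample(3:5, 1L)                # H-X(3,5)-H
    seq <- paste0(core, .filler(tail_x), "H")
    h2 <- h1 + tail_x + 1L
    last <- h2
  }
  list(seq = seq, c1 = c1, c2 = c2, h1 = h1, h2 = h2, last = last,
       type = type, degradation = deg)
}

.parse_subgroup <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)i-(Q|M|D|Mx)$", label))[[1]]
  if (length(m)) {
    n <- as.integer(m[2L])
    return(list(n = n, tandem = rep(FALSE, max(0L, n - 1L)), suffix = m[3L]))
  }
  m <- regmatches(label, regexec("^t([12])-(Q|M|D|Mx)$", label))[[1]]
  if (length(m)) {
    n <- if (m[2L] == "1") 3L else 4L
    tandem <- c(TRUE, rep(FALSE, n - 2L))
    return(list(n = n, tandem = tandem, suffix = m[3L]))
  }
  stop("unrecognized subgroup label: ", label)
}

.plan_types <- function(n, suffix) {
  rand_m <- function(k) paste0("M", sample(1:5, k, replace = TRUE))
  switch(suffix,
    Q = rep("Q", n),
    M = rand_m(n),
    D = rep("D", n),
    Mx = {
      if (n < 2L) stop("mixed-type subgroup needs >= 2 domains")
      repeat {
        cls <- sample(c("Q", "M", "D"), n, replace = TRUE)
        if (length(unique(cls)) >= 2L) break
      }
      vapply(cls, function(cl) {
        if (cl == "M") rand_m(1L) else cl
      }, character(1), USE.NAMES = FALSE)
    })
}

#' Generate a synthetic proteome with planted fingers
#'
#' Each protein embeds exactly the fingers its subgroup plan calls for (Q
#' templates, M templates with the planned number of degraded QALGGH
#' residues, D templates lacking the second histidine), separated by
#' linkers realizing the planned tandem (<= 11 aa) or dispersed (>= 12 aa)
#' spacing. Filler can never create a spurious finger.
#'
#' @param spec A [synthetic_spec()].
#' @return `list(proteins = sequence table keyed by gene id,
#'   truth = per-gene list(subgroup, domains))` where `domains` uses the
#'   same coordinate conventions as [scan_domains()].
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  subgroups <- rep(names(spec$architecture_mix), spec$architecture_mix)
  proteins <- character(spec$n_genes)
  truth <- vector("list", spec$n_genes)
  names(truth) <- spec$gene_ids
  for (g in seq_len(spec$n_genes)) {
    plan <- .parse_subgroup(subgroups[g])
    types <- .plan_types(plan$n, plan$suffix)
    doms <- lapply(types, .make_domain)
    npad <- sample(5:20, 1L)
    seqs <- .filler(npad)
    offset <- npad
    rows <- list()
    for (k in seq_along(doms)) {
      d <- doms[[k]]
      rows[[k]] <- data.frame(
        start = offset + d$c1 - 1L, end = offset + d$last,
        cys1 = offset + d$c1, cys2 = offset + d$c2,
        his1 = offset + d$h1,
        his2 = if (is.na(d$h2)) NA_integer_ else offset + d$h2,
        qalggh_window = NA_character_, degradation = d$degradation,
        type_label = d$type, stringsAsFactors = FALSE)
      seqs <- paste0(seqs, d$seq)
      offset <- offset + nchar(d$seq)
      if (k < length(doms)) {
        linker <- if (plan$tandem[k]) sample(2:11, 1L) else sample(12:30, 1L)
        # the linker runs from the last coordinating residue to the next
        # cysteine; the next domain template itself contributes 2 leading
        # filler residues, so insert linker - 2 here
        seqs <- paste0(seqs, .filler(linker - 2L))
        offset <- offset + linker - 2L
      }
    }
    seqs <- paste0(seqs, .filler(sample(5:20, 1L)))
    proteins[g] <- seqs
    dom_df <- do.call(rbind, rows)
    rownames(dom_df) <- NULL
    truth[[g]] <- list(subgroup = subgroups[g], domains = dom_df)
  }
  list(proteins = data.frame(id = spec$gene_ids, description = "",
                             residues = proteins, stringsAsFactors = FALSE),
       truth = truth)
}

#' Per-transcript protein records for isoform selection
#'
#' The planted family protein is attached to each gene's first transcript;
#' genes with a second transcript get a strictly shorter, finger-free
#' decoy so longest-isoform selection must recover the planted protein.
#'
#' @param spec A [synthetic_spec()].
#' @param proteome Output of [generate_proteome()].
#' @param genes Gene models from [generate_genome_and_gff()].
#' @return Sequence table keyed by transcript id.
#' @export
generate_isoform_proteins <- function(spec, proteome, genes) {
  set.seed(spec$seed + 7L)
  rows <- list()
  for (gid in names(genes)) {
    planted <- proteome$proteins$residues[match(gid, proteome$proteins$id)]
    tids <- names(genes[[gid]]$transcripts)
    rows[[length(rows) + 1L]] <- data.frame(
      id = tids[1L], description = gid, residues = planted,
      stringsAsFactors = FALSE)
    for (t in tids[-1L]) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = t, description = gid,
        residues = .filler(max(10L, nchar(planted) - 15L)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.realize_iupac <- function(consensus) {
  sets <- Biostrings::IUPAC_CODE_MAP[strsplit(consensus, "")[[1]]]
  paste(vapply(strsplit(sets, ""), function(b) sample(b, 1L), character(1)),
        collapse = "")
}

# build one promoter (sense orientation): A/T background + planted motifs
.build_promoter <- function(len, plan, motifs) {
  bg <- sample(c("A", "T"), len, replace = TRUE)
  hits <- data.frame(motif_id = character(0), offset = integer(0),
                     strand = character(0), stringsAsFactors = FALSE)
  occ <- list()
  for (mid in names(plan)) {
    cnt <- plan[[mid]]
    if (cnt <= 0) next
    cons <- motifs$consensus[match(mid, motifs$motif_id)]
    if (is.na(cons)) stop("planned motif not in table: ", mid)
    for (r in seq_len(cnt)) {
      anti <- !(.is_palindromic(cons)) && runif(1) < 0.25
      occ[[length(occ) + 1L]] <- list(motif_id = mid,
                                      realization = .realize_iupac(cons),
                                      strand = if (anti) "antisense" else "sense")
    }
  }
  if (length(occ)) {
    occ <- occ[sample.int(length(occ))]
    lens <- vapply(occ, function(o) nchar(o$realization), integer(1))
    need <- sum(lens) + 10L * (length(occ) + 1L)
    if (need > len) stop("promoter of ", len, " bp too short for motif plan")
    slack <- len - need
    extra <- if (length(occ)) diff(c(0, sort(sample.int(slack + 1L,
      length(occ), replace = TRUE) - 1L))) else integer(0)
    pos <- 0L
    for (k in seq_along(occ)) {
      pos <- pos + 10L + extra[k]                       # 0-based start
      o <- occ[[k]]
      ins <- if (o$strand == "antisense") .revcomp(o$realization) else
        o$realization
      bg[(pos + 1L):(pos + nchar(ins))] <- strsplit(ins, "")[[1]]
      hits <- rbind(hits, data.frame(motif_id = o$motif_id, offset = pos,
                                     strand = o$strand,
                                     stringsAsFactors = FALSE))
      pos <- pos + nchar(ins)
    }
  }
  list(seq = paste(bg, collapse = ""), hits = hits)
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

#' Generate a synthetic genome, gene models, and promoter ground truth
#'
#' Genes are laid out so that each 2-kb upstream window is exactly the
#' constructed promoter region (one gene per chromosome is placed 500 bp
#' from the contig start to exercise promoter truncation; alternating
#' genes sit on the minus strand). Half of the genes are intronless;
#' every fifth multi-exon gene carries a second, shorter transcript.
#'
#' @param spec A [synthetic_spec()].
#' @param motifs Motif table; defaults to the bundled table.
#' @return `list(genome = nucleotide sequence table, genes = gene_model
#'   list, promoter_truth = per-gene list(length, truncated, hits,
#'   counts))`.
#' @export
generate_genome_and_gff <- function(spec, motifs = motif_table()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  n <- spec$n_genes
  plan <- spec$promoter_motif_plan
  if (is.null(plan)) {
    plan <- lapply(seq_len(n), function(g) {
      ids <- sample(motifs$motif_id, 4L)
      setNames(as.list(sample(0:3, 4L, replace = TRUE)), ids)
    })
    names(plan) <- spec$gene_ids
  }
  per_chr <- 10L
  n_chr <- ceiling(n / per_chr)
  chrom_seq <- setNames(rep("", n_chr), sprintf("chr%d", seq_len(n_chr)))
  genes <- vector("list", n)
  names(genes) <- spec$gene_ids
  promoter_truth <- vector("list", n)
  names(promoter_truth) <- spec$gene_ids
  for (g in seq_len(n)) {
    gid <- spec$gene_ids[g]
    chr <- sprintf("chr%d", (g - 1L) %/% per_chr + 1L)
    first_on_chr <- (g - 1L) %% per_chr == 0L
    strand <- if (g %% 2L == 0L) "-" else "+"
    if (first_on_chr) strand <- "+"               # truncated case is + strand
    plen <- if (first_on_chr) 500L else 2000L
    gplan <- plan[[gid]]
    if (first_on_chr) {          # keep the truncated promoter satisfiable
      while (sum(unlist(gplan) * 12L) + 10L * (sum(unlist(gplan)) + 1L) > plen) {
        gplan[[which.max(unlist(gplan))]] <- gplan[[which.max(unlist(gplan))]] - 1L
      }
      plan[[gid]] <- gplan
    }
    prom <- .build_promoter(plen, gplan, motifs)
    # gene body
    intronless <- g %% 2L == 1L
    n_exons <- if (intronless) 1L else sample(2:4, 1L)
    exon_len <- sample(100:300, n_exons, replace = TRUE)
    intron_len <- if (n_exons > 1L) sample(50:200, n_exons - 1L,
                                           replace = TRUE) else integer(0)
    body_len <- sum(exon_len) + sum(intron_len)
    body <- .random_dna(body_len)
    cursor <- nchar(chrom_seq[chr])
    if (strand == "+") {
      gstart <- cursor + plen + 1L
      gend <- gstart + body_len - 1L
      chrom_seq[chr] <- paste0(chrom_seq[chr], prom$seq, body,
                               .random_dna(100L))
    } else {
      gstart <- cursor + 1L
      gend <- gstart + body_len - 1L
      chrom_seq[chr] <- paste0(chrom_seq[chr], body, .revcomp(prom$seq),
                               .random_dna(100L))
    }
    # exon coordinates (ascending file coordinates)
    ex_start <- integer(n_exons); ex_end <- integer(n_exons)
    p <- gstart
    for (e in seq_len(n_exons)) {
      ex_start[e] <- p
      ex_end[e] <- p + exon_len[e] - 1L
      p <- ex_end[e] + 1L + if (e < n_exons) intron_len[e] else 0L
    }
    exons <- data.frame(start = ex_start, end = ex_end)
    t1 <- paste0(gid, ".t1")
    transcripts <- list()
    transcripts[[t1]] <- list(transcript_id = t1, exons = exons, cds = exons)
    if (g %% 5L == 0L && n_exons > 1L) {
      t2 <- paste0(gid, ".t2")
      sub <- exons[1L, , drop = FALSE]
      transcripts[[t2]] <- list(transcript_id = t2, exons = sub, cds = sub)
    }
    genes[[gid]] <- structure(
      list(gene_id = gid, chromosome = chr, strand = strand,
           start = gstart, end = gend, transcripts = transcripts),
      class = "gene_model")
    counts <- unlist(gplan)
    promoter_truth[[gid]] <- list(length = plen,
                                  truncated = plen < 2000L,
                                  hits = prom$hits,
                                  counts = counts[counts > 0])
  }
  genome <- data.frame(id = names(chrom_seq), description = "",
                       residues = unname(chrom_seq), stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, promoter_truth = promoter_truth)
}

#' Write gene models to a GFF3 file
#'
#' @param genes Named list of `gene_model` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("##gff-version 3\n", file = con)
  row <- function(chr, type, start, end, strand, attrs) {
    cat(paste(chr, "zfscan", type, start, end, ".", strand, ".", attrs,
              sep = "\t"), "\n", sep = "", file = con)
  }
  for (g in genes) {
    row(g$chromosome, "gene", g$start, g$end, g$strand,
        sprintf("ID=%s", g$gene_id))
    for (tr in g$transcripts) {
      tstart <- min(tr$exons$start); tend <- max(tr$exons$end)
      row(g$chromosome, "mRNA", tstart, tend, g$strand,
          sprintf("ID=%s;Parent=%s", tr$transcript_id, g$gene_id))
      for (e in seq_len(nrow(tr$exons))) {
        row(g$chromosome, "exon", tr$exons$start[e], tr$exons$end[e],
            g$strand, sprintf("Parent=%s", tr$transcript_id))
      }
      for (e in seq_len(nrow(tr$cds))) {
        row(g$chromosome, "CDS", tr$cds$start[e], tr$cds$end[e],
            g$strand, sprintf("Parent=%s", tr$transcript_id))
      }
    }
  }
  invisible(path)
}

.NONSTOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
.FOURFOLD_PREFIX <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")

#' Generate a CDS pair with target Ka and Ks
#'
#' The second sequence derives from the first by planting synonymous
#' substitutions at third positions of four-fold degenerate codons and
#' nonsynonymous substitutions at first/second positions (never creating a
#' stop), in distinct codons. Substitution counts are Binomial draws with
#' success probabilities equal to the Jukes-Cantor-inverted target
#' proportions, so the Nei-Gojobori estimates scatter around the targets
#' with genuine Monte-Carlo noise.
#'
#' @param ks_target,ka_target Target synonymous/nonsynonymous distances
#'   (Jukes-Cantor scale).
#' @param n_codons Number of codons.
#' @param seed Integer seed.
#' @return `list(cds_a, cds_b, n_syn, n_nonsyn)`.
#' @export
generate_cds_pair <- function(ks_target, ka_target, n_codons = 300L,
                              seed = 1L) {
  stopifnot(ks_target >= 0, ka_target >= 0, n_codons >= 10L)
  set.seed(seed)
  codons <- sample(.NONSTOP_CODONS, n_codons, replace = TRUE)
  ps_t <- 3 / 4 * (1 - exp(-4 / 3 * ks_target))
  pn_t <- 3 / 4 * (1 - exp(-4 / 3 * ka_target))
  if (ps_t >= 0.75 || pn_t >= 0.75) stop("target outside the Jukes-Cantor domain")
  S <- sum(vapply(codons, .codon_syn_sites, numeric(1)))
  N <- 3 * n_codons - S
  m_s <- rbinom(1L, round(S), ps_t)
  m_n <- rbinom(1L, round(N), pn_t)
  fourfold <- which(substr(codons, 1L, 2L) %in% .FOURFOLD_PREFIX)
  if (m_s > length(fourfold)) stop("ks_target infeasible at n_codons")
  syn_at <- if (m_s > 0L) sample(fourfold, m_s) else integer(0)
  non_pool <- setdiff(seq_len(n_codons), syn_at)
  mutated <- codons
  for (i in syn_at) {
    third <- substr(mutated[i], 3L, 3L)
    substr(mutated[i], 3L, 3L) <- sample(setdiff(.BASES, third), 1L)
  }
  n_done <- 0L
  non_pool <- sample(non_pool)
  for (i in non_pool) {
    if (n_done >= m_n) break
    cod <- mutated[i]
    cands <- list()
    for (p in 1:2) {
      for (b in setdiff(.BASES, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- b
        if (.GENETIC_CODE[mut] != "*" &&
            .GENETIC_CODE[mut] != .GENETIC_CODE[cod]) {
          cands[[length(cands) + 1L]] <- mut
        }
      }
    }
    if (!length(cands)) next
    mutated[i] <- cands[[sample.int(length(cands), 1L)]]
    n_done <- n_done + 1L
  }
  if (n_done < m_n) stop("ka_target infeasible at n_codons")
  list(cds_a = paste(codons, collapse = ""),
       cds_b = paste(mutated, collapse = ""),
       n_syn = m_s, n_nonsyn = n_done)
}

#' Generate the seven-stage FPKM matrix with planted classes
#'
#' Planted classes: genes 1-6 are RS-specific (high FPKM only in the root
#' seedling sample), genes 7-16 are low-expression (every value below 0.6,
#' so the mean is below the 1-FPKM filter), remaining genes are broadly
#' expressed.
#'
#' @param spec A [synthetic_spec()].
#' @return `list(matrix = fpkm_matrix, truth = named character of class
#'   labels)`.
#' @export
generate_expression_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 4L)
  n <- spec$n_genes
  classes <- rep("broad", n)
  classes[seq_len(min(6L, n))] <- "RS-specific"
  if (n > 6L) classes[7L:min(16L, n)] <- "low"
  vals <- matrix(0, n, length(.STAGES),
                 dimnames = list(spec$gene_ids, .STAGES))
  for (g in seq_len(n)) {
    vals[g, ] <- switch(classes[g],
      "low" = runif(7L, 0, 0.6),
      "RS-specific" = c(runif(1L, 50, 200), runif(6L, 0, 0.5)),
      "broad" = runif(7L, 2, 50))
  }
  list(matrix = fpkm_matrix(vals), truth = setNames(classes, spec$gene_ids))
}

#' Generate a differential-expression table with a planted 6-up/8-down plan
#'
#' @param spec A [synthetic_spec()].
#' @return `list(table = DE data frame, up, down)` with the planted gene
#'   sets.
#' @export
generate_de_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 6L)
  n <- spec$n_genes
  stopifnot(n >= 30L)
  up <- spec$gene_ids[17:22]
  down <- spec$gene_ids[23:30]
  lfc <- numeric(n); fdr <- numeric(n)
  for (g in seq_len(n)) {
    gid <- spec$gene_ids[g]
    if (gid %in% up) {
      lfc[g] <- runif(1, 1, 4); fdr[g] <- runif(1, 0, 0.049)
    } else if (gid %in% down) {
      lfc[g] <- -runif(1, 1, 4); fdr[g] <- runif(1, 0, 0.049)
    } else {
      lfc[g] <- runif(1, -0.5, 0.5); fdr[g] <- runif(1, 0.2, 1)
    }
  }
  tab <- data.frame(gene_id = spec$gene_ids, tissue = "leaf",
                    condition_pair = "drought_vs_control",
                    log2fc = lfc, fdr = fdr, stringsAsFactors = FALSE)
  list(table = tab, up = up, down = down)
}

#' Generate a synthetic family MSA with subgroup-level signal
#'
#' Stand-in for an external alignment step (alignment construction is out
#' of scope): each architecture subgroup gets an independent random
#' reference sequence and each member is that reference with a few
#' substitutions, so subgroups form well-separated clades.
#'
#' @param spec A [synthetic_spec()].
#' @param length Alignment length in columns.
#' @param n_subs Substitutions per gene relative to its subgroup reference.
#' @return Aligned (gap-free, equal-length) sequence table keyed by gene
#'   id.
#' @export
generate_msa <- function(spec, length = 120L, n_subs = 5L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 5L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  subgroups <- rep(names(spec$architecture_mix), spec$architecture_mix)
  refs <- lapply(unique(subgroups), function(s) sample(aa, length,
                                                       replace = TRUE))
  names(refs) <- unique(subgroups)
  seqs <- character(spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    s <- refs[[subgroups[g]]]
    at <- sample.int(length, n_subs)
    s[at] <- sample(aa, n_subs, replace = TRUE)
    seqs[g] <- paste(s, collapse = "")
  }
  out <- data.frame(id = spec$gene_ids, description = subgroups,
                    residues = seqs, stringsAsFactors = FALSE)
  out
}
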