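#' Pipeline configuration
#'
#' Input paths may be `NULL`; [run_all()] runs every stage whose inputs are
#' present (scan/physchem need `proteins`; gene structure, naming and
#' promoters need `gff` (+ `genome` for promoters); phylogeny needs `msa`;
#' Ka/Ks needs `cds` plus either a `pairs` table or `msa`; expression needs
#' `fpkm`, optionally `de`). Unknown arguments are rejected and all
#' numeric parameters must be positive.
#'
#' @param proteins,cds,genome,gff,msa,fpkm,de,motifs,pairs Input file
#'   paths (`motifs` defaults to the bundled table, `pairs` is an optional
#'   TSV with `gene_a`/`gene_b` columns).
#' @param promoter_length Promoter window in bp (default 2000).
#' @param tandem_max_linker Tandem linker cutoff in residues (default 11).
#' @param fpkm_threshold Mean-FPKM filter cutoff (default 1).
#' @param fdr_cutoff DE significance cutoff (default 0.05).
#' @param lambda Synonymous substitution rate per site per generation
#'   (default 6.5e-9).
#' @param bootstrap Bootstrap replicates for the NJ tree (default 500).
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory.
#' @param prefix Systematic-name prefix (default `"C2H2"`).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(proteins = NULL, cds = NULL, genome = NULL,
                            gff = NULL, msa = NULL, fpkm = NULL, de = NULL,
                            motifs = NULL, pairs = NULL,
                            promoter_length = 2000L, tandem_max_linker = 11L,
                            fpkm_threshold = 1.0, fdr_cutoff = 0.05,
                            lambda = 6.5e-9, bootstrap = 500L, seed = 17L,
                            out_dir = "zfscan_out", prefix = "C2H2") {
  num <- c(promoter_length = promoter_length,
           tandem_max_linker = tandem_max_linker,
           fpkm_threshold = fpkm_threshold, fdr_cutoff = fdr_cutoff,
           lambda = lambda, bootstrap = bootstrap)
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad)) stop("config parameter must be positive: ", bad[1L])
  cfg <- list(proteins = proteins, cds = cds, genome = genome, gff = gff,
              msa = msa, fpkm = fpkm, de = de, motifs = motifs,
              pairs = pairs, promoter_length = as.integer(promoter_length),
              tandem_max_linker = as.integer(tandem_max_linker),
              fpkm_threshold = fpkm_threshold, fdr_cutoff = fdr_cutoff,
              lambda = lambda, bootstrap = as.integer(bootstrap),
              seed = as.integer(seed), out_dir = out_dir, prefix = prefix)
  structure(cfg, class = "pipeline_config")
}

.cfg_header <- function(cfg) {
  c(sprintf("# zfscan %s", .zfscan_version()),
    sprintf(paste0("# seed=%d promoter_length=%d tandem_max_linker=%d ",
                   "fpkm_threshold=%g fdr_cutoff=%g lambda=%g bootstrap=%d"),
            cfg$seed, cfg$promoter_length, cfg$tandem_max_linker,
            cfg$fpkm_threshold, cfg$fdr_cutoff, cfg$lambda, cfg$bootstrap))
}

.write_tsv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(.cfg_header(cfg), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full family-analysis pipeline
#'
#' Stages run in dependency order: domain scan and naming, gene structure,
#' physicochemical profiles, NJ tree with bootstrap, duplicate-pair Ka/Ks
#' with divergence dating, promoter cis-element counting, expression
#' filtering and DE summarization, and a consolidated per-gene
#' `report.tsv`. Partial configurations run partial pipelines; missing
#' dependencies of a requested stage stop before any stage runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the computed objects (architectures,
#'   names, profiles, tree, kaks table, cis tables, expression results)
#'   and the output directory.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$proteins)) stop("config$proteins is required")
  if (!is.null(config$genome) && is.null(config$gff)) {
    stop("promoter stage needs both genome and gff")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(out_dir = config$out_dir)
  op <- function(name) file.path(config$out_dir, name)

  ## --- scan stage -------------------------------------------------------
  prot_all <- read_fasta(config$proteins, "protein")
  genes <- NULL
  positions <- NULL
  if (!is.null(config$gff)) {
    genes <- read_gff3(config$gff)
    sel <- lapply(genes, function(g) select_longest_isoform(g, prot_all))
    family <- data.frame(
      id = names(genes), description = "",
      residues = vapply(sel, function(s) s$residues[1L], character(1)),
      stringsAsFactors = FALSE)
    positions <- data.frame(
      gene_id = names(genes),
      chromosome = vapply(genes, `[[`, character(1), "chromosome"),
      start = vapply(genes, `[[`, numeric(1), "start"),
      stringsAsFactors = FALSE)
    .stage_log("scan", "%d genes, %d transcripts, longest isoforms selected",
               length(genes), sum(vapply(genes, function(g)
                 length(g$transcripts), integer(1))))
  } else {
    family <- prot_all
    positions <- data.frame(gene_id = family$id, chromosome = "un",
                            start = seq_len(nrow(family)),
                            stringsAsFactors = FALSE)
  }
  archs <- scan_family(family, tandem_max_linker = config$tandem_max_linker)
  nm <- assign_names(archs, positions, prefix = config$prefix)
  for (i in seq_along(archs)) archs[[i]]$systematic_name <- nm[[i]]
  dom_rows <- do.call(rbind, lapply(archs, function(a) {
    d <- a$domains
    data.frame(gene_id = a$protein_id, start = d$start + 1L, end = d$end,
               type = d$type_label, degradation = d$degradation,
               qalggh_window = d$qalggh_window, stringsAsFactors = FALSE)
  }))
  arch_rows <- do.call(rbind, lapply(archs, function(a) {
    data.frame(gene_id = a$protein_id, systematic_name = a$systematic_name,
               subgroup = a$subgroup, n_domains = nrow(a$domains),
               types = paste(a$domains$type_label, collapse = ","),
               linkers = paste(a$linker_lengths, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(dom_rows) <- rownames(arch_rows) <- NULL
  .write_tsv(dom_rows, op("fam.domains.tsv"), config)      # 1-based inclusive
  .write_tsv(arch_rows, op("fam.architectures.tsv"), config)
  summ <- summarize_family(archs)
  summ_out <- rbind(summ, data.frame(subgroup = "total",
                                     n_proteins = attr(summ, "total")))
  .write_tsv(summ_out, op("fam.summary.tsv"), config)
  .stage_log("scan", "%d family members in %d subgroups",
             attr(summ, "total"), nrow(summ))
  out$architectures <- archs
  out$names <- nm
  out$family <- family

  ## --- gene structure ---------------------------------------------------
  structure_tab <- NULL
  if (!is.null(genes)) {
    structure_tab <- do.call(rbind, lapply(genes, function(g) {
      intr <- count_introns(g)
      data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
                 start = g$start, end = g$end, strand = g$strand,
                 n_transcripts = length(g$transcripts),
                 n_introns = intr$n_introns,
                 intron_lengths = paste(intr$intron_lengths, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    rownames(structure_tab) <- NULL
    .write_tsv(structure_tab, op("gene_structure.tsv"), config)
    .stage_log("structure", "%d genes, %d intronless",
               nrow(structure_tab), sum(structure_tab$n_introns == 0L))
    out$gene_structure <- structure_tab
  }

  ## --- physchem ---------------------------------------------------------
  prof <- physchem_profile(family)
  .write_tsv(prof, op("physchem.tsv"), config)
  .stage_log("physchem", "%d proteins profiled", nrow(prof))
  out$physchem <- prof

  ## --- phylogeny --------------------------------------------------------
  msa <- NULL
  if (!is.null(config$msa)) {
    msa <- read_fasta(config$msa, "protein")
    tree <- bootstrap_support(msa, n_replicates = config$bootstrap,
                              seed = config$seed)
    write_newick(tree, op("tree.nwk"))
    .stage_log("phylogeny", "NJ tree on %d taxa, %d bootstrap replicates",
               nrow(msa), config$bootstrap)
    out$tree <- tree
  }

  ## --- evolution --------------------------------------------------------
  if (!is.null(config$cds)) {
    cds <- read_fasta(config$cds, "nucleotide")
    pairs <- if (!is.null(config$pairs)) {
      read.delim(config$pairs, stringsAsFactors = FALSE, comment.char = "#")
    } else if (!is.null(msa)) {
      find_duplicate_pairs(p_distance(msa))
    } else {
      stop("Ka/Ks stage needs a pairs table or an MSA to pick pairs from")
    }
    kk <- kaks_pairs(pairs, cds, proteins = msa, lambda_ = config$lambda)
    .write_tsv(kk, op("kaks.tsv"), config)
    .stage_log("evolution", "%d duplicate pairs dated", nrow(kk))
    out$kaks <- kk
  }

  ## --- promoters --------------------------------------------------------
  if (!is.null(config$genome)) {
    genome <- read_fasta(config$genome, "nucleotide")
    motifs <- motif_table(config$motifs)
    hit_list <- lapply(genes, function(g) {
      scan_motifs(extract_upstream(genome, g, config$promoter_length), motifs)
    })
    hits <- do.call(rbind, c(hit_list, list(make.row.names = FALSE)))
    cis <- element_count_matrix(hits, motifs, gene_ids = sort(names(genes)))
    .write_tsv(hits, op("cis.hits.tsv"), config)
    .write_tsv(cis, op("cis.tsv"), config)
    .stage_log("promoters", "%d hits over %d genes", nrow(hits), nrow(cis))
    out$cis_hits <- hits
    out$cis <- cis
  }

  ## --- expression -------------------------------------------------------
  if (!is.null(config$fpkm)) {
    m <- read_fpkm(config$fpkm)
    filt <- filter_low_expression(m, config$fpkm_threshold)
    writeLines(filt$dropped_ids, op("expr.dropped.txt"))
    spec_tab <- stage_specificity(filt$kept)
    .write_tsv(spec_tab, op("stage_specificity.tsv"), config)
    lt <- log_transform(filt$kept)
    ord <- cluster_order(lt)
    kept_tab <- data.frame(gene_id = ord,
                           lt$values[ord, , drop = FALSE],
                           check.names = FALSE, stringsAsFactors = FALSE)
    rownames(kept_tab) <- NULL
    .write_tsv(kept_tab, op("expr.kept.tsv"), config)
    .stage_log("expression", "%d genes kept, %d dropped below %g FPKM",
               length(filt$kept$genes), length(filt$dropped_ids),
               config$fpkm_threshold)
    out$expression <- list(kept = filt$kept, dropped_ids = filt$dropped_ids,
                           transformed = lt, specificity = spec_tab,
                           order = ord)
    if (!is.null(config$de)) {
      det <- read.delim(config$de, stringsAsFactors = FALSE,
                        comment.char = "#")
      des <- de_summary(det, config$fdr_cutoff)
      .write_tsv(des, op("de.summary.tsv"), config)
      .stage_log("expression", "DE summary: %d up, %d down",
                 sum(des$n_up), sum(des$n_down))
      out$de_summary <- des
    }
  }

  ## --- consolidated report ---------------------------------------------
  report <- arch_rows[, c("gene_id", "systematic_name", "subgroup",
                          "n_domains")]
  report <- merge(report, prof[, c("id", "length", "mw", "pi", "gravy",
                                   "instability", "aliphatic", "unstable")],
                  by.x = "gene_id", by.y = "id", all.x = TRUE)
  if (!is.null(structure_tab)) {
    report <- merge(report, structure_tab[, c("gene_id", "n_introns")],
                    by = "gene_id", all.x = TRUE)
  }
  if (!is.null(out$cis)) {
    report <- merge(report, out$cis[, c("gene_id", "total")],
                    by = "gene_id", all.x = TRUE)
    names(report)[names(report) == "total"] <- "cis_elements"
  }
  if (!is.null(out$expression)) {
    sp <- out$expression$specificity
    cls <- ifelse(report$gene_id %in% out$expression$dropped_ids, "dropped",
                  sp$top_group[match(report$gene_id, sp$gene_id)])
    report$expr_class <- cls
  }
  report <- report[order(report$gene_id), , drop = FALSE]
  rownames(report) <- NULL
  .write_tsv(report, op("report.tsv"), config)
  out$report <- report
  invisible(out)
}

.check_row <- function(stage, check, pass) {
  data.frame(stage = stage, check = check,
             status = ifelse(pass, "PASS", "FAIL"), stringsAsFactors = FALSE)
}

#' Self-contained synthetic demonstration run
#'
#' Generates the default 40-gene synthetic dataset, writes its inputs
#' under `out_dir/inputs/`, runs every pipeline stage through [run_all()],
#' and writes `checks.tsv` comparing every stage's output against the
#' generator's ground truth. All randomness derives from `seed`, so two
#' runs with the same seed are byte-identical.
#'
#' @param seed Integer seed (default 17).
#' @param out_dir Report directory.
#' @param bootstrap Bootstrap replicates for the demo tree (default 200, a
#'   demo-scale choice; see [pipeline_config()] for the 500-replicate
#'   convention).
#' @return Invisibly, the [run_all()] result plus `checks` and the ground
#'   truth.
#' @export
run_demo <- function(seed = 17L, out_dir = "zfscan_demo", bootstrap = 200L) {
  spec <- synthetic_spec(seed = seed)
  ind <- file.path(out_dir, "inputs")
  dir.create(ind, recursive = TRUE, showWarnings = FALSE)
  prot <- generate_proteome(spec)
  gg <- generate_genome_and_gff(spec)
  iso <- generate_isoform_proteins(spec, prot, gg$genes)
  msa <- generate_msa(spec)
  expr <- generate_expression_matrix(spec)
  de <- generate_de_table(spec)
  write_fasta(iso, file.path(ind, "proteins.faa"))
  write_fasta(gg$genome, file.path(ind, "genome.fna"))
  write_gff3(gg$genes, file.path(ind, "genes.gff3"))
  write_fasta(msa, file.path(ind, "msa.faa"))
  cds_rows <- list(); pair_rows <- list()
  for (i in seq_len(nrow(spec$kaks_pair_plan))) {
    p <- spec$kaks_pair_plan[i, ]
    pr <- generate_cds_pair(p$ks_target, p$ka_target, p$n_codons,
                            seed = spec$seed + 100L + i)
    ida <- sprintf("pair%d_a", i); idb <- sprintf("pair%d_b", i)
    cds_rows[[2 * i - 1]] <- data.frame(id = ida, description = "",
                                        residues = pr$cds_a)
    cds_rows[[2 * i]] <- data.frame(id = idb, description = "",
                                    residues = pr$cds_b)
    pair_rows[[i]] <- data.frame(gene_a = ida, gene_b = idb)
  }
  write_fasta(do.call(rbind, cds_rows), file.path(ind, "cds.fna"))
  .write_tsv(do.call(rbind, pair_rows), file.path(ind, "pairs.tsv"))
  fp <- data.frame(gene_id = expr$matrix$genes, expr$matrix$values,
                   check.names = FALSE)
  .write_tsv(fp, file.path(ind, "fpkm.tsv"))
  .write_tsv(de$table, file.path(ind, "de.tsv"))

  config <- pipeline_config(
    proteins = file.path(ind, "proteins.faa"),
    cds = file.path(ind, "cds.fna"),
    genome = file.path(ind, "genome.fna"),
    gff = file.path(ind, "genes.gff3"),
    msa = file.path(ind, "msa.faa"),
    fpkm = file.path(ind, "fpkm.tsv"),
    de = file.path(ind, "de.tsv"),
    pairs = file.path(ind, "pairs.tsv"),
    bootstrap = bootstrap, seed = seed, out_dir = out_dir)
  res <- run_all(config)

  checks <- rbind(
    .check_row("scan", "domains_and_subgroups_match_truth",
               .demo_scan_recovered(res$architectures, prot$truth)),
    .check_row("scan", "systematic_names_unique",
               !anyDuplicated(unlist(res$names))),
    .check_row("structure", "half_of_genes_intronless",
               sum(res$gene_structure$n_introns == 0L) ==
                 nrow(res$gene_structure) / 2),
    .check_row("phylogeny", "subgroup_clades_monophyletic",
               .demo_monophyly(res$tree, prot$truth)),
    .check_row("evolution", "ks_recovery_and_purifying_selection",
               .demo_kaks_ok(res$kaks, spec$kaks_pair_plan)),
    .check_row("promoters", "planted_element_counts_recovered",
               .demo_promoters_ok(res$cis_hits, gg$promoter_truth)),
    .check_row("expression", "low_fpkm_genes_dropped",
               setequal(res$expression$dropped_ids,
                        names(expr$truth)[expr$truth == "low"])),
    .check_row("expression", "rs_specific_genes_assigned_rs",
               .demo_rs_ok(res$expression$specificity, expr$truth)),
    .check_row("expression", "de_plan_recovered",
               res$de_summary$n_up == length(de$up) &&
                 res$de_summary$n_down == length(de$down)))
  .write_tsv(checks, file.path(out_dir, "checks.tsv"))
  if (any(checks$status == "FAIL")) {
    warning("demo ground-truth checks failed: ",
            paste(checks$check[checks$status == "FAIL"], collapse = ", "))
  }
  res$checks <- checks
  res$truth <- list(proteome = prot$truth, promoters = gg$promoter_truth,
                    expression = expr$truth, de = de[c("up", "down")])
  invisible(res)
}

.demo_scan_recovered <- function(archs, truth) {
  all(vapply(names(truth), function(gid) {
    a <- archs[[gid]]
    if (is.null(a)) return(FALSE)
    t <- truth[[gid]]
    d <- a$domains
    identical(a$subgroup, t$subgroup) &&
      nrow(d) == nrow(t$domains) &&
      all(d$start == t$domains$start) && all(d$end == t$domains$end) &&
      all(d$cys1 == t$domains$cys1) && all(d$cys2 == t$domains$cys2) &&
      all(d$his1 == t$domains$his1) &&
      identical(is.na(d$his2), is.na(t$domains$his2)) &&
      all(d$his2 == t$domains$his2, na.rm = TRUE) &&
      all(d$type_label == t$domains$type_label) &&
      all(d$degradation == t$domains$degradation)
  }, logical(1)))
}

.demo_monophyly <- function(tree, truth) {
  sub <- vapply(truth, `[[`, character(1), "subgroup")
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  sets <- lapply(parts, function(p) sort(labs[p]))
  all(vapply(unique(sub), function(s) {
    tips <- sort(names(sub)[sub == s])
    comp <- sort(setdiff(labs, tips))
    # on an unrooted tree a group is a clade if some bipartition matches
    # the group or its complement
    any(vapply(sets, function(x) identical(x, tips) || identical(x, comp),
               logical(1)))
  }, logical(1)))
}

.demo_kaks_ok <- function(kk, plan) {
  sel_ok <- TRUE; ks_ok <- TRUE
  mixed <- which(plan$ka_target > 0)
  syn_only <- which(plan$ka_target == 0 & plan$ks_target > 0)
  if (length(mixed)) {
    ks_ok <- abs(mean(kk$ks[mixed]) - mean(plan$ks_target[mixed])) <= 0.05
    sel_ok <- all(kk$selection[mixed] == "purifying")
  }
  ka_zero_ok <- all(kk$ka[syn_only] == 0)
  t_ok <- all(abs(kk$t_mya - kk$ks / (2 * 6.5e-9) * 1e-6) < 1e-9, na.rm = TRUE)
  ks_ok && sel_ok && ka_zero_ok && t_ok
}

.demo_promoters_ok <- function(hits, truth) {
  all(vapply(names(truth), function(gid) {
    planted <- truth[[gid]]$counts
    got <- table(hits$motif_id[hits$gene_id == gid])
    pn <- sort(as.character(names(planted)))
    gn <- sort(as.character(names(got)))
    identical(pn, gn) && all(as.integer(planted[pn]) == as.integer(got[pn]))
  }, logical(1)))
}

.demo_rs_ok <- function(spec_tab, truth) {
  rs <- names(truth)[truth == "RS-specific"]
  all(spec_tab$top_group[match(rs, spec_tab$gene_id)] == "RS")
}
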