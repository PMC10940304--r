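test_that("spec validation rejects inconsistent or unsatisfiable plans", {
  expect_error(synthetic_spec(architecture_mix = c("1i-Q" = 39)),
               "sum to n_genes")
  expect_error(synthetic_spec(architecture_mix = c("1i-Q" = -1, "2i-Q" = 41)),
               ">= 0")
  spec <- synthetic_spec(architecture_mix = c("1i-Mx" = 40))
  expect_error(generate_proteome(spec), ">= 2 domains")
  expect_error(generate_proteome(
    synthetic_spec(architecture_mix = c("bogus" = 40))), "unrecognized")
})

test_that("generators are byte-deterministic under a fixed seed", {
  spec <- synthetic_spec(seed = 99)
  p1 <- generate_proteome(spec)
  p2 <- generate_proteome(spec)
  expect_identical(p1, p2)
  g1 <- generate_genome_and_gff(spec)
  g2 <- generate_genome_and_gff(spec)
  expect_identical(g1, g2)
  c1 <- generate_cds_pair(0.1, 0.02, 100, seed = 4)
  c2 <- generate_cds_pair(0.1, 0.02, 100, seed = 4)
  expect_identical(c1, c2)
  expect_identical(generate_msa(spec), generate_msa(spec))
})

test_that("proteome filler can never form a finger or a QALGGH window", {
  spec <- synthetic_spec(seed = 3)
  prot <- generate_proteome(spec)
  n_planted <- sum(vapply(prot$truth, function(t) nrow(t$domains),
                          integer(1)))
  n_found <- sum(vapply(prot$proteins$residues,
                        function(s) nrow(scan_domains(s)), integer(1)))
  expect_equal(n_found, n_planted)   # no spurious, no missed fingers
})

test_that("CDS pairs honour their substitution plans", {
  same <- generate_cds_pair(0, 0, 150, seed = 8)
  expect_identical(same$cds_a, same$cds_b)

  syn <- generate_cds_pair(0.3, 0, 200, seed = 9)
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x)))
  expect_identical(tr(syn$cds_a), tr(syn$cds_b))   # synonymous-only
  expect_gt(syn$n_syn, 0L)
  expect_equal(syn$n_nonsyn, 0L)
  # no stop codons anywhere
  expect_false(grepl("\\*", tr(syn$cds_a)))

  expect_error(generate_cds_pair(Inf, 0, 100, seed = 1), "Jukes-Cantor")
  expect_error(generate_cds_pair(-0.1, 0, 100, seed = 1))
})

test_that("expression and DE generators plant their classes", {
  spec <- synthetic_spec(seed = 13)
  ex <- generate_expression_matrix(spec)
  expect_true(all(ex$matrix$values >= 0))
  low <- names(ex$truth)[ex$truth == "low"]
  expect_true(all(rowMeans(ex$matrix$values[low, , drop = FALSE]) < 1))
  rs <- names(ex$truth)[ex$truth == "RS-specific"]
  expect_true(all(apply(ex$matrix$values[rs, , drop = FALSE], 1,
                        function(v) names(which.max(v))) == "RS"))
  de <- generate_de_table(spec)
  expect_equal(length(de$up), 6L)
  expect_equal(length(de$down), 8L)
  s <- de_summary(de$table)
  expect_equal(c(s$n_up, s$n_down), c(6L, 8L))
})

test_that("genome layout gives every gene its promoter and GFF round-trips", {
  spec <- synthetic_spec(seed = 21)
  gg <- generate_genome_and_gff(spec)
  # half intronless
  intr <- vapply(gg$genes, function(g) count_introns(g)$n_introns, integer(1))
  expect_equal(sum(intr == 0L), spec$n_genes / 2)
  # intron lengths are positive and exons partition the span
  for (g in gg$genes) {
    ex <- g$transcripts[[1]]$exons
    expect_true(all(diff(ex$start) > 0))
    if (nrow(ex) > 1) expect_true(all(count_introns(g)$intron_lengths >= 1))
  }
  # GFF3 writer/reader round trip preserves structure
  f <- tempfile(fileext = ".gff3")
  write_gff3(gg$genes, f)
  back <- read_gff3(f)
  expect_setequal(names(back), names(gg$genes))
  for (gid in names(back)) {
    expect_equal(back[[gid]]$strand, gg$genes[[gid]]$strand)
    expect_equal(back[[gid]]$transcripts[[1]]$exons$start,
                 gg$genes[[gid]]$transcripts[[1]]$exons$start)
  }
  # truncated-promoter gene flagged with a satisfiable plan
  expect_true(gg$promoter_truth$g01$truncated)
  expect_equal(gg$promoter_truth$g01$length, 500L)
})

test_that("isoform decoys are shorter and finger-free", {
  spec <- synthetic_spec(seed = 2)
  prot <- generate_proteome(spec)
  gg <- generate_genome_and_gff(spec)
  iso <- generate_isoform_proteins(spec, prot, gg$genes)
  t2 <- iso[grepl("\\.t2$", iso$id), ]
  expect_gt(nrow(t2), 0L)
  for (i in seq_len(nrow(t2))) {
    gid <- t2$description[i]
    planted <- prot$proteins$residues[match(gid, prot$proteins$id)]
    expect_lt(nchar(t2$residues[i]), nchar(planted))
    expect_equal(nrow(scan_domains(t2$residues[i])), 0L)
  }
})

test_that("synthetic MSA separates subgroups", {
  spec <- synthetic_spec(seed = 10)
  msa <- generate_msa(spec)
  expect_true(all(nchar(msa$residues) == 120L))
  d <- p_distance(msa)
  sub <- msa$description
  intra <- d[outer(sub, sub, "==") & upper.tri(d)]
  inter <- d[outer(sub, sub, "!=") & upper.tri(d)]
  expect_lt(max(intra), min(inter))
})
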