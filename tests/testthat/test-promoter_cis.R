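mk_gene <- function(id, chr, strand, start, end) {
  structure(list(gene_id = id, chromosome = chr, strand = strand,
                 start = start, end = end, transcripts = list()),
            class = "gene_model")
}

test_that("upstream extraction follows strand and clamps at contig edges", {
  set.seed(30)
  chrom <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  genome <- data.frame(id = "chr1", description = "", residues = chrom)

  plus <- extract_upstream(genome, mk_gene("p", "chr1", "+", 5001, 5600))
  expect_equal(plus$residues, substr(chrom, 3001, 5000))
  expect_false(attr(plus, "truncated"))

  minus <- extract_upstream(genome, mk_gene("m", "chr1", "-", 200, 1000),
                            length = 2000)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 1001, 3000))))
  expect_equal(minus$residues, rc)

  trunc <- extract_upstream(genome, mk_gene("t", "chr1", "+", 501, 900))
  expect_equal(nchar(trunc$residues), 500L)
  expect_true(attr(trunc, "truncated"))

  zero <- extract_upstream(genome, mk_gene("z", "chr1", "+", 1, 900))
  expect_equal(nchar(zero$residues), 0L)
  expect_true(attr(zero, "truncated"))
})

test_that("motif scanning counts planted, degenerate, and stranded sites", {
  motifs <- data.frame(motif_id = c("ABRE", "EBOX"),
                       consensus = c("ACGTG", "CANNTG"),
                       stimulus = c("Abscisic acid", "Light"))
  bg <- strrep("T", 30)
  prom <- paste0(bg, "ACGTG", bg, "ACGTG", bg, "ACGTG", bg)
  hits <- scan_motifs(prom, motifs, gene_id = "g1")
  expect_equal(sum(hits$motif_id == "ABRE" & hits$strand == "sense"), 3L)

  # IUPAC degeneracy: CANNTG matches CAGGTG
  h2 <- scan_motifs(paste0(bg, "CAGGTG", bg), motifs, gene_id = "g1")
  expect_equal(sum(h2$motif_id == "EBOX"), 1L)

  expect_equal(nrow(scan_motifs("", motifs)), 0L)
  # motif longer than promoter: zero hits, no error
  expect_equal(nrow(scan_motifs("ACG", motifs)), 0L)

  # antisense detection with sense-strand offsets
  anti <- paste0(bg, "CACGT", bg)   # revcomp of ACGTG
  h3 <- scan_motifs(anti, motifs, gene_id = "g1")
  expect_equal(h3$strand[h3$motif_id == "ABRE"], "antisense")
  expect_equal(h3$offset[h3$motif_id == "ABRE"], 30L)
})

test_that("palindromic motifs are counted once, on the sense strand", {
  motifs <- data.frame(motif_id = "PAL", consensus = "CATATG",
                       stimulus = "Light")
  h <- scan_motifs(paste0(strrep("T", 20), "CATATG", strrep("T", 20)), motifs)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "sense")
})

test_that("a promoter and its reverse complement give mirrored hit sets", {
  motifs <- motif_table()
  set.seed(31)
  prom <- paste0(strrep("T", 25), "ACGTG", strrep("A", 25), "CAACTG",
                 strrep("T", 25))
  h <- scan_motifs(prom, motifs, gene_id = "g")
  hrc <- scan_motifs(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(prom))), motifs, gene_id = "g")
  expect_equal(table(h$motif_id), table(hrc$motif_id))
  flip <- c(sense = "antisense", antisense = "sense")
  expect_equal(sort(unname(flip[h$strand])), sort(hrc$strand))
})

test_that("count matrix aggregates by stimulus and keeps zero rows", {
  motifs <- motif_table()
  hits <- data.frame(gene_id = c("g1", "g1", "g1", "g1", "g1"),
                     motif_id = c("ABRE", "ABRE", "ABRE", "MBS", "MBS"),
                     offset = 1:5, strand = "sense")
  m <- element_count_matrix(hits, motifs, gene_ids = c("g1", "g2"))
  expect_equal(m[m$gene_id == "g1", "Abscisic acid"], 3L)
  expect_equal(m[m$gene_id == "g1", "Drought"], 2L)
  expect_equal(m[m$gene_id == "g2", "total"], 0L)
  expect_equal(sum(m$total), nrow(hits))   # count conservation
  bad <- hits; bad$motif_id[1] <- "NOPE"
  expect_error(element_count_matrix(bad, motifs), "unknown motif_id")
})

test_that("bundled motif table is valid and planted plans are recovered", {
  motifs <- motif_table()
  expect_true(all(c("ABRE", "MBS", "LTR", "DRE") %in% motifs$motif_id))
  expect_false(anyDuplicated(motifs$motif_id) > 0)
  # explicit plan including a truncated promoter and minus-strand genes
  spec <- synthetic_spec(seed = 29)
  plan <- setNames(rep(list(list(ABRE = 3L, MBS = 2L, LTR = 1L)),
                       spec$n_genes), spec$gene_ids)
  spec$promoter_motif_plan <- plan
  gg <- generate_genome_and_gff(spec)
  for (gid in c("g01", "g02", "g11")) {   # g02 minus strand, g11 truncated
    g <- gg$genes[[gid]]
    pr <- extract_upstream(gg$genome, g, 2000)
    got <- table(scan_motifs(pr, motifs, gene_id = gid)$motif_id)
    planted <- gg$promoter_truth[[gid]]$counts
    expect_equal(sort(names(planted)), sort(as.character(names(got))))
    expect_equal(as.integer(planted[sort(names(planted))]),
                 as.integer(got[sort(names(planted))]))
  }
  expect_equal(gg$genes$g02$strand, "-")
  expect_true(gg$promoter_truth$g11$truncated)
})
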