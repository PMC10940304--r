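test_that("duplicate pairs are mutual nearest neighbors only", {
  labs <- c("w", "x", "y", "z")
  d <- matrix(10, 4, 4, dimnames = list(labs, labs))
  d["w", "x"] <- d["x", "w"] <- 0.1
  d["y", "z"] <- d["z", "y"] <- 0.2
  diag(d) <- 0
  pr <- find_duplicate_pairs(d)
  expect_equal(pr$gene_a, c("w", "y"))
  expect_equal(pr$gene_b, c("x", "z"))

  # chain a-b-c where b is nearest to both: only the mutual pair remains
  labs <- c("a", "b", "c")
  d <- matrix(c(0, 1, 5, 1, 0, 2, 5, 2, 0), 3, dimnames = list(labs, labs))
  pr <- find_duplicate_pairs(d)
  expect_equal(nrow(pr), 1L)
  expect_equal(c(pr$gene_a, pr$gene_b), c("a", "b"))

  one <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_equal(nrow(find_duplicate_pairs(one)), 0L)
})

test_that("codon alignment back-translates residues and gaps", {
  aln <- codon_align(c("MK", "MK"), c("ATGAAA", "ATGAAG"))
  expect_equal(aln, c("ATGAAA", "ATGAAG"))
  gap <- codon_align(c("MKV", "M-V"), c("ATGAAAGTT", "ATGGTT"))
  expect_equal(gap[2], "ATG---GTT")
  expect_error(codon_align(c("MK", "MK"), c("ATGAA", "ATGAAG")),
               "multiple of 3")
  expect_error(codon_align(c("MK", "MM"), c("ATGAAA", "ATGAAG")),
               "codon 2")
  # trailing stop codons are tolerated and excluded
  expect_equal(codon_align(c("MK", "MK"), c("ATGAAATAA", "ATGAAGTGA")),
               c("ATGAAA", "ATGAAG"))
})

test_that("NG86 limits: identical, synonymous-only, and gap handling", {
  ident <- kaks_ng86(c(strrep("ATGAAA", 20), strrep("ATGAAA", 20)))
  expect_equal(c(ident$ka, ident$ks), c(0, 0))
  syn <- kaks_ng86(c(paste0(strrep("ATGAAA", 20), "CTA"),
                     paste0(strrep("ATGAAA", 20), "CTG")))
  expect_equal(syn$ka, 0)
  expect_gt(syn$ks, 0)
  expect_error(kaks_ng86(c("---", "---")), "no ungapped codon")
  # site conservation: S + N = 3 per counted codon
  r <- kaks_ng86(c("ATGAAACTA", "ATGAAGCTG"))
  expect_equal(r$S + r$N, 3 * r$n_codons, tolerance = 1e-12)
})

test_that("NG86 is symmetric and matches exhaustive pathway enumeration", {
  set.seed(19)
  for (i in 1:25) {
    a <- paste(replicate(8, random_codon_pair()[1]), collapse = "")
    pairs <- replicate(8, random_codon_pair(), simplify = FALSE)
    s1 <- paste(vapply(pairs, `[`, character(1), 1), collapse = "")
    s2 <- paste(vapply(pairs, `[`, character(1), 2), collapse = "")
    mine <- kaks_ng86(c(s1, s2))
    flip <- kaks_ng86(c(s2, s1))
    orac <- oracle_ng86(s1, s2)
    expect_equal(mine$ka, flip$ka, tolerance = 1e-12)
    expect_equal(mine$ks, flip$ks, tolerance = 1e-12)
    expect_equal(mine$ka, orac$ka, tolerance = 1e-12)
    expect_equal(mine$ks, orac$ks, tolerance = 1e-12)
  }
})

test_that("divergence time implements T = Ks/(2 lambda) x 1e-6", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.13), 10.0)
  expect_equal(divergence_time(0.13, lambda_ = 1.3e-8), 5.0)
  ks <- seq(0, 1, by = 0.05)
  t <- vapply(ks, divergence_time, numeric(1))
  expect_equal(t, ks / (2 * 6.5e-9) * 1e-6)
  expect_error(divergence_time(-0.1), "non-negative")
})

test_that("selection calls partition the Ka/Ks plane", {
  expect_equal(selection_call(0.1, 0.5), "purifying")
  expect_equal(selection_call(0.5, 0.5), "neutral")
  expect_equal(selection_call(0.9, 0.5), "positive")
  expect_equal(selection_call(0.2, 0.0), "undefined")
  expect_equal(selection_call(0.2, NA), "undefined")
})

test_that("pair-level wrapper dates generated pairs", {
  pr <- generate_cds_pair(0.1, 0.02, 200, seed = 3)
  cds <- data.frame(id = c("a", "b"), description = "",
                    residues = c(pr$cds_a, pr$cds_b))
  kk <- kaks_pairs(data.frame(gene_a = "a", gene_b = "b"), cds)
  expect_equal(nrow(kk), 1L)
  expect_equal(kk$t_mya, kk$ks / (2 * 6.5e-9) * 1e-6)
  expect_equal(kk$selection, "purifying")
})
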