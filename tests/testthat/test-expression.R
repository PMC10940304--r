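mk_fpkm <- function(vals, genes = paste0("g", seq_len(nrow(vals))),
                    samples = paste0("s", seq_len(ncol(vals)))) {
  fpkm_matrix(matrix(vals, nrow = length(genes),
                     dimnames = list(genes, samples)))
}

test_that("log2(FPKM + 1) maps anchor values and refuses double transform", {
  m <- mk_fpkm(matrix(c(0, 1, 3), 1, 3), genes = "g1")
  t <- log_transform(m)
  expect_equal(unname(t$values[1, ]), c(0, 1, 2))
  expect_true(t$transformed)
  expect_error(log_transform(t), "already")
  expect_error(fpkm_matrix(matrix(-1, 1, 1, dimnames = list("g", "s"))),
               "non-negative")
})

test_that("low-expression filter is strictly 'mean less than threshold'", {
  m <- mk_fpkm(matrix(c(0.5, 0.5, 1.0, 1.0, 2.0, 2.0), 3, 2, byrow = TRUE))
  f <- filter_low_expression(m)
  expect_equal(f$dropped_ids, "g1")          # mean exactly 1.0 is kept
  expect_equal(f$kept$genes, c("g2", "g3"))

  none <- filter_low_expression(m, threshold = 1e-9)
  expect_equal(none$dropped_ids, character(0))

  zero <- filter_low_expression(mk_fpkm(matrix(0, 3, 2)))
  expect_equal(length(zero$dropped_ids), 3L)
  expect_error(filter_low_expression(log_transform(m)), "raw FPKM")
})

test_that("DE summary splits significant rows by sign at strict FDR", {
  det <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    tissue = "leaf", condition_pair = "drought",
                    log2fc = c(2, -1, 0, 3),
                    fdr = c(0.01, 0.2, 0.01, 0.05))
  s <- de_summary(det)
  expect_equal(s$n_up, 1L)                   # g4 at fdr exactly 0.05 excluded
  expect_equal(s$n_down, 0L)
  expect_equal(s$up_genes, "g1")
  expect_equal(attr(s, "n_zero"), 1L)        # g3: significant but lfc = 0
  empty <- de_summary(det[0, ])
  expect_equal(nrow(empty), 0L)
  expect_error(de_summary(transform(det, fdr = c(0.1, 2, 0.1, 0.1))),
               "\\[0, 1\\]")
})

test_that("raising the FDR cutoff never shrinks the DE counts", {
  set.seed(44)
  det <- data.frame(gene_id = paste0("g", 1:60), tissue = "leaf",
                    condition_pair = "drought",
                    log2fc = runif(60, -3, 3), fdr = runif(60))
  prev_up <- 0L; prev_down <- 0L
  for (cut in c(0.01, 0.05, 0.2, 0.5, 1)) {
    s <- de_summary(det, fdr_cutoff = cut)
    expect_gte(s$n_up, prev_up)
    expect_gte(s$n_down, prev_down)
    prev_up <- s$n_up; prev_down <- s$n_down
  }
})

test_that("stage specificity scores uniform, specific, and silent genes", {
  vals <- rbind(c(10, 0, 0), c(5, 5, 5), c(0, 0, 0))
  m <- mk_fpkm(vals, genes = c("rs", "flat", "off"),
               samples = c("RS", "SS", "LS"))
  sp <- stage_specificity(m)
  expect_equal(sp$top_group[sp$gene_id == "rs"], "RS")
  expect_equal(sp$specificity[sp$gene_id == "rs"], 1)
  expect_equal(sp$specificity[sp$gene_id == "flat"], 1 / 3)
  expect_true(is.na(sp$specificity[sp$gene_id == "off"]))
  expect_equal(attr(sp, "undefined_ids"), "off")
})

test_that("filtering commutes with transform-aware filtering on raw means", {
  set.seed(45)
  vals <- matrix(rexp(60, rate = 1), 10, 6)
  m <- mk_fpkm(vals)
  f_then_t <- log_transform(filter_low_expression(m)$kept)
  keep <- rowMeans(vals) >= 1
  t_aware <- log_transform(fpkm_matrix(m$values[keep, , drop = FALSE]))
  expect_equal(f_then_t$values, t_aware$values)
})

test_that("cluster order covers every gene once", {
  set.seed(46)
  m <- log_transform(mk_fpkm(matrix(rexp(40), 8, 5)))
  ord <- cluster_order(m)
  expect_setequal(ord, m$genes)
  expect_equal(length(ord), 8L)
})
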