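test_that("the finger templates are detected and typed Q/M/D", {
  q <- scan_domains("AACAACAAAAAAAQALGGHAAAH")
  expect_equal(nrow(q), 1L)
  expect_equal(q$type_label, "Q")
  expect_equal(q$degradation, 0L)
  expect_equal(q$qalggh_window, "QALGGH")
  expect_equal(c(q$cys1, q$cys2, q$his1, q$his2), c(3L, 6L, 19L, 23L))

  m1 <- scan_domains("AACAACAAAAAAAAALGGHAAAH")
  expect_equal(m1$type_label, "M1")
  expect_equal(m1$degradation, 1L)

  d <- scan_domains("AACAACAAAAAAAQALGGHAAAG")
  expect_equal(d$type_label, "D")
  expect_true(is.na(d$his2))
  expect_equal(d$end, d$his1)   # D-type ends at the QALGGH histidine

  expect_equal(nrow(scan_domains(strrep("A", 60))), 0L)
})

test_that("scanning is a pure function with variable skeleton spacings", {
  # C-X4-C and H-X5-H extremes of the skeleton
  s <- "AACAAAACAAAAAAAQALGGHAAAAAH"
  hit <- scan_domains(s)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$cys2 - hit$cys1, 5L)
  expect_equal(hit$his2 - hit$his1, 6L)
  expect_identical(scan_domains(s), scan_domains(s))
  # X in a coordinating position can never match
  expect_equal(nrow(scan_domains(sub("^AAC", "AAX", s))), 0L)
})

test_that("degradation is Hamming distance to QALGGH with length guard", {
  expect_equal(degradation_count("QALGGH"), 0L)
  expect_equal(degradation_count("AALGGH"), 1L)
  expect_equal(degradation_count("AAAGGA"), 3L)
  expect_equal(degradation_count("qalggh"), 0L)
  expect_error(degradation_count("QALGG"), "6-residue")
})

test_that("architecture subgroups follow the finger count and tandem rules", {
  expect_equal(classify_architecture(scan_domains("AACAACAAAAAAAQALGGHAAAH")),
               "1i-Q")
  two_q <- paste0("AACAACAAAAAAAQALGGHAAAH", strrep("A", 30),
                  "AACAACAAAAAAAQALGGHAAAH")
  expect_equal(classify_architecture(scan_domains(two_q)), "2i-Q")

  t1 <- scan_domains(three_finger_protein(5, 40))
  expect_equal(classify_architecture(t1), "t1-Q")
  i3 <- scan_domains(three_finger_protein(30, 40))
  expect_equal(classify_architecture(i3), "3i-Q")

  mixed <- data.frame(start = c(0, 30, 70, 110), end = c(23, 53, 93, 133),
                      cys1 = c(3, 33, 73, 113), cys2 = c(6, 36, 76, 116),
                      his1 = c(19, 49, 89, 129), his2 = c(23, 53, 93, 133),
                      qalggh_window = "QALGGH",
                      degradation = c(0, 1, 3, 0),
                      type_label = c("Q", "M1", "M3", "Q"),
                      stringsAsFactors = FALSE)
  # linker d1->d2: 33 - 23 - 1 = 9 (tandem), others 19 (dispersed)
  expect_equal(classify_architecture(mixed), "t2-Mx")
  expect_equal(classify_architecture(mixed[1:3, ]), "t1-Mx")
  expect_error(classify_architecture(mixed[0, ]), "no C2H2 domains")
})

test_that("two tandem fingers stay 2i with a warning", {
  two_tandem <- paste0("AACAACAAAAAAAQALGGHAAAH", strrep("A", 3),
                       "AACAACAAAAAAAQALGGHAAAH")
  doms <- scan_domains(two_tandem)
  expect_equal(nrow(doms), 2L)
  expect_warning(sub <- classify_architecture(doms), "2i-Q")
  expect_equal(sub, "2i-Q")
})

test_that("converting one linker across the 11-residue cutoff flips t1/3i", {
  at12 <- scan_domains(three_finger_protein(12, 30))
  at11 <- scan_domains(three_finger_protein(11, 30))
  expect_equal(classify_architecture(at12), "3i-Q")
  expect_equal(classify_architecture(at11), "t1-Q")
  # and back again, for every linker slot
  expect_equal(classify_architecture(scan_domains(
    three_finger_protein(30, 12))), "3i-Q")
  expect_equal(classify_architecture(scan_domains(
    three_finger_protein(30, 11))), "t1-Q")
})

test_that("systematic names order by position within subgroup and are unique", {
  prot <- data.frame(
    id = c("g1", "g2", "g3"), description = "",
    residues = c(paste0("AACAACAAAAAAAQALGGHAAAH", strrep("A", 30),
                        "AACAACAAAAAAAQALGGHAAAH"),
                 paste0("AACAACAAAAAAAQALGGHAAAH", strrep("A", 30),
                        "AACAACAAAAAAAQALGGHAAAH"),
                 "AACAACAAAAAAAAALGGHAAAH"))
  archs <- scan_family(prot)
  pos <- data.frame(gene_id = c("g1", "g2", "g3"),
                    chromosome = c("chr3", "chr1", "chr1"),
                    start = c(10, 99, 5))
  nm <- assign_names(archs, pos)
  expect_equal(unname(nm[c("g2", "g1")]), c("C2H2.2i-Q.01", "C2H2.2i-Q.02"))
  expect_equal(unname(nm["g3"]), "C2H2.1i-M.01")
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(unname(assign_names(archs, pos, prefix = "SrC2H2")["g3"]),
               "SrC2H2.1i-M.01")
})

test_that("family summary partitions the proteins", {
  prot <- data.frame(
    id = c("a", "b", "c"), description = "",
    residues = c("AACAACAAAAAAAQALGGHAAAH", "AACAACAAAAAAAQALGGHAAAH",
                 "AACAACAAAAAAAAALGGHAAAH"))
  archs <- scan_family(prot)
  s <- summarize_family(archs)
  expect_equal(s$n_proteins[s$subgroup == "1i-Q"], 2L)
  expect_equal(s$n_proteins[s$subgroup == "1i-M"], 1L)
  expect_equal(sum(s$n_proteins), attr(s, "total"))
  empty <- summarize_family(list())
  expect_equal(attr(empty, "total"), 0L)
  expect_equal(nrow(empty), 0L)
})

test_that("planted proteomes are recovered perfectly across seeds", {
  for (sd in c(7L, 23L)) {
    spec <- synthetic_spec(seed = sd)
    prot <- generate_proteome(spec)
    archs <- scan_family(prot$proteins)
    for (gid in names(prot$truth)) {
      a <- archs[[gid]]; t <- prot$truth[[gid]]
      expect_identical(a$subgroup, t$subgroup)
      expect_equal(a$domains$start, t$domains$start)
      expect_equal(a$domains$end, t$domains$end)
      expect_equal(a$domains$type_label, t$domains$type_label)
      expect_equal(a$domains$degradation, t$domains$degradation)
    }
  }
})
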