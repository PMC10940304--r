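# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (grid search, exhaustive enumeration,
# least squares over all topologies) kept separate from the package's own
# implementations.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

## ---- pI grid-search oracle (independent charge model, 0.001-pH steps) ----
oracle_pi <- function(protein) {
  chars <- strsplit(toupper(protein), "")[[1]]
  pos_pk <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
  neg_pk <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  nt <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
  ct <- c(D = 4.55, E = 4.75)
  if (chars[1] %in% names(nt)) pos_pk["Nterm"] <- nt[chars[1]]
  if (chars[length(chars)] %in% names(ct)) neg_pk["Cterm"] <- ct[chars[length(chars)]]
  cnt <- function(a) sum(chars == a)
  npos <- c(1, cnt("K"), cnt("R"), cnt("H"))
  nneg <- c(1, cnt("D"), cnt("E"), cnt("C"), cnt("Y"))
  grid <- seq(0, 14, by = 0.001)
  q <- rep(0, length(grid))
  for (k in seq_along(pos_pk)) q <- q + npos[k] / (1 + 10^(grid - pos_pk[k]))
  for (k in seq_along(neg_pk)) q <- q - nneg[k] / (1 + 10^(neg_pk[k] - grid))
  grid[which.min(abs(q))]
}

## ---- NG86 exhaustive-pathway oracle --------------------------------------
GC <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")

oracle_syn_sites <- function(codon) {
  s <- 0
  for (p in 1:3) for (b in setdiff(BASES, substr(codon, p, p))) {
    mut <- codon; substr(mut, p, p) <- b
    if (GC[[mut]] != "*" && GC[[mut]] == GC[[codon]]) s <- s + 1 / 3
  }
  s
}

# recursive enumeration of every ordering of the differing positions
oracle_paths <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  recurse <- function(cur, remaining) {
    if (!length(remaining)) {
      return(list(c(sd = 0, nd = 0, blocked = 0)))
    }
    out <- list()
    for (p in remaining) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      step_syn <- GC[[cur]] == GC[[nxt]]
      step_block <- GC[[nxt]] == "*"
      for (rest in recurse(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- c(
          sd = unname(rest["sd"]) + as.numeric(step_syn),
          nd = unname(rest["nd"]) + as.numeric(!step_syn),
          blocked = max(unname(rest["blocked"]), as.numeric(step_block)))
      }
    }
    out
  }
  if (!length(pos)) return(c(sd = 0, nd = 0))
  m <- do.call(rbind, recurse(c1, pos))
  use <- m[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(sd = mean(m[use, "sd"]), nd = mean(m[use, "nd"]))
}

oracle_ng86 <- function(s1, s2) {
  cs1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  cs2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  keep <- !grepl("[-N]", cs1) & !grepl("[-N]", cs2) &
    GC[cs1] != "*" & GC[cs2] != "*"
  keep[is.na(keep)] <- FALSE
  S <- 0; Sd <- 0; Nd <- 0; n <- 0
  for (i in which(keep)) {
    S <- S + (oracle_syn_sites(cs1[i]) + oracle_syn_sites(cs2[i])) / 2
    d <- oracle_paths(cs1[i], cs2[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]; n <- n + 1
  }
  N <- 3 * n - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(ka = jc(if (N > 0) Nd / N else 0), ks = jc(if (S > 0) Sd / S else 0))
}

# random codon pair with <= max_diff substitutions, both endpoints non-stop
random_codon_pair <- function(max_diff = 2) {
  nonstop <- names(GC)[GC != "*"]
  a <- sample(nonstop, 1)
  repeat {
    b <- a
    k <- sample(0:max_diff, 1)
    if (k > 0) {
      at <- sample(1:3, k)
      for (p in at) substr(b, p, p) <- sample(setdiff(BASES, substr(b, p, p)), 1)
    }
    if (GC[[b]] != "*") return(c(a, b))
  }
}

## ---- brute-force least-squares topology oracle ---------------------------
# residual sum of squares of the LS branch-length fit of dm on a topology
ls_rss <- function(topo, dm) {
  labs <- rownames(dm)
  E <- nrow(topo$edge)
  n <- length(labs)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), E)
  for (e in seq_len(E)) {
    topo$edge.length <- replace(rep(0, E), e, 1)
    cm <- ape::cophenetic.phylo(topo)[labs, labs]
    A[, e] <- cm[cbind(pairs[, 1], pairs[, 2])]
  }
  d <- dm[cbind(pairs[, 1], pairs[, 2])]
  fit <- lm.fit(A, d)
  sum(fit$residuals^2)
}

# best topology among all unrooted topologies (n <= 6 kept tractable)
oracle_best_topology <- function(dm) {
  labs <- rownames(dm)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(topos, ls_rss, numeric(1), dm = dm)
  topos[[which.min(rss)]]
}

random_additive_matrix <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = tr, dm = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
}

## ---- misc helpers --------------------------------------------------------
# support value of the bipartition separating `tips` on an unrooted tree
bipartition_support <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  tips <- sort(tips)
  comp <- sort(setdiff(labs, tips))
  for (i in seq_along(parts)) {
    s <- sort(labs[parts[[i]]])
    if (identical(s, tips) || identical(s, comp)) {
      return(as.numeric(tree$node.label[i]))
    }
  }
  NA_real_
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

# minimal two-gene GFF3 used across io tests
demo_gff_lines <- function() {
  c("##gff-version 3",
    paste("chr1", "src", "gene", "1000", "2000", ".", "+", ".", "ID=gA",
          sep = "\t"),
    paste("chr1", "src", "mRNA", "1000", "2000", ".", "+", ".",
          "ID=gA.t1;Parent=gA", sep = "\t"),
    paste("chr1", "src", "exon", "1000", "1400", ".", "+", ".",
          "Parent=gA.t1", sep = "\t"),
    paste("chr1", "src", "exon", "1600", "2000", ".", "+", ".",
          "Parent=gA.t1", sep = "\t"),
    paste("chr1", "src", "CDS", "1000", "1400", ".", "+", ".",
          "Parent=gA.t1", sep = "\t"),
    paste("chr1", "src", "CDS", "1600", "2000", ".", "+", ".",
          "Parent=gA.t1", sep = "\t"),
    paste("chr2", "src", "gene", "500", "1500", ".", "-", ".", "ID=gB",
          sep = "\t"),
    paste("chr2", "src", "mRNA", "500", "1500", ".", "-", ".",
          "ID=gB.t1;Parent=gB", sep = "\t"),
    paste("chr2", "src", "exon", "500", "1500", ".", "-", ".",
          "Parent=gB.t1", sep = "\t"),
    paste("chr2", "src", "CDS", "500", "1500", ".", "-", ".",
          "Parent=gB.t1", sep = "\t"),
    paste("chr2", "src", "mRNA", "500", "900", ".", "-", ".",
          "ID=gB.t2;Parent=gB", sep = "\t"),
    paste("chr2", "src", "exon", "500", "900", ".", "-", ".",
          "Parent=gB.t2", sep = "\t"),
    paste("chr2", "src", "CDS", "500", "900", ".", "-", ".",
          "Parent=gB.t2", sep = "\t"))
}

write_temp_gff <- function(lines = demo_gff_lines()) {
  f <- tempfile(fileext = ".gff3")
  writeLines(lines, f)
  f
}

# a protein with three fingers whose two linkers are controlled exactly
three_finger_protein <- function(linker1, linker2) {
  finger <- "NNCNNCNNNNNNNQALGGHNNNH"   # c1=3, c2=6, h1=19, h2=23
  filler <- function(n) paste(rep("N", n), collapse = "")
  paste0("NNNNN", finger, filler(linker1 - 2), finger,
         filler(linker2 - 2), finger, "NNNNN")
}

# scalar PH85 topological distance between two trees
topo_dist <- function(a, b) {
  if (ape::is.rooted(a)) a <- ape::unroot(a)
  if (ape::is.rooted(b)) b <- ape::unroot(b)
  as.numeric(ape::dist.topo(a, b))[1]
}
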