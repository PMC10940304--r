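#' Uncorrected p-distance matrix from a protein MSA
#'
#' Pairwise-deletion distances: for each sequence pair, columns with a gap
#' (`-`) in either sequence are excluded and the distance is the fraction
#' of mismatching remaining columns. Pairwise deletion (rather than
#' complete deletion) is the default because family-wide MSAs are gap-rich.
#'
#' @param msa Aligned sequences: a sequence table from [read_fasta()] or a
#'   named character vector; all sequences must have equal length.
#' @return A symmetric numeric matrix with zero diagonal and the sequence
#'   ids as dimnames.
#' @export
p_distance <- function(msa) {
  if (is.data.frame(msa)) msa <- setNames(msa$residues, msa$id)
  n <- length(msa)
  if (n < 2L) stop("need at least 2 aligned sequences")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length (got ",
         paste(unique(lens), collapse = ", "), ")")
  }
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between ", names(msa)[i], " and ",
             names(msa)[j])
      }
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion and
#' branch-length formulas. Negative branch lengths are clamped to zero
#' with the deficit transferred to the sibling branch, so the joined pair's
#' mutual distance is preserved (standard practice).
#'
#' @param dm Symmetric distance matrix with labelled dimnames (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  labels <- rownames(dm)
  n <- length(labels)
  if (is.null(labels) || n < 3L) stop("neighbor joining needs >= 3 labelled taxa")
  stopifnot(isTRUE(all.equal(dm, t(dm))), all(is.finite(dm)))
  fmt <- function(x) sprintf("%.15g", x)
  node <- .sanitize_newick_label(labels)   # growing newick fragments
  D <- dm
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    node <- c(node[keep], new_lab)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt(la), node[2], fmt(lb),
                 node[3], fmt(lc))
  ape::read.tree(text = nwk)
}

#' Bootstrap-supported neighbor-joining tree from an MSA
#'
#' Builds the full-data NJ tree from [p_distance()], then resamples
#' alignment columns with replacement `n_replicates` times; the support of
#' each internal bipartition of the full tree is the fraction of replicate
#' trees that contain it. Supports (in `[0, 1]`) are stored in
#' `tree$node.label`.
#'
#' @param msa Aligned sequences (see [p_distance()]).
#' @param n_replicates Number of bootstrap replicates (>= 1). The family
#'   analysis convention is 500.
#' @param seed Integer seed; the resampling is fully reproducible.
#' @return An [ape::phylo] tree with numeric support values as node labels.
#' @export
bootstrap_support <- function(msa, n_replicates = 500L, seed = 1L) {
  if (is.data.frame(msa)) msa <- setNames(msa$residues, msa$id)
  stopifnot(n_replicates >= 1L)
  full <- nj_tree(p_distance(msa))
  chars <- do.call(rbind, strsplit(toupper(msa), ""))
  L <- ncol(chars)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    bs <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
    reps[[b]] <- nj_tree(p_distance(setNames(bs, rownames(chars))))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- counts / n_replicates
  full
}
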