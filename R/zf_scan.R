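#' @section Domain model:
#' A C2H2 zinc finger is detected from its metal-coordinating skeleton
#' `C-X(2,4)-C-X12-H` with an optional second histidine 4-6 residues after
#' the first (`X(3-5)`). The plant-specific QALGGH hexapeptide is located as
#' the minimum-Hamming 6-mer window between the second cysteine and the
#' first histidine (the window may end on that histidine, which then serves
#' as both motif H and skeleton H). The F/L anchor positions of the long
#' consensus are recorded but not required, because degraded (M-type)
#' fingers routinely lose them.
#' @name zf_scan
NULL

QALGGH <- "QALGGH"

#' Hamming distance of a 6-residue window to QALGGH
#'
#' @param window A 6-character string.
#' @return Integer in `[0, 6]`: the number of degraded positions.
#' @export
degradation_count <- function(window) {
  if (!is.character(window) || length(window) != 1L || nchar(window) != 6L) {
    stop("window must be a single 6-residue string")
  }
  sum(strsplit(toupper(window), "")[[1]] != strsplit(QALGGH, "")[[1]])
}

.empty_domains <- function() {
  data.frame(start = integer(0), end = integer(0), cys1 = integer(0),
             cys2 = integer(0), his1 = integer(0), his2 = integer(0),
             qalggh_window = character(0), degradation = integer(0),
             type_label = character(0), stringsAsFactors = FALSE)
}

#' Scan a protein for C2H2 zinc-finger domains
#'
#' Greedy left-to-right scan for non-overlapping matches of the
#' coordinating skeleton `C-X(2,4)-C-X12-H(-X(3,5)-H)`. After a domain is
#' accepted, scanning resumes after its last coordinating residue. Domains
#' whose best QALGGH window is fully degraded (Hamming distance 6) are
#' rejected and reported in `attr(, "rejected")`. `X` can never occupy a
#' coordinating position (it is not C or H), so ambiguous residues are
#' conservatively unmatched.
#'
#' @param protein A protein sequence as a single character string, or a
#'   one-row sequence table from [read_fasta()].
#' @return A data frame of domains with 0-based half-open `start`/`end` on
#'   the protein, 1-based coordinating residue positions `cys1`, `cys2`,
#'   `his1`, `his2` (`NA` for D-type), the `qalggh_window`, its
#'   `degradation` count, and `type_label` in Q, M1-M5, D.
#' @export
scan_domains <- function(protein) {
  if (is.data.frame(protein)) protein <- protein$residues[1L]
  stopifnot(is.character(protein), length(protein) == 1L)
  chars <- strsplit(toupper(protein), "")[[1]]
  n <- length(chars)
  qal <- strsplit(QALGGH, "")[[1]]
  rows <- list()
  rejected <- 0L
  pos <- 1L
  while (pos <= n - 15L) {
    if (chars[pos] != "C") { pos <- pos + 1L; next }
    accepted <- FALSE
    for (c2 in (pos + 3L):(pos + 5L)) {       # 2-4 intervening residues
      if (c2 > n || chars[c2] != "C") next
      h1 <- c2 + 13L                          # exactly 12 intervening
      if (h1 > n || chars[h1] != "H") next
      # best QALGGH window in the span (c2, h1], leftmost on ties
      starts <- (c2 + 1L):(h1 - 5L)
      dist <- vapply(starts, function(s) sum(chars[s:(s + 5L)] != qal),
                     numeric(1))
      w <- starts[which.min(dist)]
      deg <- as.integer(min(dist))
      if (deg >= 6L) { rejected <- rejected + 1L; next }
      h2 <- NA_integer_
      for (k in (h1 + 4L):(h1 + 6L)) {        # 3-5 intervening residues
        if (k <= n && chars[k] == "H") { h2 <- k; break }
      }
      last <- if (is.na(h2)) h1 else h2
      type <- if (is.na(h2)) "D" else if (deg == 0L) "Q" else paste0("M", deg)
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos - 1L, end = last, cys1 = pos, cys2 = c2, his1 = h1,
        his2 = h2, qalggh_window = paste(chars[w:(w + 5L)], collapse = ""),
        degradation = deg, type_label = type, stringsAsFactors = FALSE)
      pos <- last + 1L
      accepted <- TRUE
      break
    }
    if (!accepted) pos <- pos + 1L
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_domains()
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

.type_class <- function(type_label) {
  ifelse(type_label == "Q", "Q", ifelse(type_label == "D", "D", "M"))
}

.linker_lengths <- function(domains) {
  k <- nrow(domains)
  if (k < 2L) return(integer(0))
  last <- ifelse(is.na(domains$his2), domains$his1, domains$his2)
  as.integer(domains$cys1[-1L] - last[-k] - 1L)
}

#' Classify a protein's zinc-finger architecture
#'
#' Subgroup rules: proteins with three or more fingers of which at least
#' two are tandem (linker of at most 11 residues between the last
#' coordinating histidine of one finger and the first cysteine of the next)
#' are `t1-` (exactly three fingers) or `t2-` (four or more); otherwise the
#' finger count gives `1i`/`2i`/`3i`/`4i` (and `<n>i` beyond four). The
#' type suffix is `Q` when all fingers are Q-type, `M` when all are
#' M-type, `D` when all are D-type, and `Mx` for any mixture. Two-finger
#' proteins are labelled `2i-*` regardless of spacing (tandem classes are
#' defined from three fingers up); a tandem two-finger protein triggers a
#' warning so such genes can be reviewed.
#'
#' @param domains A domain table from [scan_domains()] (at least one row).
#' @param tandem_max_linker Largest linker still counted as tandem
#'   (default 11 residues).
#' @return The subgroup label, e.g. `"1i-Q"`, `"3i-Mx"`, `"t2-Mx"`.
#' @export
classify_architecture <- function(domains, tandem_max_linker = 11L) {
  if (!nrow(domains)) stop("cannot classify a protein with no C2H2 domains")
  k <- nrow(domains)
  linkers <- .linker_lengths(domains)
  tandem <- linkers <= tandem_max_linker
  classes <- unique(.type_class(domains$type_label))
  suffix <- if (length(classes) > 1L) "Mx" else classes
  if (any(tandem) && k >= 3L) {
    group <- if (k == 3L) "t1" else "t2"
  } else {
    if (any(tandem) && k == 2L) {
      warning("two tandem fingers (linker <= 11) labelled 2i-", suffix,
              "; tandem subgroups are defined from three fingers up")
    }
    group <- paste0(k, "i")
  }
  paste0(group, "-", suffix)
}

#' Build the full architecture record for one protein
#'
#' @param protein_id Identifier of the protein (typically the gene id).
#' @param residues Protein sequence string.
#' @param tandem_max_linker Largest linker still counted as tandem.
#' @return A `protein_architecture`: domains, linker lengths, tandem flags,
#'   and subgroup label; `systematic_name` is filled by [assign_names()].
#' @export
protein_architecture <- function(protein_id, residues,
                                 tandem_max_linker = 11L) {
  domains <- scan_domains(residues)
  linkers <- .linker_lengths(domains)
  structure(list(
    protein_id = protein_id,
    domains = domains,
    linker_lengths = linkers,
    tandem_flags = linkers <= tandem_max_linker,
    subgroup = if (nrow(domains))
      classify_architecture(domains, tandem_max_linker) else NA_character_,
    systematic_name = NA_character_
  ), class = "protein_architecture")
}

#' Scan a whole proteome and classify every member
#'
#' @param proteins A sequence table from [read_fasta()].
#' @param keep_empty Keep proteins in which no domain was found
#'   (default drops them, as non-family members).
#' @param tandem_max_linker Largest linker still counted as tandem.
#' @return A named list of `protein_architecture` objects.
#' @export
scan_family <- function(proteins, keep_empty = FALSE,
                        tandem_max_linker = 11L) {
  archs <- lapply(seq_len(nrow(proteins)), function(i) {
    protein_architecture(proteins$id[i], proteins$residues[i],
                         tandem_max_linker)
  })
  names(archs) <- proteins$id
  if (!keep_empty) {
    archs <- Filter(function(a) nrow(a$domains) > 0L, archs)
  }
  archs
}

#' Assign systematic family names
#'
#' Within each subgroup, genes are ordered by chromosome then start
#' coordinate and numbered with zero-padded ordinals:
#' `<prefix>.<subgroup>.<NN>` (e.g. `C2H2.2i-Q.01`).
#'
#' @param architectures Named list of `protein_architecture` objects.
#' @param gene_positions Data frame with columns `gene_id`, `chromosome`,
#'   `start` covering every architecture.
#' @param prefix Name prefix, default `"C2H2"` (use e.g. `"SrC2H2"` for a
#'   species-tagged family).
#' @return Named character vector: gene id to systematic name.
#' @export
assign_names <- function(architectures, gene_positions, prefix = "C2H2") {
  ids <- vapply(architectures, `[[`, character(1), "protein_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id: ", ids[duplicated(ids)][1L])
  miss <- setdiff(ids, gene_positions$gene_id)
  if (length(miss)) stop("no genomic position for gene ", miss[1L])
  sub <- vapply(architectures, `[[`, character(1), "subgroup")
  pos <- gene_positions[match(ids, gene_positions$gene_id), , drop = FALSE]
  out <- character(length(ids))
  names(out) <- ids
  for (s in unique(sub)) {
    sel <- which(sub == s)
    ord <- sel[order(pos$chromosome[sel], pos$start[sel], ids[sel])]
    width <- max(2L, nchar(length(ord)))
    out[ord] <- sprintf("%s.%s.%0*d", prefix, s, width, seq_along(ord))
  }
  stopifnot(!anyDuplicated(out))
  out
}

#' Summarize a family by subgroup
#'
#' @param architectures Named list of `protein_architecture` objects.
#' @return A data frame `subgroup`, `n_proteins` (sorted by subgroup) with
#'   the family total in `attr(, "total")`; the counts partition the input.
#' @export
summarize_family <- function(architectures) {
  sub <- vapply(architectures, `[[`, character(1), "subgroup")
  if (!length(sub)) {
    out <- data.frame(subgroup = character(0), n_proteins = integer(0))
  } else {
    tab <- table(sub)
    out <- data.frame(subgroup = names(tab), n_proteins = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(out$subgroup), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "total") <- length(sub)
  out
}
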