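.check_protein_chars <- function(chars, allow_x = FALSE) {
  allowed <- names(.AA_MASS)
  if (allow_x) allowed <- c(allowed, "X")
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  invisible(chars)
}

.residue_chars <- function(protein) {
  if (is.data.frame(protein)) protein <- protein$residues[1L]
  strsplit(toupper(protein), "")[[1]]
}

#' Molecular weight of a protein (Daltons)
#'
#' Sum of average residue masses plus one water, the ProtParam convention.
#' `X` residues are an error unless `x_fallback = TRUE`, in which case the
#' mean residue mass is used for them.
#'
#' @param protein Sequence string or one-row sequence table.
#' @param x_fallback Substitute the mean residue mass for `X`?
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(protein, x_fallback = FALSE) {
  chars <- .residue_chars(protein)
  if (!length(chars)) stop("empty protein sequence")
  .check_protein_chars(chars, allow_x = x_fallback)
  res <- .AA_MASS - .WATER_MASS
  if (x_fallback) res <- c(res, X = mean(res))
  sum(res[chars]) + .WATER_MASS
}

# net charge at a given pH, Henderson-Hasselbalch over ionizable groups,
# with residue-specific terminal pKa where Bjellqvist defines one
.net_charge <- function(chars, ph) {
  counts <- table(factor(chars, levels = names(.AA_MASS)))
  first <- chars[1L]
  last <- chars[length(chars)]
  pos <- c(.PKA_POSITIVE["Nterm"],
           setNames(.PKA_POSITIVE[c("K", "R", "H")], c("K", "R", "H")))
  if (first %in% names(.PKA_NTERMINAL)) pos["Nterm"] <- .PKA_NTERMINAL[first]
  npos <- c(Nterm = 1, K = as.numeric(counts["K"]),
            R = as.numeric(counts["R"]), H = as.numeric(counts["H"]))
  neg <- c(.PKA_NEGATIVE["Cterm"],
           setNames(.PKA_NEGATIVE[c("D", "E", "C", "Y")], c("D", "E", "C", "Y")))
  if (last %in% names(.PKA_CTERMINAL)) neg["Cterm"] <- .PKA_CTERMINAL[last]
  nneg <- c(Cterm = 1, D = as.numeric(counts["D"]), E = as.numeric(counts["E"]),
            C = as.numeric(counts["C"]), Y = as.numeric(counts["Y"]))
  sum(npos / (1 + 10^(ph - pos))) - sum(nneg / (1 + 10^(neg - ph)))
}

#' Isoelectric point of a protein
#'
#' Bisection on the Henderson-Hasselbalch net-charge function over the
#' ionizable groups (D, E, C, Y, H, K, R and both termini) with the
#' Bjellqvist pKa set, iterated until `|charge| < 1e-4`.
#'
#' @param protein Sequence string or one-row sequence table.
#' @return The pH of zero net charge, in `(0, 14)`.
#' @export
isoelectric_point <- function(protein) {
  chars <- .residue_chars(protein)
  if (!length(chars)) stop("empty protein sequence")
  chars <- chars[chars != "X"]
  .check_protein_chars(chars)
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- .net_charge(chars, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over residues; negative values indicate
#' a hydrophilic protein. `X` residues are excluded from the denominator
#' when `x_fallback = TRUE`.
#'
#' @inheritParams molecular_weight
#' @return GRAVY score in `[-4.5, 4.5]`.
#' @export
gravy <- function(protein, x_fallback = FALSE) {
  chars <- .residue_chars(protein)
  if (!length(chars)) stop("empty protein sequence")
  .check_protein_chars(chars, allow_x = x_fallback)
  if (x_fallback) chars <- chars[chars != "X"]
  mean(.KYTE_DOOLITTLE[chars])
}

#' Instability index (Guruprasad et al. 1990)
#'
#' `(10/L) * sum of DIWV weights over consecutive dipeptides`. Values above
#' 40.00 classify the protein as unstable.
#'
#' @inheritParams molecular_weight
#' @return The instability index.
#' @export
instability_index <- function(protein, x_fallback = FALSE) {
  chars <- .residue_chars(protein)
  if (length(chars) < 2L) stop("instability index needs length >= 2")
  .check_protein_chars(chars, allow_x = x_fallback)
  if (x_fallback) chars <- chars[chars != "X"]
  L <- length(chars)
  w <- sum(.DIWV[cbind(chars[-L], chars[-1L])])
  10 / L * w
}

#' Aliphatic index (Ikai 1980)
#'
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with mole-percent
#' compositions.
#'
#' @inheritParams molecular_weight
#' @return The aliphatic index.
#' @export
aliphatic_index <- function(protein, x_fallback = FALSE) {
  chars <- .residue_chars(protein)
  if (!length(chars)) stop("empty protein sequence")
  .check_protein_chars(chars, allow_x = x_fallback)
  if (x_fallback) chars <- chars[chars != "X"]
  molp <- function(a) 100 * mean(chars == a)
  molp("A") + 2.9 * molp("V") + 3.9 * (molp("I") + molp("L"))
}

#' Full physicochemical profile of one or more proteins
#'
#' @param proteins Sequence table from [read_fasta()].
#' @param x_fallback Tolerate `X` residues (mean-mass / excluded-residue
#'   fallbacks)?
#' @return Data frame: `id`, `length`, `mw`, `pi`, `gravy`, `instability`,
#'   `aliphatic`, `unstable` (instability strictly above 40.00).
#' @export
physchem_profile <- function(proteins, x_fallback = FALSE) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$residues[i]
    inst <- instability_index(s, x_fallback)
    data.frame(id = proteins$id[i], length = nchar(s),
               mw = molecular_weight(s, x_fallback),
               pi = isoelectric_point(s),
               gravy = gravy(s, x_fallback),
               instability = inst,
               aliphatic = aliphatic_index(s, x_fallback),
               unstable = inst > 40.00,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
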