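---
title: "Methods: genome-wide C2H2 zinc-finger family analysis with zfscan"
author: "zfscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide C2H2 zinc-finger family analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfscan)
```

# Scope and model

Plant C2H2 zinc-finger proteins (C2H2-ZFPs) are transcription factors
whose DNA-binding fingers fold around a Zn²⁺ ion coordinated by two
cysteines and two histidines. Genome-wide surveys of this family follow a
stereotyped battery: identify the family members, type each finger, group
proteins by finger architecture, profile their physicochemical
properties, build a family phylogeny, date recent duplicates from
synonymous divergence, scan promoters for cis-regulatory elements, and
filter/summarize expression. `zfscan` implements that battery as plain R
functions over standard file formats (FASTA, GFF3, newick, TSV), plus a
synthetic-data generator whose outputs carry full ground truth.

## Finger detection

The scanner requires only the metal-coordinating skeleton

    C - X(2,4) - C - X12 - H [ - X(3,5) - H ]

scanned greedily left to right; after a match is accepted, scanning
resumes after its last coordinating residue, so fingers never overlap.
The classical long consensus additionally fixes interior phenylalanine
and leucine anchors, but degraded (M-type) fingers routinely lose them,
so requiring those anchors would silently drop exactly the fingers the
typing scheme is meant to count; the anchors are therefore not enforced.

Within the thirteen residues ending at the first histidine, the
hexapeptide window with minimum Hamming distance to `QALGGH` (leftmost on
ties) defines the motif window and its *degradation* count. The window
may end on the skeleton histidine itself: in the canonical Q-type
template `X2-C-X2-C-X7-QALGGH-X3-H` the motif's own H *is* the first
coordinating histidine, and we adopt that reading consistently. Types
follow the degradation count: 0 = `Q`, 1–5 = `M1`–`M5`; a finger whose
second histidine is absent is `D` regardless of degradation. A window
degraded at all six positions leaves the finger untyped: the match is
rejected and counted in `attr(, "rejected")`. Z-type fingers (defined by
alternative C2–H spacings) are not classified: their spacing ranges are
not fixed by the classification literature we follow, so such fingers
surface as ordinary skeleton matches typed by their QALGGH integrity.
Ambiguous residues (`X`) can never occupy a coordinating position, which
is the conservative behaviour for fragmentary proteomes.

## Architecture classification and naming

Linkers are counted strictly between the last coordinating histidine of
one finger and the first cysteine of the next; a linker of **at most 11
residues** makes the pair tandem. Proteins with ≥ 3 fingers of which at
least two are tandem are `t1` (exactly 3) or `t2` (≥ 4); otherwise the
finger count gives `1i`–`4i` (`<n>i` beyond four). The suffix is `Q`,
`M`, or `D` when all fingers share one type class and `Mx` otherwise.
Two-finger proteins are always `2i-*`: the tandem classes are defined
from three fingers up, and rather than invent an undefined two-finger
tandem class we keep the `2i` label and emit a warning naming such
proteins so they can be reviewed. The tandem cutoff is exposed as
`tandem_max_linker` but its default, 11, is the family convention and is
what the boundary tests pin down (a 12→11 linker change flips `3i-*` to
`t1-*`).

Systematic names are `<prefix>.<subgroup>.<NN>` with ordinals assigned by
(chromosome, start) within each subgroup; ties and the prefix (default
`"C2H2"`) are deterministic, so naming is a pure function of the inputs.

## Physicochemical profile

Five ProtParam-convention properties per protein: molecular weight from
*average* residue masses plus one water; GRAVY as mean Kyte–Doolittle
hydropathy; instability index `10/L · Σ DIWV(xᵢ, xᵢ₊₁)` with the
Guruprasad dipeptide table, classified unstable strictly above 40.00;
aliphatic index `X(A) + 2.9·X(V) + 3.9·(X(I)+X(L))` in mole percent; and
isoelectric point as the root of the Henderson–Hasselbalch net-charge
function over D, E, C, Y, H, K, R and both termini with the Bjellqvist
pKa set (the set ProtParam uses, so family-level ranges are comparable
with ProtParam output). The pI root is found by bisection on pH ∈ [0, 14]
to |charge| < 10⁻⁴; the tests compare it against a 0.001-pH grid-search
oracle. `X` residues are an error by default; with `x_fallback = TRUE`
they take the mean residue mass for MW and are excluded from the
GRAVY/instability/aliphatic denominators and from the charge model.

## Phylogeny

Distances are uncorrected p-distances with pairwise deletion: columns
with a gap in either sequence of a pair are excluded for that pair only.
Pairwise (rather than complete) deletion is the default because
family-wide MSAs are gap-rich and complete deletion can discard most
columns; no substitution correction is applied by default since the
family convention we reproduce used the alignment directly. The NJ
implementation is the standard Saitou–Nei agglomeration (Q-criterion,
usual branch-length formulas). Negative branch-length estimates are
clamped to zero with the deficit transferred to the sibling branch, so
the joined pair's mutual distance is preserved — the standard practical
fix; it never triggers on additive inputs, which the tests reproduce to
1e-9. Bootstrap support resamples alignment columns with replacement;
the support of each internal bipartition of the full-data tree is the
fraction of replicate trees containing it. The replicate count is a
parameter: 500 is the textual convention of the analysis we follow, but
published figure captions in this literature also use 1,000, so no
default silently resolves that ambiguity — `pipeline_config(bootstrap=)`
and the CLI flag make it explicit (the demo uses 200 as its documented
demo-scale choice). MSA *construction* is out of scope: the package
consumes an aligned FASTA.

## Duplicates, Ka/Ks, and dating

"Most similar proteins" is operationalized as mutual nearest neighbors on
the protein distance matrix (ties broken lexicographically), which makes
pair selection a distance statement rather than a tree-topology
statement and guarantees each gene joins at most one pair. Codon
alignments are back-translations of the protein alignment (gap → `---`),
validated codon-by-codon against the CDS translation.

Ka/Ks follows Nei–Gojobori (1986): per-codon synonymous site fractions
averaged over the two sequences; observed differences partitioned by
equal-weight averaging over all minimal mutational pathways; Jukes–Cantor
correction `d = -(3/4)·ln(1 - (4/3)p)`, undefined (NA) at p ≥ 3/4. Two
conventions are fixed explicitly: a point change that creates a stop
codon counts as nonsynonymous in site counting (so every codon
contributes exactly S + N = 3 sites), and pathways passing through a stop
codon are excluded from the averaging, falling back to all pathways in
the (three-difference) corner case where every pathway is blocked. Codons
containing gaps, `N`, or a stop are skipped entirely. The tests hold the
implementation to an exhaustive pathway-enumeration oracle at 1e-12.

Divergence time is `T = Ks/(2λ) × 10⁻⁶` million years with λ the
synonymous substitution rate per site per generation, default
6.5 × 10⁻⁹ (a rate commonly used for asterid dating); λ is configurable.
Selection calls are purifying/neutral/positive for Ka/Ks </=/> 1 and
undefined when Ks is zero or the correction diverges.

## Promoters

The promoter is the 2-kb window strictly upstream of the *gene* feature
(not the start codon), since gene models are what a GFF reliably
provides; on the minus strand this is the window after the gene's
file-coordinate end, reverse-complemented, so promoters are always
reported 5'→3' relative to transcription. Windows are truncated, and
flagged, at contig edges — a gene 500 bp from the contig start yields a
500-bp promoter, not an error.

Element definitions are *data*: a TSV of (motif_id, IUPAC consensus,
stimulus). The bundled default covers the elements this literature
reports (ABRE, CGTCA-motif, AuxRR-core, TGA-element, GARE-motif, P-box,
TATC-box, TCA-element, SARE, DRE, MBS, LTR, TC-rich repeats), but these
consensi are working definitions, not the internal matrices of any
prediction server — counts on real genomes are table-dependent and
should be read as such. Matching is IUPAC-degenerate on both strands,
leftmost-greedy non-overlapping per motif and strand; a palindromic
consensus is scanned on the sense strand only so a site is never counted
twice as its own reverse complement. Whether servers used historically
for such counts allow overlaps or double-count strands is not published;
our convention is explicit and tested, not claimed equivalent.

## Expression

Filtering uses the strict rule "arithmetic mean across all samples less
than the threshold" (default 1 FPKM): a mean exactly at the threshold is
kept. The filter refuses transformed input, which enforces the intended
order (filter on raw FPKM, then log2(FPKM+1)); the equivalence of
"filter-then-transform" with a transform-aware filter on raw means is
property-tested. DE summaries count `fdr < cutoff` (strict, default
0.05) split by log2FC sign; a significant row with log2FC exactly 0
counts in neither direction and is reported separately. Stage
specificity is computed on raw FPKM as (max group mean)/(sum of group
means), so a uniform gene scores 1/n groups and a single-stage gene
scores 1; all-zero genes are flagged undefined. Heatmap-style output is
an ordered TSV, rows ordered by complete-linkage clustering under
correlation distance of the transformed rows (constant rows, where the
correlation is undefined, are appended in input order). Upstream read
processing (QC, alignment, assembly, DE fitting) is consumed, not
reproduced: inputs are an FPKM TSV and a DE TSV.

# The synthetic study conditions

The generator (`synthetic_spec()` defaults) defines the package's
reference conditions:

* **Proteome** — 40 genes in 10 subgroups × 4 (`1i-Q`, `1i-M`, `2i-Q`,
  `2i-M`, `2i-Mx`, `3i-M`, `3i-Mx`, `4i-Mx`, `t1-M`, `t2-Mx`), a
  1/5-scale echo of a ~200-gene plant family's subgroup structure.
  Planted fingers use the canonical templates with randomized C–C
  (2–4) and H–H (3–5) spacings; tandem linkers are drawn from 2–11
  residues and dispersed linkers from 12–30. Filler sequence is drawn
  from an alphabet excluding C, H, Q, A, L, G — filler can therefore
  never complete a skeleton nor beat a planted QALGGH window, which
  guarantees zero spurious fingers by construction. This is simpler and
  stronger than spacing-aware filler placement, and it is itself tested
  (found = planted, exactly).
* **Genome/GFF** — one gene per 2.1-kb-plus slot so that each 2-kb
  upstream window is exactly the constructed promoter; alternating genes
  on the minus strand; the first gene of each chromosome sits 500 bp
  from the contig start to exercise promoter truncation; half the genes
  are intronless (exons 100–300 bp, introns 50–200 bp); every fifth
  multi-exon gene carries a shorter second transcript whose protein is a
  finger-free decoy, so longest-isoform selection is actually exercised.
* **Promoters** — A/T-only background; every bundled motif consensus
  contains at least one C/G-obligate position, so background alone can
  never match; planted occurrences (about a quarter on the antisense
  strand for non-palindromic motifs) are separated by ≥ 10 bp.
* **CDS pairs** — five pairs at (Ks, Ka) targets (0.1, 0.02) and one
  synonymous-only pair at Ks 0.2, 300 codons each. Substitution counts
  are Binomial draws at the Jukes–Cantor-inverted target proportions;
  synonymous changes go to third positions of four-fold codons and
  nonsynonymous changes to first/second positions of distinct codons,
  never creating stops. Binomial (not deterministic) counts mean the
  estimator is held to its real Monte-Carlo scatter (mean within 3·SE
  over 20 seeds) instead of a rounding artifact.
* **Expression** — seven developmental-stage samples (RS, SS, LS, LV,
  LB, LIF, LPF); 6 root-seedling-specific genes (50–200 FPKM in RS,
  < 0.5 elsewhere), 10 low-expression genes (all values < 0.6, mean
  < 1), the rest broad (2–50 FPKM); a DE table with 6 up- and
  8 down-regulated genes at FDR < 0.05 under a drought contrast.
* **MSA** — alignment construction is out of scope, so the demo uses a
  synthetic stand-in: one random 120-column reference per subgroup, each
  member = reference + 5 substitutions. Subgroups are cleanly separated
  (max within < min between), which is what makes the monophyly and
  bootstrap checks sharp.

All randomness flows from one integer seed (per-generator fixed
offsets), so a fixed seed makes every output byte-identical — the demo
directory is bit-reproducible, which the acceptance-style tests verify
with checksums.

**What passing these conditions does and does not show.** Recovery is
exact because the generator is noiseless by design: real proteomes
contain fragmentary proteins, nonstandard spacings, and Z-type fingers;
real promoters have G/C-rich backgrounds where consensus matching has a
nonzero false-positive rate and counts depend on the motif table; real
MSAs have gaps and saturation. The synthetic results validate the
*implementations* (and their edge conventions), not field performance on
any particular genome.

# Numerical and scale choices

* pI bisection: 100 iterations max, stop at |charge| < 1e-4; agreement
  with a 0.001-pH grid oracle within 1e-3 is the tested contract.
* NJ tie-breaks: first minimal Q-cell in column-major order;
  deterministic. Branch lengths are serialized at 15 significant digits,
  so additive matrices round-trip to well below the 1e-9 test tolerance.
* Topology testing: the brute-force least-squares oracle enumerates all
  unrooted topologies for 5–6 taxa; at 7–8 taxa the suite instead uses
  the fact that an additive matrix has a unique tree realization (exact
  cophenetic reproduction certifies the topology) plus an independent NJ
  implementation as cross-check — full enumeration at 8 taxa (10,395
  topologies) buys no additional certainty for additive inputs.
* Test/demo problem sizes — 40-gene family, 120-column MSA, 300-codon
  pairs, 20-seed recovery runs, 100–200 bootstrap replicates in tests and
  demo — are the package's chosen reference scale: large enough that
  every rule fires (all 10 subgroups, both strands, truncation, ties),
  small enough to iterate on quickly.

# Known limitations

* Z-type fingers are not typed; they are reported by QALGGH integrity.
* Promoter counts are only as meaningful as the motif table supplied;
  the bundled table is a curated default, not a server reimplementation.
* NG86 is the method of record for Ka/Ks; maximum-likelihood (GY94-type)
  estimation is out of scope, as are genome-scale synteny-based
  duplication typing, MSA construction, and figure rendering — tables
  and newick are the products.
* `read_gff3` expects well-formed GFF3 (gene/mRNA/exon/CDS with
  ID/Parent); GTF is not supported, and transcripts lacking CDS features
  are rejected rather than guessed at.
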