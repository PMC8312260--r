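---
title: "Methods: comparative evolution of proglucagon and its receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative evolution of proglucagon and its receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcgevo)
```

# Scope and scientific question

The mammalian proglucagon gene (*Gcg*) encodes three related hormones —
glucagon, GLP-1, and GLP-2 — released from a single precursor by
tissue-specific prohormone convertase cleavage, and each hormone signals
through its own class B1 G-protein-coupled receptor (*Gcgr*, *Glp1r*,
*Glp2r*). Comparative questions about this system take a common shape: which
peptide regions of the precursor tolerate substitutions and which do not; are
the proteolytic processing sites intact in every species; do the receptor
genes sit in conserved genomic neighborhoods; do the three receptors
experience different intensities of purifying selection; and do substitutions
at different sites co-occur on the same lineages, as expected for
compensatory change. `gcgevo` implements each of these analyses as a small,
deterministic, testable operation on standard inputs (aligned FASTA, Newick,
TSV tables), together with seeded simulators that generate every input with
known ground truth.

# The precursor region model

Peptide regions are 1-based inclusive intervals on the ungapped mature human
precursor (`region_map()`). The shipped defaults follow the standard human
annotation: GRPP 1–30, glicentin 1–69, glucagon 33–61, miniglucagon 51–61
(glucagon 19–29), OXM 33–69, IP-1 62–69, GLP-1(1–37) 72–108, GLP-1(7–37)
78–108, IP-2 111–122, GLP-2 126–158, and MPGF 72–158, over a 160-residue
mature precursor preceded by a 20-residue signal peptide. The constructor
enforces the structural facts these intervals encode: miniglucagon is nested
in glucagon, OXM is exactly glucagon plus IP-1, and glicentin contains GRPP,
glucagon, and IP-1. Signal peptides are handled as a single fixed offset
rather than per-species prediction, since full-precursor alignments place
every downstream coordinate 20 columns to the right.

Two conventions are worth stating explicitly. First, IP-2's boundaries vary
slightly across annotation sources; the default (111–122) is the standard
human one, and every interval is overridable through the YAML region map.
Second, GLP-2 is taken as 33 residues (126–158); published summaries of this
system are not fully consistent about whether GLP-2 has 32 or 33 positions,
and the shipped default keeps the 33-residue convention rather than trying to
resolve the discrepancy.

Regions are lifted onto alignment columns through the reference row: the
columns holding the reference's ungapped residues `start..end` are returned
in order, so gaps in the reference shift downstream regions correctly and a
region extending past the reference's ungapped length is an error rather than
a silent truncation.

## Processing sites

Prohormone convertase cleavage requires basic residues; the checks here are
deliberately motif-level, not machine-learned cleavage prediction. A
processing site (`site_spec()`) is a set of region-relative positions plus a
required residue class (default K/R). The two bundled sites are the dibasic
pair at glucagon 17–18, required for the secondary processing of glucagon to
miniglucagon, and the basic pair immediately following GLP-1(1–37) (MPGF
positions 38–39), required for C-terminal GLP-1 maturation. A species is
`intact` when every checked position carries a residue of the class,
`disrupted` when a non-class residue is present, and `indeterminate` when any
checked position is a gap — gaps in genome-derived alignments usually mean
incomplete assembly, and treating them as disruptions would manufacture
biology out of missing data.

# Variability statistics

Variability is reference-anchored: each species is compared to the human row
over a region's columns, and columns where either sequence has a gap are
excluded from substitution calls (they are tallied separately). The summary
bundle per region reports the number of species compared, the number
identical to the reference, the range of per-species difference counts, the
mean count among differing species, the per-residue substitution rate, the
number of positions accepting at least one substitution, and the number of
distinct substitution types (`"X<pos>Y"` strings, region-relative by default
with a precursor-numbering mode).

The per-residue rate divides the total number of substitutions over **all**
compared species by `n_species * peptide_len`. The alternative reading —
dividing the mean among differing species by peptide length — does not
reproduce the classically reported value pattern for the well-conserved
peptides (glucagon ≈ 0.013 with 161 species compared), while the
all-species reading does; published per-residue values for some of the faster
regions are internally inconsistent with either reading, and the package
implements the definition rather than forcing agreement with any particular
printed cell.

Consensus composition (`consensus_matrix()`) is the tabular core of a
sequence logo: per column, the frequency of each amino acid plus the gap
fraction, summing to one.

# Substitution impact scores

External variant-effect services cannot be vendored into a reproducible
package, so `gcgevo` ships two transparent alignment-based scores with the
same two-flag category semantics, and an import path
(`read_impact_calls()`) so externally computed annotations can be slotted in
unchanged.

* **Tolerance score** — a pseudocounted column frequency,
  `(count(Y) + 1) / (n + 20)`, computed on the column with the focal
  species' own residue removed (no self-support). Substitutions below
  0.05 are flagged; the cutoff matches the conventional operating point of
  frequency-based tolerance classifiers.
* **Matrix delta** — the mean over column residues `a` of
  `BLOSUM62[a, Y] − BLOSUM62[a, ref]`; deltas at or below −2.5 are flagged,
  again the conventional operating point for alignment-score deltas.

A substitution is `both_flagged` only when both flags fire; this conjunction
is the package's "predicted functional consequence" category, and it is the
only category that can promote a receptor site to `impact_flagged`. These
scores make no claim of numeric agreement with dedicated tools; recovery
tests only require that substitutions injected at deeply conserved columns
are flagged with probability approaching one as column depth grows, which
both scores guarantee by construction.

# Genomic neighborhoods

The synteny module classifies each species' record into `both_flanks`,
`left_only`, `right_only`, or `none` from the flank presence flags alone.
Contig-edge information never changes the class; it sets a *caveat* flag when
a missing flank coincides with a contig edge or when a non-conserved class
sits on a short contig (≤ 3 genes by default — assembly fragmentation, not
rearrangement, is then the parsimonious explanation). Translocation evidence
(a missing flank found elsewhere in the assembly, as with the rodent
*Glp1r*–*Saysd1* separation) is carried as an optional boolean column and
surfaces as a `relocated` annotation, because the input schema deliberately
contains per-gene records rather than whole-genome gene tables.

# Selection intensity

Between-gene differences in purifying selection are tested at desk scale
with the Nei–Gojobori (1986) counting estimator plus a column permutation
test, rather than a branch-site likelihood machinery. The claim consumed
downstream is the *ordering* and significance of between-gene constraint,
which counting methods test adequately; exact published dN/dS values from
likelihood methods are explicitly not reproduction targets.

Site counts per codon put each of the nine single-nucleotide mutants in the
synonymous class only when it preserves the amino acid and is not a stop
(mutations to stops are nonsynonymous), so counts always sum to 3. Pairwise
difference counts average over all orderings of single-nucleotide steps,
excluding pathways through stop codons; in the (unobserved for sense–sense
pairs) case where every pathway is blocked, all pathways are used. Proportions
are corrected with the Jukes–Cantor transform `d = −(3/4)ln(1 − 4p/3)`,
`NA` at saturation (`p ≥ 3/4`). Gene-level `omega` is the ratio of mean dN to
mean dS over all unordered pairs; pairs with `dS = 0` or saturated distances
are dropped from the means with a reported count, avoiding infinite ratios.

The permutation test pools the codon columns of both genes and reassigns
them to two pseudo-genes of the original lengths, recomputing the omega
difference each time; `p = (1 + #(null ≥ observed)) / (n_perm + 1)` is valid
and conservative by construction. Columns, not species, are permuted: the
two genes share their species set and tree, so shuffling columns preserves
the tree-induced covariance of pairwise distances approximately, whereas
shuffling species would destroy it. This approximation is documented rather
than corrected; the null-calibration test (uniform p under equal omega)
checks that it is adequate at the study conditions.

# Co-substitution screening

Compensatory evolution leaves pairs of sites substituting on the same
branches. The screen maps each protein column to a branch set by Fitch
parsimony (codon inputs are translated first, since reported co-evolving
pairs are amino-acid sites) and tests every pair of non-empty maps for
branch-set overlap with a one-sided hypergeometric test, BH-corrected over
tested pairs; pairs are reported at `q ≤ 0.05` or concordance
`both/(both + i_only + j_only) ≥ 0.5`. The 0.5 concordance default carries
over the conventional 50% posterior threshold of Bayesian co-evolution
screens into this deterministic setting.

Ancestral ambiguity is resolved deterministically: the root takes the
alphabetically smallest member of its down-pass set, and every other node
inherits its parent's resolved state when admissible, otherwise takes its
own set's smallest member. Parent-inheritance is what makes the resolved
branch-set size equal the Fitch score exactly (a per-node "smallest member"
rule without inheritance can inflate changes above the minimum); the
alphabetical tie-break makes results reproducible. Because a single minimal
reconstruction is chosen rather than sampling all of them, reported
co-occurrence is a lower bound. Gap leaves carry the full state set (missing
data). Multifurcating trees are not supported; inputs are binary rooted
trees.

# The simulators and what they do (and do not) emulate

Every pipeline input has a seeded generator, and the defaults are the study
conditions used by the package's tests:

* **Tree** — Yule (pure birth), rescaled to unit height, so `base_rate`
  reads as expected substitutions per site root-to-tip.
* **Precursor alignment** — Poisson substitutions per site per branch with
  region multipliers (defaults: glucagon 0.5, GLP-1(7–37) 0.4, GLP-2 3.0 —
  slow hormone cores and a fast GLP-2, matching the qualitative ordering
  observed in mammals; base rate 0.3). Replacements are uniform over the 19
  other residues: a substitution event always changes the residue, and
  multiple events on one branch collapse to one visible change. There is no
  empirical exchangeability matrix and no indel process — impact-score and
  rate-ordering recovery only require a conservation contrast, not realism —
  so passing tests demonstrate correct bookkeeping and calibration, not that
  real proglucagon alignments look like these.
* **Codon alignment** — nucleotide proposals at 0.4/site with
  transition:transversion weight 2.0; stop-creating proposals rejected,
  synonymous proposals accepted, nonsynonymous accepted with probability
  `min(1, omega)`. This is a proposal/acceptance scheme, not an exact M0
  process, so recovery tests check ordering across the omega ladder
  0.05 < 0.10 < 0.25 (the Glp1r < Gcgr < Glp2r constraint ordering) and
  interval containment, never exact omega equality.
* **Neighborhoods** — per side, truncation with probability *t* (contig
  edge set, short contig) else relocation with probability *r* (no edge,
  flank recorded elsewhere); the expected both-flank fraction is
  `((1−t)(1−r))^2`.
* **Disruptions** — targeted residue replacement at a processing site for
  chosen species, leaving all other cells untouched.

## Problem sizes used in the checks

The test suite runs at sizes chosen to give stable statistics on one CPU:
rate-ordering recovery over 100 replicates of 64 taxa; omega-difference
detection over 20 replicates of 16 taxa × 300 codons at 200 permutations;
null calibration over 100 replicates of 8 taxa × 80 codons at 99
permutations; co-substitution recovery over 100 replicates of 64 taxa × 30
columns with one coupled pair (large trees resolve parsimony maps well;
small trees misplace changes often enough that a coupled pair can drop below
perfect concordance); false-positive control over 20 independent-evolution
replicates of 16 taxa × 100 columns; and neighborhood calibration at
n = 1000, t = 0.2. Enumeration oracles (all 61 sense codons, 100 random
codon pairs, exhaustive ancestral labelings on 100 random 5-taxon fixtures)
are recomputed from an independent genetic-code source inside the tests.

# Numerical and policy choices

* Permutation p-values use the add-one estimator and a user-supplied seed;
  results are bit-for-bit reproducible.
* BH FDR at 0.05 is the multiple-testing policy for the co-substitution
  screen. The between-gene omega test reports raw permutation p for up to
  three gene pairs (the three receptor comparisons); beyond that the
  pipeline BH-adjusts across pairs.
* Species exclusion (e.g. the highly divergent platypus) is a single global
  config list applied before every stage, so "excluding" equals deleting the
  rows.
* Degenerate inputs have defined behavior: invariant columns map to empty
  branch sets (not errors), all-identical codon alignments give `omega = NA`,
  all-gap columns and empty difference tables are errors, and a gap at a
  checked processing site is `indeterminate`, never `disrupted`.

# Known limitations

The impact scores are stand-ins with the right operating semantics, not
reimplementations of published variant-effect predictors. The NG86 +
permutation test measures average constraint, not branch-specific selection,
and cannot detect episodic selection. The co-substitution screen's
single-reconstruction parsimony mapping undercounts co-occurrence on deep or
poorly resolved trees. The simulators omit indels, empirical amino-acid
exchangeabilities, and codon frequency bias. Real-data headline numbers from
large genome panels therefore are not reproduction targets for the synthetic
pipeline; the package's claims are about the correctness and calibration of
the operations themselves.
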