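---
title: "Methods: strain-specific markers and absolute quantification"
author: "strainmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-specific markers and absolute quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strainmark` turns a collection of annotated bacterial genomes into
strain-specific qPCR assays: pangenome partitioning to find genes carried
by exactly one strain, a nucleotide-level specificity screen, primer design
with in-silico PCR certification, and absolute quantification from
standard curves. This vignette records the models, the tunable parameters
and the design decisions, in the package's own terms.

## Gene family clustering

Genes are clustered at the protein level by a single-pass greedy centroid
algorithm. All genes are sorted by amino-acid length (descending, ties by
genome id then gene tag) and each joins the earliest-founded centroid for
which

* global-alignment identity >= `min_identity` (default **0.90**), where
  identity = identical aligned residues / alignment columns, terminal gaps
  excluded (alignment scores +1/−1, gap −2, free terminal gaps);
* length ratio (shorter/longer) >= **0.7**; and
* the aligned region spans >= 70% of the shorter protein.

Otherwise the gene founds a new centroid. The third condition exists
because free-end-gap alignments of unrelated proteins can produce short,
high-identity chance overlaps; without a span requirement such overlaps
would occasionally merge unrelated families. A 6-mer inverted index over
centroids prunes candidates: only centroids sharing at least
`max(3, 5%)` of the query's 6-mers are aligned, which cannot exclude a
genuine >= 90% match (such a pair shares roughly half its 6-mers in
expectation) but eliminates almost all chance pairs.

Greedy centroid clustering replaces the multi-tool cascade
(CD-HIT, all-vs-all BLASTP, MCL) used by conventional pangenome pipelines;
it is deterministic, dependency-free and adequate at the scale this package
targets. For fidelity studies an externally produced
`gene_presence_absence.csv` can be imported instead
(`read_presence_absence_csv()`), including its paralog cells (collapsed to
a single presence) and its variable statistic columns (recognised by
name).

## Pangenome partition

With N genomes and a family carried by k of them, the category is:
**unique** if k = 1 (checked first), else by fraction k/N: **core**
>= 0.99, **soft-core** [0.95, 0.99), **shell** [0.15, 0.95), **cloud**
below 0.15. The unique check precedes the fractional bands because for
large N a single-carrier family falls below any published cloud lower
bound; treating cloud's lower bound as exclusive-zero with unique carved
out makes the five categories exhaustive for every N. Rarefaction curves
report, for random genome orderings and each prefix size m, the mean
number of families present in at least one (total) and in all (conserved)
of the first m genomes; an `exhaustive` flag enumerates all N! orderings
for small collections (used by the tests against a subset-enumeration
oracle).

## Nucleotide specificity screen

Protein-level uniqueness does not guarantee nucleotide-level uniqueness,
so candidates are re-screened against every contig of every non-target
genome, and optionally against an external FASTA database standing in for
a comprehensive nucleotide collection. The engine seeds on exact 11-mers
(both strands, 2-bit rolling encoding with a bitmap prefilter), extends
ungapped with an X-drop rule (drop-off 20), and re-aligns promising
extensions with a local affine-gap DP over a padded window (scores
+2/−3, gap open 5, extend 2 — the classic BLASTN parameterisation). A
subject **hit** is

* any local alignment of >= 60 columns at >= 80% identity, or
* any exact match of >= 25 bp,

and a candidate passes a tier only with zero hits. The hit definition is a
package default, configurable via `screen_params()` and recorded in every
report: the criterion used by the original BLASTN-based screens (e-value?
coverage?) is not published, so this is a declared stand-in rather than a
reconstruction. The gapped stage only runs when the ungapped extension is
promising (>= 60% of the minimum hit length, or a long exact run): chance
11-mer seeds die within a few bases and cannot meet the hit definition, a
property the tests verify by comparing verdicts against a full
Smith–Waterman oracle under the same definition. Marker selection keeps
candidates whose executed tiers all passed and whose length is >=
`min_len` (default **300 bp**, room for a 100–250 bp amplicon with primer
flanks), sorted by length.

## Melting temperature and primer design

Duplex Tm uses the unified nearest-neighbor dinucleotide
enthalpy/entropy set (SantaLucia 1998) with terminal initiation terms, the
entropic salt correction 0.368 (N−1) ln[Na+], and
Tm = 1000 ΔH / (ΔS + R ln(C/4)) − 273.15 for a non-self-complementary
duplex with both strands equimolar (defaults: 50 mM monovalent, 400 nM
total primer). Regression fixtures computed with an independent
implementation of the same parameter set pin the model in the tests.

`enumerate_pairs()` scans every window of 17–24 nt and keeps those with
GC in [0.40, 0.60], homopolymers <= 4, Tm in [57, 63] °C and a 3'-anchored
self-complementary run <= 4; windows are paired when the product length
lies in [100, 250] bp and |ΔTm| <= 3 °C. Pairs with a 3'-anchored
cross-complementary run longer than `max_3p_self + 2` are rejected
outright (a hard gate rather than a penalty term — the run is anchored at
a 3' terminus, so the test reduces to one fixed-string search per
direction and enumeration stays tractable on markers that admit tens of
thousands of pairs). Surviving pairs are ranked by

penalty = |Tm_f − 60| + |Tm_r − 60| + 10 (|GC_f − 0.5| + |GC_r − 0.5|)
        + 0.5 (hairpin_f + hairpin_r + self3'_f + self3'_r) + |ΔTm|,

with deterministic tie-breaks; only the ordering is meaningful. The
published assays report a proprietary "Primer Score" with no public
definition, so reports carry this penalty instead, clearly labelled.

**In-silico PCR** declares a primer bound where it matches the template
with <= 2 mismatches and its 3'-terminal 3 bases exact (both tunable); an
amplicon is any convergent, opposed pair of bound sites within 2000 bp,
and both orientations of the pair are searched so markers integrated on
either strand are found. `certify_specificity()` passes a pair only if the
collection yields exactly one amplicon, in the target genome, of exactly
the designed length. The mismatch tolerance is a deliberately conservative
model of PCR annealing — real polymerases are not characterised by a
sharp mismatch count — which is why certification, not binding, is the
contract.

## Core SNPs and phylogeny

For every strict-core family (>= 99% carriage; soft-core is excluded
under a strict reading of "core genome"), each genome's copy is globally
aligned to the reference genome's copy (+1/−1, gap −2, free terminal
gaps); the longest copy is used when a genome carries paralogs, and
families missing from a genome are skipped with a warning. Reference
columns where every genome shows an unambiguous A/C/G/T (sites containing
gaps or N are dropped first) and exactly two distinct bases occur are
concatenated in (family, reference position) order. Pairwise distances
are Hamming distances on these strings. Because the in-package generator
plants substitutions only, the gene-wise alignments are gapless at the
optimum and the called distances equal the planted ones exactly; with real
data the gene-level alignment is an approximation to whole-genome mapping
and inherits its usual blind spots (regions absent from annotation,
recombination, repeats).

Neighbor joining follows Saitou–Nei with the standard Q criterion, ties
broken by the lowest (row, column) pair, negative branch lengths clamped
to zero, and a trifurcating root as is conventional for unrooted NJ trees;
the result is an `ape::phylo`. On additive matrices the path-length matrix
of the output reproduces the input (tested to 1e−9, and cross-checked
against `ape::nj`).

## qPCR standard curves and absolute quantification

Calibration points (log10 CFU, Ct) are fitted by unweighted OLS;
R² is the squared Pearson correlation; the linear range is the span of
input levels; efficiency E(%) = (10^(−1/slope) − 1) × 100 is reported to
one decimal, matching the precision conventionally printed. A fitted slope
>= 0 is a hard error (no amplification relationship), as is a series with
fewer than three distinct levels. One published slope/efficiency pair
(−3.5901 / 90.0%) recomputes to 89.9% under the same formula — presumed
rounding at the source; the formula is applied as printed, not adjusted.
Unknowns invert the curve (CFU per reaction = 10^((Ct − intercept)/slope))
and scale to CFU per gram by (elution / template) × dilution / mass. These
conversion factors are not stated in published protocols, so they are
explicit inputs with defaults (100 µL elution, 2 µL template — the
template volume of a standard 20 µL reaction — 0.1 g sample, no extra
dilution) recorded in every report. Samples whose implied log10 CFU falls
outside the calibration range are flagged rather than rejected.

## The synthetic collection generator

`simulate_collection()` emulates the structure such a pipeline consumes:
a gene pool split into core/shell/cloud/unique compartments, per-genome
diverged core copies, and planted strain-unique genes. Defaults are the
package's reference study condition: 20 genomes, 300 core + 500 shell +
800 cloud families, 5 unique genes per genome, core substitution rate
0.003 per site per genome, gene lengths log-normal (mean 900 bp, sd
500 bp) clamped to [150, 6000] bp, genes concatenated with 50–300 bp
random spacers into 1–5 contigs, and genes written as proper ORFs (ATG,
no internal stops, trailing stop). All randomness flows through one RNG
stream keyed on the seed, so a fixed seed reproduces the collection byte
for byte.

Shell and cloud carriage counts are drawn from the binomial carriage model
but constrained inside their frequency bands, with accessory families
required to have at least two carriers: a single-carrier shell or cloud
draw would be indistinguishable from a planted unique gene and would make
the planted truth ambiguous. This constraint implies cloud families need a
collection of at least 14 genomes (so that two carriers stay below 15%);
smaller configurations must set `cloud_families = 0`, and the
configuration validator says so.

Planted unique genes carry a strong guarantee: no 15-mer of a unique gene
(either strand) occurs in any other emitted gene sequence, including the
other genomes' unique genes. At realistic pool sizes a random gene
violates this many times over by chance alone, so the generator does not
reject whole genes; it builds each gene codon by codon, redrawing any
codon that would complete a forbidden 15-mer (the forbidden set is a
sorted 2-bit-encoded index of every pool k-mer, both strands, queried by
vectorised binary search). The result is a random-looking ORF with an
exact disjointness certificate — a clean positive control for the
screening stage, verified independently in the tests by brute-force k-mer
intersection. Intergenic spacers are excluded from the constraint: they
are not gene sequences, and a chance 15-mer in a spacer cannot produce a
hit under the hit definition.

What the generator does **not** emulate: realistic codon usage and GC
content, rearrangements, horizontal transfer, paralog expansion,
pseudogenes, assembly or sequencing error. Passing the recovery tests
therefore demonstrates the pipeline's internal consistency on collections
with known truth, not its performance on real assemblies, where
annotation quality and repeat content dominate.

## Problem sizes and numerical choices

The test suite exercises the full marker-recovery chain at the reference
condition (20 genomes, 1700 accessory+core families, 100 planted unique
genes) and the remaining operations on 4–14 genome collections; the suite
completes in a few minutes on one CPU. Tolerances: NJ path lengths and
quantification round trips to 1e−9; the curve refit to 1e−10; Tm
regression fixtures to 1e−5 (the printed precision of the frozen oracle
values). Determinism contracts (clustering order rules, penalty
tie-breaks, seeded rarefaction and simulation) are asserted by re-running
the operation and requiring identical output.

## Known limitations

* Greedy centroid clustering is order-dependent by design; it matches the
  declared sort order exactly but is not identical to Roary's MCL
  clusters on borderline families.
* The screening engine's seeds require an exact 11-mer; alignments near
  the 60 bp / 80% identity boundary whose mismatches are adversarially
  spaced can in principle evade seeding. The Smith–Waterman agreement
  tests sample substitution-mutated homologies, where seeding is
  effectively certain.
* Hairpin and dimer metrics are contiguous-complementarity run lengths,
  not thermodynamic folding energies.
* Gene-level SNP calling cannot see intergenic SNPs and depends on the
  annotation agreeing across genomes; it is a desk-scale stand-in for
  whole-genome alignment.
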