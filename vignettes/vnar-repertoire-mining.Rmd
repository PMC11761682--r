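---
title: "Mining immunized VNAR repertoires from paired-end amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining immunized VNAR repertoires from paired-end amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnarmine)
```

## The problem

Sharks mount heavy-chain-only antibody responses whose antigen-binding
domain, the VNAR (~11 kDa), is attractive for therapeutic and imaging
applications. After immunization, a phage-display library built from the
animal's B cells contains antigen-specific clones diluted in an enormous
background. The classical route to find them -- biopanning -- is laborious
and samples the library shallowly. `vnarmine` implements the computational
alternative: sequence the library deeply, reconstruct the amino-acid
repertoire, and nominate candidate binders *in silico* by comparing the
antigen-immunized library against a library from the same platform
immunized with an unrelated antigen. Clonal expansion driven by the
immunization should enrich antigen-specific lineages in the target library
only, so clusters of related CDR3s that are both prevalent and
target-unique are strong candidates -- without a single round of panning.

## Pipeline model and assumptions

The read-processing model assumes primer-anchored amplicons: each sequenced
molecule is `flank5 + insert + flank3`, with the VNAR coding sequence in a
fixed reading frame starting immediately after the 5' anchor. Stages:

1. **Quality trim** (3' sliding window, width 4, mean Phred >= 20 by
   default; a terminal base below the threshold is always dropped), with
   optional adapter read-through removal at <= 1 mismatch. The upstream
   assay delegates this to a standard trimmer; any monotone 3' rule
   suffices, and this one is documented and configurable.
2. **Overlap merge** of each pair: the reverse mate is reverse-complemented
   and the overlap maximizing matching bases is chosen among overlaps of at
   least `min_overlap_nt` (default 10) with mismatch fraction at most
   `max_overlap_mismatch_frac` (default 0.25); equally good overlaps
   resolve to the shortest, and disagreeing bases to the higher-quality
   read. Templates whose self-overlap mimics a longer perfect overlap are
   intrinsically ambiguous for any match-maximizing merger; the tests
   enumerate them explicitly.
3. **Flank filter**: the insert is the interval strictly between the first
   occurrence of the conserved 5' anchor (Hamming matching, default exact)
   and the first subsequent occurrence of the 3' anchor; both orientations
   are searched. Amplicon designs differ in whether a single conserved
   sequence anchors the insert upstream, downstream, or on both sides, so
   the two flanks are independent configuration values: `flank5` defaults
   to the platform's conserved anchor, `flank3` to the synthetic anchor
   used by the simulator and may be empty (the insert then runs to the end
   of the merged amplicon).
4. **Translation** at frame 0 with the standard genetic code (no
   initiator-codon special-casing). Inserts failing frame, containing a
   codon with N, containing a stop codon, or translating outside 80--220 aa
   are rejected with a named reason. Codons with N are rejected rather than
   translated as X because dereplication on amino acids must not merge
   distinct molecules through wildcards. The length bounds accommodate
   hyper-elongated CDR3 loops of over 80 aa while excluding truncations.

Dereplication collates identical proteins and ranks by read count, ties
broken by ascending sequence so that ranks -- and any "top N" selection
derived from them -- are deterministic.

## Region annotation and subtypes

VNARs carry CDR1 and CDR3 (no CDR2) plus two hypervariable loops, HV2 and
HV4. Non-canonical cysteines outside the conserved immunoglobulin-fold pair
define subtypes: Type I (framework 2 and 4 cysteines disulfide-bonded to a
CDR3 pair), Type II (a CDR1--CDR3 cysteine pair), Type III (like Type II
with a conserved CDR1 motif), Type IV (canonical pair only).

Annotation is anchor-based rather than fixed-position, because CDR length
variation shifts absolute coordinates: the first canonical cysteine is the
first C in the FR1 window (positions 15--30, 0-based), the second is the
last C in a framework window at offsets +45..+55 from the first, and FR4
starts at the last match of the FR4 motif (default `DGAGT`, <= 1 mismatch)
after that cysteine. CDR3 is everything strictly between the second
canonical cysteine and FR4. The second anchor's window is keyed to the
*first* cysteine rather than to the FR4 motif: CDR3 cysteines (Types
I--III) sit between FR3b and FR4, so a window keyed to FR4 would routinely
capture a CDR3 cysteine instead of the canonical one. This choice assumes
indel-free frameworks between the two anchors -- true of this platform's
fixed scaffold and of the simulator, approximate for heavily indel-edited
real repertoires (a known limitation). An `absolute` mode with fixed
template coordinates is available for strict reproduction on clean
scaffolds. The exact FR4 start motif varies with the germline scaffold and
is not fixed across platforms; `DGAGT` is a configurable synthetic
default, as is the CDR1 conservation marker (`W`) that separates Type III
from Type II.

The subtype call is a pure rule table over cysteine-count flags, proven
exhaustive and mutually exclusive by enumeration in the tests. An odd CDR3
cysteine count alongside FR2/FR4 cysteines is left unclassified rather than
forced into Type I, because Type I is defined by *paired* CDR3 cysteines.

CDR3 length statistics use midpoint-exclusive linear-interpolation
quartiles (`quantile type 6`; no single quartile convention is canonical,
so one is fixed and documented), with box-plot whiskers at 1.5 IQR clamped
to observed values.

## Clonotypes, trees and differential mining

"Homology" is implemented as percent identity: the two terms are used
interchangeably in this field and no substitution matrix is assumed. Equal
lengths use Hamming identity; unequal lengths use a parameter-free global
alignment (match 1, mismatch 0, gap 0, normalized by the longer length),
used only outside the equal-length mining path. All thresholds are strict
(`>`); at a threshold of 100 every unique sequence is its own cluster.

Clonotypes and clades are **single-linkage components** of the graph whose
edges join pairs above the threshold. Clades could equally be defined by
cutting a drawn tree; threshold components are adopted because they are
unambiguous and directly testable, and match the neighborhood-expansion
semantics of "find every sequence with a similar clonotype" (complete
linkage is available as an option). UPGMA trees (average linkage, distance
`1 - identity/100`) are built for reporting only, and serialize to
canonical Newick with siblings ordered by smallest descendant label so
output is byte-reproducible.

Differential mining pools the top `N = 2000` most prevalent records *per
library* -- selecting per library before pooling keeps the two libraries'
depth comparable; a pooled-selection mode is a configuration change --
restricted to one CDR3 length, clusters the pooled CDR3s at the clonotype
threshold (default 85), flags clades with zero control-library members as
target-unique, and nominates those with at least `K = 30` unique
sequences. The floor is inclusive and counts *unique sequences* rather
than raw members, which makes it invariant to read depth; both the floor
and its semantics are configurable. Each candidate's representative is its
highest-count target-library full-length sequence, ties broken by
lexicographic order everywhere so reports are deterministic.

## The synthetic-data generator

No accession is available for the study's sequencing data, so a simulator
defines the study conditions and supplies ground truth. It emulates:

- **Abundance skew**: each unique variant's read count is 1 with
  probability 0.909 (the observed singleton fraction), otherwise drawn from
  a power-law tail (exponent 1.8) capped at 1e4, reproducing both the
  rare-clone mass and the handful of ~1e4-repeat clones.
- **Clonal expansion**: lineages are point-mutation clouds around a seed
  (1 + Poisson(rate x length) substitutions per variant, default rate
  0.01/residue). Substitutions never touch cysteines, the FR4 motif or the
  CDR1 marker, and never introduce C or W, so a lineage keeps its subtype
  and, at the default rate, its clonotype. Lineage sizes are Zipf
  (exponent 1, cap 25); with 2000 background lineages per library this
  yields roughly 13,000 unique variants and 5e4 reads per library.
  The cap sits below the clade floor K = 30 deliberately: candidate
  discovery in recovery experiments is then attributable to the planted
  lineages, which default to four target-specific lineages of 40 unique
  14-aa-CDR3 variants.
- **Subtype structure**: lineage subtypes are drawn Type-II-dominant
  (I/II/III/IV = 0.15/0.60/0.15/0.10).
- **CDR3 lengths**: round(Normal(15, 3.7)) clamped to [5, 25] -- placing
  the 1.5 IQR whiskers at about 5 and 25 aa -- plus ultralong outliers
  (probability 0.002, uniform 60--80 aa).
- **Sharing**: five small shared lineages (cap 4 variants) appear in both
  libraries with independently drawn counts, keeping sequence sharing well
  under 0.2% per library; planted lineages never appear in the control.
- **Sequencing**: uniform random codons (codon usage is irrelevant to an
  amino-acid analysis but must be deterministic), flanks attached, one
  forward/reverse pair per molecule copy, substitution-only errors
  (default 1e-3; indels would break the fixed-frame logic and are out of
  scope), constant Q30 qualities (trimming is not the object under test).

What the simulator does **not** model: realistic Illumina error profiles,
PCR amplification bias, chimeras, indels, germline V(D)J structure, or any
sequence-level relationship between "antigen-specific" and background
clones beyond library membership. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct under its stated
assumptions, not that it is robust to every artifact of real sequencing
data.

## Numerical and reproducibility choices

Strict thresholds are evaluated with an epsilon-shifted integer mismatch
bound so floating-point rounding cannot flip a boundary case. All ordering
ties (ranks, representatives, cluster ids, candidate ranking, Newick
siblings) resolve lexicographically. The pipeline driver fans a single seed
out to fixed per-stage offsets, and two runs with the same seed and
configuration produce byte-identical outputs, verified checksum-by-checksum
in the tests.

Problem sizes used by the test-suite and acceptance runs are the package's
defaults: ~2000 lineages and ~5e4 reads per library for round-trip checks,
10,000 scaffolds for classifier exactness, 200 sequences against the
brute-force clustering oracle, and an exhaustive enumeration of all
two-letter templates of lengths 8--12 for the merge oracle.

## A worked example

```{r example, eval = FALSE}
library(vnarmine)

gen <- generator_config(sequencing_error_rate = 0, rng_seed = 1L)
pair <- generate_library_pair(gen)
target <- annotate_repertoire(pair$target)
control <- annotate_repertoire(pair$control)

abundance_summary(target)            # singleton fraction ~0.91
library_overlap(target, control)     # sharing < 0.2%

report <- mine_differential_clades(target, control, pipeline_config(), 14L)
rank_candidates(report)              # the four planted clades
```

The numbered scripts under `analysis/` run the same stages end to end over
simulated FASTQ and write their tables under `results/`.
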