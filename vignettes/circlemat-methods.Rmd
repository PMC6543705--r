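---
title: "Methods: circular contigs, mini-circles, decontamination and supermatrix curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular contigs, mini-circles, decontamination and supermatrix curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlemat)
```

# Scope and model

`circlemat` implements the computational pipeline used to characterise
extrachromosomal circular DNA in a highly fragmented parasite genome assembly
and to curate a phylogenomic supermatrix from contaminated transcriptomes.
The package has three layers:

1. **circle analysis** — classification of assembly contigs as circular,
   pool splitting, low-complexity masking, length-periodicity estimation,
   family clustering, motif scanning and enrichment, mitochondrial
   mini-circle annotation and a paired-read precursor test;
2. **decontamination** — a three-step best-hit cascade separating parasite
   proteins from host (cephalopod) and prokaryote contamination;
3. **supermatrix curation** — chimeric-OTU merging, gap trimming,
   invariant-site removal, concatenation with missing-data accounting, RCFV
   compositional filtering, Dayhoff-6 recoding, and the per-position
   synapomorphy statistic q(i) used to select signal-bearing partitions.

A synthetic-data layer (`gen_assembly()`, `gen_proteomes()`,
`gen_partitions()`, `gen_read_pairs()`, `gen_circle_lengths()`) generates
inputs with known ground truth so each stage is testable without downloads.

# Circular contigs

De Bruijn assemblers emit contigs built from circular molecules with the
same k-mer at both ends. `detect_circles()` therefore classifies a contig as
circular iff its longest exact prefix that is also a suffix — with the two
copies not overlapping — is at least `k_repeat` nucleotides (default 77, the
largest assembly k-mer; the bound is inclusive). Repeats are exact matches:
the duplication is an artifact of identical k-mers, not of homology, so
mismatches are not tolerated. Trimming removes exactly `k_repeat` bases from
the 3' end (the assembler's duplicated terminal k-mer), never the full
border, and all downstream lengths refer to the trimmed sequence. Contigs
shorter than `2 * k_repeat` cannot carry a valid repeat and are classified
linear rather than raising an error.

Circles split into a **short pool** (trimmed length strictly below 500 bp)
and a **long pool** (at least 500 bp). The boundary convention follows the
wording "less than 500 bp" for the short pool; whether the cutoff applies to
trimmed or raw lengths is not dictated by the upstream description, and we
adopt trimmed lengths since those are the molecule sizes.

## Low complexity

`dust_fraction()` is a classic windowed DUST: in every sliding 64-bp window
the triplet score $S = \sum_t n_t(n_t-1)/2 \,/\, (w_t - 1)$ is computed over
the 64 trinucleotides ($w_t$ = triplets per window) and windows with
$S > 2$ are masked whole. The returned value is the masked fraction of the
sequence. Window size and level are exposed; triplets containing `N` are not
counted. We use the windowed variant rather than SDUST because the windowed
score is the one whose threshold semantics are simple enough to test
exactly; the per-base mask is verified against a naive per-window
recomputation in the test suite.

## Length periodicity

The long-circle length distribution carries an ~10.4-bp comb — the number of
base pairs per turn of B-DNA. `peak_spacing()` estimates the comb spacing
with a Gaussian KDE (bandwidth 1.0 bp, grid step 0.25 bp over 600–800 bp);
peaks are local maxima with prominence at least 10% of the global maximum
and the estimate is the mean successive-peak difference. Bandwidth 1.0 bp
was chosen so that integer binning of lengths does not alias the ~10.4-bp
comb (a bandwidth at or above half the spacing merges adjacent peaks; far
below 0.5 bp the integer rounding of lengths re-emerges as 1-bp structure).
An autocorrelation-based secondary estimate (first off-origin peak of the
autocovariance of 1-bp binned counts) is reported as a cross-check; it is
quantised to whole base pairs and so is the coarser of the two. Fewer than
two qualifying peaks yields a flagged, undefined spacing, and fewer than 200
lengths in the window is an error rather than a silent low-power estimate.

The synthetic length generator draws from a Gaussian mixture with component
means spaced by the target periodicity (default 10.44 bp, sd 1.5 bp),
rounded to integer lengths and truncated to the window; component means are
kept half a spacing away from the window edges so truncation does not shift
the outer peaks. Rounding reproduces the real situation of estimating a
fractional spacing from integer contig lengths. Across 20 seeded replicates
at n = 3,000 the estimator's mean error is below 0.1 bp and its RMSE below
0.3 bp (asserted in the test suite).

## Length-distribution comparison

`ks_compare()` implements the two-sample Kolmogorov–Smirnov test with the
asymptotic p-value series
$Q(\lambda) = 2\sum_{j\ge1}(-1)^{j-1}e^{-2j^2\lambda^2}$,
$\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D$, truncated when terms
fall below 1e-12. The Stephens correction makes p slightly smaller than R's
plain asymptotic version; the null calibration (type-I error within
[0.03, 0.07] at $\alpha = 0.05$ over 2,000 simulated pairs) is part of the
test suite.

# Families, motifs

`build_families()` mirrors an all-against-all blastn graph: an edge joins
two circles when their best local alignment (either strand) has Karlin–
Altschul E-value $E = K m n e^{-\lambda S} \le$ 1e-10, and families are
connected components. The aligner parameters (+1/−2, affine gaps 5+2L,
$\lambda = 1.28$, $K = 0.46$) approximate blastn statistics for the unstated
original settings; the component-structure contract is parameter-free and is
checked against a transitive-closure oracle. Self-hits are excluded. "Has at
least one fairly similar contig" is formalised as "has at least one graph
neighbor".

`scan_motif()` follows FIMO semantics: words are scored as log-odds against
the background, the score-to-p-value map is computed exactly by dynamic
programming over positions with scores discretised to 1e-3 bits, and a hit
is any window (either strand) whose p-value is at or below 1e-4.
Overlapping and double-strand hits count individually. The p-value of the
rate contrast between pools is a 1-df chi-squared on hit counts with
expectations proportional to base-pair exposure; rates are reported in the
"one hit every X bp" form. Both-strand counting is a deliberate convention
(the original rate statement does not specify strandedness) and is noted in
printed reports.

# Mini-circles

`circular_sixframe()` translates the doubled circle sequence in all six
frames so genes spanning the origin remain contiguous; stops are kept as `*`
in the streams. `annotate_circles()` assigns the best reference protein by
local alignment (BLOSUM62, gap costs 11 + 1L, gapped-BLOSUM62
$\lambda = 0.267$, $K = 0.041$) at E-value at most 0.008. Pseudogene flags:
`in_frame_stop` when the aligned span contains `*`, `frameshift` when two
same-strand hits to the assigned gene fall in different frames with mostly
disjoint reference spans (the signature of a single-base indel). Reference
proteins are supplied by the user; tests plant exact back-translations
(alphabetically first codon per residue, for bit-stable fixtures) and
seeded lesions.

`precursor_pair_test()` asks whether paired reads ever bridge out of a
mini-circle, as they would if the circles were cut from a longer precursor
molecule. Mates are mapped by exact 31-mer seeding on doubled circles with
ungapped extension at 90% identity — a deliberate stand-in for the
original's short-word blastn mapping, which the source does not parameterise.
Partners with DUST fraction above 0.5 are set aside as low complexity before
mapping. Precursor evidence is declared when more than 1% of anchored pairs
have their partner elsewhere.

# Decontamination cascade

Three sequential filters, each applied to the survivors of the previous:

1. remove queries whose best hit across all references is **prokaryotic** at
   identity $\ge 50\%$;
2. remove queries whose best **host** score strictly beats every other
   database and whose host identity is strictly $> 70\%$;
3. query the host proteome against the references plus the surviving
   candidates and remove candidates captured as a host query's best hit at
   identity $\ge 80\%$.

The threshold strictness (>= / strictly > / >=) follows the cascade's
wording exactly and is pinned by sweep tests. Identity is
$100 \times$ identical positions / aligned columns with gaps counted in the
denominator. Best-hit ties break by higher identity then lexicographic
subject id, for determinism. Step 2's 70% is measured on the host hit
itself, not on the margin over the runner-up — the wording is ambiguous and
the host-hit reading is the conservative one. Reference databases are plain
FASTA sets with a per-database taxon label; no taxonomy service is involved.

# Supermatrix curation

* `best_per_species()` keeps the candidate with the highest summed local
  alignment score against the existing group members.
* `merge_chimeric()` implements a deterministic chimera rule: within each
  partition, the member with the most non-missing residues represents the
  chimera and the rest are dropped; there is no intra-partition sequence
  fusion. This is a simplification of Scafos's options, chosen for
  reproducibility; the shipped 15-row merge table
  (`inst/extdata/chimeric_taxa.tsv`) lists the merged species pairs.
* `trim_columns()` retains a column iff its gap fraction is at most 0.5
  (inclusive boundary; gap is `-` only, `X` counts as a residue here).
  TrimAl's similarity criterion (threshold 0.001) depends on its internal
  similarity matrices and is deliberately not reproduced — trimming here is
  purely gap-based.
* `remove_invariant()` drops columns with at most one distinct non-missing
  residue.
* `concatenate_partitions()` unions taxa, pads absent blocks with `-`, and
  reports the missing fraction counting both `-` and `X`. `X` is missing for
  frequency and missing-data computations but a residue for gap trimming —
  the convention that matches "missing data (gaps or X's)" in the q(i)
  definition while keeping trimming purely gap-based.
* `rcfv()` computes relative composition frequency variability,
  $\mathrm{RCFV} = \sum_s \sum_t |f_{ts} - \mu_s| / n_{taxa}$ over
  non-missing residues, and `rcfv_filter()` discards partitions strictly
  above 0.115.
* `dayhoff_recode()` maps the 20 amino acids onto the six Dayhoff exchange
  groups AGPST / DENQ / HKR / FWY / ILMV / C (the conventional grouping;
  the upstream description names only "six amino acid groups").

# Synapomorphy signal and validation

For an ingroup $G_1$ and outgroup $G_2$, a column is **considered** when it
has no more than half missing data in each group (integer arithmetic, so the
boundary is exact); on considered columns
$q = \max_a\,(f_{G_1}(a) - f_{G_2}(a))$ over all 20 residues, with the
maximising residue reported and ties resolved alphabetically. The signed
difference is the default — the statistic is ingroup-oriented by
construction — with an absolute-value variant behind `signed = FALSE`.
A column is flagged when $q$ strictly exceeds 0.5; a partition is selected
when at least 3% of its considered columns are flagged (inclusive, over
considered positions rather than raw alignment length, consistent with
"positions with q" phrasing). The maximum over all 20 residues equals the
maximum over residues present in $G_1$ for the signed statistic, so the
choice is cosmetic.

The validation harness builds neighbor-joining trees (uncorrected
p-distances, pairwise deletion; `ape::nj`) for selected and rejected
partitions and compares how often each group recovers the planted ingroup
clade as a bipartition. NJ is consistent on additive distances, which the
tests exploit with exact oracles; it is a harness, not a substitute for
model-based inference, which is out of scope.

# Synthetic data: what it does and does not emulate

The assembly generator plants exact terminal repeats, a Gaussian-mixture
length comb, homopolymer/dinucleotide low-complexity tracts (unambiguously
low complexity under any DUST variant), planted motif consensus copies,
exact back-translated mito genes and seeded stop/indel lesions, with every
planted property recorded in a truth table sufficient to score the
classifiers. It does not emulate sequencing error beyond uniform
substitution, chimeric misassembly, or host-genome-scale contamination, so
passing tests demonstrate correctness of the computations, not robustness to
artifacts absent from the model. The proteome generator gives every genuine
parasite protein a diverged metazoan ortholog (default 60% identity), as
real parasite proteins have in the reference databases — without this the
best-hit cascade would have no signal to protect them. Contaminants are
substitution-only mutants at evenly spaced interior positions, so planted
identity is exact under full-span local alignment. The partition generator
plants perfect synapomorphy columns (fixed in the ingroup, absent outside)
and controls compositional bias through per-taxon Dirichlet compositions
whose heterogeneity grows with the bias parameter.

Default generator settings are the study's stated conditions: k-repeat 77
nt, long circles 600–800 bp with 10.44-bp peak spacing, short-pool
low-complexity fraction 0.381, FIMO threshold 1e-4, mini-circle E-value
0.008, cascade thresholds 50/70/80, gap threshold 0.5, RCFV cutoff 0.115,
q-cut 0.5 and 3% selection.

# Numerical choices and problem sizes

Score discretisation for PWM p-values is 1e-3 bits (exact agreement with
word enumeration is asserted for widths up to 6). Local-alignment gap costs
are `open + extend * L`. All stochastic tests fix seeds, and generators are
pure functions of (spec, seed) with the caller's RNG state restored. Test
problem sizes are chosen to keep the full suite comfortably interactive on
one core: assemblies of a few hundred contigs, 3,000 lengths for spacing
recovery (20 replicates), 2,000 null pairs for each calibration check, 100
replicates for the motif rate contrast, proteome mixtures of tens of
sequences, and 30-partition selection/recovery studies over 5 seeds.

# Known limitations

* E-values use fixed Karlin–Altschul constants rather than per-alignment
  estimation; absolute E-values are approximate, and contracts that matter
  (family structure, annotation assignment) are tested parameter-free.
* The precursor mapper is seed-and-extend, not an aligner; reads whose
  first/middle/last 31-mers all span lesions can fail to anchor.
* Gap-only trimming is not TrimAl; partitions trimmed here can differ from
  TrimAl output at similarity-driven columns.
* NJ validation measures topological signal only; it says nothing about
  model-based posterior support.
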