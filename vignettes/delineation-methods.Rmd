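---
title: "Methods: polyphasic cryptic-species delineation with ribodelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyphasic cryptic-species delineation with ribodelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodelim)
```

`ribodelim` delineates cryptic species in complexes of closely related
protists — its template is the *Amoebophrya ceratii* complex, syndinian
parasites of bloom-forming dinoflagellates — by combining independent lines
of evidence that each bear on reproductive isolation: compensatory base
changes in the ITS2 secondary structure, whole-genome k-mer composition,
and tree structure of the rDNA itself; and it then carries the resulting
species units into ecology (niche overlap, population fitness). This
vignette is the package's own account of each method, its assumptions, the
tunable parameters, and the choices made where the design was genuinely
open.

## 1. ITS2 sequence-structure analysis

### Model

ITS2 folds into a conserved four-helix hairpin architecture. Because the
structure is under stronger constraint than the sequence, substitutions at
paired sites come in two kinds: *compensatory base changes* (CBCs), where
both partners change and canonical pairing (Watson–Crick or G·U wobble) is
preserved, e.g. A-U → G-C; and *hemi-CBCs*, where one side changes and the
pair survives, e.g. G-C → G-U. Empirically, the presence of even one CBC
between two ITS2 sequences is strongly associated with reproductive
isolation, which makes the zero-CBC relation a practical species criterion
for lineages known mostly from sequence data.

Each position of a sequence is encoded as one of 12 letters — nucleotide
(A, C, G, U) × structural state (unpaired, pair-opening, pair-closing) — so
that sequence and structure are aligned *simultaneously*. Pairwise
alignment is global Needleman–Wunsch/Gotoh with affine gaps; the multiple
alignment is progressive (pairwise score distances → neighbor-joining guide
tree → profile merges under "once a gap, always a gap").

### Parameters

* **Scoring** (`scoring_scheme()`): additive by default — nucleotide +2
  match / −1 mismatch, structural state +2 match / −2 mismatch, gap open −8,
  gap extend −2 (dimensionless scores). Published sequence-structure
  substitution matrices exist but are not redistributed here; what the
  downstream statistics depend on is the *behaviour* (structure-aware
  matching), not the constants, and the matrix can be replaced wholesale via
  the `matrix` argument.
* **Distances**: the 12-state Jukes–Cantor correction
  `d = −(11/12)·ln(1 − (12/11)·p)` on the fraction `p` of differing letters
  over mutually ungapped columns. Saturation (`p ≥ 11/12`) is an error, not
  a clamp. GTR-style corrections and parsimony/likelihood trees are out of
  scope.
* **Trees**: standard neighbor-joining (via `ape`); negative branch lengths
  are clamped to zero and counted. Bootstrap support resamples alignment
  columns (100 replicates by default) and maps bipartition frequencies onto
  the point-estimate tree.

### Numerical and convention choices

* Traceback ties in the aligner prefer the diagonal, then the vertical
  move, making alignments deterministic.
* The multiple alignment processes sequences in identifier-sorted order
  internally and restores input order afterwards, so column content is
  invariant to input order.
* A pair couple is *comparable* only when **both** sequences pair the same
  two columns; couples where only one sequence is paired are skipped.
  Comparable couples with a non-canonical pair on either side are skipped
  too and tallied separately as `disrupted`. CBC and hemi-CBC counts are
  reported separately throughout; the species partition uses full CBCs
  only.
* The species partition is the connected-component closure of the zero-CBC
  graph; non-transitive zero patterns (i~j, j~k, but cbc(i,k) > 0) are kept
  in one component and reported as conflicts rather than silently resolved.

## 2. k-mer genome comparison

Reads are filtered by length (≥ 90 bp) and mononucleotide Shannon entropy
(≥ 1.5 bits, computed per read in bits; the threshold is applied as
"discard below"), then decomposed into canonical k-mers (k = 21; the
canonical form is the lexicographic minimum of a k-mer and its reverse
complement, making sets strand-neutral — genomic read orientation is
arbitrary). Because single-cell and cultured libraries differ greatly in
coverage, comparisons use presence/absence only, with the three
binary-association distances that weight double presence: Kulczynski,
Ochiai and Chord (the latter equals `sqrt(2 × Ochiai distance)`
identically). Kulczynski is the reported default; the others are always
computable from the same profiles.

Clustering is hierarchical with average linkage (single and complete
exposed as options) cut at the expected number of ribotypes K. Stability
is assessed clusterboot-style: individuals are resampled with replacement,
the induced distance submatrix is reclustered, and each original cluster is
scored by its maximum Jaccard overlap with the replicate clusters, computed
on the resampled multiset; a cluster unrepresented in a replicate scores 0.
Stability is the mean over 100 replicates.

## 3. Operon copy number and genome size

Copy number is the ratio of operon mean aligned-region coverage to the
arithmetic mean of single-copy gene coverages ("average" is read as the
per-gene mean of means; a median-based estimate is emitted alongside as a
robust alternative). Genes flagged `multi_copy` or `no_hit` upstream are
discarded; the flags are trusted input — BLAST capture and reciprocal-best-
hit vetting are outside the package. The estimator is scale-invariant in
coverage and unbiased as depth grows.

Genome size: fluorescence ratio × 20.9 fg (reference 1C mass of the
internal standard) × 0.978 Mb/fg (the standard genome-size conversion).

## 4. Phenotype ordination and niche analysis

Phenotype contrasts between ribotypes use two-sided Mann–Whitney tests on
log(x+1) data with the tie-corrected normal approximation; the pairwise
family is Holm-adjusted (conservative default, switchable). The ordination
of strains uses Bray–Curtis distances on range-standardized phenotypes
concatenated with raw 0/1 infection columns (binary columns are already in
[0, 1] and are left untouched), followed by classical PCoA; negative
eigenvalues are dropped without Cailliez correction and their share of
total absolute inertia reported. Descriptor fitting onto the first two axes
is a least-squares fit reporting R², the unit direction vector, and a
permutation p computed as `(hits + 1)/(n_perm + 1)` — the add-one form is
exactly discrete-uniform under the null and cannot return zero.

The Outlying Mean Index (OMI) measures a taxon's niche position as the
squared distance between its abundance-weighted mean environmental position
(marginality) and the average conditions of the survey. Environmental
descriptors are range-standardized to [0, 1] *before* centering — following
the survey convention rather than z-scoring — so that the origin is the
uniform-weight sample mean. Abundances are Hellinger transformed first. Per
taxon, inertia decomposes exactly as OMI + tolerance (variance along the
marginality direction) + residual tolerance; niche axes are eigenvectors of
the taxon-weighted marginality cross-product, so the eigenvalue sum equals
the weighted OMI sum. Axis signs are canonicalized (largest-magnitude
loading positive).

Realized niches are Gaussian product-kernel densities of the sample
positions on the first two OMI axes, weighted by the taxon's abundances, on
a shared 100 × 100 grid spanning the axis ranges extended 10% per side.
Bandwidths follow Silverman's rule on the weighted samples (effective
sample size `(Σw)²/Σw²`), per axis and per taxon; when the weighting is
degenerate (nearly all mass on one sample) the bandwidth falls back to 5%
of the axis range so the density stays well defined. Overlap is Schoener's
`D = 1 − ½Σ|p₁ − p₂|` over grid cells, and the overlap matrix is ordered
for display by average-linkage clustering on 1 − D.

## 5. Fitness analysis

Relative read abundances are divided by the ribotype's mean operon copy
number ("normalized abundance") — rDNA amplicon counts otherwise inflate
taxa with expanded arrays. Persistence is the calendar-day span of the
longest run of samples whose relative contribution exceeds a threshold
(default 10%), where a gap of up to `max_gap_days` (default 2, matching the
1–2-day sampling cadence) between qualifying samples is tolerated *only
when no intervening sample was taken*: a sampled value below threshold
always breaks the run. The contribution denominator defaults to parasite
reads rather than total reads: a 10% threshold on total reads would be
unreachable for taxa that peak at a few percent of a community, so the
parasite-read scale is the only one on which the definition is operative;
both options are exposed (`fitness_params()`).

Host range is counted at the host-*species* level (several strains of one
species count once), maximized over the strains of a ribotype, and grouped
into classes (default {1}, {2–3}, {4–5}, configurable). Fitness contrasts
between classes use tie-corrected Kruskal–Wallis on log(x+1) responses,
with Dunn z tests (Holm-adjusted) when the omnibus test is significant at
α = 0.05.

## 6. The synthetic-data generator

The generator (`synth_config()` and the `simulate_*` functions) encodes the
emulated study design; its defaults are the study conditions, not tuning
knobs:

* **Sequences**: one ancestor scaffold of four hairpin helices (16, 14, 22
  and 16 base pairs — helix III longest, as in real ITS2 — 68 pair columns,
  173 nt). Every planted CBC occupies a dedicated pair couple: the two
  ribotypes of the pair carry canonical pairs differing at both nucleotides
  (drawn from {AU, UA, GC, CG}, whose members are pairwise double-
  different), and every other ribotype carries a non-canonical (disrupted)
  pair there, which the CBC counter skips. All templates therefore share
  one structure and length, the multiple alignment is gapless, and the
  recovered CBC matrix equals the planted one exactly. The default planted
  matrix gives every ribotype pair ≥ 1 CBC with values spanning 1–9
  (68 pair columns accommodate its 64 planted changes; a matrix that does
  not fit fails loudly, naming the first pair). Intra-ribotype variation is
  ≤ 3 substitutions per strain, placed at unpaired sites only — the
  placement is a design choice (recorded in the truth object) that forces
  the observed zero within-ribotype CBC count by construction.
* **k-mer profiles**: each ribotype owns a private core pool of canonical
  21-mers (pool size = profile size, 1000 by default); a strain draws a
  `kmer_core_fraction` (0.8) of its profile from its pool and the rest from
  a 20×-larger shared background pool. The between/within distance contrast
  rises monotonically with the core fraction; at 0.8 the eight planted
  clusters separate cleanly, at 0 the profiles carry no cluster signal.
* **Coverage**: 7–55 single-copy genes per strain at 30× depth with
  per-base Poisson noise over 1 kb aligned regions; one operon row at
  depth × copies over 5 kb; planted copies span 58–270 evenly across
  strains; ~15% extra genes are flagged `multi_copy` (inflated) or `no_hit`
  (zero) and must be discarded by the estimator.
* **Community**: 48 samples in 3 late-spring blocks sampled every 1–2
  days; smooth seasonal trajectories for temperature, salinity,
  precipitation, tide coefficient, NO3, PO4 and Si(OH)4; taxon counts are
  Poisson (optionally negative-binomial) around
  `peak_count · exp(−‖x_i − μ_s‖²/(2σ_s²))` in range-standardized
  descriptor space. Default optima spread the taxa along the temperature
  axis with breadth σ = 0.3 — wide enough that niches overlap substantially,
  as co-occurring congeners' do. The first eight taxa are the parasite
  ribotypes and carry copy numbers and host-range classes.
* **Host/phenotype tables**: nine host species (54 strains); every
  parasite infects the reference host species, and host sets grow with the
  ribotype's class; flow-cytometry phenotypes are log-normal around
  ribotype-level means, with fluorescence ratios placed so genome sizes
  land in the ~120–250 Mb range.

What the generator does **not** emulate: sequencing error profiles,
whole-genome-amplification bias, chimeras, taxonomic mis-annotation,
alignment ambiguity from indel-rich ITS2 regions, or environmental
covariate measurement error. Passing tests therefore demonstrate
correctness of the statistical machinery and recoverability of planted
structure under idealized noise — not robustness to every artefact of real
surveys.

## 7. Problem sizes and determinism

The shipped tests and the acceptance script run the full design at its
study scale (64 strains, 48 samples, 100 bootstrap replicates, 173-nt
sequences; the full pipeline takes well under a minute for the k-mer line
and a few tens of seconds for the 64-taxon multiple alignment). Oracle
comparisons (brute-force CBC enumeration, full-matrix alignment DP,
set-algebra distances, rank-formula tests) run on 100–1000 small random
instances each. Every stochastic step takes an explicit integer seed, and
identical seed + configuration reproduces outputs byte-identically; the
generators derive independent substreams by fixed small offsets from the
configured seed.

## 8. Known limitations

* The CBC criterion is asymmetric by nature: CBCs predict distinct species
  far more reliably than their absence predicts conspecificity; the
  package reports zero-CBC *components* and their internal conflicts, and
  the consensus step deliberately takes the strict meet across evidence
  lines rather than trusting any single one.
* The aligner is desk-scale (hundreds of sequences of hundreds of
  positions), not an optimized production MSA engine.
* k-mer profiles are in-memory sets; genome-scale disk-based k-mer counting
  is out of scope.
* OMI axes are computed from the taxon-weighted marginality matrix; per-
  taxon permutation significance of OMI is available but optional, as the
  downstream overlap analysis does not use it.
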