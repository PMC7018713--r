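# ribodelim

Polyphasic delineation of cryptic species from ribosomal and genomic
signatures, modelled on the *Amoebophrya ceratii* species complex
(Syndiniales) — widespread marine parasites of dinoflagellates whose
diversity is known almost entirely from rDNA metabarcodes. Closely related
ribotypes in such complexes can differ by only a handful of nucleotides in
the SSU rDNA, far below classical OTU thresholds, yet behave as distinct
biological species. `ribodelim` implements the combination of evidence used
to draw those species boundaries, and the downstream ecology of the
resulting species, as a tested R pipeline with a synthetic-data generator
standing in for raw survey data.

## What it computes

**ITS2 compensatory base changes (CBCs).** ITS2 sequences and their
secondary structures are analysed simultaneously on a 12-letter alphabet
(nucleotide × {unpaired, pair-open, pair-close}): global affine-gap
pairwise alignment, guide-tree progressive multiple alignment,
neighbor-joining trees under a 12-state Jukes–Cantor correction
`d = −(11/12)·ln(1 − (12/11)·p)` with column-bootstrap support. A CBC is a
double substitution at a conserved base pair that preserves canonical
pairing (e.g. A-U → G-C); a hemi-CBC changes one side only (G-C → G-U).
Taxa are conspecific when they show zero CBCs; the species partition is the
component structure of the zero-CBC graph.

**Alignment-free genome comparison.** Reads are filtered (length ≥ 90 bp,
mononucleotide Shannon entropy ≥ 1.5 bits), decomposed into canonical
21-mers, and compared by presence/absence distances that weight double
presence — Kulczynski `1 − ½(a/(a+b) + a/(a+c))`, Ochiai
`1 − a/√((a+b)(a+c))`, and Chord `√(2·(1 − a/√((a+b)(a+c))))` — followed by
average-linkage clustering whose stability is scored by bootstrap Jaccard
coefficients over 100 replicates.

**rDNA operon copy number and genome size.** Copies per genome are the
ratio of operon read coverage to the mean coverage of vetted single-copy
genes; flow-cytometric fluorescence ratios against a reference of known DNA
content (1C = 20.9 fg) convert to genome sizes at 0.978 Mb/fg.

**Phenotype and niche.** Range-standardized phenotypes plus binary
host-range columns feed a Bray–Curtis PCoA with permutation-tested
descriptor fitting. Metabarcoding time series are Hellinger transformed and
analysed by the Outlying Mean Index (OMI): marginality, tolerance and
residual tolerance per taxon, with niche axes from the taxon-weighted
marginality cross-product. Realized niches are abundance-weighted Gaussian
kernel densities on the first two OMI axes, compared by Schoener's
`D = 1 − ½Σ|p₁ − p₂|`. Population fitness (maximal copy-number-normalized
abundance, persistence in days above a contribution threshold) is compared
between host-range classes by Kruskal–Wallis with Dunn post hoc tests.

**Consensus.** The strict consensus (partition meet) of the CBC, k-mer and
tree-clade partitions, with pairwise conflicts reported.

The synthetic-data module generates every input with planted ground truth:
8 ribotypes with ≤ 3 intra-ribotype SNPs and 1–9 planted inter-ribotype
CBCs, 64 strain k-mer profiles in 8 clusters, operon copies spanning
58–270, and 48 samples over 3 seasons of counts driven by Gaussian niche
responses to 7 environmental descriptors.

## Worked example

```r
library(ribodelim)

cfg <- synth_config(seed = 1)   # 8 ribotypes x 8 strains, full study design
res <- run_pipeline(cfg)
res
#> <pipeline_result>
#>   CBC partition:  8 species
#>   consensus:      8 species, 0 conflicting pairs
#>   k-mer stability (min): 1.000

res$cbc$cbc[c("RIB1_S01", "RIB2_S01", "RIB8_S01"),
            c("RIB1_S01", "RIB2_S01", "RIB8_S01")]
#>          RIB1_S01 RIB2_S01 RIB8_S01
#> RIB1_S01        0        2        9
#> RIB2_S01        2        0        8
#> RIB8_S01        9        8        0

res$kmer_stability
#> <cluster_stability> 8 clusters, 100 bootstrap replicates (average linkage)
#>   mean Jaccard stability per cluster: 1.00 1.00 1.00 1.00 1.00 1.00 1.00 1.00

head(res$copy_estimates, 3)
#>     strain   copies copies_median copies_rounded n_genes_used
#> 1 RIB1_S01 57.98971      57.96724             58           11
#> 2 RIB1_S02 60.96329      60.87966             61           22
#> 3 RIB1_S03 65.10486      65.05927             65           35
```

The CBC matrix reports, per strain pair, the number of compensatory base
changes recovered from the multiple sequence-structure alignment: zero
within ribotypes, the planted 1–9 between them, so the zero-CBC partition
recovers exactly eight species. All eight k-mer clusters are perfectly
stable under bootstrap resampling, and the coverage-ratio estimator
recovers each strain's planted operon copy number to within a few percent.
The three lines of evidence agree, so their strict consensus is the planted
eight-species partition with no conflicting pairs.

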