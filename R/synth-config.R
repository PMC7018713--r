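# Study-design configuration for the synthetic-data generators. Defaults
# encode the study conditions: eight ribotypes, <=3 intra-ribotype SNPs and
# 1-9 inter-ribotype CBCs, 58-270 operon copies, 48 samples over 3 years
# with 7 environmental descriptors.

#' Default planted CBC matrix
#'
#' A symmetric matrix in which every ribotype pair shows at least one CBC
#' and the counts span the observed 1-9 range: all pairs carry 1 CBC except
#' `(1, j) = j` for `j = 2..7`, `(1, 8) = 9` and `(2, 8) = 8`.
#'
#' @param n_ribotypes number of ribotypes.
#' @return an `n x n` symmetric integer matrix with zero diagonal.
#' @export
default_planted_cbc <- function(n_ribotypes = 8) {
  D <- matrix(1L, n_ribotypes, n_ribotypes)
  diag(D) <- 0L
  if (n_ribotypes >= 3) {
    for (j in 2:min(n_ribotypes, 7)) D[1, j] <- D[j, 1] <- as.integer(j)
  }
  if (n_ribotypes >= 8) {
    D[1, 8] <- D[8, 1] <- 9L
    D[2, 8] <- D[8, 2] <- 8L
  }
  rn <- paste0("RIB", seq_len(n_ribotypes))
  dimnames(D) <- list(rn, rn)
  D
}

#' Synthetic study configuration
#'
#' Collects every parameter of the synthetic study design with defaults
#' matching the emulated survey: 8 ribotypes, up to 3 intra-ribotype SNPs,
#' planted CBC counts spanning 1-9, 64 strain k-mer profiles (core fraction
#' 0.8, k = 21), operon copies spread over 58-270 at 30-fold coverage, and
#' 48 samples over 3 years with 7 environmental descriptors driving
#' Gaussian niche responses.
#'
#' @param n_ribotypes number of ribotypes.
#' @param strains_per_ribotype strains generated per ribotype.
#' @param planted_cbc symmetric integer matrix of pairwise CBC counts to
#'   plant (zero diagonal, values in `[0, 9]`).
#' @param intra_snps maximum substitutions per strain, restricted to
#'   unpaired positions.
#' @param helix_pairs base pairs per hairpin helix of the template scaffold
#'   (four helices; helix III longest, as in real ITS2).
#' @param kmer_core_fraction fraction of each strain's k-mers drawn from its
#'   ribotype's private core pool (the rest come from a shared background
#'   pool), in `(0, 1]`; 0 is accepted and yields pure background profiles.
#' @param n_kmers k-mers per strain profile.
#' @param k k-mer size.
#' @param background_pool_factor background pool size as a multiple of
#'   `n_kmers`.
#' @param planted_copies operon copies per strain; default evenly spans
#'   58-270 across all strains.
#' @param coverage_depth mean fold coverage of single-copy genes.
#' @param gene_length,operon_length aligned-region lengths (bp) over which
#'   coverage is averaged.
#' @param flagged_fraction fraction of generated genes flagged `multi_copy`
#'   or `no_hit` (excluded from estimation).
#' @param n_samples,n_years metabarcoding samples and year blocks.
#' @param n_taxa taxa in the community (the first `n_ribotypes` are the
#'   parasite ribotypes, the rest background lineages).
#' @param niche_optima `n_taxa x 7` matrix of niche optima in standardized
#'   descriptor space (default spreads taxa along the temperature axis).
#' @param niche_breadth per-taxon niche breadth (positive; recycled).
#' @param peak_count expected count of a taxon in a sample at its optimum.
#' @param dispersion negative-binomial overdispersion (0 = Poisson counts).
#' @param seed integer seed; all generators derive their randomness from it.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_ribotypes = 8,
                         strains_per_ribotype = 8,
                         planted_cbc = default_planted_cbc(n_ribotypes),
                         intra_snps = 3,
                         helix_pairs = c(16, 14, 22, 16),
                         kmer_core_fraction = 0.8,
                         n_kmers = 1000,
                         k = 21,
                         background_pool_factor = 20,
                         planted_copies = NULL,
                         coverage_depth = 30,
                         gene_length = 1000,
                         operon_length = 5000,
                         flagged_fraction = 0.15,
                         n_samples = 48,
                         n_years = 3,
                         n_taxa = 20,
                         niche_optima = NULL,
                         niche_breadth = 0.3,
                         peak_count = 300,
                         dispersion = 0,
                         seed = 1) {
  stopifnot(n_ribotypes >= 1, strains_per_ribotype >= 1, intra_snps >= 0,
            n_kmers >= 1, k >= 1, background_pool_factor >= 1,
            coverage_depth > 0, n_samples >= 1, n_years >= 1,
            n_taxa >= n_ribotypes, all(niche_breadth > 0),
            dispersion >= 0, length(helix_pairs) >= 1, all(helix_pairs >= 2))
  planted_cbc <- as.matrix(planted_cbc)
  if (nrow(planted_cbc) != n_ribotypes || ncol(planted_cbc) != n_ribotypes) {
    stop("planted_cbc must be ", n_ribotypes, " x ", n_ribotypes,
         call. = FALSE)
  }
  if (any(diag(planted_cbc) != 0)) {
    stop("planted_cbc diagonal must be zero", call. = FALSE)
  }
  if (max(abs(planted_cbc - t(planted_cbc))) > 0) {
    stop("planted_cbc must be symmetric", call. = FALSE)
  }
  if (any(planted_cbc < 0) || any(planted_cbc > 9)) {
    stop("planted_cbc values must lie in [0, 9]", call. = FALSE)
  }
  if (!(kmer_core_fraction >= 0 && kmer_core_fraction <= 1)) {
    stop("kmer_core_fraction must lie in [0, 1]", call. = FALSE)
  }
  n_strains <- n_ribotypes * strains_per_ribotype
  if (is.null(planted_copies)) {
    planted_copies <- round(seq(58, 270, length.out = n_strains))
  }
  stopifnot(length(planted_copies) == n_strains, all(planted_copies > 0))
  ribotypes <- paste0("RIB", seq_len(n_ribotypes))
  dimnames(planted_cbc) <- list(ribotypes, ribotypes)
  strains <- paste0(rep(ribotypes, each = strains_per_ribotype), "_S",
                    sprintf("%02d", rep(seq_len(strains_per_ribotype),
                                        n_ribotypes)))
  names(planted_copies) <- strains
  if (is.null(niche_optima)) {
    niche_optima <- matrix(0.5, n_taxa, 7)
    niche_optima[, 1] <- seq(0.15, 0.85, length.out = n_taxa)
  }
  niche_optima <- as.matrix(niche_optima)
  stopifnot(nrow(niche_optima) == n_taxa, ncol(niche_optima) == 7)
  niche_breadth <- rep_len(niche_breadth, n_taxa)
  structure(list(n_ribotypes = n_ribotypes,
                 strains_per_ribotype = strains_per_ribotype,
                 planted_cbc = planted_cbc, intra_snps = intra_snps,
                 helix_pairs = helix_pairs,
                 kmer_core_fraction = kmer_core_fraction, n_kmers = n_kmers,
                 k = k, background_pool_factor = background_pool_factor,
                 planted_copies = planted_copies,
                 coverage_depth = coverage_depth, gene_length = gene_length,
                 operon_length = operon_length,
                 flagged_fraction = flagged_fraction,
                 n_samples = n_samples, n_years = n_years, n_taxa = n_taxa,
                 niche_optima = niche_optima, niche_breadth = niche_breadth,
                 peak_count = peak_count, dispersion = dispersion,
                 seed = as.integer(seed),
                 ribotypes = ribotypes, strains = strains),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_ribotypes, " ribotypes x ",
      x$strains_per_ribotype, " strains; ", x$n_samples, " samples / ",
      x$n_years, " years; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Ribotype of every strain in a configuration
#'
#' @param config a [synth_config()].
#' @return named character vector strain -> ribotype.
#' @export
ribotype_of_strain <- function(config) {
  setNames(rep(config$ribotypes, each = config$strains_per_ribotype),
           config$strains)
}
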