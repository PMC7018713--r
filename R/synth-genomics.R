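# Synthetic genomic inputs: strain k-mer profiles planted in ribotype
# clusters, and coverage tables with planted operon copy numbers.

.random_kmers <- function(n, k) {
  out <- character(0)
  while (length(out) < n) {
    m <- matrix(sample(c("A", "C", "G", "T"), 2 * n * k, replace = TRUE),
                ncol = k)
    km <- unique(canonical_kmer(apply(m, 1, paste, collapse = "")))
    out <- unique(c(out, km))
  }
  out[seq_len(n)]
}

#' Simulate strain k-mer profiles with planted ribotype clusters
#'
#' Each ribotype receives a private core pool of canonical k-mers (disjoint
#' between ribotypes); each strain draws `kmer_core_fraction` of its
#' profile from its ribotype's pool and the remainder from a shared
#' background pool. Within-ribotype distances are therefore stochastically
#' smaller than between-ribotype distances, with the contrast controlled by
#' the core fraction.
#'
#' @param config a [synth_config()].
#' @return a list of class `synth_kmers`: `profiles` (list of
#'   [kmer_profile()]) and `truth` (strain-to-ribotype map, pool sizes).
#' @export
simulate_kmer_profiles <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  R <- config$n_ribotypes
  n <- config$n_kmers
  n_core <- round(config$kmer_core_fraction * n)
  n_bg <- n - n_core
  bg_size <- round(config$background_pool_factor * n)
  if (n_bg > bg_size) {
    stop("background pool too small to sample without replacement",
         call. = FALSE)
  }
  all_kmers <- .random_kmers(R * n + bg_size, config$k)
  core_pools <- split(all_kmers[seq_len(R * n)],
                      rep(seq_len(R), each = n))
  bg_pool <- all_kmers[R * n + seq_len(bg_size)]

  ribo_of <- ribotype_of_strain(config)
  profiles <- lapply(seq_along(config$strains), function(s) {
    r <- match(ribo_of[s], config$ribotypes)
    kmers <- c(if (n_core) sample(core_pools[[r]], n_core),
               if (n_bg) sample(bg_pool, n_bg))
    .kmer_profile_from_set(kmers, config$k, config$strains[s])
  })
  names(profiles) <- config$strains
  structure(list(profiles = profiles,
                 truth = list(ribotype_of_strain = ribo_of,
                              core_pool_size = n, background_pool = bg_size,
                              core_fraction = config$kmer_core_fraction)),
            class = "synth_kmers")
}

#' Simulate a coverage table with planted operon copy numbers
#'
#' Per strain: 7-55 single-copy genes with mean aligned-region coverage
#' around `coverage_depth` (per-base Poisson noise), one operon row with
#' coverage around `coverage_depth * planted copies`, and a configurable
#' fraction of extra genes flagged `multi_copy` (inflated coverage) or
#' `no_hit` (zero coverage) that the estimator must discard.
#'
#' @param config a [synth_config()].
#' @param noise `"poisson"` (default) or `"none"` for exact construction.
#' @return a list of class `synth_coverage`: `table` (long data frame with
#'   `strain`, `feature`, `flag`, `mean_coverage`) and `truth`
#'   (`copies_of_strain`, depth).
#' @export
simulate_coverage_table <- function(config, noise = c("poisson", "none")) {
  stopifnot(inherits(config, "synth_config"))
  noise <- match.arg(noise)
  set.seed(config$seed + 2L)
  depth <- config$coverage_depth
  glen <- config$gene_length
  olen <- config$operon_length
  cov_of <- function(lambda, len) {
    if (noise == "none") lambda else rpois(length(lambda), lambda * len) / len
  }
  rows <- lapply(config$strains, function(s) {
    n_ok <- sample(7:55, 1)
    n_flag <- round(config$flagged_fraction /
                      max(1 - config$flagged_fraction, 1e-9) * n_ok)
    flags <- c(rep("ok", n_ok),
               if (n_flag) sample(c("multi_copy", "no_hit"), n_flag,
                                  replace = TRUE))
    lambda <- ifelse(flags == "ok", depth,
                     ifelse(flags == "multi_copy",
                            depth * runif(length(flags), 2, 5), 0))
    cov <- cov_of(lambda, glen)
    op_cov <- cov_of(depth * config$planted_copies[s], olen)
    data.frame(strain = s,
               feature = c(sprintf("gene%03d", seq_along(flags)), "operon"),
               flag = c(flags, "ok"),
               mean_coverage = c(cov, op_cov))
  })
  structure(list(table = do.call(rbind, rows),
                 truth = list(copies_of_strain = config$planted_copies,
                              depth = depth)),
            class = "synth_coverage")
}
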