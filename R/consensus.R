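# Cross-evidence consensus: the strict-consensus (meet) of species
# partitions from CBCs, k-mer clusters and tree clades, and the end-to-end
# pipeline runner.

.as_partition <- function(p) {
  if (inherits(p, "species_partition")) p <- p$species
  if (inherits(p, "cluster_stability")) p <- p$assignment
  if (is.null(names(p))) stop("partitions must be named by individual",
                              call. = FALSE)
  p
}

#' Strict consensus of species partitions
#'
#' Computes the partition meet: two individuals are conspecific in the
#' consensus if and only if they are conspecific in *every* input
#' partition. Pairs on which the inputs disagree (conspecific in some
#' partitions but not all) are listed as conflicts.
#'
#' @param partitions a named list of two or more labelings of the same
#'   individuals (named vectors, [delineate_species()] results or
#'   [cluster_with_stability()] results).
#' @return a list of class `consensus_report`: `consensus` (named integer
#'   membership), `n_species`, `conflicts` (data frame of disagreeing
#'   pairs with the per-partition agreement pattern), and
#'   `conflicted_individuals`.
#' @export
consensus_delineation <- function(partitions) {
  stopifnot(length(partitions) >= 2)
  parts <- lapply(partitions, .as_partition)
  ids <- sort(names(parts[[1]]))
  for (p in parts[-1]) {
    if (!identical(sort(names(p)), ids)) {
      stop("partitions cover different individual sets", call. = FALSE)
    }
  }
  parts <- lapply(parts, function(p) p[ids])
  labs <- do.call(paste, c(lapply(parts, as.character), sep = "\r"))
  consensus <- match(labs, unique(labs))
  names(consensus) <- ids

  n <- length(ids)
  conflicts <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- vapply(parts, function(p) p[i] == p[j], logical(1))
      if (any(same) && !all(same)) {
        conflicts <- rbind(conflicts, data.frame(
          id_a = ids[i], id_b = ids[j],
          agree_in = paste(names(partitions)[same], collapse = ",")))
      }
    }
  }
  if (is.null(conflicts)) {
    conflicts <- data.frame(id_a = character(), id_b = character(),
                            agree_in = character())
  }
  structure(list(consensus = consensus, n_species = max(consensus),
                 conflicts = conflicts,
                 conflicted_individuals =
                   sort(unique(c(conflicts$id_a, conflicts$id_b)))),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> ", x$n_species, " consensus species over ",
      length(x$consensus), " individuals; ", nrow(x$conflicts),
      " conflicting pairs\n", sep = "")
  invisible(x)
}

#' Partition of tree leaves into k groups
#'
#' Cuts the cophenetic (path) distances of a tree by average-linkage
#' clustering into `k` groups, giving a clade-based partition comparable to
#' the CBC and k-mer partitions.
#'
#' @param tree a `phylo` tree.
#' @param k number of groups.
#' @return named integer membership vector over the leaf labels.
#' @export
tree_partition <- function(tree, k) {
  d <- cophenetic(tree)
  cutree(hclust(as.dist(d), method = "average"), k = k)
}

#' Run the full delineation pipeline on synthetic data
#'
#' Generates every input from a [synth_config()], runs the three
#' delineation lines of evidence (ITS2 CBCs, k-mer clustering, NJ tree
#' clades) at strain level, and combines them by strict consensus. Also
#' estimates operon copy numbers and returns the planted truth for
#' comparison.
#'
#' @param config a [synth_config()].
#' @param n_boot bootstrap replicates for the k-mer cluster stability.
#' @param its2_bootstrap whether to compute ITS2 tree bootstrap supports
#'   (column resampling; off by default as the consensus does not use
#'   them).
#' @return a list of class `pipeline_result` with elements `alignment`,
#'   `cbc`, `cbc_partition`, `tree`, `tree_partition`, `kmer_stability`,
#'   `copy_estimates`, `consensus`, and `truth`.
#' @export
run_pipeline <- function(config = synth_config(), n_boot = 100,
                         its2_bootstrap = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  seqs <- simulate_ribotype_sequences(config)
  aln <- align_progressive(lapply(seqs$sequences, encode12))
  cbc <- cbc_matrix(aln)
  cbc_part <- delineate_species(cbc)

  D <- aln_distance_matrix(aln)
  tree <- if (its2_bootstrap) {
    bootstrap_support(aln, n = 100, seed = config$seed + 5L)
  } else {
    nj_tree(D)
  }
  tree_part <- tree_partition(tree, config$n_ribotypes)

  km <- simulate_kmer_profiles(config)
  kd <- kmer_distance_matrix(km$profiles, metric = "kulczynski")
  stab <- cluster_with_stability(kd, K = config$n_ribotypes,
                                 n_boot = n_boot,
                                 seed = config$seed + 6L)

  cov <- simulate_coverage_table(config)
  copies <- estimate_operon_copies(cov$table)

  cons <- consensus_delineation(list(cbc = cbc_part,
                                     kmer = stab$assignment,
                                     tree = tree_part))
  structure(list(alignment = aln, cbc = cbc, cbc_partition = cbc_part,
                 tree = tree, tree_partition = tree_part,
                 kmer_stability = stab, copy_estimates = copies,
                 consensus = cons,
                 truth = list(ribotype_of_strain = ribotype_of_strain(config),
                              planted_cbc = config$planted_cbc,
                              planted_copies = config$planted_copies)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n",
      "  CBC partition:  ", x$cbc_partition$n_species, " species\n",
      "  consensus:      ", x$consensus$n_species, " species, ",
      nrow(x$consensus$conflicts), " conflicting pairs\n",
      "  k-mer stability (min): ",
      sprintf("%.3f", min(x$kmer_stability$stability)), "\n", sep = "")
  invisible(x)
}
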