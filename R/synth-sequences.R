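# Synthetic ITS2 sequences with planted compensatory base changes.
#
# A single pseudoknot-free scaffold of four hairpin helices serves as the
# common ancestor. Every planted CBC is realized on a dedicated pair couple:
# the two ribotypes of the pair carry two canonical pairs differing at both
# nucleotides (drawn from {AU, UA, GC, CG}, whose members are pairwise
# double-different), while every other ribotype carries a non-canonical
# (disrupted) pair there, which the CBC counter skips, so the couple
# contributes a CBC only to the intended ribotype pair. All templates share
# one structure and one length, keeping the multiple alignment gapless.
# Intra-ribotype SNPs are restricted to unpaired positions, forcing zero
# CBCs within ribotypes.

.DOUBLE_DIFF_PAIRS <- c("AU", "UA", "GC", "CG")
.NONCANONICAL_PAIRS <- c("AG", "GA", "AA", "CU", "UC", "CC")

# scaffold: lead, four hairpins separated by linkers, tail
.build_template <- function(helix_pairs, rng_loop = 4, linker = 5, flank = 3) {
  db <- strrep(".", flank)
  couples <- list()
  for (h in seq_along(helix_pairs)) {
    p <- helix_pairs[h]
    start <- nchar(db)
    db <- paste0(db, strrep("(", p), strrep(".", rng_loop), strrep(")", p))
    open <- start + seq_len(p)
    close <- start + 2 * p + rng_loop + 1 - seq_len(p)
    couples[[h]] <- cbind(open, close)
    if (h < length(helix_pairs)) db <- paste0(db, strrep(".", linker))
  }
  db <- paste0(db, strrep(".", flank))
  list(structure = db, couples = do.call(rbind, couples))
}

#' Simulate ITS2 ribotype sequences with planted CBCs
#'
#' Generates one structured template per ribotype from a common four-helix
#' hairpin scaffold, planting exactly `planted_cbc[i, j]` compensatory base
#' changes between every ribotype pair, then derives
#' `strains_per_ribotype` strains per ribotype carrying at most
#' `intra_snps` substitutions at unpaired positions (so within-ribotype CBC
#' counts are zero by construction).
#'
#' @param config a [synth_config()].
#' @return a list of class `synth_sequences`: `sequences` (list of
#'   [structured_seq()], one per strain) and `truth` (planted CBC matrix,
#'   strain-to-ribotype map, per-ribotype templates, SNP positions, and the
#'   note that SNP placement at unpaired sites is a design choice).
#' @export
simulate_ribotype_sequences <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  R <- config$n_ribotypes
  tmpl <- .build_template(config$helix_pairs)
  couples <- tmpl$couples
  n_couples <- nrow(couples)
  L <- nchar(tmpl$structure)
  db_chars <- strsplit(tmpl$structure, "", fixed = TRUE)[[1]]

  # how many dedicated couples each ribotype pair needs
  need <- NULL
  if (R >= 2) {
    for (i in 1:(R - 1)) {
      for (j in (i + 1):R) {
        cnt <- config$planted_cbc[i, j]
        if (cnt > 0) need <- rbind(need, cbind(i, j, seq_len(cnt)))
      }
    }
  }
  n_need <- if (is.null(need)) 0L else nrow(need)
  if (n_need > n_couples) {
    over <- need[n_couples + 1L, ]
    stop("infeasible planted_cbc: ", n_need, " CBCs requested but only ",
         n_couples, " pair couples available in the template; first pair ",
         "that does not fit: (", config$ribotypes[over[1]], ", ",
         config$ribotypes[over[2]], ")", call. = FALSE)
  }
  slot_of <- if (n_need) sample.int(n_couples, n_need) else integer(0)

  # ancestor nucleotides: canonical pairs at couples, random bases elsewhere
  anc <- character(L)
  unpaired_template <- which(db_chars == ".")
  anc[unpaired_template] <- sample(RIBO_NT, length(unpaired_template),
                                   replace = TRUE)
  pair_pool <- c(.DOUBLE_DIFF_PAIRS, "GU", "UG")
  anc_pair <- sample(pair_pool, n_couples, replace = TRUE,
                     prob = c(rep(0.225, 4), 0.05, 0.05))
  anc_pair[slot_of] <- sample(.DOUBLE_DIFF_PAIRS, n_need, replace = TRUE)
  anc[couples[, 1]] <- substr(anc_pair, 1, 1)
  anc[couples[, 2]] <- substr(anc_pair, 2, 2)

  # per-ribotype templates
  seq_r <- matrix(rep(anc, R), nrow = R, byrow = TRUE)
  db_r <- matrix(rep(db_chars, R), nrow = R, byrow = TRUE)
  if (n_need) {
    for (u in seq_len(n_need)) {
      i <- need[u, 1]; j <- need[u, 2]; cpl <- couples[slot_of[u], ]
      alt <- sample(setdiff(.DOUBLE_DIFF_PAIRS, anc_pair[slot_of[u]]), 1)
      seq_r[j, cpl[1]] <- substr(alt, 1, 1)
      seq_r[j, cpl[2]] <- substr(alt, 2, 2)
      # everyone else gets a disrupted (non-canonical) pair at this couple,
      # invisible to the CBC counter
      broken <- sample(.NONCANONICAL_PAIRS, 1)
      others <- setdiff(seq_len(R), c(i, j))
      seq_r[others, cpl[1]] <- substr(broken, 1, 1)
      seq_r[others, cpl[2]] <- substr(broken, 2, 2)
    }
  }

  ribo_of <- ribotype_of_strain(config)
  sequences <- vector("list", length(config$strains))
  names(sequences) <- config$strains
  snps <- list()
  for (s in seq_along(config$strains)) {
    r <- match(ribo_of[s], config$ribotypes)
    nt <- seq_r[r, ]
    unpaired_r <- which(db_r[r, ] == ".")
    n_snp <- if (config$intra_snps == 0) 0L else
      sample(0:config$intra_snps, 1)
    pos <- if (n_snp) sample(unpaired_r, n_snp) else integer(0)
    for (p in pos) nt[p] <- sample(setdiff(RIBO_NT, nt[p]), 1)
    snps[[config$strains[s]]] <- pos
    sequences[[s]] <- structured_seq(config$strains[s],
                                     paste(nt, collapse = ""),
                                     paste(db_r[r, ], collapse = ""))
  }

  templates <- lapply(seq_len(R), function(r) {
    structured_seq(config$ribotypes[r], paste(seq_r[r, ], collapse = ""),
                   paste(db_r[r, ], collapse = ""))
  })
  names(templates) <- config$ribotypes

  structure(list(
    sequences = sequences,
    truth = list(planted_cbc = config$planted_cbc,
                 ribotype_of_strain = ribo_of,
                 templates = templates, snps = snps,
                 snp_placement = "unpaired sites only (design choice)")),
    class = "synth_sequences")
}

#' @export
print.synth_sequences <- function(x, ...) {
  cat("<synth_sequences> ", length(x$sequences), " strains in ",
      length(x$truth$templates), " ribotypes; planted CBC range ",
      min(x$truth$planted_cbc[upper.tri(x$truth$planted_cbc)]), "-",
      max(x$truth$planted_cbc), "\n", sep = "")
  invisible(x)
}
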