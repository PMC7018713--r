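# Population-fitness analysis: copy-number-normalized abundances,
# persistence of ribotypes in the sampled system, host-range classes and
# Kruskal-Wallis / Dunn comparisons.

#' Fitness analysis parameters
#'
#' @param persistence_threshold relative-contribution threshold above which
#'   a sample qualifies for a persistence run (fraction in `(0, 1)`).
#' @param persistence_denominator whether relative contributions are taken
#'   against all reads or against parasite reads only (the printed 10%
#'   threshold is only attainable on the parasite-read scale, so that is
#'   the default).
#' @param max_gap_days maximum number of calendar days tolerated between
#'   consecutive qualifying samples when no intervening sample was taken; an
#'   intervening below-threshold sample always breaks the run.
#' @return a list of class `fitness_params`.
#' @export
fitness_params <- function(persistence_threshold = 0.10,
                           persistence_denominator = c("parasite_reads",
                                                       "total_reads"),
                           max_gap_days = 2) {
  stopifnot(persistence_threshold > 0, persistence_threshold < 1,
            max_gap_days >= 1)
  structure(list(persistence_threshold = persistence_threshold,
                 persistence_denominator =
                   match.arg(persistence_denominator),
                 max_gap_days = max_gap_days),
            class = "fitness_params")
}

#' Copy-number-normalized abundance
#'
#' Divides a ribotype's relative read abundance by its average rDNA operon
#' copy number, correcting read counts for rDNA array expansion.
#'
#' @param rel_abundance relative read abundance (fraction).
#' @param copies average operon copies per genome (> 0).
#' @return the normalized abundance.
#' @export
normalize_abundance <- function(rel_abundance, copies) {
  if (any(copies <= 0)) stop("operon copies must be positive", call. = FALSE)
  rel_abundance / copies
}

#' Persistence of a ribotype in a sampled season
#'
#' Finds the longest run of samples whose relative contribution exceeds the
#' threshold, where consecutive qualifying samples must be at most
#' `max_gap_days` apart and no intervening sample may fall below the
#' threshold. Persistence is the number of calendar days spanned by the run
#' (`last - first + 1`); 0 when no sample qualifies.
#'
#' @param dates sample dates (`Date` or integer day numbers), sorted
#'   increasing.
#' @param contributions relative contributions at those dates.
#' @param params a [fitness_params()].
#' @return persistence in days.
#' @export
persistence <- function(dates, contributions, params = fitness_params()) {
  stopifnot(length(dates) == length(contributions))
  day <- as.numeric(dates)
  if (is.unsorted(day, strictly = FALSE)) {
    stop("dates must be sorted increasing", call. = FALSE)
  }
  qual <- contributions > params$persistence_threshold
  best <- 0
  run_start <- NA_real_
  prev_day <- NA_real_
  for (k in seq_along(day)) {
    if (qual[k]) {
      if (is.na(run_start) || day[k] - prev_day > params$max_gap_days) {
        run_start <- day[k]
      }
      prev_day <- day[k]
      best <- max(best, day[k] - run_start + 1)
    } else {
      run_start <- NA_real_   # a sampled failure breaks the run
      prev_day <- NA_real_
    }
  }
  best
}

#' Host-range classes from a cross-infection matrix
#'
#' Counts, per parasite strain, the number of distinct host *species*
#' infected (several strains of one species count once); takes, per
#' ribotype, the maximum over its strains; and groups the maxima into
#' host-range classes.
#'
#' @param h binary infection matrix, parasite strains x host strains
#'   (1 = infection).
#' @param species_of_host named character vector mapping every host strain
#'   (column) to its species.
#' @param ribotype_of_strain named vector mapping every parasite strain
#'   (row) to its ribotype.
#' @param classes named list mapping class labels to the host-species
#'   counts they cover.
#' @return a list: `strain_counts` (species infected per strain, strains
#'   with empty rows flagged in `empty_strains`), `ribotype_max`, and
#'   `ribotype_class`.
#' @export
host_range_class <- function(h, species_of_host, ribotype_of_strain,
                             classes = list("1" = 1, "3" = 2:3,
                                            "4-5" = 4:5)) {
  h <- as.matrix(h)
  stopifnot(all(h %in% c(0, 1)))
  hosts <- colnames(h)
  if (is.null(hosts)) hosts <- paste0("host", seq_len(ncol(h)))
  unmapped <- setdiff(hosts, names(species_of_host))
  if (length(unmapped)) {
    stop("host strains without a species mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  sp <- species_of_host[hosts]
  strain_counts <- apply(h, 1, function(row) length(unique(sp[row == 1])))
  empty <- names(strain_counts)[strain_counts == 0]
  ribos <- ribotype_of_strain[rownames(h)]
  ribotype_max <- tapply(strain_counts, ribos, max)
  ribotype_class <- vapply(ribotype_max, function(cnt) {
    hit <- names(classes)[vapply(classes, function(v) cnt %in% v,
                                 logical(1))]
    if (length(hit)) hit[1] else as.character(cnt)
  }, character(1))
  list(strain_counts = strain_counts, empty_strains = empty,
       ribotype_max = ribotype_max, ribotype_class = ribotype_class)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis omnibus test on `log(x + 1)` transformed
#' responses; when the omnibus p is below `alpha`, pairwise Dunn z tests
#' with Holm-adjusted p values are reported.
#'
#' @param values numeric responses (e.g. maximal normalized abundance or
#'   persistence per ribotype-year).
#' @param groups class labels (>= 2 classes with >= 2 records each).
#' @param alpha omnibus significance level gating the post hoc step.
#' @param adjust p-adjustment method for the Dunn pairs.
#' @return a list of class `kruskal_dunn`: `H`, `p`, `dunn` (data frame
#'   with `group_a`, `group_b`, `z`, `p`, `p_adjusted`; `NULL` when the
#'   omnibus test is not significant).
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05, adjust = "holm") {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two classes", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every class needs at least two records", call. = FALSE)
  }
  y <- log(values + 1)
  kw <- kruskal.test(y, factor(groups))
  dunn <- NULL
  if (kw$p.value < alpha) {
    N <- length(y)
    rk <- rank(y)
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    mean_rk <- tapply(rk, groups, mean)
    n_g <- tapply(rk, groups, length)
    pairs <- combn(names(mean_rk), 2)
    z <- apply(pairs, 2, function(gp) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) *
                   (1 / n_g[gp[1]] + 1 / n_g[gp[2]]))
      (mean_rk[gp[1]] - mean_rk[gp[2]]) / se
    })
    p <- 2 * pnorm(-abs(z))
    dunn <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
                       p = p, p_adjusted = p.adjust(p, method = adjust))
  }
  structure(list(H = unname(kw$statistic), p = kw$p.value, dunn = dunn),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat("<kruskal_dunn> H = ", signif(x$H, 4), ", p = ", signif(x$p, 4),
      if (is.null(x$dunn)) "; post hoc not triggered" else
        paste0("; ", nrow(x$dunn), " Dunn pairs"), "\n", sep = "")
  invisible(x)
}
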