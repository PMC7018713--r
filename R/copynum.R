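# rDNA operon copy-number estimation from coverage ratios, and genome sizes
# from flow-cytometric fluorescence ratios.

#' Select single-copy reference genes from a coverage table
#'
#' Keeps only genes flagged `ok`; genes flagged `multi_copy` or `no_hit`
#' (case-insensitive) are discarded, as in the single-copy reference list
#' protocol.
#'
#' @param tab data frame with columns `strain`, `feature`, `flag`,
#'   `mean_coverage`; exactly one `feature == "operon"` row per strain.
#' @param strain strain id to extract genes for.
#' @return data frame of retained gene rows; errors when none remain.
#' @export
select_reference_genes <- function(tab, strain) {
  rows <- tab[tab$strain == strain & tab$feature != "operon", , drop = FALSE]
  keep <- rows[tolower(rows$flag) == "ok", , drop = FALSE]
  if (!nrow(keep)) {
    stop("no usable single-copy genes for strain '", strain, "'",
         call. = FALSE)
  }
  keep
}

#' Estimate rDNA operon copies per genome
#'
#' Copies = operon coverage divided by the mean coverage of the retained
#' single-copy genes. A median-based estimate is reported alongside as a
#' robust alternative.
#'
#' @param tab coverage table (see [select_reference_genes()]).
#' @param strains strain ids to estimate; defaults to all strains in `tab`.
#' @return data frame with `strain`, `copies` (mean-based), `copies_median`,
#'   `copies_rounded`, `n_genes_used`.
#' @export
estimate_operon_copies <- function(tab, strains = unique(tab$strain)) {
  out <- lapply(strains, function(s) {
    genes <- select_reference_genes(tab, s)
    op <- tab[tab$strain == s & tab$feature == "operon", , drop = FALSE]
    if (nrow(op) != 1) {
      stop("expected exactly one operon row for strain '", s, "'",
           call. = FALSE)
    }
    if (op$mean_coverage <= 0) {
      stop("non-positive operon coverage for strain '", s, "'",
           call. = FALSE)
    }
    mu <- mean(genes$mean_coverage)
    if (mu <= 0) {
      stop("zero mean single-copy coverage for strain '", s, "'",
           call. = FALSE)
    }
    if (nrow(genes) == 1) {
      warning("single retained gene for strain '", s, "'", call. = FALSE)
    }
    data.frame(strain = s,
               copies = op$mean_coverage / mu,
               copies_median = op$mean_coverage / median(genes$mean_coverage),
               copies_rounded = round(op$mean_coverage / mu),
               n_genes_used = nrow(genes))
  })
  do.call(rbind, out)
}

#' Genome size from a flow-cytometric fluorescence ratio
#'
#' Converts the ratio of a dinospore population's mean DNA fluorescence to
#' that of the internal reference (*Micromonas pusilla* RCC299, 1C = 20.9
#' fg) into a haploid genome mass, then to megabases using the standard
#' 0.978 Mb/fg conversion.
#'
#' @param ratio fluorescence ratio(s) to the reference (> 0).
#' @param reference_fg reference 1C DNA mass in femtograms.
#' @param mb_per_fg conversion constant in megabases per femtogram.
#' @return data frame with `ratio`, `mass_fg`, `size_mb`.
#' @export
genome_size_from_ratio <- function(ratio, reference_fg = 20.9,
                                   mb_per_fg = 0.978) {
  if (any(ratio <= 0)) stop("fluorescence ratio must be positive",
                            call. = FALSE)
  mass <- ratio * reference_fg
  data.frame(ratio = ratio, mass_fg = mass, size_mb = mass * mb_per_fg)
}

#' Correlation between operon copies and genome size
#'
#' Pearson product-moment correlation with a two-sided test, used to ask
#' whether rDNA array expansion tracks genome size.
#'
#' @param copies,sizes paired numeric vectors (n >= 3).
#' @return list with `r`, `p`, `n`.
#' @export
copies_size_correlation <- function(copies, sizes) {
  stopifnot(length(copies) == length(sizes))
  if (length(copies) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(copies) == 0 || sd(sizes) == 0) {
    stop("constant input vector", call. = FALSE)
  }
  ct <- cor.test(copies, sizes, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(copies))
}
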