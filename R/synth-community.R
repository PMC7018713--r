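# Synthetic metabarcoding time series driven by Gaussian niche responses to
# environmental gradients, and host-range / flow-cytometry phenotype tables.

.ENV_DESCRIPTORS <- c("temperature", "salinity", "precipitation",
                      "tide_coefficient", "NO3", "PO4", "SiOH4")

# default per-ribotype host-range classes: narrow (one host species) for
# most ribotypes, one intermediate, broad for the rest
.default_host_classes <- function(ribotypes) {
  base <- c("1", "4-5", "1", "4-5", "3", "1", "1", "4-5")
  setNames(rep_len(base, length(ribotypes)), ribotypes)
}

#' Simulate a metabarcoding community time series with environment
#'
#' Generates `n_samples` dated samples in `n_years` seasonal blocks
#' (sampling every 1-2 days in a late-spring window), smooth per-year
#' trajectories for the 7 environmental descriptors (temperature, salinity,
#' precipitation, tide coefficient, NO3, PO4, SiOH4), and taxon counts with
#' expectation `peak_count * exp(-||x_i - mu_s||^2 / (2 sigma_s^2))` in
#' range-standardized descriptor space, realized as Poisson draws (or
#' negative binomial when `dispersion > 0`). The first `n_ribotypes` taxa
#' are the parasite ribotypes and also carry operon copy numbers (the mean
#' of their strains' planted copies) and host-range classes.
#'
#' @param config a [synth_config()].
#' @return a list of class `synth_community`: `counts` (samples x taxa),
#'   `env` (samples x 7 data frame), `samples` (data frame with `sample`,
#'   `date`, `year`), and `truth` (optima, breadths, parasite copies and
#'   host-range classes).
#' @export
simulate_community_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 3L)
  per_year <- ceiling(config$n_samples / config$n_years)
  date <- as.Date(character(0)); year <- integer(0)
  for (y in seq_len(config$n_years)) {
    start <- as.Date(sprintf("%d-05-20", 2009 + y))
    offs <- cumsum(c(0, sample(1:2, per_year - 1, replace = TRUE)))
    date <- c(date, start + offs)
    year <- c(year, rep(y, per_year))
  }
  keep <- seq_len(config$n_samples)
  date <- as.Date(date[keep], origin = "1970-01-01"); year <- year[keep]
  t_in_year <- unlist(lapply(split(date, year), function(d) {
    as.numeric(d - min(d))
  }), use.names = FALSE)

  n <- config$n_samples
  env <- data.frame(
    temperature = 13 + 0.15 * t_in_year + rnorm(n, 0, 0.4),
    salinity = 33.5 - 0.05 * t_in_year + rnorm(n, 0, 0.3),
    precipitation = round(pmax(rnorm(n, 4 - 0.08 * t_in_year, 2.5), 0), 1),
    tide_coefficient = 70 + 35 * sin(2 * pi * (t_in_year + 3 * year) / 14),
    NO3 = 20 * exp(-0.05 * t_in_year) * exp(rnorm(n, 0, 0.15)),
    PO4 = 1.5 * exp(-0.04 * t_in_year) * exp(rnorm(n, 0, 0.15)),
    SiOH4 = 8 * exp(-0.03 * t_in_year) * exp(rnorm(n, 0, 0.15)))
  X <- range_standardize(env)

  taxa <- c(config$ribotypes,
            sprintf("BG%02d", seq_len(config$n_taxa - config$n_ribotypes)))
  counts <- matrix(0L, n, config$n_taxa, dimnames = list(NULL, taxa))
  for (s in seq_len(config$n_taxa)) {
    d2 <- rowSums(sweep(X, 2, config$niche_optima[s, ])^2)
    lambda <- config$peak_count * exp(-d2 / (2 * config$niche_breadth[s]^2))
    counts[, s] <- if (config$dispersion > 0) {
      stats::rnbinom(n, mu = lambda, size = 1 / config$dispersion)
    } else {
      rpois(n, lambda)
    }
  }

  copies_by_ribo <- tapply(config$planted_copies,
                           ribotype_of_strain(config), mean)
  classes <- .default_host_classes(config$ribotypes)
  structure(list(
    counts = counts, env = env,
    samples = data.frame(sample = sprintf("S%02d", seq_len(n)),
                         date = date, year = year),
    truth = list(optima = config$niche_optima,
                 breadth = config$niche_breadth,
                 peak_count = config$peak_count,
                 parasite_copies = copies_by_ribo[config$ribotypes],
                 host_range_class = classes)),
    class = "synth_community")
}

#' Simulate host-range and flow-cytometry phenotype tables
#'
#' Builds a binary cross-infection matrix in which all parasite strains
#' infect the reference host (*S. acuminata* STR1-like) and strains of one
#' ribotype share a host-species set determined by the ribotype's
#' host-range class; and a phenotype table (FSC, SSC, green fluorescence,
#' fluorescence ratio to the reference) with values drawn around
#' ribotype-level means.
#'
#' @param config a [synth_config()].
#' @param host_classes optional named vector ribotype -> class
#'   (`"1"`, `"3"`, `"4-5"`).
#' @return a list of class `synth_host`: `infection` (parasite strains x
#'   host strains binary matrix), `species_of_host`, `phenotypes` (data
#'   frame with `strain`, `ribotype`, `FSC`, `SSC`, `green`, `ratio`), and
#'   `truth` (the classes and per-ribotype phenotype means).
#' @export
simulate_host_phenotype <- function(config, host_classes = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 4L)
  if (is.null(host_classes)) {
    host_classes <- .default_host_classes(config$ribotypes)
  }
  species <- c("S.acuminata_STR1", "S.acuminata_STR2", "S.donghaienis",
               "S.lachrymosa", "Scrippsiella_sp", "H.triquetra",
               "H.rotundata", "A.minutum", "G.spinifera")
  strains_per_species <- c(8, 6, 6, 6, 6, 8, 5, 5, 4)
  species_of_host <- rep(species, strains_per_species)
  hosts <- paste0(species_of_host, "_h",
                  unlist(lapply(strains_per_species, seq_len)))
  names(species_of_host) <- hosts

  # host-species set per class; class "4-5" splits into 4 or 5 species
  set_of_class <- function(cl, r) {
    switch(cl,
           "1" = species[1],
           "3" = species[1:3],
           "4-5" = species[1:(4 + r %% 2)],
           species[1])
  }
  ribo_of <- ribotype_of_strain(config)
  infection <- matrix(0L, length(config$strains), length(hosts),
                      dimnames = list(config$strains, hosts))
  for (s in seq_along(config$strains)) {
    r <- match(ribo_of[s], config$ribotypes)
    set <- set_of_class(host_classes[ribo_of[s]], r)
    infection[s, species_of_host %in% set] <- 1L
  }

  ribo_means <- data.frame(
    ribotype = config$ribotypes,
    FSC = exp(rnorm(config$n_ribotypes, log(5e4), 0.35)),
    SSC = exp(rnorm(config$n_ribotypes, log(2e4), 0.35)),
    green = exp(rnorm(config$n_ribotypes, log(1e3), 0.4)),
    ratio = runif(config$n_ribotypes, 6, 12))
  idx <- match(ribo_of, config$ribotypes)
  phen <- data.frame(
    strain = config$strains, ribotype = unname(ribo_of),
    FSC = ribo_means$FSC[idx] * exp(rnorm(length(idx), 0, 0.08)),
    SSC = ribo_means$SSC[idx] * exp(rnorm(length(idx), 0, 0.08)),
    green = ribo_means$green[idx] * exp(rnorm(length(idx), 0, 0.08)),
    ratio = ribo_means$ratio[idx] * exp(rnorm(length(idx), 0, 0.04)))
  structure(list(infection = infection, species_of_host = species_of_host,
                 phenotypes = phen,
                 truth = list(host_classes = host_classes,
                              ribotype_means = ribo_means)),
            class = "synth_host")
}
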