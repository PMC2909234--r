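# Population-genetic rate arithmetic: theta from SNP density, the
# mutation rate from theta = 4*Ne*mu, divergence projections over time
# and generation time, and the inverse generation-time solver.

#' Silent-site diversity from SNP density
#'
#' Converts an observed SNP density (one SNP every `1/snps_per_bp` base
#' pairs) into a per-silent-site diversity estimate by multiplying with
#' the number of positions per silent site (3, under the assumption that
#' most SNPs are neutral and third codon positions are nearly neutral).
#'
#' @param snps_per_bp SNP density per base pair, in `(0, 1]` (0 allowed
#'   for the degenerate no-polymorphism case).
#' @param positions_per_silent_site Scaling factor (default 3).
#' @return Theta, the per-silent-site diversity.
#' @examples
#' theta_from_snp_density(1 / 149)  # ~0.02
#' @export
theta_from_snp_density <- function(snps_per_bp,
                                   positions_per_silent_site = 3) {
  if (snps_per_bp < 0 || snps_per_bp > 1)
    stop("snps_per_bp must lie in [0, 1]")
  snps_per_bp * positions_per_silent_site
}

#' Mutation rate from diversity and effective population size
#'
#' Inverts `theta = 4 * Ne * mu` for the per-site per-generation mutation
#' rate.
#'
#' @param theta Average genetic diversity.
#' @param ne Effective population size (default 1e4, an upper bound
#'   consistent with the number of S-alleles in natural populations).
#' @return `mu = theta / (4 * ne)`.
#' @examples
#' mu_from_theta(0.02, 1e4)     # 5e-7
#' mu_from_theta(0.00466, 1e4)  # ~1.2e-7
#' @export
mu_from_theta <- function(theta, ne = 1e4) {
  if (ne <= 0) stop("ne must be positive")
  theta / (4 * ne)
}

#' Project silent-site divergence over time
#'
#' `divergence = mu * (years / gen_time_years)`: the number of
#' generations elapsed times the per-generation mutation rate. The
#' default reproduces the single-lineage convention; set
#' `two_lineage = TRUE` to double the divergence for two independently
#' evolving lineages.
#'
#' @param mu Per-site per-generation mutation rate.
#' @param years Elapsed time in years.
#' @param gen_time_years Generation time in years (must be positive).
#' @param two_lineage Double the projection for a lineage pair
#'   (default `FALSE`).
#' @return Projected divergence.
#' @examples
#' project_divergence(1.2e-7, 5e6, 50)  # 0.012
#' project_divergence(5e-7, 5e6, 25)    # 0.10
#' @export
project_divergence <- function(mu, years, gen_time_years,
                               two_lineage = FALSE) {
  if (gen_time_years <= 0) stop("gen_time_years must be positive")
  d <- mu * (years / gen_time_years)
  if (two_lineage) 2 * d else d
}

#' Generation time consistent with an observed divergence
#'
#' Exact inverse of [project_divergence()]:
#' `gen_time = mu * years / divergence`.
#'
#' @param divergence Observed silent-site divergence (must be positive).
#' @param mu Per-site per-generation mutation rate.
#' @param years Elapsed time in years.
#' @param two_lineage Use the two-lineage convention (default `FALSE`).
#' @return Generation time in years.
#' @examples
#' generation_time_for(0.012, 1.2e-7, 5e7)  # 500
#' @export
generation_time_for <- function(divergence, mu, years,
                                two_lineage = FALSE) {
  if (divergence <= 0) stop("divergence must be positive")
  d <- if (two_lineage) divergence / 2 else divergence
  mu * years / d
}

#' Divergence projections over a grid of generation times
#'
#' Labelled table of theta, mu and projected divergences for a set of
#' generation times, the summary printed by the population-genetics
#' stage of the pipeline.
#'
#' @param theta Diversity estimate.
#' @param ne Effective population size.
#' @param years Elapsed time in years.
#' @param gen_times Vector of generation times in years.
#' @param two_lineage Divergence convention flag.
#' @return Data frame with columns `gen_time_years`, `theta`, `mu`,
#'   `divergence`.
#' @export
popgen_table <- function(theta, ne = 1e4, years = 5e6,
                         gen_times = c(25, 50), two_lineage = FALSE) {
  mu <- mu_from_theta(theta, ne)
  data.frame(gen_time_years = gen_times, theta = theta, mu = mu,
             divergence = vapply(gen_times, function(g)
               project_divergence(mu, years, g, two_lineage), numeric(1)))
}
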