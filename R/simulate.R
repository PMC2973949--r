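#' Simulate a ring species with isolated outlier demes
#'
#' Structured-coalescent simulation of a circular stepping-stone model:
#' `n_demes` demes arranged on a circle exchange migrants only with their
#' two adjacent neighbors (a fraction `migration_frac` of each deme per
#' generation from each neighbor), plus `n_outlier_demes` isolated demes
#' that exchange no migrants and join the ring ancestral population
#' `outlier_split` coalescent time units in the past.  Each locus is an
#' independent genealogy conditioned on exactly one segregating site
#' (a single mutation placed uniformly along the branch lengths), and
#' diploids are formed by pairing haplotypes within demes.
#'
#' Time is scaled in units of `4 N` generations with `N = deme_size`
#' diploids per deme, the usual coalescent convention, so the per-neighbor
#' scaled migration rate is `4 * deme_size * migration_frac`.
#'
#' @param n_demes ring demes (default 100).
#' @param samples_per_deme diploids sampled per deme (default 10).
#' @param n_loci independent biallelic loci (default 10000).
#' @param migration_frac per-generation migrant fraction from each adjacent
#'   deme, in (0, 0.5\] (default 0.1).
#' @param n_outlier_demes isolated outlier demes (default 2).
#' @param deme_size diploid deme size N setting the migration scale
#'   (default 50).
#' @param outlier_split split time of the outlier demes in units of 4N
#'   generations; the default, `2.5 * (n_demes + n_outlier_demes)`,
#'   corresponds to ten times the total population size in generations.
#' @param seed RNG seed (required).
#' @param max_retries per-locus retry cap for non-segregating draws.
#' @return Object of class `sim_sample`: `genotypes` ([snp_genotypes]),
#'   `deme_labels` (1..n_demes then outliers), `deme_angle` (radians;
#'   `NA` for outlier individuals), `is_outlier`, `params`.
#' @export
simulate_ring <- function(n_demes = 100L, samples_per_deme = 10L,
                          n_loci = 10000L, migration_frac = 0.1,
                          n_outlier_demes = 2L, deme_size = 50L,
                          outlier_split = 2.5 * (n_demes + n_outlier_demes),
                          seed, max_retries = 100L) {
  if (missing(seed)) stop_input("seed is required")
  if (migration_frac <= 0 || migration_frac > 0.5)
    stop_input("migration_frac must be in (0, 0.5]")
  if (n_demes < 3L) stop_input("need at least 3 ring demes")
  if (n_outlier_demes < 0L) stop_input("n_outlier_demes must be >= 0")
  mig_rate <- 4 * deme_size * migration_frac
  g <- with_seed(seed,
    simulate_ring_loci_cpp(as.integer(n_demes), as.integer(n_outlier_demes),
                           as.integer(2L * samples_per_deme),
                           as.integer(n_loci), mig_rate, outlier_split,
                           as.integer(max_retries)))
  D <- n_demes + n_outlier_demes
  deme <- rep(seq_len(D), each = samples_per_deme)
  is_outlier <- deme > n_demes
  angle <- ifelse(is_outlier, NA_real_, 2 * pi * (deme - 1) / n_demes)
  ids <- sprintf("D%03d_I%02d", deme,
                 sequence(rep(samples_per_deme, D)))
  markers <- data.frame(id = sprintf("L%05d", seq_len(n_loci)), chrom = "1",
                        pos = 10000L * seq_len(n_loci),
                        stringsAsFactors = FALSE)
  structure(list(genotypes = snp_genotypes(g, ids, markers),
                 deme_labels = deme, deme_angle = angle,
                 is_outlier = is_outlier,
                 params = list(n_demes = n_demes,
                               samples_per_deme = samples_per_deme,
                               n_loci = n_loci, migration_frac = migration_frac,
                               n_outlier_demes = n_outlier_demes,
                               deme_size = deme_size,
                               outlier_split = outlier_split,
                               mig_rate_4Nm = mig_rate, seed = seed)),
            class = "sim_sample")
}

#' Simulate discrete subpopulations under the Balding-Nichols model
#'
#' Per locus, an ancestral frequency `p ~ Uniform(0.1, 0.9)` is drawn and
#' each population's frequency comes from
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)`, so population
#' frequencies have mean `p` and variance `fst * p * (1 - p)`.  Genotypes
#' are `Binomial(2, p_pop) / 2`.  Loci monomorphic in the pooled sample are
#' redrawn.
#'
#' @param n_pops number of populations.
#' @param fst differentiation parameter in (0, 0.5).
#' @param samples_per_pop diploids per population.
#' @param n_loci loci.
#' @param seed RNG seed (required).
#' @return `sim_sample` (deme fields describe the populations; no angles).
#' @export
simulate_discrete_pops <- function(n_pops, fst, samples_per_pop, n_loci,
                                   seed) {
  if (missing(seed)) stop_input("seed is required")
  if (fst <= 0 || fst >= 0.5) stop_input("fst must be in (0, 0.5)")
  if (n_pops < 2L || samples_per_pop < 1L || n_loci < 1L)
    stop_input("counts must be positive (and n_pops >= 2)")
  n <- n_pops * samples_per_pop
  pop <- rep(seq_len(n_pops), each = samples_per_pop)
  g <- with_seed(seed, {
    draw_locus <- function() {
      for (try in 1:100) {
        p <- runif(1, 0.1, 0.9)
        pp <- rbeta(n_pops, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
        x <- rbinom(n, 2, pp[pop]) / 2
        if (length(unique(x)) > 1L) return(x)
      }
      stop_numeric("locus failed to segregate after 100 draws")
    }
    vapply(seq_len(n_loci), function(i) draw_locus(), numeric(n))
  })
  ids <- sprintf("P%02d_I%03d", pop, sequence(rep(samples_per_pop, n_pops)))
  markers <- data.frame(id = sprintf("L%05d", seq_len(n_loci)), chrom = "1",
                        pos = 10000L * seq_len(n_loci),
                        stringsAsFactors = FALSE)
  structure(list(genotypes = snp_genotypes(g, ids, markers),
                 deme_labels = pop, deme_angle = rep(NA_real_, n),
                 is_outlier = rep(FALSE, n),
                 params = list(n_pops = n_pops, fst = fst,
                               samples_per_pop = samples_per_pop,
                               n_loci = n_loci, seed = seed)),
            class = "sim_sample")
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("sim_sample: %d individuals x %d loci, %d demes (%d outlier)\n",
              nrow(x$genotypes$genotypes), ncol(x$genotypes$genotypes),
              length(unique(x$deme_labels)),
              length(unique(x$deme_labels[x$is_outlier]))))
  invisible(x)
}

#' Hudson's FST estimator for two populations
#'
#' Ratio-of-sums estimator: per locus the numerator is
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the denominator
#' `p1(1-p2) + p2(1-p1)`, with `n1`, `n2` allele counts; sums are taken
#' across loci before the ratio.
#'
#' @param G [snp_genotypes] or genotype matrix.
#' @param labels two-level population labels per sample.
#' @return Scalar FST estimate.
#' @export
hudson_fst <- function(G, labels) {
  g <- if (inherits(G, "snp_genotypes")) G$genotypes else G
  lev <- unique(labels)
  if (length(lev) != 2L) stop_input("hudson_fst needs exactly 2 populations")
  g1 <- g[labels == lev[1], , drop = FALSE]
  g2 <- g[labels == lev[2], , drop = FALSE]
  n1 <- 2 * colSums(!is.na(g1)); n2 <- 2 * colSums(!is.na(g2))
  p1 <- colMeans(g1, na.rm = TRUE); p2 <- colMeans(g2, na.rm = TRUE)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den) & den > 0
  sum(num[ok]) / sum(den[ok])
}
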