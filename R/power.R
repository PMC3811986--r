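# Monte-Carlo power of the allelic case-control test.

#' Power of the single-stratum allelic case-control test
#'
#' Simulates replicate biallelic markers: control genotypes under HWE at
#' allele frequency `maf`, case genotypes under a multiplicative
#' per-allele genotype relative risk `grr` (genotype g weighted by
#' `grr^g`), then applies the allelic 2 x 2 chi-square (the K = 1
#' Cochran-Mantel-Haenszel test) and counts rejections at `alpha`.
#'
#' @param n_case,n_control sample sizes (defaults: the discovery study's
#'   385 cases and 379 controls).
#' @param maf control a1 allele frequency.
#' @param grr per-allele genotype relative risk in cases.
#' @param alpha significance threshold (default genome-wide 5e-8).
#' @param n_rep number of replicate markers.
#' @param seed RNG seed.
#' @return list: `power` (fraction of replicates with `P < alpha`),
#'   `n_rep`, `mean_stat`.
#' @export
allelic_power <- function(n_case = 385, n_control = 379, maf = 0.30,
                          grr = 2.0, alpha = 5e-8, n_rep = 2000,
                          seed = 1) {
  if (maf <= 0 || maf >= 1) stop("maf must be in (0,1)")
  if (grr <= 0) stop("grr must be positive")
  set.seed(seed)
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)   # g = 0,1,2
  case_p <- hwe * grr^(0:2)
  case_p <- case_p / sum(case_p)
  Gcase <- stats::rmultinom(n_rep, n_case, case_p)     # 3 x n_rep
  Gctrl <- stats::rmultinom(n_rep, n_control, hwe)
  a <- 2 * Gcase[3, ] + Gcase[2, ]                     # case a1 alleles
  b <- 2 * n_case - a
  c <- 2 * Gctrl[3, ] + Gctrl[2, ]
  d <- 2 * n_control - c
  res <- .cmh_core(matrix(a, 1), matrix(b, 1), matrix(c, 1),
                   matrix(d, 1))
  list(power = mean(res$p < alpha, na.rm = TRUE), n_rep = n_rep,
       mean_stat = mean(res$stat, na.rm = TRUE))
}
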