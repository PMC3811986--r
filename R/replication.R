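# Family-based replication: TDT, mother-vs-father allele test, trio
# analogues of the three mother-child interaction models, random-effects
# meta-analysis, a merged fallback, and the Bonferroni replication gate.
#
# Mothers and fathers from the same trio are treated as independent
# observations, matching the unmatched chi-square design of the
# replication tests; no continuity correction anywhere.

# dosage vectors at one marker aligned to the trios
.trio_dosages <- function(gm, trios, marker) {
  g <- unclass(gm)
  list(f = g[match(trios$father_id, rownames(gm)), marker],
       m = g[match(trios$mother_id, rownames(gm)), marker],
       c = g[match(trios$child_id, rownames(gm)), marker])
}

.pearson_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (min(a + b, c + d, a + c, b + d) == 0 || n < 2)
    return(list(chisq = NA_real_, p = NA_real_))
  chisq <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# odds ratio and Woolf log-OR standard error from a 2x2 table;
# Haldane-Anscombe 0.5 added to every cell only when some cell is zero
.or_woolf <- function(a, b, c, d, haldane = TRUE) {
  if (haldane && min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (min(a, b, c, d) == 0)
    return(list(or = NA_real_, se = NA_real_))
  list(or = a * d / (b * c), se = sqrt(1/a + 1/b + 1/c + 1/d))
}

.trio_result <- function(test, marker, chisq, p, or, se, n, table = NULL,
                         flag = NA_character_) {
  structure(list(marker = marker, test = test, chi_square = chisq,
                 p_value = p, odds_ratio = or, se_log_or = se,
                 informative_n = n, table = table, flag = flag),
            class = "trio_test_result")
}

#' @export
print.trio_test_result <- function(x, ...) {
  cat(sprintf("%s @ %s: chi2 = %s, P = %s, OR = %s (n = %d)\n",
              x$test, x$marker,
              format(x$chi_square, digits = 4),
              format(x$p_value, digits = 4),
              format(x$odds_ratio, digits = 4), x$informative_n))
  invisible(x)
}

#' Transmission disequilibrium test
#'
#' Counts transmissions of a1 (`b`) versus a2 (`c`) from heterozygous
#' parents to affected children; `chi2 = (b - c)^2 / (b + c)`,
#' `OR = b / c`.  Trio-markers with a Mendelian inconsistency or a
#' missing member are skipped.
#'
#' @param gm a [geno_matrix()] covering all trio members.
#' @param trios a [trio_set()] (only affected-child trios are used).
#' @param marker marker ID.
#' @return a `trio_test_result` (`p_value = NA` when no heterozygous
#'   parent transmits).
#' @export
tdt <- function(gm, trios, marker) {
  trios <- trios[trios$affected, , drop = FALSE]
  d <- .trio_dosages(gm, trios, marker)
  ok <- !(is.na(d$f) | is.na(d$m) | is.na(d$c))
  f <- d$f[ok]; m <- d$m[ok]; c <- d$c[ok]
  h <- (f == 1) + (m == 1)                 # heterozygous parents
  hom_a1 <- (f == 2) + (m == 2)
  x <- c - hom_a1                          # a1 transmitted by het parents
  valid <- x >= 0 & x <= h
  b <- sum(x[valid])
  cc <- sum(h[valid] - x[valid])
  if (b + cc == 0)
    return(.trio_result("tdt", marker, NA_real_, NA_real_, NA_real_,
                        NA_real_, 0L))
  chisq <- (b - cc)^2 / (b + cc)
  or <- if (cc > 0 && b > 0) b / cc else NA_real_
  se <- if (b > 0 && cc > 0) sqrt(1/b + 1/cc) else NA_real_
  .trio_result("tdt", marker, chisq,
               stats::pchisq(chisq, 1, lower.tail = FALSE),
               or, se, sum(valid & h > 0),
               table = c(b = b, c = cc))
}

#' Mother-versus-father allele-frequency test
#'
#' 2 x 2 allelic chi-square with the mothers considered "cases" and the
#' fathers "controls" (each genotyped parent contributes two allele
#' observations); detects maternal-specific allele-frequency shifts in
#' ascertained families.
#'
#' @inheritParams tdt
#' @return a `trio_test_result`; the odds ratio is for a1 in mothers
#'   versus fathers.
#' @export
parent_freq_test <- function(gm, trios, marker) {
  d <- .trio_dosages(gm, trios, marker)
  m <- d$m[!is.na(d$m)]; f <- d$f[!is.na(d$f)]
  if (!length(m) || !length(f)) stop("need >= 1 genotyped parent per role")
  a <- sum(m); b <- 2 * length(m) - a
  c <- sum(f); dd <- 2 * length(f) - c
  pe <- .pearson_2x2(a, b, c, dd)
  orw <- .or_woolf(a, b, c, dd)
  .trio_result("parent_freq", marker, pe$chisq, pe$p, orw$or, orw$se,
               length(m) + length(f),
               table = matrix(c(a, b, c, dd), 2, byrow = TRUE,
                              dimnames = list(c("mother", "father"),
                                              c("a1", "a2"))))
}

.TRIO_TE_TESTS <- c("offhet_rep", "mathet_rep", "diff_rep")

# 2x2 parent-role x category table for a trio interaction analogue
.trio_te_table <- function(test, f, m, c) {
  ok <- !(is.na(f) | is.na(m) | is.na(c))
  f <- f[ok]; m <- m[ok]; c <- c[ok]
  if (test == "offhet_rep") {
    sel <- c == 1                          # heterozygous offspring
    cat_m <- m[sel] != 1                   # homozygous parent
    cat_f <- f[sel] != 1
  } else if (test == "mathet_rep") {
    sel <- c != 1                          # homozygous offspring
    cat_m <- m[sel] == 1                   # heterozygous parent
    cat_f <- f[sel] == 1
  } else {                                 # diff_rep: all trios
    sel <- rep(TRUE, length(c))
    cat_m <- m[sel] != c[sel]              # opposite genotype to proband
    cat_f <- f[sel] != c[sel]
  }
  matrix(c(sum(cat_m), sum(!cat_m), sum(cat_f), sum(!cat_f)),
         2, byrow = TRUE,
         dimnames = list(c("mother", "father"), c("yes", "no")))
}

#' Trio analogues of the transgenerational interaction models
#'
#' 2 x 2 Pearson chi-square (1 df, no continuity correction) comparing
#' mothers to fathers of affected children:
#' * `offhet_rep` — among trios with a heterozygous child, homozygous
#'   vs heterozygous parents;
#' * `mathet_rep` — among trios with a homozygous child, heterozygous
#'   vs homozygous parents;
#' * `diff_rep` — all trios, parent genotype different from vs identical
#'   to the child's.
#'
#' @param test one of `"offhet_rep"`, `"mathet_rep"`, `"diff_rep"`.
#' @inheritParams tdt
#' @return a `trio_test_result`; the odds ratio is mothers-vs-fathers
#'   for the first (model-defining) column.
#' @export
trio_te_test <- function(test, gm, trios, marker) {
  test <- match.arg(test, .TRIO_TE_TESTS)
  trios <- trios[trios$affected, , drop = FALSE]
  d <- .trio_dosages(gm, trios, marker)
  tab <- .trio_te_table(test, d$f, d$m, d$c)
  pe <- .pearson_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  orw <- .or_woolf(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  .trio_result(test, marker, pe$chisq, pe$p, orw$or, orw$se,
               sum(tab), table = tab)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-dataset log odds ratios: fixed weights `w = 1/se^2`,
#' heterogeneity `Q = sum w (x - xbar_fixed)^2`,
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, then
#' random-effects weights `w* = 1/(se^2 + tau2)` give the pooled
#' estimate, its standard error `(sum w*)^{-1/2}` and a two-sided
#' normal P-value.
#'
#' @param log_or per-dataset log odds ratios.
#' @param se per-dataset standard errors (finite, positive).
#' @return list of class `meta_result`: `pooled_log_or`, `se`, `tau2`,
#'   `q`, `z`, `p_value`, `k`, `inputs`; a single dataset is passed
#'   through with `flag = "single_dataset"`.
#' @export
dl_meta <- function(log_or, se) {
  ok <- is.finite(log_or) & is.finite(se) & se > 0
  log_or <- log_or[ok]; se <- se[ok]
  k <- length(log_or)
  if (k == 0) stop("no usable dataset estimates")
  if (k == 1) {
    z <- log_or / se
    return(structure(list(pooled_log_or = log_or, se = se, tau2 = 0,
                          q = 0, z = z,
                          p_value = 2 * stats::pnorm(-abs(z)), k = 1L,
                          inputs = data.frame(log_or, se),
                          flag = "single_dataset"),
                     class = "meta_result"))
  }
  w <- 1 / se^2
  xf <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - xf)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * log_or) / sum(ws)
  se_p <- 1 / sqrt(sum(ws))
  z <- pooled / se_p
  structure(list(pooled_log_or = pooled, se = se_p, tau2 = tau2, q = q,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)), k = k,
                 inputs = data.frame(log_or, se), flag = NA_character_),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "DL meta (k = %d): logOR = %.4f (se %.4f), tau2 = %.4f, P = %.4g\n",
    x$k, x$pooled_log_or, x$se, x$tau2, x$p_value))
  invisible(x)
}

#' Merged replication test across datasets
#'
#' When an allelic combination has zero observations in any single
#' dataset, the datasets are considered jointly: per-dataset 2 x 2
#' tables (or TDT `(b, c)` pairs) are summed element-wise and a single
#' chi-square computed on the merged counts.
#'
#' @param tables list of same-orientation 2 x 2 matrices, or of named
#'   `c(b =, c =)` TDT count pairs.
#' @param test test label (determines the chi-square form: `"tdt"` uses
#'   the transmission form, everything else Pearson).
#' @param marker marker ID for the result.
#' @return a `trio_test_result` flagged `"merged"` (`p = NA` when a
#'   margin is still zero after merging).
#' @export
merged_test <- function(tables, test = "diff_rep", marker = NA_character_) {
  tot <- Reduce(`+`, tables)
  if (test == "tdt") {
    b <- tot[["b"]]; cc <- tot[["c"]]
    if (b + cc == 0)
      return(.trio_result("tdt", marker, NA_real_, NA_real_, NA_real_,
                          NA_real_, 0L, flag = "merged"))
    chisq <- (b - cc)^2 / (b + cc)
    or <- if (b > 0 && cc > 0) b / cc else NA_real_
    se <- if (b > 0 && cc > 0) sqrt(1/b + 1/cc) else NA_real_
    return(.trio_result("tdt", marker, chisq,
                        stats::pchisq(chisq, 1, lower.tail = FALSE),
                        or, se, as.integer(b + cc), table = tot,
                        flag = "merged"))
  }
  pe <- .pearson_2x2(tot[1, 1], tot[1, 2], tot[2, 1], tot[2, 2])
  orw <- .or_woolf(tot[1, 1], tot[1, 2], tot[2, 1], tot[2, 2])
  .trio_result(test, marker, pe$chisq, pe$p, orw$or, orw$se,
               sum(tot), table = tot, flag = "merged")
}

#' Bonferroni replication gate
#'
#' A result replicates when its replication P-value beats `alpha /
#' n_tests` *and* the replication effect points the same way as the
#' discovery effect; it is nominal when `P < alpha` with the same
#' direction.
#'
#' @param results data.frame with columns `p_value`, `log_or`
#'   (replication) and `discovery_log_or`.
#' @param n_tests Bonferroni denominator: the number of results taken
#'   into replication.
#' @param alpha nominal level (default 0.05).
#' @return `results` with logical columns `same_direction`, `nominal`,
#'   `replicated` appended.
#' @export
bonferroni_gate <- function(results, n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  same <- sign(results$log_or) == sign(results$discovery_log_or) &
    results$log_or != 0
  same[is.na(same)] <- FALSE
  p <- results$p_value
  results$same_direction <- same
  results$nominal <- !is.na(p) & p < alpha & same
  results$replicated <- !is.na(p) & p < alpha / n_tests & same
  results
}
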