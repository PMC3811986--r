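# Sample- and marker-level quality control for duo genotype data.
#
# Thresholds follow the discovery pipeline conventions: sample call rate
# strictly > 0.97, marker call rate >= 0.97 (fail iff < 0.97), <= 10
# mother-child Mendelian inconsistencies per marker, and a Hardy-Weinberg
# exact P >= 1e-10 in control mothers.

#' Per-sample and per-marker call rates
#'
#' @param gm a [geno_matrix()].
#' @param sample_thresh samples pass when call rate is strictly greater
#'   than this (default 0.97).
#' @param marker_thresh markers pass when call rate is at least this
#'   (default 0.97; a marker fails iff its rate is below the threshold).
#' @return list with data.frames `sample` (`id`, `call_rate`, `pass`) and
#'   `marker` (`id`, `call_rate`, `pass`).
#' @export
call_rates <- function(gm, sample_thresh = 0.97, marker_thresh = 0.97) {
  if (nrow(gm) == 0 || ncol(gm) == 0) stop("empty genotype matrix")
  ok <- !is.na(unclass(gm))
  sr <- rowMeans(ok)
  mr <- colMeans(ok)
  list(sample = data.frame(id = rownames(gm), call_rate = sr,
                           pass = sr > sample_thresh,
                           row.names = NULL),
       marker = data.frame(id = marker_map(gm)$id, call_rate = mr,
                           pass = mr >= marker_thresh,
                           row.names = NULL))
}

# dosage matrices for the mothers and children of a duo set, rows aligned
# to the duos
.duo_dosages <- function(gm_m, gm_c, duos) {
  im <- match(duos$mother_id, rownames(gm_m))
  ic <- match(duos$child_id, rownames(gm_c))
  if (anyNA(im)) stop("mothers missing from maternal matrix: ",
                      paste(utils::head(duos$mother_id[is.na(im)]),
                            collapse = ", "))
  if (anyNA(ic)) stop("children missing from child matrix: ",
                      paste(utils::head(duos$child_id[is.na(ic)]),
                            collapse = ", "))
  list(m = unclass(gm_m)[im, , drop = FALSE],
       c = unclass(gm_c)[ic, , drop = FALSE])
}

#' Mother-child Mendelian inconsistencies
#'
#' For biallelic markers the only duo-detectable Mendelian error is the
#' opposite-homozygote configuration: mother and child share no allele,
#' i.e. dosages (0,2) or (2,0).
#'
#' @param gm_m,gm_c maternal and child [geno_matrix()] objects sharing a
#'   marker panel.
#' @param duos a [duo_set()].
#' @param max_errors markers with more than this many errors fail
#'   (default 10).
#' @return list with data.frames `marker` (`id`, `errors`, `pass`) and
#'   `duo` (`mother_id`, `child_id`, `errors`).
#' @export
duo_mendel_errors <- function(gm_m, gm_c, duos, max_errors = 10) {
  d <- .duo_dosages(gm_m, gm_c, duos)
  err <- (d$m == 0L & d$c == 2L) | (d$m == 2L & d$c == 0L)
  err[is.na(err)] <- FALSE
  me <- colSums(err)
  list(marker = data.frame(id = marker_map(gm_m)$id, errors = me,
                           pass = me <= max_errors, row.names = NULL),
       duo = data.frame(mother_id = duos$mother_id,
                        child_id = duos$child_id,
                        errors = rowSums(err), row.names = NULL))
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test: the P-value is the sum of probabilities of all
#' heterozygote counts (with the same allele totals and parity) whose
#' probability does not exceed that of the observed count, where
#' `P(k hets) \propto 2^k n! / (n_aa! k! n_bb!)` under fixed allele
#' counts.  Enumeration is carried out in log space and is exact for
#' totals up to about 1e5.  The standard (not mid-p) tail definition is
#' used.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectors are recycled to common
#'   length and tested element-wise).
#' @return exact two-sided P-value(s) in `[0,1]`.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  mapply(.hwe_exact_one, n_aa, n_ab, n_bb, USE.NAMES = FALSE)
}

.hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  if (min(n_aa, n_ab, n_bb) < 0) stop("negative genotype count")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("total genotype count must be >= 1")
  nr <- 2L * min(n_aa, n_bb) + n_ab        # rare-allele copies
  if (nr == 0L) return(1)
  ks <- seq.int(nr %% 2L, min(nr, 2L * n - nr), by = 2L)
  lp <- ks * log(2) - lfactorial((nr - ks) / 2) - lfactorial(ks) -
    lfactorial(n - (nr + ks) / 2)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  obs <- p[ks == n_ab]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Inbreeding coefficient F from known allele frequencies
#'
#' `F = (O_hom - E_hom) / (L - E_hom)` per sample, where `O_hom` is the
#' observed homozygous call count, `E_hom = sum_i (1 - 2 q_i (1 - q_i))`
#' over that sample's non-missing markers, and `L` is the non-missing
#' marker count.  Frequencies are supplied (typically estimated from
#' control mothers) rather than re-estimated per subset.
#'
#' @param gm a [geno_matrix()].
#' @param freqs per-marker a1 allele frequencies in (0,1), aligned with
#'   the marker map.
#' @param flag_thresh samples with `F` below this are flagged as
#'   potentially contaminated (default -0.15).
#' @return data.frame `id`, `f`, `n_markers`, `flag` (`f` is `NA` when
#'   the denominator degenerates, and such samples are flagged).
#' @export
inbreeding_f <- function(gm, freqs, flag_thresh = -0.15) {
  if (length(freqs) != ncol(gm))
    stop("freqs length must equal marker count")
  if (any(freqs <= 0 | freqs >= 1))
    stop("freqs must lie strictly inside (0,1)")
  g <- unclass(gm)
  ok <- !is.na(g)
  hom <- ok & g != 1L
  ehom_marker <- 1 - 2 * freqs * (1 - freqs)
  e_hom <- ok %*% ehom_marker
  o_hom <- rowSums(hom)
  L <- rowSums(ok)
  den <- L - e_hom
  f <- ifelse(abs(den) < 1e-12, NA_real_, (o_hom - e_hom) / den)
  data.frame(id = rownames(gm), f = as.numeric(f), n_markers = L,
             flag = is.na(f) | f < flag_thresh, row.names = NULL)
}

#' IBS sharing and relatedness for mother-child duos
#'
#' Computes per-duo IBS0 (opposite-homozygote) rate and the
#' method-of-moments pi-hat from observed IBS0/IBS1/IBS2 counts given
#' supplied allele frequencies (the PLINK `--genome` moment estimator).
#' A duo with IBS0 rate above `ibs0_thresh` is flagged as misidentified:
#' true parent-offspring pairs cannot be IBS0 in error-free data.
#'
#' @param gm_m,gm_c maternal and child matrices on a shared panel.
#' @param duos a [duo_set()].
#' @param freqs per-marker a1 frequencies in (0,1).
#' @param ibs0_thresh misidentification flag threshold (default 0.01).
#' @param min_markers minimum jointly non-missing markers per duo
#'   (default 100).
#' @return data.frame `mother_id`, `child_id`, `n_markers`, `ibs0_rate`,
#'   `pihat`, `flag`.
#' @export
duo_relatedness <- function(gm_m, gm_c, duos, freqs, ibs0_thresh = 0.01,
                            min_markers = 100) {
  if (length(freqs) != ncol(gm_m))
    stop("freqs length must equal marker count")
  d <- .duo_dosages(gm_m, gm_c, duos)
  ok <- !is.na(d$m) & !is.na(d$c)
  n_ok <- rowSums(ok)
  if (any(n_ok < min_markers))
    stop("duo(s) with fewer than ", min_markers,
         " jointly non-missing markers")
  diffd <- abs(d$m - d$c)
  ibs0 <- ok & diffd == 2L
  ibs1 <- ok & diffd == 1L
  ibs2 <- ok & diffd == 0L

  p <- freqs; q <- 1 - freqs
  # expected per-marker IBS-class probabilities for unrelated (IBD0) and
  # one-allele-shared (IBD1) pairs
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e1_ibs2 <- p^3 + q^3 + p^2 * q + p * q^2

  s0 <- ok %*% e0_ibs0
  s0_1 <- ok %*% e0_ibs1
  s0_2 <- ok %*% e0_ibs2
  s1_1 <- ok %*% e1_ibs1
  s1_2 <- ok %*% e1_ibs2

  n0 <- rowSums(ibs0); n1 <- rowSums(ibs1); n2 <- rowSums(ibs2)
  p0 <- as.numeric(n0 / s0)
  p1 <- as.numeric((n1 - p0 * s0_1) / s1_1)
  p2 <- as.numeric((n2 - p0 * s0_2 - p1 * s1_2) / n_ok)
  # clamp to the simplex as the moment estimator can stray outside it
  p0 <- pmin(pmax(p0, 0), 1)
  p1 <- pmin(pmax(p1, 0), 1)
  p2 <- pmin(pmax(p2, 0), 1)
  tot <- p0 + p1 + p2
  pihat <- (p1 / 2 + p2) / tot
  ibs0_rate <- n0 / n_ok
  data.frame(mother_id = duos$mother_id, child_id = duos$child_id,
             n_markers = n_ok, ibs0_rate = ibs0_rate,
             pihat = pmin(pmax(pihat, 0), 1),
             flag = ibs0_rate > ibs0_thresh, row.names = NULL)
}

#' Default QC thresholds
#'
#' @param sample_call_rate samples kept when call rate is strictly above
#'   this.
#' @param marker_call_rate markers kept when call rate is at least this.
#' @param mendel_max markers kept when duo Mendelian errors do not
#'   exceed this.
#' @param hwe_min_p markers kept when the Hardy-Weinberg exact P in
#'   control mothers is at least this.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(sample_call_rate = 0.97,
                          marker_call_rate = 0.97,
                          mendel_max = 10,
                          hwe_min_p = 1e-10) {
  list(sample_call_rate = sample_call_rate,
       marker_call_rate = marker_call_rate,
       mendel_max = mendel_max, hwe_min_p = hwe_min_p)
}

#' Apply the full duo QC pipeline
#'
#' Stages: (1) sample call-rate filter in each matrix, dropping duos that
#' lose a member; (2) marker call-rate filter separately in the maternal
#' and child sets; (3) duo Mendelian-error filter; (4) Hardy-Weinberg
#' exact filter in control mothers.  The marker set carried into
#' transgenerational analysis is the intersection of the maternal-pass
#' and child-pass sets; every exclusion is logged with a reason code.
#' Idempotent: re-running on its own output removes nothing.
#'
#' @param gm_m,gm_c maternal and child [geno_matrix()] objects on a
#'   shared marker panel.
#' @param duos a [duo_set()].
#' @param thresholds a [qc_thresholds()] list.
#' @return list with elements `gm_m`, `gm_c`, `duos` (filtered) and
#'   `report` (list of per-sample, per-marker and per-duo tables plus an
#'   `exclusions` data.frame of `entity`, `id`, `reason`).
#' @export
apply_qc <- function(gm_m, gm_c, duos, thresholds = qc_thresholds()) {
  th <- thresholds
  excl <- list()
  note <- function(entity, id, reason) {
    if (length(id))
      excl[[length(excl) + 1L]] <<- data.frame(entity = entity, id = id,
                                               reason = reason)
  }

  cr_m <- call_rates(gm_m, th$sample_call_rate, th$marker_call_rate)
  cr_c <- call_rates(gm_c, th$sample_call_rate, th$marker_call_rate)
  keep_sm <- cr_m$sample$id[cr_m$sample$pass]
  keep_sc <- cr_c$sample$id[cr_c$sample$pass]
  note("sample", setdiff(cr_m$sample$id, keep_sm), "sample_call_rate")
  note("sample", setdiff(cr_c$sample$id, keep_sc), "sample_call_rate")

  keep_duo <- duos$mother_id %in% keep_sm & duos$child_id %in% keep_sc
  note("duo", duos$child_id[!keep_duo], "member_failed_sample_qc")
  duos2 <- duos[keep_duo, , drop = FALSE]
  class(duos2) <- class(duos)
  if (nrow(duos2) == 0) stop("no duos survive sample QC")
  gm_m2 <- gm_m[duos2$mother_id, ]
  gm_c2 <- gm_c[duos2$child_id, ]

  # marker call rate, per set, on QC-passing samples
  cr_m2 <- call_rates(gm_m2, th$sample_call_rate, th$marker_call_rate)
  cr_c2 <- call_rates(gm_c2, th$sample_call_rate, th$marker_call_rate)
  pass_call <- cr_m2$marker$pass & cr_c2$marker$pass
  note("marker", cr_m2$marker$id[!pass_call], "marker_call_rate")

  me <- duo_mendel_errors(gm_m2, gm_c2, duos2, th$mendel_max)
  note("marker", me$marker$id[!me$marker$pass & pass_call], "mendel")

  ctrl_m <- unclass(gm_m2)[duos2$status == "control", , drop = FALSE]
  n_aa <- colSums(ctrl_m == 2L, na.rm = TRUE)  # a1 homozygotes
  n_ab <- colSums(ctrl_m == 1L, na.rm = TRUE)
  n_bb <- colSums(ctrl_m == 0L, na.rm = TRUE)
  tot <- n_aa + n_ab + n_bb
  hwe_p <- rep(1, ncol(gm_m2))
  nz <- tot >= 1
  hwe_p[nz] <- hwe_exact_p(n_aa[nz], n_ab[nz], n_bb[nz])
  pass_hwe <- hwe_p >= th$hwe_min_p
  note("marker", marker_map(gm_m2)$id[!pass_hwe & pass_call &
                                        me$marker$pass], "hwe")

  keep_mark <- pass_call & me$marker$pass & pass_hwe
  if (!any(keep_mark)) stop("no markers survive QC")

  gm_m3 <- gm_m2[, which(keep_mark)]
  gm_c3 <- gm_c2[, which(keep_mark)]
  report <- list(
    sample_m = cr_m$sample, sample_c = cr_c$sample,
    marker = data.frame(id = cr_m2$marker$id,
                        call_rate_m = cr_m2$marker$call_rate,
                        call_rate_c = cr_c2$marker$call_rate,
                        mendel_errors = me$marker$errors,
                        hwe_p = hwe_p, pass = keep_mark,
                        row.names = NULL),
    duo = me$duo,
    exclusions = if (length(excl)) do.call(rbind, excl)
    else data.frame(entity = character(), id = character(),
                    reason = character()),
    thresholds = th)
  list(gm_m = gm_m3, gm_c = gm_c3, duos = duos2, report = report)
}
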