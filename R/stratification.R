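# Empirical stratification: identity-by-state distance, complete-linkage
# clustering, genomic inflation, and inflation-guided choice of K.

#' Pairwise identity-by-state distance
#'
#' `d(i,j) = 1 - IBS(i,j)` where IBS is the mean, over jointly
#' non-missing markers, of (shared allele count)/2.  For dosages this is
#' `mean(|g_i - g_j|)/2`, computed via the Manhattan distance (which
#' rescales over missing entries exactly as required).
#'
#' @param gm a [geno_matrix()] (at least 2 samples).
#' @return a symmetric distance matrix with sample IDs as dimnames.
#' @export
ibs_distance <- function(gm) {
  if (nrow(gm) < 2) stop("need at least 2 samples")
  d <- as.matrix(stats::dist(unclass(gm), method = "manhattan")) /
    (2 * ncol(gm))
  if (anyNA(d))
    stop("sample pair(s) with zero overlapping markers")
  d
}

#' Complete-linkage clustering of an IBS distance matrix
#'
#' Agglomerative complete-linkage clustering cut at `K` groups.
#' Deterministic given the input; with continuous IBS distances ties are
#' essentially impossible and the assignment is stable under sample
#' permutation.
#'
#' @param dist_mat symmetric distance matrix (e.g. [ibs_distance()]).
#' @param K number of clusters, `1 <= K <= n`.
#' @return named integer vector mapping sample ID to cluster in `1..K`.
#' @export
cluster_samples <- function(dist_mat, K) {
  n <- nrow(dist_mat)
  if (K < 1 || K > n) stop("K must lie in 1..n_samples")
  if (K == 1) return(stats::setNames(rep(1L, n), rownames(dist_mat)))
  hc <- stats::hclust(stats::as.dist(dist_mat), method = "complete")
  stats::cutree(hc, k = K)
}

#' Genomic inflation factor
#'
#' `lambda = median(statistics) / qchisq(0.5, 1)` for 1-df chi-square
#' association statistics; `lambda` near 1 indicates adequate control of
#' confounding.
#'
#' @param statistics numeric vector of 1-df chi-square statistics
#'   (at least 100; `NA`s dropped).
#' @return the inflation factor lambda.
#' @export
genomic_lambda <- function(statistics) {
  statistics <- statistics[!is.na(statistics)]
  if (length(statistics) < 100)
    stop("need >= 100 statistics for a stable lambda")
  stats::median(statistics) / stats::qchisq(0.5, 1)
}

#' Observed/expected quantiles for a QQ plot
#'
#' @param p vector of P-values.
#' @return data.frame with `expected` and `observed` -log10 P columns,
#'   sorted for plotting.
#' @export
qq_data <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(pmax(p, 1e-300)))
}

#' Choose the cluster count K by minimizing genomic inflation
#'
#' For each `K` in `1..k_max`, mothers and children are clustered
#' separately (complete linkage on 1-IBS); the maternal solution
#' stratifies the maternal main-effect scan and the proband solution the
#' proband scan.  Genome-wide CMH statistics give `lambda_proband` and
#' `lambda_maternal`; the selected `K` minimizes
#' `max(|lambda_p - 1|, |lambda_m - 1|)` (deflation is penalized too),
#' with ties resolved toward the smaller `K`.
#'
#' @param gm_m,gm_c maternal and child matrices (QC'd, shared panel).
#' @param duos a [duo_set()].
#' @param k_max largest cluster count to consider.
#' @param thin test every `thin`-th marker in the lambda scans
#'   (default 1 = every marker).
#' @return object of class `cluster_solution`: list with `K`,
#'   `maternal` and `proband` assignments (named vectors for all
#'   candidate K, element `assignments[[K]]`), the selected assignment
#'   vectors, `lambda_table` (K, lambda_proband, lambda_maternal,
#'   criterion) and the distance matrices are not retained.
#' @export
select_k <- function(gm_m, gm_c, duos, k_max = 3, thin = 1) {
  if (k_max < 1) stop("k_max must be >= 1")
  keep <- seq(1, ncol(gm_m), by = thin)
  gm_m_s <- gm_m[, keep]
  gm_c_s <- gm_c[, keep]
  dm <- ibs_distance(gm_m[duos$mother_id, ])
  dc <- ibs_distance(gm_c[duos$child_id, ])
  hc_m <- stats::hclust(stats::as.dist(dm), method = "complete")
  hc_c <- stats::hclust(stats::as.dist(dc), method = "complete")

  tab <- data.frame(K = seq_len(k_max), lambda_proband = NA_real_,
                    lambda_maternal = NA_real_, criterion = NA_real_)
  assign_m <- assign_c <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    am <- if (K == 1) stats::setNames(rep(1L, nrow(dm)), rownames(dm))
    else stats::cutree(hc_m, k = K)
    ac <- if (K == 1) stats::setNames(rep(1L, nrow(dc)), rownames(dc))
    else stats::cutree(hc_c, k = K)
    assign_m[[K]] <- am; assign_c[[K]] <- ac
    sp <- scan_assoc(gm_m_s, gm_c_s, duos, "proband",
                     strata = list(proband = ac))
    sm <- scan_assoc(gm_m_s, gm_c_s, duos, "maternal",
                     strata = list(maternal = am))
    lp <- genomic_lambda(sp$stat)
    lm <- genomic_lambda(sm$stat)
    tab$lambda_proband[K] <- lp
    tab$lambda_maternal[K] <- lm
    tab$criterion[K] <- max(abs(lp - 1), abs(lm - 1))
  }
  best <- which.min(tab$criterion)   # which.min takes the first (smallest K)
  structure(list(K = best,
                 maternal = assign_m[[best]],
                 proband = assign_c[[best]],
                 lambda_table = tab),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: K =", x$K, "\n")
  print(x$lambda_table, row.names = FALSE)
  invisible(x)
}
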