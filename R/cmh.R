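# Cochran-Mantel-Haenszel stratified association test and the
# genome-wide scan driver for the five discovery models.

# core CMH arithmetic over K x M count matrices (one column per marker),
# vectorized across markers.  Strata with n_k < 2 or a zero margin
# contribute nothing; a marker is untestable (NA) if all strata drop.
.cmh_core <- function(a, b, c, d) {
  storage.mode(a) <- storage.mode(b) <- "double"
  storage.mode(c) <- storage.mode(d) <- "double"
  n <- a + b + c + d
  valid <- n >= 2 & (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  a[!valid] <- b[!valid] <- c[!valid] <- d[!valid] <- 0
  n <- a + b + c + d
  e <- ifelse(valid, (a + b) * (a + c) / n, 0)
  v <- ifelse(valid,
              (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1)), 0)
  sum_a <- colSums(a); sum_e <- colSums(e); sum_v <- colSums(v)
  any_valid <- colSums(valid) > 0
  stat <- ifelse(any_valid & sum_v > 0, (sum_a - sum_e)^2 / sum_v,
                 NA_real_)
  or_num <- colSums(ifelse(valid, a * d / n, 0))
  or_den <- colSums(ifelse(valid, b * c / n, 0))
  or <- ifelse(any_valid & or_den > 0 & or_num > 0, or_num / or_den,
               NA_real_)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       or = or, n_eff = colSums(n))
}

#' Cochran-Mantel-Haenszel test of a stratified 2 x 2 table
#'
#' With per-stratum tables `[[a,b],[c,d]]` and `n = a+b+c+d`, the 1-df
#' statistic is `(sum a_k - sum E_k)^2 / sum V_k` with
#' `E = (a+b)(a+c)/n` and `V = (a+b)(c+d)(a+c)(b+d)/(n^2 (n-1))`;
#' no continuity correction.  The Mantel-Haenszel common odds ratio is
#' `sum(a_k d_k / n_k) / sum(b_k c_k / n_k)`.  Strata with fewer than
#' two observations or a zero margin are dropped; when every stratum
#' drops the result is untestable (`p = NA`), not an error.
#'
#' @param stack a [stratified_table()] (2 x 2 x K array: group x class x
#'   stratum) or a 2 x 2 matrix (treated as K = 1).
#' @return list of class `assoc_result`: `statistic`, `df`, `p_value`,
#'   `or_mh`, `n_effective`.
#' @export
cmh_test <- function(stack) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(2, 2, 1))
  if (!(length(dim(stack)) == 3 && all(dim(stack)[1:2] == 2)))
    stop("stack must be a 2 x 2 x K array")
  a <- matrix(stack[1, 1, ], ncol = 1)
  b <- matrix(stack[1, 2, ], ncol = 1)
  c <- matrix(stack[2, 1, ], ncol = 1)
  d <- matrix(stack[2, 2, ], ncol = 1)
  res <- .cmh_core(a, b, c, d)
  structure(list(statistic = res$stat, df = 1L, p_value = res$p,
                 or_mh = res$or, n_effective = res$n_eff),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("CMH chi-square = %.4f (df = 1), P = %.4g, OR_MH = %s, n = %d\n",
              x$statistic, x$p_value,
              ifelse(is.na(x$or_mh), "NA", sprintf("%.4f", x$or_mh)),
              x$n_effective))
  invisible(x)
}

.SCAN_MODELS <- c("proband", "maternal", "offhet", "mathet", "diff")

# per-(stratum, status) a/b/c/d count matrices for the allele test,
# vectorized over markers.  X: samples x markers dosages; status, strat
# aligned with rows.
.allele_counts <- function(X, status, strat, K) {
  M <- ncol(X)
  a <- b <- c <- d <- matrix(0, K, M)
  ok <- !is.na(X)
  X0 <- X; X0[!ok] <- 0L
  for (k in seq_len(K)) {
    ca <- strat == k & status == "case"
    co <- strat == k & status == "control"
    a[k, ] <- colSums(X0[ca, , drop = FALSE])
    b[k, ] <- 2 * colSums(ok[ca, , drop = FALSE]) - a[k, ]
    c[k, ] <- colSums(X0[co, , drop = FALSE])
    d[k, ] <- 2 * colSums(ok[co, , drop = FALSE]) - c[k, ]
  }
  list(a = a, b = b, c = c, d = d)
}

# exposed/unexposed counts for a binary-classifier model, vectorized
# over markers via a classify_pair-derived lookup table
.binary_counts <- function(Dm, Dc, status, strat, K, model, mode) {
  combos <- expand.grid(m = c(0L, 1L, 2L, NA), c = c(0L, 1L, 2L, NA))
  lut <- as.character(classify_pair(model, combos$m, combos$c, mode))
  idx_m <- ifelse(is.na(Dm), 4L, Dm + 1L)       # 1..4
  idx_c <- ifelse(is.na(Dc), 4L, Dc + 1L)
  cls <- matrix(lut[idx_m + 4L * (idx_c - 1L)], nrow = nrow(Dm))
  E <- cls == "exposed"
  U <- cls == "unexposed"
  M <- ncol(Dm)
  a <- b <- c <- d <- matrix(0, K, M)
  for (k in seq_len(K)) {
    ca <- strat == k & status == "case"
    co <- strat == k & status == "control"
    a[k, ] <- colSums(E[ca, , drop = FALSE])
    b[k, ] <- colSums(U[ca, , drop = FALSE])
    c[k, ] <- colSums(E[co, , drop = FALSE])
    d[k, ] <- colSums(U[co, , drop = FALSE])
  }
  list(a = a, b = b, c = c, d = d)
}

#' Genome-wide stratified CMH scan
#'
#' Runs one of the five discovery models over every marker:
#' * `proband` — allele-frequency case/control test in the children,
#'   stratified by the proband cluster solution;
#' * `maternal` — the same test in the mothers, with "affected" defined
#'   as having a case child, stratified by the maternal solution;
#' * `offhet`, `mathet`, `diff` — CMH tests of the binary mother-child
#'   classifiers between case and control pairs, stratified by the
#'   maternal solution.
#'
#' @param gm_m,gm_c maternal and child [geno_matrix()] objects (QC'd,
#'   shared panel).
#' @param duos a [duo_set()].
#' @param model one of `"proband"`, `"maternal"`, `"offhet"`,
#'   `"mathet"`, `"diff"`.
#' @param strata a `cluster_solution` from [select_k()], or a list with
#'   named-vector elements `maternal` and/or `proband` mapping sample ID
#'   to stratum; `NULL` = a single stratum.
#' @param mode classifier mode for the three interaction models.
#' @return data.frame with one row per marker: `marker`, `chrom`, `pos`,
#'   `a1`, `a2`, `model`, `stat`, `df`, `p`, `or_mh`, `n_eff`.
#' @export
scan_assoc <- function(gm_m, gm_c, duos, model, strata = NULL,
                       mode = c("literal", "conditioned")) {
  if (!model %in% .SCAN_MODELS)
    stop("unknown model: ", model, " (expected one of ",
         paste(.SCAN_MODELS, collapse = ", "), ")")
  mode <- match.arg(mode)
  get_assign <- function(which, ids) {
    v <- if (inherits(strata, "cluster_solution")) strata[[which]]
    else strata[[which]]
    if (is.null(v)) return(rep(1L, length(ids)))
    out <- unname(v[ids])
    if (anyNA(out)) stop("strata assignment missing for some samples")
    as.integer(out)
  }
  status <- as.character(duos$status)
  if (model == "proband") {
    strat <- get_assign("proband", duos$child_id)
    X <- unclass(gm_c)[match(duos$child_id, rownames(gm_c)), ,
                       drop = FALSE]
    cnt <- .allele_counts(X, status, strat, max(strat))
    map <- marker_map(gm_c)
  } else if (model == "maternal") {
    strat <- get_assign("maternal", duos$mother_id)
    X <- unclass(gm_m)[match(duos$mother_id, rownames(gm_m)), ,
                       drop = FALSE]
    cnt <- .allele_counts(X, status, strat, max(strat))
    map <- marker_map(gm_m)
  } else {
    strat <- get_assign("maternal", duos$mother_id)
    Dm <- unclass(gm_m)[match(duos$mother_id, rownames(gm_m)), ,
                        drop = FALSE]
    Dc <- unclass(gm_c)[match(duos$child_id, rownames(gm_c)), ,
                        drop = FALSE]
    cnt <- .binary_counts(Dm, Dc, status, strat, max(strat), model, mode)
    map <- marker_map(gm_m)
  }
  res <- .cmh_core(cnt$a, cnt$b, cnt$c, cnt$d)
  data.frame(marker = map$id, chrom = map$chrom, pos = map$pos,
             a1 = map$a1, a2 = map$a2, model = model,
             stat = res$stat, df = 1L, p = res$p, or_mh = res$or,
             n_eff = res$n_eff, row.names = NULL,
             stringsAsFactors = FALSE)
}
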