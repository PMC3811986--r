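# Multinomial maximum-likelihood model (MMLM) for case-control duo
# genotype counts, and nested likelihood-ratio tests.
#
# Population duo distribution under HWE and random mating:
#   mu(m, c) = HWE(m; q) * P(c | m, q),
# where the mother transmits a1 with probability m/2 and the random-mate
# father with probability q.  Disease risk is multiplicative:
#   rho(m, c) = r1^{[c=1]} r1^2{[c=2]} * s1^{[m=1]} s1^2{[m=2]} *
#               j^{I_model(m, c)},
# with interaction indicators
#   I_diff   = [m != c],
#   I_offhet = [c = 1 and m in {0,2}],
#   I_mathet = [m = 1 and c in {0,2}].
# Case duos follow mu*rho renormalized (ascertainment absorbs the
# baseline risk alpha, so only relative risks are identifiable);
# control duos follow mu itself (rare-disease approximation).

.MMLM_MODELS <- c("maternal", "offhet", "mathet", "diff")

# 3x3 grids of m (rows) and c (cols)
.M_GRID <- matrix(rep(0:2, 3), 3, 3)
.C_GRID <- t(.M_GRID)

#' Interaction indicator for a transgenerational model
#'
#' @param model `"maternal"` (no interaction term, all-zero indicator),
#'   `"offhet"`, `"mathet"` or `"diff"`.
#' @return 3 x 3 0/1 matrix over mother (rows 0..2) and child
#'   (cols 0..2) dosage.
#' @export
interaction_indicator <- function(model) {
  model <- match.arg(model, .MMLM_MODELS)
  switch(model,
         maternal = matrix(0, 3, 3),
         diff = (.M_GRID != .C_GRID) + 0,
         offhet = (.C_GRID == 1 & .M_GRID != 1) + 0,
         mathet = (.M_GRID == 1 & .C_GRID != 1) + 0)
}

# risk multiplier grid rho(m, c)
.rho_grid <- function(r1, s1, j, model) {
  r1^.C_GRID * s1^.M_GRID * j^interaction_indicator(model)
}

#' Expected duo genotype-cell probabilities
#'
#' Returns the 3 x 3 (mother x child dosage) probability tables for case
#' and control duos implied by allele frequency `q` and the
#' multiplicative risk parameters.  Mendelian-impossible cells (0,2) and
#' (2,0) have probability zero; each table sums to 1.
#'
#' @param q a1 allele frequency in (0,1).
#' @param r1 child per-copy relative risk (two copies act as `r1^2`).
#' @param s1 maternal per-copy relative risk (two copies as `s1^2`).
#' @param j interaction multiplier on the model's exposed cells.
#' @param model transgenerational model (see
#'   [interaction_indicator()]).
#' @return list with 3 x 3 matrices `case` and `control` (rows m = 0..2,
#'   cols c = 0..2).
#' @export
duo_cell_probs <- function(q, r1 = 1, s1 = 1, j = 1, model = "diff") {
  if (q <= 0 || q >= 1) stop("q must lie strictly inside (0,1)")
  if (min(r1, s1, j) <= 0) stop("risk parameters must be positive")
  hwe_m <- c((1 - q)^2, 2 * q * (1 - q), q^2)      # m = 0,1,2
  # transmitted-from-mother probability: P(tm = 1 | m) = m/2
  p_tm <- .M_GRID / 2
  # P(c | m): child = tm + tf, tf ~ Bernoulli(q)
  p_c_m <- matrix(0, 3, 3)
  for (m in 0:2) {
    ptm <- m / 2
    p_c_m[m + 1, 1] <- (1 - ptm) * (1 - q)
    p_c_m[m + 1, 2] <- (1 - ptm) * q + ptm * (1 - q)
    p_c_m[m + 1, 3] <- ptm * q
  }
  mu <- hwe_m * p_c_m
  rho <- .rho_grid(r1, s1, j, model)
  case <- mu * rho
  list(case = case / sum(case), control = mu)
}

#' Observed duo genotype counts
#'
#' @param gm_m,gm_c maternal and child matrices.
#' @param duos a [duo_set()].
#' @param marker marker ID.
#' @return list of class `duo_counts` with 3 x 3 integer matrices `case`
#'   and `control` (rows m, cols c); Mendelian-inconsistent and
#'   incomplete pairs are dropped.
#' @export
duo_counts <- function(gm_m, gm_c, duos, marker) {
  m <- unclass(gm_m)[match(duos$mother_id, rownames(gm_m)), marker]
  c <- unclass(gm_c)[match(duos$child_id, rownames(gm_c)), marker]
  ok <- !is.na(m) & !is.na(c) & !((m == 0 & c == 2) | (m == 2 & c == 0))
  tab <- function(sel) {
    t <- table(factor(m[sel], levels = 0:2), factor(c[sel], levels = 0:2))
    matrix(as.integer(t), 3, 3)
  }
  structure(list(case = tab(ok & duos$status == "case"),
                 control = tab(ok & duos$status == "control")),
            class = "duo_counts")
}

# moment estimate of q from control duos (population approximation);
# falls back to all duos when there are no controls
.q_moment <- function(counts) {
  use <- if (sum(counts$control) > 0) counts$control else
    counts$case + counts$control
  tot <- sum(use * (.M_GRID + .C_GRID)) / (4 * sum(use))
  min(max(tot, 1e-4), 1 - 1e-4)
}

.mmlm_loglik <- function(q, r1, s1, j, model, counts) {
  pr <- duo_cell_probs(q, r1, s1, j, model)
  lp_case <- suppressWarnings(log(pr$case))
  lp_ctrl <- suppressWarnings(log(pr$control))
  lp_case[counts$case == 0] <- 0
  lp_ctrl[counts$control == 0] <- 0
  sum(counts$case * lp_case) + sum(counts$control * lp_ctrl)
}

#' Fit the multinomial duo risk model by maximum likelihood
#'
#' Maximizes the multinomial log-likelihood of the case and control duo
#' count tables over the requested free parameters; fixed risk
#' parameters are pinned at 1 and a fixed `q` at its moment estimate
#' from the control duos.  Optimization is on the log (risk) / logit
#' (frequency) scale with bounds `|ln theta| <= ln 50`, using L-BFGS-B
#' from three starts (free risk parameters scaled by 0.5, 1 and 2).
#'
#' @param counts a [duo_counts()] list (`case`, `control` 3 x 3).
#' @param model transgenerational model; `"maternal"` fits main effects
#'   only (no `j`).
#' @param free character subset of `c("q", "r1", "s1", "j")`.
#' @param loglik_tol convergence tolerance on the log-likelihood.
#' @return list of class `mmlm_fit`: `params` (q, r1, s1, j), `loglik`,
#'   `converged`, `free`, `model`.
#' @export
fit_mmlm <- function(counts, model = "diff",
                     free = c("q", "r1", "s1", "j"),
                     loglik_tol = 1e-8) {
  model <- match.arg(model, .MMLM_MODELS)
  allp <- c("q", "r1", "s1", "j")
  free <- intersect(allp, free)
  if (model == "maternal" && "j" %in% free)
    stop("the maternal main-effect model has no interaction parameter")
  if (sum(counts$case) + sum(counts$control) < 1)
    stop("empty count tables")
  q0 <- .q_moment(counts)
  base <- c(q = q0, r1 = 1, s1 = 1, j = 1)

  lb <- log(1 / 50); ub <- log(50)
  to_par <- function(theta) {           # named full param vector
    p <- base
    for (nm in free) {
      p[nm] <- if (nm == "q") stats::plogis(theta[[nm]]) else
        exp(theta[[nm]])
    }
    p
  }
  nll <- function(th) {
    names(th) <- free
    p <- to_par(th)
    -.mmlm_loglik(p[["q"]], p[["r1"]], p[["s1"]], p[["j"]], model, counts)
  }
  risk_free <- setdiff(free, "q")
  starts <- lapply(c(0.5, 1, 2), function(s) {
    th <- numeric(length(free)); names(th) <- free
    if ("q" %in% free) th["q"] <- stats::qlogis(q0)
    th[risk_free] <- log(s)
    th
  })
  lower <- ifelse(free == "q", stats::qlogis(1e-4), lb)
  upper <- ifelse(free == "q", stats::qlogis(1 - 1e-4), ub)

  best <- NULL
  conv <- FALSE
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = loglik_tol /
                                    .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 0) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) {
    return(structure(list(params = base, loglik = -nll(starts[[2]]),
                          converged = FALSE, free = free, model = model),
                     class = "mmlm_fit"))
  }
  th <- best$par; names(th) <- free
  structure(list(params = to_par(th), loglik = -best$value,
                 converged = conv, free = free, model = model),
            class = "mmlm_fit")
}

#' @export
print.mmlm_fit <- function(x, ...) {
  cat("mmlm_fit (", x$model, "): logLik =", format(x$loglik), "\n")
  print(round(x$params, 4))
  if (!x$converged) cat("  [not converged]\n")
  invisible(x)
}

#' Likelihood-ratio test between nested duo risk models
#'
#' Fits the full and null parameter sets (the null must be the full set
#' minus exactly one parameter) and compares twice the log-likelihood
#' difference to chi-square with 1 df.  The standard applications are
#' the maternal-effect test (full `{q, r1, s1}` vs null `{q, r1}`) and
#' the transgenerational test (full `{q, r1, s1, j}` vs null
#' `{q, r1, s1}`).
#'
#' @param counts a [duo_counts()] list.
#' @param model transgenerational model label.
#' @param full_free,null_free free-parameter sets for the two fits.
#' @return list of class `lrt_result`: `loglik_full`, `loglik_null`,
#'   `lrt_stat`, `df`, `p_value`, `fit_full`, `fit_null`.
#' @export
mmlm_lrt <- function(counts, model = "diff",
                     full_free = c("q", "r1", "s1", "j"),
                     null_free = c("q", "r1", "s1")) {
  extra <- setdiff(full_free, null_free)
  if (length(extra) != 1 || length(setdiff(null_free, full_free)))
    stop("null_free must be full_free minus exactly one parameter")
  f1 <- fit_mmlm(counts, model, full_free)
  f0 <- fit_mmlm(counts, model, null_free)
  stat <- max(2 * (f1$loglik - f0$loglik), 0)
  structure(list(loglik_full = f1$loglik, loglik_null = f0$loglik,
                 lrt_stat = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 fit_full = f1, fit_null = f0),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*dlogLik = %.4f (df = 1), P = %.4g\n",
              x$lrt_stat, x$p_value))
  invisible(x)
}
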