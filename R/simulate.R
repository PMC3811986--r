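# Synthetic duo / trio genotype generator.
#
# Genotypes are biallelic, unlinked, drawn under HWE and random mating.
# Population structure follows the Balding-Nichols model: each stratum's
# allele frequency is Beta(q(1-F)/F, (1-q)(1-F)/F) around the ancestral
# frequency q with divergence F (Fst).  Disease risk acts through the
# same multiplicative mother/child/interaction model the MMLM fits
# (baseline alpha, child r1, maternal s1, interaction j on one causal
# marker); all other markers are pure noise.  Case and control duos are
# drawn from the exact conditional genotype distributions implied by the
# risk model, so the generated data follow the target distribution
# without a rare-disease approximation.

#' Simulation configuration
#'
#' Defaults mirror the discovery study conditions: 366 case and 369
#' control mother-child pairs, a small baseline risk (0.01) so controls
#' approximate the population, and marker frequencies uniform on
#' (0.05, 0.5).
#'
#' @param n_case_duos,n_control_duos duo counts by status.
#' @param n_trios affected-child trio count (trio generator).
#' @param n_markers marker count.
#' @param seed RNG seed (recorded in the truth record).
#' @param maf_range range of ancestral a1 frequencies for noise markers.
#' @param strata list with `weights` (summing to 1) and either `fst`
#'   (per-stratum Balding-Nichols divergence, scalar or per-stratum) or
#'   explicit `freqs` (strata x markers matrix).
#' @param risk list: `model` (`"null"`, `"proband"`, `"maternal"`,
#'   `"offhet"`, `"mathet"`, `"diff"`), `alpha` baseline risk, `r1`,
#'   `s1`, `j` multiplicative effects, `maf` causal-marker a1 frequency.
#' @param causal index of the causal marker (0 = none; ignored when
#'   `risk$model == "null"`).
#' @param status_stratum_bias per-stratum multiplier on the baseline
#'   risk (confounds status with stratum when unequal).
#' @param missing_rate per-call missing probability.
#' @param paternal_s1 paternal per-copy risk (trio generator only;
#'   default 1 = maternal effects are maternal-specific).
#' @param dataset dataset label for generated trios.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_case_duos = 366, n_control_duos = 369,
                       n_trios = 500, n_markers = 1000, seed = 1,
                       maf_range = c(0.05, 0.5),
                       strata = list(weights = 1, fst = 0),
                       risk = list(model = "null", alpha = 0.01,
                                   r1 = 1, s1 = 1, j = 1, maf = 0.3),
                       causal = 0,
                       status_stratum_bias = NULL,
                       missing_rate = 0, paternal_s1 = 1,
                       dataset = "sim") {
  risk <- utils::modifyList(
    list(model = "null", alpha = 0.01, r1 = 1, s1 = 1, j = 1, maf = 0.3),
    risk)
  w <- strata$weights
  if (abs(sum(w) - 1) > 1e-8) stop("stratum weights must sum to 1")
  if (risk$maf <= 0 || risk$maf >= 1) stop("causal maf must be in (0,1)")
  if (risk$model != "null" && causal == 0) causal <- 1
  bias <- status_stratum_bias
  if (is.null(bias)) bias <- rep(1, length(w))
  if (length(bias) != length(w))
    stop("status_stratum_bias must match the stratum count")
  structure(list(n_case_duos = n_case_duos,
                 n_control_duos = n_control_duos, n_trios = n_trios,
                 n_markers = n_markers, seed = seed,
                 maf_range = maf_range, strata = strata, risk = risk,
                 causal = causal, status_stratum_bias = bias,
                 missing_rate = missing_rate, paternal_s1 = paternal_s1,
                 dataset = dataset),
            class = "sim_config")
}

# strata x markers allele-frequency matrix
.stratum_freqs <- function(cfg, q0) {
  S <- length(cfg$strata$weights)
  if (!is.null(cfg$strata$freqs)) {
    fr <- cfg$strata$freqs
    if (!all(dim(fr) == c(S, cfg$n_markers)))
      stop("explicit stratum freqs must be strata x markers")
    return(fr)
  }
  fst <- rep_len(cfg$strata$fst, S)
  out <- matrix(rep(q0, each = S), S, cfg$n_markers)
  for (s in seq_len(S)) {
    if (fst[s] > 0) {
      f <- fst[s]
      out[s, ] <- stats::rbeta(cfg$n_markers, q0 * (1 - f) / f,
                               (1 - q0) * (1 - f) / f)
    }
  }
  pmin(pmax(out, 1e-3), 1 - 1e-3)
}

# child dosages from maternal dosages and paternal transmission freq
.transmit <- function(m, q) {
  tm <- stats::rbinom(length(m), 1, m / 2)
  tf <- stats::rbinom(length(m), 1, q)
  as.integer(tm + tf)
}

.risk_grid <- function(risk) {
  r1 <- risk$r1; s1 <- risk$s1; j <- risk$j
  if (risk$model %in% c("null", "proband")) {
    # proband planted effect: child main effect only
    r1 <- if (risk$model == "proband") risk$r1 else 1
    return(r1^.C_GRID)
  }
  if (risk$model == "maternal") return(r1^.C_GRID * s1^.M_GRID)
  .rho_grid(r1, s1, j, risk$model)
}

.inject_missing <- function(x, rate) {
  if (rate <= 0) return(x)
  x[stats::runif(length(x)) < rate] <- NA_integer_
  x
}

.sim_map <- function(n_markers) {
  data.frame(id = sprintf("snp%05d", seq_len(n_markers)),
             chrom = as.character(1 + (seq_len(n_markers) - 1) %% 22),
             pos = 10000L * seq_len(n_markers), a1 = "A", a2 = "B",
             stringsAsFactors = FALSE)
}

#' Simulate a case-control duo dataset
#'
#' Draws mother-child pairs stratum by stratum under HWE and Mendelian
#' transmission, plants the configured risk model on the causal marker,
#' and fills the remaining markers with effect-free genotypes at the
#' stratum frequencies.  Case and control genotype cells at the causal
#' marker are drawn from the exact conditional distributions
#' `mu * pi / sum` and `mu * (1 - pi) / sum` with
#' `pi = min(1, alpha * bias_k * rho)`.  Fully reproducible from the
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `gm_m`, `gm_c` ([geno_matrix()] mothers/children),
#'   `duos` (a [duo_set()] with the true stratum), and `truth`
#'   (seed, config, causal marker, per-duo stratum).
#' @export
sim_duos <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  M <- cfg$n_markers
  S <- length(cfg$strata$weights)
  w <- cfg$strata$weights
  q0 <- stats::runif(M, cfg$maf_range[1], cfg$maf_range[2])
  if (cfg$causal > 0) q0[cfg$causal] <- cfg$risk$maf
  qs <- .stratum_freqs(cfg, q0)

  rho <- .risk_grid(cfg$risk)
  alpha <- cfg$risk$alpha
  bias <- cfg$status_stratum_bias
  # joint (stratum, mother-cell, child-cell) sampling frame at the
  # causal marker; with no causal marker only the stratum is sampled
  frame <- do.call(rbind, lapply(seq_len(S), function(s) {
    qc <- if (cfg$causal > 0) qs[s, cfg$causal] else cfg$risk$maf
    mu <- duo_cell_probs(qc)$control
    pi <- pmin(1, alpha * bias[s] * rho)
    dim(pi) <- dim(rho)               # pmin drops the matrix shape
    cells <- which(mu > 0, arr.ind = TRUE)
    data.frame(stratum = s, m = cells[, 1] - 1L, c = cells[, 2] - 1L,
               p_case = w[s] * mu[cells] * pi[cells],
               p_ctrl = w[s] * mu[cells] * (1 - pi[cells]))
  }))
  if (sum(frame$p_case) <= 0)
    stop("case quota unattainable: alpha * rho is zero everywhere")
  if (sum(frame$p_ctrl) <= 0)
    stop("control quota unattainable: alpha * rho is one everywhere")

  n_case <- cfg$n_case_duos; n_ctrl <- cfg$n_control_duos
  i_case <- sample.int(nrow(frame), n_case, replace = TRUE,
                       prob = frame$p_case)
  i_ctrl <- sample.int(nrow(frame), n_ctrl, replace = TRUE,
                       prob = frame$p_ctrl)
  idx <- c(i_case, i_ctrl)
  status <- rep(c("case", "control"), c(n_case, n_ctrl))
  strat <- frame$stratum[idx]
  n <- n_case + n_ctrl

  # noise markers: mother ~ Binom(2, q), child by transmission
  Qd <- qs[strat, , drop = FALSE]                  # duo x marker freqs
  Gm <- matrix(stats::rbinom(n * M, 2, Qd), n, M)
  Tm <- matrix(stats::rbinom(n * M, 1, Gm / 2), n, M)
  Tf <- matrix(stats::rbinom(n * M, 1, Qd), n, M)
  Gc <- Tm + Tf
  if (cfg$causal > 0) {
    Gm[, cfg$causal] <- frame$m[idx]
    Gc[, cfg$causal] <- frame$c[idx]
  }
  storage.mode(Gm) <- "integer"; storage.mode(Gc) <- "integer"
  Gm <- .inject_missing(Gm, cfg$missing_rate)
  Gc <- .inject_missing(Gc, cfg$missing_rate)

  mids <- sprintf("M%05d", seq_len(n))
  cids <- sprintf("C%05d", seq_len(n))
  rownames(Gm) <- mids; rownames(Gc) <- cids
  map <- .sim_map(M)
  ph <- ifelse(status == "case", 2L, 1L)
  fam_m <- data.frame(fid = sprintf("FAM%05d", seq_len(n)), iid = mids,
                      pat = "0", mat = "0", sex = 2L, pheno = ph)
  fam_c <- data.frame(fid = sprintf("FAM%05d", seq_len(n)), iid = cids,
                      pat = "0", mat = mids, sex = 0L, pheno = ph)
  duos <- duo_set(mids, cids, status, stratum = strat)
  list(gm_m = geno_matrix(Gm, map, fam_m),
       gm_c = geno_matrix(Gc, map, fam_c),
       duos = duos,
       truth = list(seed = cfg$seed, config = cfg, causal = cfg$causal,
                    base_freq = q0, stratum = strat))
}

#' Simulate affected-offspring trios
#'
#' Father, mother and affected child per family; ascertainment is on an
#' affected child under the configured risk model (paternal effects are
#' absent unless `paternal_s1 != 1`, so maternal effects are
#' maternal-specific by default).  The causal-marker (father, mother,
#' child) genotype triple is drawn from the exact affected-conditional
#' distribution; noise markers are effect-free.
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (fathers + mothers + children, fam table with
#'   pedigree links), `trios` (a [trio_set()]) and `truth`.
#' @export
sim_trios <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  M <- cfg$n_markers
  S <- length(cfg$strata$weights)
  w <- cfg$strata$weights
  q0 <- stats::runif(M, cfg$maf_range[1], cfg$maf_range[2])
  if (cfg$causal > 0) q0[cfg$causal] <- cfg$risk$maf
  qs <- .stratum_freqs(cfg, q0)

  rho <- .risk_grid(cfg$risk)
  alpha <- cfg$risk$alpha
  # affected-conditional joint over (stratum, f, m, c)
  frame <- do.call(rbind, lapply(seq_len(S), function(s) {
    qc <- if (cfg$causal > 0) qs[s, cfg$causal] else cfg$risk$maf
    hwe <- c((1 - qc)^2, 2 * qc * (1 - qc), qc^2)
    rows <- expand.grid(f = 0:2, m = 0:2, c = 0:2)
    ptrans <- function(par, t) ifelse(t == 1, par / 2, 1 - par / 2)
    # child = tm + tf; P(c | m, f) by enumeration of transmissions
    pc <- mapply(function(f, m, c) {
      p <- 0
      for (tm in 0:1) {
        tf <- c - tm
        if (tf %in% 0:1)
          p <- p + ptrans(m, tm) * ptrans(f, tf)
      }
      p
    }, rows$f, rows$m, rows$c)
    rr <- rho[cbind(rows$m + 1, rows$c + 1)] *
      cfg$paternal_s1^rows$f
    paff <- pmin(1, alpha * cfg$status_stratum_bias[s] * rr)
    data.frame(stratum = s, rows,
               p = w[s] * hwe[rows$f + 1] * hwe[rows$m + 1] * pc * paff)
  }))
  if (sum(frame$p) <= 0) stop("affected-trio quota unattainable")

  n <- cfg$n_trios
  idx <- sample.int(nrow(frame), n, replace = TRUE, prob = frame$p)
  strat <- frame$stratum[idx]

  Qd <- qs[strat, , drop = FALSE]
  Gf <- matrix(stats::rbinom(n * M, 2, Qd), n, M)
  Gm <- matrix(stats::rbinom(n * M, 2, Qd), n, M)
  Tm <- matrix(stats::rbinom(n * M, 1, Gm / 2), n, M)
  Tf <- matrix(stats::rbinom(n * M, 1, Gf / 2), n, M)
  Gc <- Tm + Tf
  if (cfg$causal > 0) {
    Gf[, cfg$causal] <- frame$f[idx]
    Gm[, cfg$causal] <- frame$m[idx]
    Gc[, cfg$causal] <- frame$c[idx]
  }
  storage.mode(Gf) <- "integer"
  storage.mode(Gm) <- "integer"
  storage.mode(Gc) <- "integer"
  Gf <- .inject_missing(Gf, cfg$missing_rate)
  Gm <- .inject_missing(Gm, cfg$missing_rate)
  Gc <- .inject_missing(Gc, cfg$missing_rate)

  fids <- sprintf("F%05d", seq_len(n))
  mids <- sprintf("M%05d", seq_len(n))
  cids <- sprintf("C%05d", seq_len(n))
  G <- rbind(Gf, Gm, Gc)
  rownames(G) <- c(fids, mids, cids)
  famid <- sprintf("FAM%05d", seq_len(n))
  fam <- data.frame(
    fid = rep(famid, 3), iid = c(fids, mids, cids),
    pat = c(rep("0", 2 * n), fids), mat = c(rep("0", 2 * n), mids),
    sex = c(rep(1L, n), rep(2L, n), rep(0L, n)),
    pheno = c(rep(1L, 2 * n), rep(2L, n)))
  trios <- trio_set(fids, mids, cids, affected = TRUE,
                    dataset = cfg$dataset)
  list(gm = geno_matrix(G, .sim_map(M), fam), trios = trios,
       truth = list(seed = cfg$seed, config = cfg, causal = cfg$causal,
                    base_freq = q0, stratum = strat))
}

#' Simulate an effect-free genotype panel
#'
#' Independent markers with ancestral frequencies uniform on
#' `maf_range`, optional Balding-Nichols stratum divergence, and no
#' phenotype effects anywhere; intended for inflation and type-I-error
#' studies.
#'
#' @param n_samples,n_markers panel dimensions (`n_markers >= 100`).
#' @param strata as in [sim_config()].
#' @param seed RNG seed.
#' @param maf_range ancestral frequency range.
#' @return list with `gm`, per-sample `stratum`, and the frequency
#'   matrix `freqs`.
#' @export
sim_null_genome <- function(n_samples, n_markers,
                            strata = list(weights = 1, fst = 0),
                            seed = 1, maf_range = c(0.05, 0.5)) {
  if (n_markers < 100) stop("n_markers must be >= 100")
  cfg <- sim_config(n_markers = n_markers, seed = seed,
                    maf_range = maf_range, strata = strata)
  set.seed(seed)
  q0 <- stats::runif(n_markers, maf_range[1], maf_range[2])
  qs <- .stratum_freqs(cfg, q0)
  strat <- sample.int(length(strata$weights), n_samples, replace = TRUE,
                      prob = strata$weights)
  Q <- qs[strat, , drop = FALSE]
  G <- matrix(stats::rbinom(n_samples * n_markers, 2, Q),
              n_samples, n_markers)
  storage.mode(G) <- "integer"
  rownames(G) <- sprintf("S%05d", seq_len(n_samples))
  list(gm = geno_matrix(G, .sim_map(n_markers)), stratum = strat,
       freqs = qs)
}

#' Write a simulated duo dataset to disk
#'
#' Emits PED/MAP files for mothers and children, the pair file, the
#' allele-reference file, and a JSON truth record.
#'
#' @param sim output of [sim_duos()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_duo_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mother_ped = file.path(dir, "mothers.ped"),
             mother_map = file.path(dir, "mothers.map"),
             child_ped = file.path(dir, "children.ped"),
             child_map = file.path(dir, "children.map"),
             pairs = file.path(dir, "pairs.txt"),
             alleles = file.path(dir, "alleles.txt"),
             truth = file.path(dir, "truth.json"))
  write_ped_map(sim$gm_m, paths["mother_ped"], paths["mother_map"])
  write_ped_map(sim$gm_c, paths["child_ped"], paths["child_map"])
  utils::write.table(
    data.frame(sim$duos$mother_id, sim$duos$child_id,
               as.character(sim$duos$status)),
    paths["pairs"], quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  write_allele_ref(sim$gm_m, paths["alleles"])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
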