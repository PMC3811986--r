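# End-to-end discovery and replication orchestration.

#' Pipeline configuration
#'
#' @param qc a [qc_thresholds()] list.
#' @param k_max largest stratum count tried by [select_k()].
#' @param sig_suggestive,sig_top,sig_genomewide reporting tiers
#'   (defaults 1e-4, 1e-5, 5e-8).
#' @param classifier_mode `"literal"` or `"conditioned"` (see
#'   [classify_pair()]).
#' @param replication_alpha nominal replication level.
#' @param lrt_threshold discovery P below which a marker gets MMLM
#'   likelihood-ratio follow-up (defaults to the suggestive tier).
#' @param seed seed recorded in output headers.
#' @param thin marker thinning for the lambda-vs-K scans.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(), k_max = 3,
                            sig_suggestive = 1e-4, sig_top = 1e-5,
                            sig_genomewide = 5e-8,
                            classifier_mode = "literal",
                            replication_alpha = 0.05,
                            lrt_threshold = sig_suggestive,
                            seed = 1, thin = 1) {
  structure(list(qc = qc, k_max = k_max,
                 sig_suggestive = sig_suggestive, sig_top = sig_top,
                 sig_genomewide = sig_genomewide,
                 classifier_mode = classifier_mode,
                 replication_alpha = replication_alpha,
                 lrt_threshold = lrt_threshold, seed = seed,
                 thin = thin),
            class = "pipeline_config")
}

# tiny rolling hash so reports can carry a config fingerprint without
# external dependencies (31-bit to stay exact in double arithmetic)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.report_header <- function(config) {
  c(sprintf("# duogwas discovery report"),
    sprintf("# config_hash=%s seed=%d", .config_hash(config),
            config$seed))
}

#' Run the discovery pipeline
#'
#' Stages, in order: quality control ([apply_qc()]); stratum-count
#' selection ([select_k()]); the five genome-wide CMH scans
#' ([scan_assoc()]), sharing the single QC output and cluster solution;
#' MMLM likelihood-ratio follow-up ([mmlm_lrt()]) of every marker-model
#' result below the suggestive tier (maternal model: drop the maternal
#' effect; interaction models: drop the interaction); and a combined
#' report (CMH P, CMH OR, LRT P).
#'
#' @param gm_m,gm_c maternal and child [geno_matrix()] objects.
#' @param duos a [duo_set()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes
#'   `results.tsv`, `report.tsv`, `lambda.tsv` and per-model
#'   `qq_<model>.tsv` files, each headed by the config hash and seed.
#' @return list of class `discovery_result`: `qc`, `clusters`, `scans`
#'   (all five scans row-bound), `report` (suggestive-tier rows with
#'   LRT columns), `lambda_table`, `config`.
#' @export
run_discovery <- function(gm_m, gm_c, duos, config = pipeline_config(),
                          out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("discovery stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  qc <- stage("qc", apply_qc(gm_m, gm_c, duos, config$qc))
  clusters <- stage("select_k",
                    select_k(qc$gm_m, qc$gm_c, qc$duos,
                             k_max = config$k_max, thin = config$thin))
  scans <- stage("scan", do.call(rbind, lapply(.SCAN_MODELS, function(mod)
    scan_assoc(qc$gm_m, qc$gm_c, qc$duos, mod, strata = clusters,
               mode = config$classifier_mode))))

  top <- scans[!is.na(scans$p) & scans$p < config$lrt_threshold &
                 scans$model != "proband", , drop = FALSE]
  lrt_rows <- stage("lrt", {
    if (nrow(top) == 0) {
      data.frame(marker = character(), model = character(),
                 loglik_full = numeric(), loglik_null = numeric(),
                 lrt_stat = numeric(), lrt_p = numeric())
    } else {
      do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
        mod <- top$model[i]
        cnt <- duo_counts(qc$gm_m, qc$gm_c, qc$duos, top$marker[i])
        lr <- if (mod == "maternal")
          mmlm_lrt(cnt, "maternal", full_free = c("q", "r1", "s1"),
                   null_free = c("q", "r1"))
        else
          mmlm_lrt(cnt, mod, full_free = c("q", "r1", "s1", "j"),
                   null_free = c("q", "r1", "s1"))
        data.frame(marker = top$marker[i], model = mod,
                   loglik_full = lr$loglik_full,
                   loglik_null = lr$loglik_null,
                   lrt_stat = lr$lrt_stat, lrt_p = lr$p_value)
      }))
    }
  })
  report <- merge(top, lrt_rows, by = c("marker", "model"),
                  all.x = TRUE, sort = FALSE)
  report <- report[order(report$model, report$p), , drop = FALSE]
  # proband-model suggestive hits are reported without LRT (not
  # applicable: nothing to remove below the child main effect)
  top_pro <- scans[!is.na(scans$p) & scans$p < config$lrt_threshold &
                     scans$model == "proband", , drop = FALSE]
  if (nrow(top_pro)) {
    top_pro[, c("loglik_full", "loglik_null", "lrt_stat", "lrt_p")] <-
      NA_real_
    report <- rbind(report, top_pro[, names(report)])
  }
  rownames(report) <- NULL

  out <- structure(list(qc = qc, clusters = clusters, scans = scans,
                        report = report,
                        lambda_table = clusters$lambda_table,
                        config = config),
                   class = "discovery_result")
  if (!is.null(out_dir)) .write_discovery(out, out_dir)
  out
}

.write_discovery <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- .report_header(res$config)
  write_results(res$scans, file.path(out_dir, "results.tsv"),
                header_lines = hdr)
  write_tsv_hdr <- function(d, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(d, digits = 8, trim = TRUE), con,
                       quote = FALSE, sep = "\t", row.names = FALSE)
  }
  write_tsv_hdr(res$report, file.path(out_dir, "report.tsv"))
  write_tsv_hdr(res$lambda_table, file.path(out_dir, "lambda.tsv"))
  for (mod in unique(res$scans$model)) {
    qd <- qq_data(res$scans$p[res$scans$model == mod])
    write_tsv_hdr(qd, file.path(out_dir, paste0("qq_", mod, ".tsv")))
  }
  invisible(out_dir)
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("discovery_result: K =", x$clusters$K, ",",
      nrow(x$scans) / length(.SCAN_MODELS), "markers x 5 models;",
      nrow(x$report), "suggestive rows\n")
  invisible(x)
}

# discovery model -> trio replication test
.REP_TEST_FOR <- c(proband = "tdt", maternal = "parent_freq",
                   offhet = "offhet_rep", mathet = "mathet_rep",
                   diff = "diff_rep")

.run_trio_test <- function(test, gm, trios, marker) {
  switch(test,
         tdt = tdt(gm, trios, marker),
         parent_freq = parent_freq_test(gm, trios, marker),
         trio_te_test(test, gm, trios, marker))
}

.rep_table_of <- function(r, test) {
  if (test == "tdt") r$table else r$table
}

#' Run the family-based replication pipeline
#'
#' For every discovery marker-model carried into replication, runs the
#' matching trio test in each dataset, pools the per-dataset log odds
#' ratios with DerSimonian-Laird random-effects meta-analysis — or,
#' when any dataset has a zero cell, sums the per-dataset tables and
#' reports the merged chi-square — then applies the Bonferroni gate
#' against the number of results taken into replication.  Markers
#' absent from a dataset's panel are excluded from that dataset (and
#' reported untested if absent everywhere).
#'
#' @param discovery a `discovery_result` (or a data.frame with columns
#'   `marker`, `model`, `p`, `or_mh`).
#' @param trio_datasets named list of datasets, each a list with
#'   elements `gm` (a [geno_matrix()]) and `trios` (a [trio_set()]).
#' @param config a [pipeline_config()].
#' @return data.frame of class `replication_result`: per marker-model
#'   the replication test, per-dataset count `k`, pooled `log_or`,
#'   `p_value`, `method` (`meta`, `merged` or `untested`) and the gate
#'   columns from [bonferroni_gate()].
#' @export
run_replication <- function(discovery, trio_datasets,
                            config = pipeline_config()) {
  rep_in <- if (inherits(discovery, "discovery_result"))
    discovery$report else discovery
  if (nrow(rep_in) == 0) stop("no discovery results to replicate")
  n_tests <- nrow(rep_in)

  rows <- lapply(seq_len(nrow(rep_in)), function(i) {
    marker <- rep_in$marker[i]
    model <- as.character(rep_in$model[i])
    test <- .REP_TEST_FOR[[model]]
    per <- list(); tables <- list()
    for (ds in names(trio_datasets)) {
      dat <- trio_datasets[[ds]]
      if (!marker %in% marker_map(dat$gm)$id) next   # absent -> skip ds
      r <- .run_trio_test(test, dat$gm, dat$trios, marker)
      per[[ds]] <- r
      tables[[ds]] <- r$table
    }
    base <- data.frame(marker = marker, model = model, test = test,
                       discovery_p = rep_in$p[i],
                       discovery_log_or = log(rep_in$or_mh[i]))
    if (length(per) == 0)
      return(cbind(base, data.frame(k = 0L, log_or = NA_real_,
                                    se = NA_real_, p_value = NA_real_,
                                    method = "untested")))
    zero_cell <- vapply(per, function(r)
      is.na(r$odds_ratio) || is.na(r$se_log_or) ||
        (!is.null(r$table) && any(unlist(r$table) == 0)),
      logical(1))
    if (any(zero_cell) || length(per) == 1) {
      mg <- merged_test(tables, test = test, marker = marker)
      lo <- if (is.na(mg$odds_ratio)) NA_real_ else log(mg$odds_ratio)
      cbind(base, data.frame(k = length(per), log_or = lo,
                             se = mg$se_log_or, p_value = mg$p_value,
                             method = "merged"))
    } else {
      mt <- dl_meta(vapply(per, function(r) log(r$odds_ratio),
                           numeric(1)),
                    vapply(per, function(r) r$se_log_or, numeric(1)))
      cbind(base, data.frame(k = mt$k, log_or = mt$pooled_log_or,
                             se = mt$se, p_value = mt$p_value,
                             method = "meta"))
    }
  })
  out <- do.call(rbind, rows)
  out <- bonferroni_gate(out, n_tests = n_tests,
                         alpha = config$replication_alpha)
  class(out) <- c("replication_result", "data.frame")
  out
}
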