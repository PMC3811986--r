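# Trio replication tests, meta-analysis, merged fallback, gate.

test_that("TDT counts transmissions from heterozygous parents", {
  # 15 trios: father het, mother homozygous a2; 10 children inherit a1
  f <- rep(1L, 15); m <- rep(0L, 15)
  c <- c(rep(1L, 10), rep(0L, 5))
  fx <- trio_fixture(f, m, c)
  r <- tdt(fx$gm, fx$trios, "m001")
  expect_equal(r$chi_square, 25 / 15, tolerance = 1e-12)
  expect_equal(r$odds_ratio, 2.0)
  expect_equal(unname(r$table), c(10, 5))
  # balanced transmissions
  fx2 <- trio_fixture(rep(1L, 10), rep(0L, 10), rep(c(0L, 1L), 5))
  expect_equal(tdt(fx2$gm, fx2$trios, "m001")$chi_square, 0)
  # both parents heterozygous, child het: one of each transmitted
  fx3 <- trio_fixture(1L, 1L, 1L)
  r3 <- tdt(fx3$gm, fx3$trios, "m001")
  expect_equal(unname(r3$table), c(1, 1))
  # no heterozygous parent -> untestable
  fx4 <- trio_fixture(0L, 0L, 0L)
  expect_true(is.na(tdt(fx4$gm, fx4$trios, "m001")$p_value))
})

test_that("mother-vs-father allele test matches hand computation", {
  fx <- trio_fixture(rep(0L, 5), rep(2L, 5), rep(1L, 5))
  r <- parent_freq_test(fx$gm, fx$trios, "m001")
  # mothers all a1/a1, fathers all a2/a2: [[10,0],[0,10]] -> chi2 = 20
  expect_equal(r$chi_square, 20)
  expect_equal(unname(r$table["mother", ]), c(10, 0))
  # identical parental frequencies -> 0
  fx2 <- trio_fixture(rep(1L, 8), rep(1L, 8), rep(1L, 8))
  r2 <- parent_freq_test(fx2$gm, fx2$trios, "m001")
  expect_equal(r2$chi_square, 0)
  expect_equal(r2$odds_ratio, 1)
})

test_that("trio interaction analogues equal the tally + Pearson oracle", {
  # hand example: mothers (6 yes, 4 no), fathers (2 yes, 8 no)
  pe <- duogwas:::.pearson_2x2(6, 4, 2, 8)
  expect_equal(pe$chisq, 10 / 3, tolerance = 1e-12)

  # diff analogue classification: child het, mother het (same), father
  # homozygous (opposite)
  tab <- trio_te_oracle("diff_rep", f = 0L, m = 1L, c = 1L)
  expect_equal(tab["mother", "yes"], 0)
  expect_equal(tab["father", "yes"], 1)

  set.seed(450)
  for (i in 1:25) {
    n <- 120
    m <- sample(0:2, n, replace = TRUE)
    f <- sample(0:2, n, replace = TRUE)
    tm <- rbinom(n, 1, m / 2); tf <- rbinom(n, 1, f / 2)
    c <- as.integer(tm + tf)
    fx <- trio_fixture(f, m, c)
    for (test in c("offhet_rep", "mathet_rep", "diff_rep")) {
      r <- trio_te_test(test, fx$gm, fx$trios, "m001")
      tab <- trio_te_oracle(test, f, m, c)
      expect_equal(unclass(r$table), unclass(tab), label = test)
      if (!is.na(r$chi_square))
        expect_equal(r$chi_square,
                     duogwas:::.pearson_2x2(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2])$chisq,
                     tolerance = 1e-10, label = test)
    }
  }
})

test_that("DerSimonian-Laird pooling matches closed forms and metafor", {
  m <- dl_meta(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(m$tau2, 0)
  expect_equal(m$pooled_log_or, 0.5)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-12)

  m0 <- dl_meta(c(0, 0, 0), c(0.1, 0.2, 0.3))
  expect_equal(m0$pooled_log_or, 0)
  expect_equal(m0$p_value, 1)

  lo <- c(0.8, -0.1, 0.35); se <- c(0.15, 0.2, 0.12)
  m3 <- dl_meta(lo, se)
  expect_gt(m3$tau2, 0)
  expect_gt(m3$pooled_log_or, min(lo))
  expect_lt(m3$pooled_log_or, max(lo))
  # tau2 = 0 reduces to inverse-variance fixed-effect pooling
  w <- 1 / se^2
  m_id <- dl_meta(rep(0.4, 3), se)
  expect_equal(m_id$pooled_log_or, sum(w * 0.4) / sum(w))
  expect_equal(m_id$se, 1 / sqrt(sum(w)))
  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = lo, sei = se, method = "DL")
  expect_equal(m3$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(m3$se, ref$se, tolerance = 1e-8)
  expect_equal(m3$tau2, ref$tau2, tolerance = 1e-8)
})

test_that("merged fallback sums tables and preserves the OR", {
  t1 <- matrix(c(6, 4, 2, 8), 2, byrow = TRUE)
  mg <- merged_test(list(t1, t1), test = "diff_rep")
  expect_equal(unclass(mg$table), unclass(2 * t1))
  expect_equal(mg$odds_ratio, 6)            # doubling preserves OR
  expect_equal(mg$chi_square,
               duogwas:::.pearson_2x2(12, 8, 4, 16)$chisq)
  expect_equal(mg$flag, "merged")
  # a zero-cell dataset becomes testable after merging
  tz <- matrix(c(0, 10, 5, 5), 2, byrow = TRUE)
  mg2 <- merged_test(list(tz, t1), test = "offhet_rep")
  expect_false(is.na(mg2$p_value))
  # TDT merged path
  mg3 <- merged_test(list(c(b = 10, c = 5), c(b = 0, c = 3)),
                     test = "tdt")
  expect_equal(mg3$chi_square, (10 - 8)^2 / 18)
})

test_that("the Bonferroni gate requires strength and direction", {
  res <- data.frame(p_value = c(0.001, 0.031, 0.0001),
                    log_or = c(0.4, 0.3, -0.5),
                    discovery_log_or = c(0.6, 0.5, 0.7))
  g <- bonferroni_gate(res, n_tests = 40)
  expect_equal(g$replicated, c(TRUE, FALSE, FALSE))
  expect_equal(g$nominal, c(TRUE, TRUE, FALSE))
  expect_false(g$same_direction[3])
})

test_that("maternal-specific signal favors the parent test over the TDT", {
  set.seed(451)
  reps <- 40
  hit_pf <- hit_tdt <- 0
  for (r in seq_len(reps)) {
    ts <- sim_trios(sim_config(n_trios = 400, n_markers = 100,
                               seed = 4600 + r,
                               risk = list(model = "maternal", s1 = 1.6,
                                           maf = 0.3), causal = 1))
    pf <- parent_freq_test(ts$gm, ts$trios, "snp00001")
    td <- tdt(ts$gm, ts$trios, "snp00001")
    if (!is.na(pf$p_value) && pf$p_value < 0.05) hit_pf <- hit_pf + 1
    if (!is.na(td$p_value) && td$p_value < 0.05) hit_tdt <- hit_tdt + 1
  }
  expect_gt(hit_pf, hit_tdt)
})
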