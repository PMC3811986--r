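# Multinomial duo risk model and likelihood-ratio tests.

sim_counts <- function(n_case, n_ctrl, q, r1 = 1, s1 = 1, j = 1,
                       model = "diff") {
  p <- duo_cell_probs(q, r1, s1, j, model)
  structure(list(case = matrix(rmultinom(1, n_case, p$case), 3, 3),
                 control = matrix(rmultinom(1, n_ctrl, p$control), 3, 3)),
            class = "duo_counts")
}

test_that("duo cell probabilities obey HWE, Mendel and normalization", {
  p <- duo_cell_probs(0.5)
  expect_equal(p$control[1, 1], 0.125)       # P(M=0) * P(C=0 | M=0)
  expect_equal(p$case, p$control)            # all effects 1
  set.seed(440)
  for (i in 1:2000) {
    q <- runif(1, 0.01, 0.99)
    pr <- duo_cell_probs(q, exp(runif(1, -1, 1)), exp(runif(1, -1, 1)),
                         exp(runif(1, -1, 1)),
                         sample(c("offhet", "mathet", "diff"), 1))
    expect_equal(sum(pr$case), 1, tolerance = 1e-12)
    expect_equal(sum(pr$control), 1, tolerance = 1e-12)
    expect_equal(pr$case[1, 3], 0)           # (m=0, c=2) impossible
    expect_equal(pr$case[3, 1], 0)
  }
  expect_error(duo_cell_probs(1.2), "q must")
})

test_that("the difference-model interaction multiplies mismatched cells", {
  q <- 0.3; r1 <- 1.4; s1 <- 1.2; j <- 1.7
  p0 <- duo_cell_probs(q, r1, s1, 1, "diff")
  p1 <- duo_cell_probs(q, r1, s1, j, "diff")
  # cell (m=2, c=1): homozygous mother, heterozygous child -> exposed;
  # relative risk alpha r1 s1^2 j vs null alpha r1 s1^2
  ratio <- (p1$case[3, 2] / p0$case[3, 2]) /
    (p1$case[3, 3] / p0$case[3, 3])          # (m=2,c=2) is unexposed
  expect_equal(ratio, j, tolerance = 1e-12)
  ind <- interaction_indicator("diff")
  expect_equal(ind[3, 2], 1)
  expect_equal(ind[3, 3], 0)
})

test_that("likelihoods are invariant to allele relabeling", {
  set.seed(441)
  for (i in 1:20) {
    q <- runif(1, 0.1, 0.9)
    r1 <- exp(runif(1, -0.5, 0.5)); s1 <- exp(runif(1, -0.5, 0.5))
    j <- exp(runif(1, -0.5, 0.5))
    p <- duo_cell_probs(q, r1, s1, j, "diff")
    # relabel: q -> 1-q, dosages d -> 2-d, risks -> inverse per copy
    p_rel <- duo_cell_probs(1 - q, 1 / r1, 1 / s1, j, "diff")
    flip <- function(x) x[3:1, 3:1]
    # case tables match after flipping both axes (diff indicator is
    # label-invariant; per-copy risks invert)
    expect_equal(flip(p_rel$control), p$control, tolerance = 1e-12)
    expect_equal(flip(p_rel$case), p$case, tolerance = 1e-12)
  }
})

test_that("maximum likelihood recovers generating parameters", {
  set.seed(442)
  cnt <- sim_counts(2500, 2500, q = 0.3)     # all effects 1
  f <- fit_mmlm(cnt, "diff", free = c("q", "r1", "s1", "j"))
  expect_true(f$converged)
  expect_true(all(f$params[c("r1", "s1", "j")] > 0.9 &
                    f$params[c("r1", "s1", "j")] < 1.1))
  expect_equal(unname(f$params["q"]), 0.3, tolerance = 0.03)
  # MLE dominance on the fitting sample
  ll_truth <- duogwas:::.mmlm_loglik(0.3, 1, 1, 1, "diff", cnt)
  expect_gte(f$loglik, ll_truth - 1e-6)

  # planted maternal effect s1 = 1.5 at n = 2000: median recovery
  s1_hat <- replicate(20, {
    cnt2 <- sim_counts(1000, 1000, q = 0.3, s1 = 1.5, model = "maternal")
    unname(fit_mmlm(cnt2, "maternal",
                    free = c("q", "r1", "s1"))$params["s1"])
  })
  expect_equal(median(s1_hat), 1.5, tolerance = 0.1)
})

test_that("LRT machinery: nesting, power, scaling", {
  expect_error(mmlm_lrt(sim_counts(100, 100, 0.3), "diff",
                        full_free = c("q", "r1"),
                        null_free = c("q", "s1")),
               "exactly one")
  set.seed(443)
  cnt <- sim_counts(1000, 1000, q = 0.3, j = 2, model = "diff")
  lr <- mmlm_lrt(cnt, "diff", c("q", "r1", "s1", "j"),
                 c("q", "r1", "s1"))
  expect_lt(lr$p_value, 0.05)
  expect_gte(lr$lrt_stat, 0)
  # doubling all counts doubles the raw statistic
  cnt2 <- cnt
  cnt2$case <- 2L * cnt$case; cnt2$control <- 2L * cnt$control
  lr2 <- mmlm_lrt(cnt2, "diff", c("q", "r1", "s1", "j"),
                  c("q", "r1", "s1"))
  expect_equal(lr2$lrt_stat, 2 * lr$lrt_stat, tolerance = 0.02)
})

test_that("null LRT P-values are roughly uniform", {
  set.seed(444)
  ps <- replicate(120, {
    cnt <- sim_counts(400, 400, q = runif(1, 0.2, 0.5))
    mmlm_lrt(cnt, "maternal", c("q", "r1", "s1"), c("q", "r1"))$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
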