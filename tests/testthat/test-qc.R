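# Call rates, Mendelian errors, HWE exact test, inbreeding, relatedness,
# and the assembled QC filter.

test_that("call rates use strict > for samples and >= for markers", {
  calls <- matrix(0L, 4, 100,
                  dimnames = list(sprintf("s%d", 1:4), NULL))
  calls[1, 1:3] <- NA          # sample 1 at exactly 0.97
  calls[2:4, 100] <- NA        # marker 100 missing in 3 of 4 samples
  gm <- gm_fixture(calls, ids = rownames(calls))
  cr <- call_rates(gm)
  expect_equal(cr$sample$call_rate[1], 0.97)
  expect_false(cr$sample$pass[1])           # 0.97 fails the strict rule
  expect_true(all(cr$sample$pass[2:4]))
  expect_equal(cr$marker$call_rate[1], 0.75)
  expect_false(cr$marker$pass[1])
  expect_equal(cr$marker$call_rate[100], 0.25)
  expect_false(cr$marker$pass[100])
  expect_true(all(cr$marker$pass[4:99]))
  # the marker rule is >=: a fully called marker sits at 1 and passes
  cr2 <- call_rates(gm, marker_thresh = 0.75)
  expect_true(cr2$marker$pass[1])           # exactly at threshold passes
  expect_false(cr2$marker$pass[100])
})

test_that("duo Mendelian errors are opposite homozygotes only", {
  m <- rbind(c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, NA))
  c <- rbind(c(2L, 0L, 2L, 2L), c(0L, 2L, 0L, 1L))
  gm_m <- gm_fixture(m, prefix = "m")
  gm_c <- gm_fixture(c, prefix = "c")
  duos <- duo_set(rownames(gm_m), rownames(gm_c), c("case", "control"))
  me <- duo_mendel_errors(gm_m, gm_c, duos)
  # marker 1: (0,2) and (2,0) -> 2 errors; marker 2: het mothers -> 0;
  # marker 3: (2,2) and (0,0) -> 0; marker 4: missing -> 0
  expect_equal(me$marker$errors, c(2, 0, 0, 0))
  expect_equal(me$duo$errors, c(1, 1))
})

test_that("Mendelian check never fires on error-free transmissions", {
  sim <- sim_duos(sim_config(n_case_duos = 50, n_control_duos = 50,
                             n_markers = 1000, seed = 77))
  me <- duo_mendel_errors(sim$gm_m, sim$gm_c, sim$duos)
  expect_equal(sum(me$marker$errors), 0)
})

test_that("HWE exact P matches enumeration oracle and known values", {
  expect_equal(hwe_exact_p(50, 0, 0), 1.0)
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3)
  set.seed(402)
  for (i in 1:200) {
    n <- sample(1:200, 1)
    ab <- sample(0:n, 1)
    aa <- sample(0:(n - ab), 1)
    bb <- n - ab - aa
    expect_equal(hwe_exact_p(aa, ab, bb), hwe_oracle(aa, ab, bb),
                 tolerance = 1e-10)
  }
})

test_that("HWE exact test is conservative under the null", {
  set.seed(403)
  n <- 200; reps <- 2000
  q <- runif(reps, 0.1, 0.5)
  g <- vapply(q, function(qq) {
    x <- rbinom(n, 2, qq)
    c(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(3))
  p <- hwe_exact_p(g[1, ], g[2, ], g[3, ])
  alpha <- 0.05
  expect_lte(mean(p < alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / reps))
})

test_that("inbreeding F hits its closed-form extremes and null mean", {
  gm_het <- gm_fixture(matrix(1L, 1, 10))
  expect_equal(inbreeding_f(gm_het, rep(0.5, 10))$f, -1)
  gm_hom <- gm_fixture(matrix(c(0L, 2L), 1, 10))
  expect_equal(inbreeding_f(gm_hom, rep(0.5, 10))$f, 1)
  set.seed(404)
  q <- runif(500, 0.2, 0.8)
  calls <- vapply(q, function(qq) rbinom(200, 2, qq), integer(200))
  gm <- gm_fixture(calls)
  f <- inbreeding_f(gm, q)$f
  expect_lt(abs(mean(f)), 0.01)
  expect_equal(sum(f < -0.15), sum(inbreeding_f(gm, q)$flag))
})

test_that("duo relatedness recovers parent-offspring sharing", {
  sim <- sim_duos(sim_config(n_case_duos = 30, n_control_duos = 30,
                             n_markers = 2000, seed = 78,
                             maf_range = c(0.2, 0.5)))
  q <- colMeans(rbind(unclass(sim$gm_m), unclass(sim$gm_c))) / 2
  rel <- duo_relatedness(sim$gm_m, sim$gm_c, sim$duos, q)
  expect_true(all(rel$ibs0_rate == 0))       # transmission forbids IBS0
  expect_true(all(abs(rel$pihat - 0.5) < 0.08))
  expect_false(any(rel$flag))
  # unrelated pairs at q = 0.5: expected IBS0 rate 2 q^2 (1-q)^2 = 0.125
  set.seed(405)
  ga <- gm_fixture(matrix(rbinom(10 * 4000, 2, 0.5), 10, 4000),
                   prefix = "a")
  gb <- gm_fixture(matrix(rbinom(10 * 4000, 2, 0.5), 10, 4000),
                   prefix = "b")
  duos <- duo_set(rownames(ga), rownames(gb), rep("control", 10))
  rel2 <- duo_relatedness(ga, gb, duos, rep(0.5, 4000))
  expect_equal(mean(rel2$ibs0_rate), 0.125, tolerance = 0.02)
  expect_true(all(rel2$flag))                # flagged as misidentified
  expect_true(all(rel2$pihat < 0.1))
})

test_that("apply_qc removes exactly the planted defects and is idempotent", {
  sim <- sim_duos(sim_config(n_case_duos = 60, n_control_duos = 60,
                             n_markers = 120, seed = 79))
  clean <- apply_qc(sim$gm_m, sim$gm_c, sim$duos)
  expect_equal(ncol(clean$gm_m), 120)
  expect_equal(nrow(clean$duos), 120)

  # plant 11 opposite-homozygote errors at marker 5 (and confirm the
  # boundary: 10 errors at marker 6 is retained)
  gm_m <- sim$gm_m; gm_c <- sim$gm_c
  gm_m[1:11, 5] <- 0L; gm_c[1:11, 5] <- 2L
  gm_m[1:10, 6] <- 0L; gm_c[1:10, 6] <- 2L
  qc <- apply_qc(gm_m, gm_c, sim$duos)
  removed <- setdiff(marker_map(sim$gm_m)$id, marker_map(qc$gm_m)$id)
  expect_equal(removed, "snp00005")
  ex <- qc$report$exclusions
  expect_equal(ex$reason[ex$id == "snp00005"], "mendel")

  # a marker failing call rate only in the child set leaves the
  # combined panel
  gm_c2 <- sim$gm_c; gm_c2[1:20, 7] <- NA
  qc2 <- apply_qc(sim$gm_m, gm_c2, sim$duos)
  expect_false("snp00007" %in% marker_map(qc2$gm_m)$id)

  # idempotence
  qc_again <- apply_qc(qc$gm_m, qc$gm_c, qc$duos)
  expect_identical(unclass(qc_again$gm_m)[, ], unclass(qc$gm_m)[, ])
  expect_identical(qc_again$duos$child_id, qc$duos$child_id)
})
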