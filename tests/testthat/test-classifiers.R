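# Mother-child classifiers and stratified count stacks.

test_that("classifier truth tables match the hand-enumerated oracle", {
  oracle <- classifier_oracle()
  for (model in c("offhet", "mathet", "diff")) {
    for (mode in c("literal", "conditioned")) {
      ref <- oracle[[paste(model, mode, sep = ".")]]
      got <- as.character(classify_pair(model, ref$m, ref$c, mode))
      expect_equal(got, as.character(ref$class),
                   label = paste(model, mode))
    }
  }
})

test_that("classes partition the input space and respect implications", {
  grid <- expand.grid(m = c(0, 1, 2, NA), c = c(0, 1, 2, NA))
  for (model in c("offhet", "mathet", "diff")) {
    for (mode in c("literal", "conditioned")) {
      cls <- classify_pair(model, grid$m, grid$c, mode)
      expect_false(anyNA(cls))               # exhaustive
      exp_i <- which(cls == "exposed")
      if (model == "offhet") expect_true(all(grid$c[exp_i] == 1))
      if (model == "mathet") expect_true(all(grid$m[exp_i] == 1))
    }
  }
  # diff is symmetric in (m, c)
  d1 <- classify_pair("diff", grid$m, grid$c)
  d2 <- classify_pair("diff", grid$c, grid$m)
  expect_identical(d1, d2)
  expect_error(classify_pair("diff", 3, 0), "dosage")
})

test_that("classification is invariant to allele relabeling", {
  grid <- expand.grid(m = c(0, 1, 2, NA), c = c(0, 1, 2, NA))
  for (model in c("offhet", "mathet", "diff")) {
    for (mode in c("literal", "conditioned")) {
      a <- classify_pair(model, grid$m, grid$c, mode)
      b <- classify_pair(model, 2 - grid$m, 2 - grid$c, mode)
      expect_identical(a, b, label = paste(model, mode))
    }
  }
})

test_that("binary stacks tally exposed/unexposed by status and stratum", {
  # 8 duos in one stratum: 2 case-exposed, 2 case-unexposed,
  # 2 control-exposed, 2 control-unexposed under the diff model
  m <- c(0, 1, 0, 1, 2, 1, 2, 1)
  c <- c(1, 0, 0, 1, 1, 2, 2, 1)
  gm_m <- gm_fixture(cbind(as.integer(m)), prefix = "m")
  gm_c <- gm_fixture(cbind(as.integer(c)), prefix = "k")
  duos <- duo_set(rownames(gm_m), rownames(gm_c),
                  rep(c("case", "control"), each = 4),
                  stratum = 1L)
  st <- build_binary_stack(gm_m, gm_c, duos, "m001", "diff")
  expect_equal(as.vector(st[, , 1]), c(2L, 2L, 2L, 2L))

  # brute-force tally on a random 20-duo, 2-stratum fixture
  set.seed(420)
  mm <- sample(0:2, 20, replace = TRUE)
  cc <- ifelse(mm == 0, sample(0:1, 20, replace = TRUE),
               ifelse(mm == 2, sample(1:2, 20, replace = TRUE),
                      sample(0:2, 20, replace = TRUE)))
  g1 <- gm_fixture(cbind(as.integer(mm)), prefix = "m")
  g2 <- gm_fixture(cbind(as.integer(cc)), prefix = "k")
  duos2 <- duo_set(rownames(g1), rownames(g2),
                   sample(c("case", "control"), 20, replace = TRUE),
                   stratum = sample(1:2, 20, replace = TRUE))
  for (model in c("offhet", "mathet", "diff")) {
    st2 <- build_binary_stack(g1, g2, duos2, "m001", model)
    cls <- as.character(classify_pair(model, mm, cc))
    for (k in 1:2) for (grp in c("case", "control")) {
      sel <- duos2$stratum == k & duos2$status == grp
      expect_equal(st2[grp, "exposed", k],
                   sum(cls[sel] == "exposed"), ignore_attr = TRUE)
      expect_equal(st2[grp, "unexposed", k],
                   sum(cls[sel] == "unexposed"), ignore_attr = TRUE)
    }
  }

  # all pairs excluded -> untestable
  g3 <- gm_fixture(cbind(rep(NA_integer_, 4)), prefix = "m")
  g4 <- gm_fixture(cbind(rep(NA_integer_, 4)), prefix = "k")
  duos3 <- duo_set(rownames(g3), rownames(g4), rep("case", 4),
                   stratum = 1L)
  st3 <- build_binary_stack(g3, g4, duos3, "m001", "diff")
  expect_true(isTRUE(attr(st3, "untestable")))
  expect_equal(sum(st3), 0)
})

test_that("allele stacks count two observations per individual", {
  g <- gm_fixture(cbind(c(2L, 1L, 0L, 1L)), prefix = "s")
  samples <- data.frame(id = rownames(g),
                        status = c("case", "control", "case", "control"),
                        stratum = 1L)
  st <- build_allele_stack(g, samples, "m001")
  expect_equal(st["case", "a1", 1], 2L, ignore_attr = TRUE)
  expect_equal(st["case", "a2", 1], 2L, ignore_attr = TRUE)
  expect_equal(st["control", "a1", 1], 2L, ignore_attr = TRUE)
  expect_equal(st["control", "a2", 1], 2L, ignore_attr = TRUE)

  set.seed(421)
  g2 <- gm_fixture(cbind(sample(c(0:2, NA), 50, replace = TRUE)))
  samples2 <- data.frame(id = rownames(g2),
                         status = sample(c("case", "control"), 50,
                                         replace = TRUE),
                         stratum = sample(1:3, 50, replace = TRUE))
  st2 <- build_allele_stack(g2, samples2, "m001")
  dos <- unclass(g2)[, 1]
  for (k in 1:3) for (grp in c("case", "control")) {
    sel <- samples2$stratum == k & samples2$status == grp & !is.na(dos)
    expect_equal(st2[grp, "a1", k], sum(dos[sel]), ignore_attr = TRUE)
    expect_equal(st2[grp, "a2", k], sum(2 - dos[sel]),
                 ignore_attr = TRUE)
  }
  expect_equal(sum(st2), 2 * sum(!is.na(dos)))
})
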