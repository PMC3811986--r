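# Independent oracles and fixture builders shared across the suite.

# hand-built geno_matrix from a dosage matrix
gm_fixture <- function(calls, ids = NULL, prefix = "s") {
  calls <- as.matrix(calls)
  if (is.null(ids)) ids <- sprintf("%s%03d", prefix, seq_len(nrow(calls)))
  rownames(calls) <- ids
  m <- ncol(calls)
  map <- data.frame(id = sprintf("m%03d", seq_len(m)),
                    chrom = "1", pos = seq_len(m) * 100L,
                    a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  geno_matrix(calls, map)
}

# closed-form HWE exact probability of k heterozygotes given n genotypes
# and nr rare-allele copies: C(n,k) C(n-k,(nr-k)/2) 2^k / C(2n, nr)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nr <- 2 * min(n_aa, n_bb) + n_ab
  if (nr == 0) return(1)
  ks <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  pk <- choose(n, ks) * choose(n - ks, (nr - ks) / 2) * 2^ks /
    choose(2 * n, nr)
  obs <- pk[ks == n_ab]
  sum(pk[pk <= obs * (1 + 1e-12)])
}

# first-principles CMH over a 2x2xK stack: direct per-stratum sums
cmh_oracle <- function(stack) {
  sa <- se <- sv <- num <- den <- 0
  K <- dim(stack)[3]
  used <- 0
  for (k in seq_len(K)) {
    a <- stack[1, 1, k]; b <- stack[1, 2, k]
    c <- stack[2, 1, k]; d <- stack[2, 2, k]
    n <- a + b + c + d
    if (n < 2 || (a + b) == 0 || (c + d) == 0 || (a + c) == 0 ||
        (b + d) == 0) next
    used <- used + 1
    sa <- sa + a
    se <- se + (a + b) * (a + c) / n
    sv <- sv + (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
    num <- num + a * d / n
    den <- den + b * c / n
  }
  if (used == 0 || sv == 0) return(list(stat = NA_real_, or = NA_real_))
  list(stat = (sa - se)^2 / sv,
       or = if (den > 0 && num > 0) num / den else NA_real_)
}

pearson_oracle <- function(tab) {
  tab <- matrix(as.numeric(tab), 2)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# hand-enumerated classifier truth tables: list model -> mode ->
# data.frame(m, c, class), written out rule by rule (independent of
# classify_pair's vectorized logic)
classifier_oracle <- function() {
  grid <- expand.grid(m = c(0, 1, 2, NA), c = c(0, 1, 2, NA))
  one <- function(model, mode) {
    cls <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      m <- grid$m[i]; c <- grid$c[i]
      if (is.na(m) || is.na(c)) { cls[i] <- "excluded_missing"; next }
      if ((m == 0 && c == 2) || (m == 2 && c == 0)) {
        cls[i] <- "excluded_mendel"; next
      }
      if (model == "diff") {
        cls[i] <- if (m != c) "exposed" else "unexposed"
      } else if (model == "offhet") {
        if (mode == "conditioned" && c != 1) {
          cls[i] <- "excluded_uninformative"
        } else if (c == 1 && (m == 0 || m == 2)) {
          cls[i] <- "exposed"
        } else cls[i] <- "unexposed"
      } else {                       # mathet
        if (mode == "conditioned" && m != 1) {
          cls[i] <- "excluded_uninformative"
        } else if (m == 1 && (c == 0 || c == 2)) {
          cls[i] <- "exposed"
        } else cls[i] <- "unexposed"
      }
    }
    cbind(grid, class = cls)
  }
  out <- list()
  for (model in c("offhet", "mathet", "diff"))
    for (mode in c("literal", "conditioned"))
      out[[paste(model, mode, sep = ".")]] <- one(model, mode)
  out
}

# brute-force tally of a trio interaction analogue table
trio_te_oracle <- function(test, f, m, c) {
  ok <- !(is.na(f) | is.na(m) | is.na(c))
  f <- f[ok]; m <- m[ok]; c <- c[ok]
  yes_m <- yes_f <- no_m <- no_f <- 0
  for (i in seq_along(c)) {
    if (test == "offhet_rep") {
      if (c[i] != 1) next
      if (m[i] != 1) yes_m <- yes_m + 1 else no_m <- no_m + 1
      if (f[i] != 1) yes_f <- yes_f + 1 else no_f <- no_f + 1
    } else if (test == "mathet_rep") {
      if (c[i] == 1) next
      if (m[i] == 1) yes_m <- yes_m + 1 else no_m <- no_m + 1
      if (f[i] == 1) yes_f <- yes_f + 1 else no_f <- no_f + 1
    } else {
      if (m[i] != c[i]) yes_m <- yes_m + 1 else no_m <- no_m + 1
      if (f[i] != c[i]) yes_f <- yes_f + 1 else no_f <- no_f + 1
    }
  }
  matrix(c(yes_m, no_m, yes_f, no_f), 2, byrow = TRUE,
         dimnames = list(c("mother", "father"), c("yes", "no")))
}

# trio fixture: explicit dosage vectors -> geno_matrix + trio_set
trio_fixture <- function(f, m, c) {
  n <- length(c)
  fids <- sprintf("f%03d", 1:n); mids <- sprintf("mo%03d", 1:n)
  cids <- sprintf("c%03d", 1:n)
  gm <- gm_fixture(cbind(c(f, m, c)), ids = c(fids, mids, cids))
  list(gm = gm, trios = trio_set(fids, mids, cids))
}

binom99 <- function(p0, n) p0 + c(-1, 1) * qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
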