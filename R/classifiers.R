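# The three binary mother-child genotype classifiers and the stratified
# count stacks they feed.
#
# Models (a1 dosage coding; m = mother, c = child):
#   offhet — "offspring heterozygous": the child carries an allele the
#            mother does not, i.e. c == 1 with m homozygous;
#   mathet — "maternal heterozygous": the mother carries an allele the
#            child does not, i.e. m == 1 with c homozygous;
#   diff   — genotypes not identical (m != c).
# Opposite homozygotes (0,2)/(2,0) are Mendelian-impossible and excluded;
# pairs with a missing member are excluded.  In "conditioned" mode the
# offhet model additionally drops homozygous-child pairs and mathet drops
# homozygous-mother pairs (mirroring the trio replication analogues);
# "literal" mode classifies every Mendelian-consistent complete pair.

.PAIR_CLASSES <- c("exposed", "unexposed", "excluded_mendel",
                   "excluded_uninformative", "excluded_missing")

#' Classify a mother-child genotype pair under a transgenerational model
#'
#' @param model one of `"offhet"`, `"mathet"`, `"diff"`.
#' @param m,c maternal and child a1 dosages in `{0,1,2,NA}` (vectors are
#'   recycled to common length).
#' @param mode `"literal"` (default: every Mendelian-consistent complete
#'   pair is exposed or unexposed) or `"conditioned"` (offhet restricts
#'   to heterozygous children, mathet to heterozygous mothers; other
#'   pairs are `excluded_uninformative`).
#' @return factor with levels exposed, unexposed, excluded_mendel,
#'   excluded_uninformative, excluded_missing.
#' @export
classify_pair <- function(model = c("offhet", "mathet", "diff"), m, c,
                          mode = c("literal", "conditioned")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  n <- max(length(m), length(c))
  m <- rep_len(as.integer(m), n)
  c <- rep_len(as.integer(c), n)
  if (any(!(m %in% c(0L, 1L, 2L, NA))) || any(!(c %in% c(0L, 1L, 2L, NA))))
    stop("dosages must be 0, 1, 2 or NA")
  out <- rep("unexposed", n)
  miss <- is.na(m) | is.na(c)
  mendel <- !miss & ((m == 0L & c == 2L) | (m == 2L & c == 0L))
  exposed <- switch(model,
    diff   = !miss & m != c,
    offhet = !miss & c == 1L & m != 1L,
    mathet = !miss & m == 1L & c != 1L)
  out[exposed] <- "exposed"
  if (mode == "conditioned") {
    uninf <- switch(model,
      diff   = rep(FALSE, n),
      offhet = !miss & c != 1L,
      mathet = !miss & m != 1L)
    out[uninf] <- "excluded_uninformative"
  }
  out[mendel] <- "excluded_mendel"
  out[miss] <- "excluded_missing"
  factor(out, levels = .PAIR_CLASSES)
}

#' An empty stratified 2 x 2 x K count stack
#'
#' Dimensions: group (case, control) x class x stratum.  For binary-
#' classifier stacks the classes are exposed/unexposed; for allele stacks
#' they are the a1/a2 allele counts.
#'
#' @param K number of strata.
#' @param classes column labels.
#' @return a zero integer array of class `stratified_table`.
#' @export
stratified_table <- function(K, classes = c("exposed", "unexposed")) {
  structure(array(0L, dim = c(2, 2, K),
                  dimnames = list(group = c("case", "control"),
                                  class = classes,
                                  stratum = seq_len(K))),
            class = "stratified_table")
}

#' Stratified exposed/unexposed counts for one marker
#'
#' Tallies the binary classifier over duos by case/control status and
#' stratum.  Duos carry stratum assignments from the maternal cluster
#' solution; excluded classes contribute nothing.
#'
#' @param gm_m,gm_c maternal and child matrices.
#' @param duos a [duo_set()] with `stratum` filled in (NA = unassigned,
#'   treated as a single stratum 1 if all NA).
#' @param marker marker ID.
#' @param model classifier model (see [classify_pair()]).
#' @param mode classifier mode.
#' @return a [stratified_table()] with attribute `untestable = TRUE` when
#'   every duo is excluded.
#' @export
build_binary_stack <- function(gm_m, gm_c, duos, marker,
                               model = c("offhet", "mathet", "diff"),
                               mode = c("literal", "conditioned")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  strat <- duos$stratum
  if (all(is.na(strat))) strat <- rep(1L, nrow(duos))
  if (anyNA(strat)) stop("duos with unassigned stratum")
  K <- max(strat)
  m <- unclass(gm_m)[match(duos$mother_id, rownames(gm_m)), marker]
  c <- unclass(gm_c)[match(duos$child_id, rownames(gm_c)), marker]
  cls <- classify_pair(model, m, c, mode)
  st <- stratified_table(K)
  keep <- cls %in% c("exposed", "unexposed")
  if (!any(keep)) {
    attr(st, "untestable") <- TRUE
    return(st)
  }
  tab <- table(group = factor(ifelse(duos$status[keep] == "case",
                                     "case", "control"),
                              levels = c("case", "control")),
               class = factor(as.character(cls[keep]),
                              levels = c("exposed", "unexposed")),
               stratum = factor(strat[keep], levels = seq_len(K)))
  st[] <- as.integer(tab)
  st
}

#' Stratified allele-count table for one marker
#'
#' Each non-missing individual contributes two allele observations
#' (dosage copies of a1 and `2 - dosage` of a2) to its (status, stratum)
#' cell — the allele-frequency case/control comparison.
#'
#' @param gm a [geno_matrix()].
#' @param samples data.frame with columns `id`, `status`
#'   (case/control) and `stratum`.
#' @param marker marker ID.
#' @return a [stratified_table()] with classes `a1`, `a2`.
#' @export
build_allele_stack <- function(gm, samples, marker) {
  strat <- samples$stratum
  if (all(is.na(strat))) strat <- rep(1L, nrow(samples))
  if (anyNA(strat)) stop("samples with unassigned stratum")
  K <- max(strat)
  g <- unclass(gm)[match(samples$id, rownames(gm)), marker]
  st <- stratified_table(K, classes = c("a1", "a2"))
  ok <- !is.na(g)
  for (k in seq_len(K)) {
    for (grp in c("case", "control")) {
      sel <- ok & strat == k & samples$status == grp
      st[grp, "a1", k] <- sum(g[sel])
      st[grp, "a2", k] <- sum(2L - g[sel])
    }
  }
  st
}
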