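# Genotype containers and PED/MAP-dialect text I/O.
#
# Genotypes are stored as integer dosages of the a1 allele (0, 1, 2 or NA)
# in a samples x markers matrix.  a1 is fixed per marker by an explicit
# allele-reference table so that coding is identical across the maternal
# and child matrices and across subsets; it is never inferred from
# observed frequency, which can flip between sample sets.

#' Construct a genotype matrix
#'
#' Bundles an integer dosage matrix (samples in rows, markers in columns,
#' entries counting copies of the marker's a1 allele, `NA` = missing) with
#' its marker map and optional family/phenotype information.
#'
#' @param calls integer matrix of a1 dosages in `{0,1,2,NA}`; rownames are
#'   sample IDs, colnames marker IDs.
#' @param map data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`,
#'   one row per column of `calls`.
#' @param fam optional data.frame with one row per sample: columns `fid`,
#'   `iid`, `pat`, `mat`, `sex`, `pheno` (PED conventions: pheno 2 = case,
#'   1 = control, 0/-9 = missing).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map, fam = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map))
    stop("map has ", nrow(map), " markers but calls has ", ncol(calls),
         " columns")
  need <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(map)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$id))
    stop("duplicated marker IDs in map")
  if (any(map$a1 == map$a2))
    stop("a1 == a2 for markers: ",
         paste(utils::head(map$id[map$a1 == map$a2]), collapse = ", "))
  if (any(map$pos < 1))
    stop("marker positions must be >= 1")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE))
    stop("dosage calls must be 0, 1, 2 or NA")
  if (is.null(rownames(calls)))
    stop("calls must have sample IDs as rownames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicated sample IDs")
  colnames(calls) <- map$id
  rownames(map) <- NULL
  structure(calls, map = map, fam = fam, class = c("geno_matrix", "matrix"))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x), "samples x", ncol(x), "markers\n")
  miss <- mean(is.na(x))
  cat(sprintf("  missing rate %.4f\n", miss))
  invisible(x)
}

#' Marker map of a genotype matrix
#' @param gm a [geno_matrix()].
#' @return the marker map data.frame (`id`, `chrom`, `pos`, `a1`, `a2`).
#' @export
marker_map <- function(gm) attr(gm, "map")

#' Family/phenotype table of a genotype matrix
#' @param gm a [geno_matrix()].
#' @return the fam data.frame, or `NULL` if none was attached.
#' @export
fam_table <- function(gm) attr(gm, "fam")

# subsetting keeps map/fam in sync
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  map <- attr(x, "map")
  fam <- attr(x, "fam")
  y <- unclass(x)
  attr(y, "map") <- NULL; attr(y, "fam") <- NULL
  out <- y[i, j, drop = FALSE]
  if (!missing(j)) {
    jj <- if (is.character(j)) match(j, map$id) else seq_len(nrow(map))[j]
    map <- map[jj, , drop = FALSE]
  }
  if (!missing(i) && !is.null(fam)) {
    ii <- if (is.character(i)) match(i, fam$iid) else seq_len(nrow(fam))[i]
    fam <- fam[ii, , drop = FALSE]
  }
  geno_matrix(out, map, fam)
}

.split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read PED/MAP genotype files
#'
#' Reads the 6-column PED dialect (`FID IID PAT MAT SEX PHENO` followed by
#' two single-token allele columns per marker; missing genotype coded
#' `0 0`) with its companion MAP file (`CHR SNP CM BP`).  Dosages count
#' copies of the a1 allele; a1/a2 come from `allele_ref` when supplied
#' (recommended — deterministic coding across sample sets), otherwise the
#' observed alleles are taken in sorted order.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @param allele_ref optional allele-reference: a path to a 3-column
#'   whitespace-delimited file (`marker a1 a2`) or an equivalent
#'   data.frame.
#' @return a [geno_matrix()] with the PED fam columns attached.
#' @export
read_ped_map <- function(ped_path, map_path, allele_ref = NULL) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  names(map_raw) <- c("chrom", "id", "cm", "pos")
  m <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- .split_ws(lines)
  want <- 6L + 2L * m
  len <- lengths(toks)
  if (any(len != want))
    stop("PED parse error: line ", which(len != want)[1], " has ",
         len[len != want][1], " fields, expected ", want)
  n <- length(toks)
  tokmat <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  fam <- data.frame(fid = tokmat[, 1], iid = tokmat[, 2],
                    pat = tokmat[, 3], mat = tokmat[, 4],
                    sex = as.integer(tokmat[, 5]),
                    pheno = as.integer(tokmat[, 6]),
                    stringsAsFactors = FALSE)
  al1 <- tokmat[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  al2 <- tokmat[, 6L + 2L * seq_len(m), drop = FALSE]

  if (!is.null(allele_ref)) {
    ref <- if (is.character(allele_ref) && length(allele_ref) == 1)
      read_allele_ref(allele_ref) else as.data.frame(allele_ref)
    idx <- match(map_raw$id, ref$marker)
    if (anyNA(idx))
      stop("allele reference missing markers: ",
           paste(utils::head(map_raw$id[is.na(idx)]), collapse = ", "))
    a1 <- ref$a1[idx]; a2 <- ref$a2[idx]
  } else {
    a1 <- character(m); a2 <- character(m)
    for (k in seq_len(m)) {
      obs <- sort(setdiff(unique(c(al1[, k], al2[, k])), "0"))
      if (length(obs) > 2)
        stop("marker ", map_raw$id[k], " has ", length(obs),
             " alleles; only biallelic markers are supported")
      a1[k] <- if (length(obs) >= 1) obs[1] else "A"
      a2[k] <- if (length(obs) == 2) obs[2] else "B"
    }
  }

  calls <- matrix(NA_integer_, n, m)
  for (k in seq_len(m)) {
    x1 <- al1[, k]; x2 <- al2[, k]
    miss <- x1 == "0" | x2 == "0"
    ok <- c(a1[k], a2[k])
    extra <- setdiff(unique(c(x1[!miss], x2[!miss])), ok)
    if (length(extra))
      stop("marker ", map_raw$id[k], " carries allele(s) ",
           paste(extra, collapse = ","), " not in its allele pair")
    calls[, k] <- (x1 == a1[k]) + (x2 == a1[k])
    calls[miss, k] <- NA_integer_
  }
  rownames(calls) <- fam$iid
  map <- data.frame(id = map_raw$id, chrom = map_raw$chrom,
                    pos = map_raw$pos, a1 = a1, a2 = a2,
                    stringsAsFactors = FALSE)
  geno_matrix(calls, map, fam)
}

#' Write PED/MAP genotype files
#'
#' Inverse of [read_ped_map()]: round trips preserve every call, ID and
#' allele label.
#'
#' @param gm a [geno_matrix()].
#' @param ped_path,map_path output paths.
#' @return invisibly, `gm`.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  map <- marker_map(gm)
  utils::write.table(
    data.frame(map$chrom, map$id, 0,
               format(map$pos, scientific = FALSE, trim = TRUE)),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  fam <- fam_table(gm)
  if (is.null(fam))
    fam <- data.frame(fid = rownames(gm), iid = rownames(gm),
                      pat = "0", mat = "0", sex = 0L, pheno = 0L)
  n <- nrow(gm); m <- ncol(gm)
  a1 <- matrix(rep(map$a1, each = n), n, m)
  a2 <- matrix(rep(map$a2, each = n), n, m)
  g <- unclass(gm)
  first <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
  second <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
  geno_cols <- matrix("", n, 2L * m)
  geno_cols[, seq(1, 2 * m, 2)] <- first
  geno_cols[, seq(2, 2 * m, 2)] <- second
  out <- cbind(fam$fid, fam$iid, fam$pat, fam$mat, fam$sex, fam$pheno,
               geno_cols)
  con <- file(ped_path, "w")
  on.exit(close(con))
  writeLines(apply(out, 1, paste, collapse = " "), con)
  invisible(gm)
}

#' Read / write an allele-reference table
#'
#' Three whitespace-delimited columns: marker, a1, a2.  The a1 column
#' fixes the dosage coding for [read_ped_map()].
#'
#' @param path file path.
#' @return data.frame with columns `marker`, `a1`, `a2`.
#' @export
read_allele_ref <- function(path) {
  ref <- utils::read.table(path, header = FALSE, colClasses = "character")
  names(ref) <- c("marker", "a1", "a2")
  ref
}

#' @rdname read_allele_ref
#' @param gm a [geno_matrix()] whose marker map supplies the alleles.
#' @export
write_allele_ref <- function(gm, path) {
  map <- marker_map(gm)
  utils::write.table(data.frame(map$id, map$a1, map$a2), path,
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a mother-child pair file
#'
#' Whitespace-delimited columns `mother_id child_id status`.  Status
#' tokens `case`/`control` (any case) and the PED convention `2` =
#' case/affected, `1` = control are accepted.  Each child may appear
#' once (one mother per child).
#'
#' @param path file path.
#' @return data.frame of class `duo_set` with columns `mother_id`,
#'   `child_id`, `status` (factor case/control) and `stratum`
#'   (`NA` until assigned).
#' @export
read_pairs <- function(path) {
  d <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(d) < 3) stop("pair file needs 3 columns: mother child status")
  names(d)[1:3] <- c("mother_id", "child_id", "status")
  duo_set(d$mother_id, d$child_id, d$status)
}

#' Construct a duo set
#'
#' @param mother_id,child_id character vectors of sample IDs.
#' @param status case/control status; accepts `"case"`/`"control"`
#'   (case-insensitive) or `2`/`1`.
#' @param stratum optional integer cluster assignment (1..K).
#' @return data.frame of class `duo_set`.
#' @export
duo_set <- function(mother_id, child_id, status, stratum = NA_integer_) {
  status <- tolower(as.character(status))
  status[status == "2"] <- "case"
  status[status == "1"] <- "control"
  bad <- !status %in% c("case", "control")
  if (any(bad))
    stop("unknown status token(s): ",
         paste(unique(status[bad]), collapse = ", "))
  if (any(mother_id == child_id))
    stop("mother_id equals child_id for some pairs")
  if (anyDuplicated(child_id))
    stop("duplicated child_id (one mother per child): ",
         paste(utils::head(unique(child_id[duplicated(child_id)])),
               collapse = ", "))
  d <- data.frame(mother_id = as.character(mother_id),
                  child_id = as.character(child_id),
                  status = factor(status, levels = c("control", "case")),
                  stratum = as.integer(stratum),
                  stringsAsFactors = FALSE)
  class(d) <- c("duo_set", "data.frame")
  d
}

#' Construct a trio set
#'
#' @param father_id,mother_id,child_id character sample IDs; distinct
#'   within each trio.
#' @param affected logical affection flag of the child (default `TRUE`;
#'   replication datasets are ascertained on affected offspring).
#' @param dataset non-empty dataset label.
#' @return data.frame of class `trio_set`.
#' @export
trio_set <- function(father_id, mother_id, child_id, affected = TRUE,
                     dataset = "rep1") {
  ids <- cbind(father_id, mother_id, child_id)
  if (any(apply(ids, 1, function(r) anyDuplicated(r) > 0)))
    stop("trio members must be three distinct IDs")
  if (any(!nzchar(dataset))) stop("dataset label must be non-empty")
  d <- data.frame(father_id = as.character(father_id),
                  mother_id = as.character(mother_id),
                  child_id = as.character(child_id),
                  affected = rep_len(as.logical(affected),
                                     length(child_id)),
                  dataset = rep_len(as.character(dataset),
                                    length(child_id)),
                  stringsAsFactors = FALSE)
  class(d) <- c("trio_set", "data.frame")
  d
}

#' Extract trios from a PED-style fam table
#'
#' Children are rows whose `pat` and `mat` both point at samples present
#' in the table; affection comes from the child's pheno column.
#'
#' @param gm a [geno_matrix()] carrying a fam table.
#' @param dataset dataset label for the resulting trios.
#' @return a [trio_set()].
#' @export
trios_from_fam <- function(gm, dataset = "rep1") {
  fam <- fam_table(gm)
  if (is.null(fam)) stop("geno_matrix has no fam table")
  is_child <- fam$pat %in% fam$iid & fam$mat %in% fam$iid &
    fam$pat != "0" & fam$mat != "0"
  kids <- fam[is_child, , drop = FALSE]
  trio_set(kids$pat, kids$mat, kids$iid,
           affected = kids$pheno == 2L, dataset = dataset)
}

#' Write an association result table
#'
#' Tab-delimited with one header line and columns
#' `CHR SNP BP A1 A2 MODEL STAT P OR`, sorted by (model, chromosome,
#' position).  Undefined odds ratios are written as `NA`.
#'
#' @param rows a result data.frame as returned by [scan_assoc()] (columns
#'   `marker`, `chrom`, `pos`, `a1`, `a2`, `model`, `stat`, `p`, `or_mh`).
#' @param path output path.
#' @param header_lines optional character vector of `#`-prefixed comment
#'   lines written before the header.
#' @return invisibly, the sorted data.frame that was written.
#' @export
write_results <- function(rows, path, header_lines = NULL) {
  if (nrow(rows) == 0) stop("no result rows to write")
  chrn <- suppressWarnings(as.numeric(rows$chrom))
  chr_key <- ifelse(is.na(chrn), 1e6 + as.numeric(factor(rows$chrom)), chrn)
  ord <- order(as.character(rows$model), chr_key, rows$pos)
  rows <- rows[ord, , drop = FALSE]
  out <- data.frame(CHR = rows$chrom, SNP = rows$marker, BP = rows$pos,
                    A1 = rows$a1, A2 = rows$a2,
                    MODEL = as.character(rows$model),
                    STAT = formatC(rows$stat, digits = 6, format = "g"),
                    P = formatC(rows$p, digits = 6, format = "g"),
                    OR = ifelse(is.na(rows$or_mh) | !is.finite(rows$or_mh),
                                "NA",
                                formatC(rows$or_mh, digits = 6,
                                        format = "g")))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(rows)
}
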