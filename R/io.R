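#' Read PLINK-style PED/MAP text genotypes
#'
#' Whitespace-separated PED (FID IID PAT MAT SEX PHENO allele pairs) with a
#' matching 4-column MAP (chrom, id, cM, pos). Genotype "0 0" is missing. Per
#' variant, allele coding follows first observation: the first allele seen
#' becomes `a1` and calls count copies of the other allele `a2`.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @return A [genotype_matrix()]; the PED family id is kept as sample column
#'   `breed` when informative.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "id", "cm", "pos")
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want))
    stop(sprintf("PED parse error: line %d has %d fields, expected %d",
                 which(lens != want)[1], lens[lens != want][1], want))
  n <- length(toks)
  fid <- vapply(toks, `[[`, "", 1L)
  iid <- vapply(toks, `[[`, "", 2L)
  if (anyDuplicated(iid))
    stop("duplicate sample id: ",
         paste(unique(iid[duplicated(iid)]), collapse = ", "))
  al <- matrix("0", nrow = n, ncol = 2L * m)
  for (i in seq_len(n)) al[i, ] <- toks[[i]][-(1:6)]
  calls <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x <- al[, 2L * j - 1L]; y <- al[, 2L * j]
    ok <- x != "0" & y != "0"
    seen <- c(rbind(x[ok], y[ok]))
    u <- unique(seen)
    if (length(u) > 2L)
      stop("more than two alleles at variant ", map$id[j])
    a1[j] <- if (length(u) >= 1L) u[1] else "0"
    a2[j] <- if (length(u) == 2L) u[2] else "0"
    calls[ok, j] <- (x[ok] == a2[j]) + (y[ok] == a2[j])
  }
  samples <- data.frame(id = iid)
  if (length(unique(fid)) > 1L || !all(fid == iid)) samples$breed <- fid
  genotype_matrix(calls, data.frame(chrom = map$chrom, pos = map$pos,
                                    id = map$id, a1 = a1, a2 = a2), samples)
}

#' Write a genotype matrix as PED/MAP
#'
#' Inverse of [read_ped_map()] up to per-variant allele labelling: calls of
#' 0/1/2 are written as `a1 a1` / `a1 a2` / `a2 a2`, missing as `0 0`.
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  va <- gm$variants
  utils::write.table(
    data.frame(va$chrom, va$id, 0, va$pos),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  a1 <- ifelse(va$a1 == "0", "A", va$a1)
  a2 <- ifelse(va$a2 == "0", ifelse(a1 == "B", "C", "B"), va$a2)
  n <- nrow(gm$calls); m <- ncol(gm$calls)
  fid <- gm$samples$breed
  if (is.null(fid) || all(is.na(fid))) fid <- gm$samples$id
  con <- file(ped_path, "w"); on.exit(close(con))
  for (i in seq_len(n)) {
    x <- gm$calls[i, ]
    g1 <- ifelse(is.na(x), "0", ifelse(x >= 1L, a2, a1))
    g2 <- ifelse(is.na(x), "0", ifelse(x == 2L, a2, a1))
    writeLines(paste(c(fid[i], gm$samples$id[i], 0, 0, 0, -9,
                       as.vector(rbind(g1, g2))), collapse = " "), con)
  }
  invisible(c(ped_path, map_path))
}

#' Read a phased VCF into a haplotype matrix
#'
#' Requires biallelic records and fully phased GT fields ("|" separator).
#' Haplotype order is (sample, hapA) then (sample, hapB) in file sample order.
#'
#' @param path VCF path (v4.x, plain or bgzipped).
#' @return A [haplotype_matrix()].
#' @export
read_vcf_phased <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)       # single-record files drop dims
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  multi <- grepl(",", fx$ALT)
  if (any(multi))
    stop("multi-allelic records not supported: ",
         paste(utils::head(fx$ID[multi], 5), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fx),
                 dimnames = list(fx$ID, colnames(v@gt)[-1]))
  unph <- grepl("/", gt, fixed = TRUE)    # dims dropped by grepl
  if (any(unph)) {
    bad <- unique(rownames(gt)[((which(unph) - 1L) %% nrow(gt)) + 1L])
    stop("unphased genotypes at records: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyNA(gt) || any(grepl("\\.", gt)))
    stop("missing genotypes not allowed in phased input")
  sample_ids <- colnames(gt)
  m <- nrow(gt); n <- length(sample_ids)
  hapA <- matrix(as.integer(substr(gt, 1, 1)), m, n)
  hapB <- matrix(as.integer(substr(gt, 3, 3)), m, n)
  alleles <- matrix(0L, 2L * n, m)
  alleles[seq(1L, 2L * n, 2L), ] <- t(hapA)
  alleles[seq(2L, 2L * n, 2L), ] <- t(hapB)
  ids <- fx$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fx$CHROM, ":", fx$POS)[is.na(ids) | ids == "."]
  haplotype_matrix(alleles, sample_ids,
                   data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS),
                              id = ids, a1 = fx$REF, a2 = fx$ALT))
}

#' Write a haplotype matrix as a phased VCF
#'
#' @param h a [haplotype_matrix()].
#' @param path output path (plain text, VCF v4.2).
#' @return Invisibly, `path`.
#' @export
write_vcf_phased <- function(h, path) {
  va <- h$variants
  ref <- if ("a1" %in% names(va)) va$a1 else rep("A", nrow(va))
  alt <- if ("a2" %in% names(va)) va$a2 else rep("T", nrow(va))
  ref[ref %in% c("0", "")] <- "A"
  alt[alt %in% c("0", "")] <- "T"
  n <- length(h$sample_ids)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popgenpipe",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", h$sample_ids), collapse = "\t")), con)
  hapA <- h$alleles[seq(1L, 2L * n, 2L), , drop = FALSE]
  hapB <- h$alleles[seq(2L, 2L * n, 2L), , drop = FALSE]
  for (j in seq_len(nrow(va))) {
    gts <- paste0(hapA[, j], "|", hapB[, j])
    writeLines(paste(c(va$chrom[j], va$pos[j], va$id[j], ref[j], alt[j],
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a BED interval file
#'
#' Standard BED dialect: 0-based half-open intervals, at least three columns
#' (chrom, start, end), optional fourth name column.
#'
#' @param path BED path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`
#'   (0-based half-open coordinates preserved).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  toks <- strsplit(lines, "\t| +")
  out <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    t <- toks[[i]]
    if (length(t) < 3L)
      stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.integer(t[2])); e <- suppressWarnings(as.integer(t[3]))
    if (is.na(s) || is.na(e) || s < 0L || e <= s)
      stop("malformed BED line ", i, ": bad interval [", t[2], ", ", t[3], ")")
    out[[i]] <- data.frame(chrom = t[1], start = s, end = e,
                           name = if (length(t) >= 4L) t[4] else
                             paste0(t[1], ":", s, "-", e))
  }
  do.call(rbind, out)
}

#' Write intervals to BED
#'
#' Input intervals are 1-based inclusive (the in-memory convention); they are
#' converted to BED's 0-based half-open dialect on output.
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   optional further columns, written as extra BED fields.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  out <- data.frame(df$chrom, df$start - 1L, df$end)
  for (cl in extra) out[[cl]] <- df[[cl]]
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column sample hierarchy TSV (sample, population, group)
#' @param path TSV path with header.
#' @return data.frame with columns `sample`, `population`, `group`.
#' @export
read_hierarchy <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  if (!all(c("sample", "population", "group") %in% names(h)))
    stop("hierarchy TSV needs columns sample, population, group")
  h
}
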