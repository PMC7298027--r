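#' Construct a genotype matrix
#'
#' The central genotype container: a samples x variants matrix of alternate
#' allele counts (0, 1, 2, or `NA` for missing), together with ordered variant
#' records (chromosome, 1-based position, alleles, id) and sample records
#' carrying optional group labels (breed, lineage, use).
#'
#' @param calls integer matrix, samples in rows, variants in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `a1`, `a2`.
#'   `a1` is the reference-coded allele (0 copies of `a2`), `a2` the counted
#'   allele. Positions must be strictly increasing within a chromosome.
#' @param samples data.frame with column `id` and optional columns `breed`,
#'   `lineage`, `use`. Ids must be unique.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  req <- c("chrom", "pos", "id", "a1", "a2")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (!"id" %in% names(samples)) stop("samples must have an 'id' column")
  for (lab in c("breed", "lineage", "use"))
    if (!lab %in% names(samples)) samples[[lab]] <- NA_character_
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  samples$id <- as.character(samples$id)
  if (nrow(samples) != nrow(calls) || nrow(variants) != ncol(calls))
    stop("calls dimensions do not match samples/variants tables")
  if (anyDuplicated(samples$id)) stop("duplicate sample id: ",
    paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  if (anyDuplicated(variants$id)) stop("duplicate variant id")
  if (any(variants$pos < 1L)) stop("positions must be >= 1")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("calls must be 0, 1, 2 or NA")
  rownames(calls) <- samples$id
  colnames(calls) <- variants$id
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' Construct a phased haplotype matrix
#'
#' Phased binary haplotypes, two per sample, over an ordered variant set.
#' Phased data are complete: no missing alleles are allowed.
#'
#' @param alleles integer matrix (0/1), haplotypes in rows, variants in
#'   columns. Rows `2k-1` and `2k` are the two haplotypes of sample `k`.
#' @param sample_ids character vector of sample ids (one per diploid sample).
#' @param variants variant table as in [genotype_matrix()].
#' @return An object of class `haplotype_matrix`. Row names are
#'   `<sample>_h1` / `<sample>_h2`.
#' @export
haplotype_matrix <- function(alleles, sample_ids, variants) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  sample_ids <- as.character(sample_ids)
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("alleles must have exactly 2 rows per sample")
  if (anyDuplicated(sample_ids)) stop("duplicate sample id")
  if (anyNA(alleles)) stop("phased haplotypes cannot contain missing alleles")
  if (!all(alleles %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (nrow(variants) != ncol(alleles))
    stop("variant table does not match allele matrix")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  hap_sample <- rep(sample_ids, each = 2L)
  rownames(alleles) <- paste0(hap_sample, "_h", rep(1:2, length(sample_ids)))
  colnames(alleles) <- variants$id
  structure(list(alleles = alleles, sample_ids = sample_ids,
                 hap_sample = hap_sample, variants = variants),
            class = "haplotype_matrix")
}

#' Collapse phased haplotypes to genotype calls
#'
#' Sums each sample's two haplotypes into 0/1/2 alternate-allele counts.
#'
#' @param h a [haplotype_matrix()].
#' @param samples optional sample table (defaults to ids only).
#' @return A [genotype_matrix()].
#' @export
haplotypes_to_genotypes <- function(h, samples = NULL) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- length(h$sample_ids)
  calls <- h$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
           h$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  if (is.null(samples)) samples <- data.frame(id = h$sample_ids)
  va <- h$variants
  if (!"a1" %in% names(va)) va$a1 <- "A"
  if (!"a2" %in% names(va)) va$a2 <- "B"
  genotype_matrix(calls, va, samples)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d chromosome%s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1) "" else "s"))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes (%d samples) x %d variants\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles)))
  invisible(x)
}

#' Alternate allele frequencies of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional character vector restricting to a sample subset.
#' @return Numeric vector of per-variant alternate-allele frequencies
#'   (NaN where no sample is genotyped).
#' @export
allele_freqs <- function(gm, samples = NULL) {
  calls <- gm$calls
  if (!is.null(samples)) {
    if (!all(samples %in% gm$samples$id)) stop("unknown sample id")
    calls <- calls[gm$samples$id %in% samples, , drop = FALSE]
  }
  n <- 2L * colSums(!is.na(calls))
  colSums(calls, na.rm = TRUE) / n
}

#' Minor allele frequencies
#' @inheritParams allele_freqs
#' @return per-variant MAF in [0, 0.5].
#' @export
maf <- function(gm, samples = NULL) {
  p <- allele_freqs(gm, samples)
  pmin(p, 1 - p)
}

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param variants logical/integer index or variant ids to keep.
#' @param samples logical/integer index or sample ids to keep.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, variants = NULL, samples = NULL) {
  vi <- .resolve_index(variants, gm$variants$id, ncol(gm$calls))
  si <- .resolve_index(samples, gm$samples$id, nrow(gm$calls))
  genotype_matrix(gm$calls[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$samples[si, , drop = FALSE])
}

#' Subset a haplotype matrix by variants and/or samples
#' @param h a [haplotype_matrix()].
#' @param variants index or ids of variants to keep.
#' @param samples index or ids of samples to keep (both haplotypes kept).
#' @return A [haplotype_matrix()].
#' @export
subset_haplotypes <- function(h, variants = NULL, samples = NULL) {
  vi <- .resolve_index(variants, h$variants$id, ncol(h$alleles))
  si <- .resolve_index(samples, h$sample_ids, length(h$sample_ids))
  hi <- as.vector(rbind(2L * si - 1L, 2L * si))
  haplotype_matrix(h$alleles[hi, vi, drop = FALSE], h$sample_ids[si],
                   h$variants[vi, , drop = FALSE])
}

.resolve_index <- function(idx, ids, n) {
  if (is.null(idx)) return(seq_len(n))
  if (is.character(idx)) {
    m <- match(idx, ids)
    if (anyNA(m)) stop("unknown id: ", paste(idx[is.na(m)], collapse = ", "))
    return(m)
  }
  if (is.logical(idx)) return(which(idx))
  as.integer(idx)
}
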