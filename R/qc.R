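#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the expectation at the sample allele frequency. Monomorphic sites
#' return p = 1 (nothing to test).
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer genotype counts.
#' @return The p-value.
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(cts < 0) || any(cts != round(cts))) stop("counts must be non-negative integers")
  n <- sum(cts)
  if (n == 0) stop("all counts are zero")
  p <- (2 * n_hom_alt + n_het) / (2 * n)
  if (p == 0 || p == 1) return(1.0)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((cts - e)^2 / e)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

.new_filter_report <- function() {
  structure(list(stages = data.frame(stage = character(), parameter = character(),
                                     removed = integer(), retained = integer())),
            class = "filter_report")
}

.report_add <- function(rep, stage, parameter, removed, retained) {
  rep$stages <- rbind(rep$stages,
                      data.frame(stage = stage, parameter = parameter,
                                 removed = as.integer(removed),
                                 retained = as.integer(retained)))
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Variant quality-control filter chain
#'
#' Applies, in fixed precedence, (1) a per-variant missingness ceiling, (2) a
#' minor-allele-frequency floor, and (3) a Hardy-Weinberg equilibrium test
#' with Bonferroni correction over the number of variants actually tested.
#' HWE may be assessed on a designated sample subset (e.g. a multi-origin
#' subgroup) rather than the full cohort. A variant failing several criteria
#' is counted once, at the first failing stage.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minor-allele-frequency floor (variants with MAF strictly
#'   below are removed); default 0.01.
#' @param max_missing_rate maximum tolerated fraction of missing calls;
#'   default 0.2 (i.e. an 80% genotyping-rate floor).
#' @param hwe_alpha significance level for the HWE filter before Bonferroni
#'   correction; 0 disables the filter. Default 0.005.
#' @param hwe_test_samples sample ids on which HWE is assessed; default all.
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `filter_report`).
#' @export
filter_variants <- function(gm, maf_min = 0.01, max_missing_rate = 0.2,
                            hwe_alpha = 0.005, hwe_test_samples = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            max_missing_rate >= 0, max_missing_rate <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1)
  if (!is.null(hwe_test_samples) && !all(hwe_test_samples %in% gm$samples$id))
    stop("hwe_test_samples must be a subset of sample ids")
  rep <- .new_filter_report()
  m0 <- ncol(gm$calls)

  miss <- colMeans(is.na(gm$calls))
  keep <- miss <= max_missing_rate
  rep <- .report_add(rep, "missingness",
                     sprintf("max_missing_rate=%g", max_missing_rate),
                     sum(!keep), sum(keep))
  gm <- subset_genotypes(gm, variants = keep)

  mafs <- maf(gm)
  mafs[is.nan(mafs)] <- 0
  keep <- mafs >= maf_min
  rep <- .report_add(rep, "maf", sprintf("maf_min=%g", maf_min),
                     sum(!keep), sum(keep))
  gm <- subset_genotypes(gm, variants = keep)

  if (hwe_alpha > 0) {
    calls <- gm$calls
    if (!is.null(hwe_test_samples))
      calls <- calls[gm$samples$id %in% hwe_test_samples, , drop = FALSE]
    m_test <- ncol(calls)
    alpha <- hwe_alpha / m_test
    pv <- vapply(seq_len(m_test), function(j) {
      x <- calls[, j]; x <- x[!is.na(x)]
      if (!length(x)) return(1.0)
      hwe_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    }, 0)
    keep <- pv >= alpha
    rep <- .report_add(rep, "hwe",
                       sprintf("hwe_alpha=%g (bonferroni %g over %d)",
                               hwe_alpha, alpha, m_test),
                       sum(!keep), sum(keep))
    gm <- subset_genotypes(gm, variants = keep)
  } else {
    rep <- .report_add(rep, "hwe", "disabled", 0L, ncol(gm$calls))
  }
  if (ncol(gm$calls) == 0L)
    stop("no variants retained after filtering (started with ", m0, ")")
  list(genotypes = gm, report = rep)
}

#' Greedy sliding-window linkage-disequilibrium pruning
#'
#' PLINK `--indep-pairwise`-style pruning: in sliding windows of
#' `window_snps` variants advanced by `step_snps`, while any retained pair
#' has squared genotype correlation above `r2_max`, the later-positioned
#' member of the currently highest-r2 pair is removed. Windows never span
#' chromosomes. The result is deterministic.
#'
#' @param gm a [genotype_matrix()].
#' @param window_snps,step_snps window size and step in SNPs (defaults 50, 5).
#' @param r2_max maximum tolerated pairwise r-squared (default 0.5).
#' @return Integer indices (into `gm$variants`) of the variants kept.
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  stopifnot(window_snps > step_snps, step_snps >= 1)
  keep <- rep(TRUE, ncol(gm$calls))
  calls <- gm$calls
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    s <- 1L
    while (s <= length(idx)) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      win <- win[keep[win]]
      repeat {
        if (length(win) < 2L) break
        r2 <- suppressWarnings(
          stats::cor(calls[, win, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        mx <- max(r2)
        if (mx <= r2_max) break
        hit <- which(r2 == mx, arr.ind = TRUE)[1, ]
        drop <- win[max(hit)]   # later-positioned member of the pair
        keep[drop] <- FALSE
        win <- win[win != drop]
      }
      if (s + window_snps - 1L >= length(idx)) break
      s <- s + step_snps
    }
  }
  which(keep)
}

#' Merge two genotype datasets on shared variants
#'
#' Variant set is the intersection by (chromosome, position). Alleles are
#' reconciled: where `b`'s allele pair is `a`'s swapped, `b`'s calls are
#' recoded `2 - x`; strand-ambiguous variants (A/T, C/G) and variants whose
#' allele pairs cannot be reconciled are dropped and counted in the report.
#'
#' @param a,b two [genotype_matrix()] objects with disjoint sample ids.
#' @return list with `genotypes` (merged matrix, samples of `a` then `b`)
#'   and `report` (a `filter_report` itemising dropped variants).
#' @export
merge_genotypes <- function(a, b) {
  if (length(intersect(a$samples$id, b$samples$id)))
    stop("shared sample ids between datasets")
  key_a <- paste(a$variants$chrom, a$variants$pos)
  key_b <- paste(b$variants$chrom, b$variants$pos)
  ia <- which(key_a %in% key_b)
  if (!length(ia)) stop("no shared variants between datasets")
  ib <- match(key_a[ia], key_b)
  rep <- .new_filter_report()

  amb <- .is_strand_ambiguous(a$variants$a1[ia], a$variants$a2[ia])
  rep <- .report_add(rep, "strand_ambiguous", "A/T and C/G dropped",
                     sum(amb), sum(!amb))
  ia <- ia[!amb]; ib <- ib[!amb]

  same <- a$variants$a1[ia] == b$variants$a1[ib] &
          a$variants$a2[ia] == b$variants$a2[ib]
  swap <- a$variants$a1[ia] == b$variants$a2[ib] &
          a$variants$a2[ia] == b$variants$a1[ib] & !same
  ok <- same | swap
  rep <- .report_add(rep, "allele_mismatch", "unreconcilable pairs dropped",
                     sum(!ok), sum(ok))
  ia <- ia[ok]; ib <- ib[ok]; swap <- swap[ok]
  if (!length(ia)) stop("no shared variants after allele reconciliation")

  cb <- b$calls[, ib, drop = FALSE]
  if (any(swap)) cb[, swap] <- 2L - cb[, swap]
  calls <- rbind(a$calls[, ia, drop = FALSE], cb)
  samples <- merge_sample_tables(a$samples, b$samples)
  list(genotypes = genotype_matrix(calls, a$variants[ia, , drop = FALSE],
                                   samples),
       report = rep)
}

merge_sample_tables <- function(sa, sb) {
  cols <- union(names(sa), names(sb))
  for (cl in setdiff(cols, names(sa))) sa[[cl]] <- NA
  for (cl in setdiff(cols, names(sb))) sb[[cl]] <- NA
  rbind(sa[cols], sb[cols])
}

.is_strand_ambiguous <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "CG", "GC")
}
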