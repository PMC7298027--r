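#' Reference-panel allele frequencies for ancestry assignment
#'
#' Per-group, per-variant alternate-allele frequencies from phased reference
#' panels, shrunk by one pseudo-allele of each type
#' (\eqn{(k + 1)/(n + 2)}) so that no frequency is exactly 0 or 1 and window
#' log-likelihoods stay finite.
#'
#' @param haps_by_group named list of [haplotype_matrix()] panels over the
#'   same variant set; each panel needs at least 10 haplotypes.
#' @return matrix of frequencies, groups in rows, variants in columns, with
#'   the variant table attached as attribute `variants`.
#' @export
reference_freqs <- function(haps_by_group) {
  stopifnot(is.list(haps_by_group), length(haps_by_group) >= 2,
            !is.null(names(haps_by_group)))
  va <- haps_by_group[[1]]$variants
  out <- matrix(NA_real_, length(haps_by_group), nrow(va),
                dimnames = list(names(haps_by_group), va$id))
  for (g in names(haps_by_group)) {
    h <- haps_by_group[[g]]
    if (nrow(h$alleles) < 10L)
      stop("reference group '", g, "' has fewer than 10 haplotypes")
    if (nrow(h$variants) != nrow(va) || any(h$variants$pos != va$pos))
      stop("reference panels must share one variant set")
    out[g, ] <- (colSums(h$alleles) + 1) / (nrow(h$alleles) + 2)
  }
  attr(out, "variants") <- va
  out
}

#' Window-based local ancestry assignment
#'
#' A window-independent naive-Bayes classifier honouring a hard posterior
#' contract: each non-overlapping window of `window_snps` SNPs on a query
#' haplotype gets a per-group log-likelihood
#' \eqn{\sum_j \log f_g(\mathrm{allele}_j)} from the reference frequencies,
#' a posterior by softmax under a uniform prior, and a label only if the top
#' posterior reaches `threshold`; otherwise the window is `unassigned`.
#' Consecutive same-label windows are merged into segments. Segment
#' boundaries tile the scanned span (first to last SNP), splitting between
#' adjacent windows at the midpoint of their edge SNPs.
#'
#' @param haps query [haplotype_matrix()] (all haplotypes are scanned).
#' @param ref_freqs output of [reference_freqs()] over the same variants.
#' @param window_snps SNPs per window (default 50); a trailing remainder of
#'   at least one SNP forms a final, shorter window.
#' @param threshold posterior needed to assign a label (default 0.99).
#' @return An object of class `ancestry_segments`: data.frame with columns
#'   `hap`, `sample`, `chrom`, `start`, `end`, `label`, `posterior`.
#' @export
assign_windows <- function(haps, ref_freqs, window_snps = 50,
                           threshold = 0.99) {
  va <- attr(ref_freqs, "variants")
  if (ncol(haps$alleles) != ncol(ref_freqs) ||
      any(haps$variants$pos != va$pos))
    stop("query variants do not match the reference table")
  groups <- rownames(ref_freqs)
  logf1 <- log(ref_freqs)
  logf0 <- log(1 - ref_freqs)
  segs <- list()
  for (ch in unique(va$chrom)) {
    sel <- which(va$chrom == ch)
    pos <- va$pos[sel]
    m <- length(sel)
    n_win <- max(1L, ceiling(m / window_snps))
    starts <- pmin((seq_len(n_win) - 1L) * window_snps + 1L, m)
    ends <- pmin(starts + window_snps - 1L, m)
    ok <- starts <= ends & starts <= m
    starts <- starts[ok]; ends <- ends[ok]
    # window bp bounds tiling [first SNP, last SNP]
    lo <- pos[starts]; hi <- pos[ends]
    bnd_lo <- c(lo[1], floor((hi[-length(hi)] + lo[-1]) / 2) + 1L)
    bnd_hi <- c(bnd_lo[-1] - 1L, hi[length(hi)])
    for (r in seq_len(nrow(haps$alleles))) {
      x <- haps$alleles[r, sel]
      lab <- character(length(starts))
      post <- numeric(length(starts))
      for (k in seq_along(starts)) {
        cols <- starts[k]:ends[k]
        ll <- logf1[, sel[cols], drop = FALSE] %*% x[cols] +
              logf0[, sel[cols], drop = FALSE] %*% (1 - x[cols])
        ll <- drop(ll)
        pp <- exp(ll - max(ll)); pp <- pp / sum(pp)
        top <- which.max(pp)
        post[k] <- pp[top]
        lab[k] <- if (pp[top] >= threshold) groups[top] else "unassigned"
      }
      # merge consecutive same-label windows
      r_rle <- rle(lab)
      e_idx <- cumsum(r_rle$lengths)
      s_idx <- e_idx - r_rle$lengths + 1L
      segs[[length(segs) + 1L]] <- data.frame(
        hap = rownames(haps$alleles)[r],
        sample = haps$hap_sample[r],
        chrom = ch,
        start = bnd_lo[s_idx],
        end = bnd_hi[e_idx],
        label = r_rle$values,
        posterior = vapply(seq_along(s_idx), function(q)
          min(post[s_idx[q]:e_idx[q]]), 0))
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  structure(out, threshold = threshold, groups = groups,
            window_snps = as.integer(window_snps),
            class = c("ancestry_segments", "data.frame"))
}

#' Per-sample ancestry fractions
#'
#' Base-pair-weighted fraction of the scanned genome assigned to each
#' reference label (and `unassigned`), pooling each sample's two haplotypes.
#' Fractions sum to 1 per sample.
#'
#' @param segments an `ancestry_segments` object.
#' @return data.frame: one row per sample, one column per label plus
#'   `unassigned`.
#' @export
ancestry_fractions <- function(segments) {
  labs <- unique(c(attr(segments, "groups"), "unassigned"))
  samples <- unique(segments$sample)
  bp <- segments$end - segments$start + 1
  out <- matrix(0, length(samples), length(labs),
                dimnames = list(samples, labs))
  agg <- stats::aggregate(bp, by = list(sample = segments$sample,
                                        label = segments$label), FUN = sum)
  for (k in seq_len(nrow(agg)))
    out[agg$sample[k], agg$label[k]] <- agg$x[k]
  out <- out / rowSums(out)
  data.frame(sample = samples, out, row.names = NULL, check.names = FALSE)
}
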