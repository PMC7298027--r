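#' Per-individual heterozygosity and method-of-moments inbreeding
#'
#' PLINK `--het`-style estimates: for each sample, observed heterozygosity
#' Ho over its non-missing calls, the observed homozygous count O(hom), the
#' expected homozygous count under random mating
#' \eqn{E(hom) = \sum_j [1 - 2 p_j (1-p_j) n_j/(n_j-1)]} (sample allele
#' frequency \eqn{p_j}, allele count \eqn{n_j}), and the moment inbreeding
#' coefficient \eqn{F = (O - E) / (L - E)}.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @param freq_samples optional sample ids used to estimate allele
#'   frequencies (default: all samples).
#' @return data.frame, one row per sample: `id`, `n_nonmissing`, `o_hom`,
#'   `e_hom`, `ho`, `f`.
#' @export
individual_heterozygosity <- function(gm, freq_samples = NULL) {
  if (nrow(gm$calls) < 2L) stop("need >= 2 samples to estimate frequencies")
  p <- allele_freqs(gm, freq_samples)
  nall <- 2L * colSums(!is.na(
    if (is.null(freq_samples)) gm$calls
    else gm$calls[gm$samples$id %in% freq_samples, , drop = FALSE]))
  ehom_j <- ifelse(nall > 1, 1 - 2 * p * (1 - p) * nall / (nall - 1), NA_real_)
  calls <- gm$calls
  nm <- !is.na(calls)
  if (any(rowSums(nm) == 0L))
    stop("sample with zero non-missing calls: ",
         paste(gm$samples$id[rowSums(nm) == 0L], collapse = ", "))
  hom <- !is.na(calls) & calls != 1L
  o_hom <- rowSums(hom)
  L <- rowSums(nm)
  e_hom <- as.vector(nm %*% ifelse(is.na(ehom_j), 0, ehom_j))
  ho <- 1 - o_hom / L
  f <- ifelse(abs(L - e_hom) > 0, (o_hom - e_hom) / (L - e_hom), NA_real_)
  data.frame(id = gm$samples$id, n_nonmissing = L, o_hom = o_hom,
             e_hom = e_hom, ho = ho, f = f, row.names = NULL)
}

#' Fhat3 inbreeding coefficient
#'
#' PLINK `--ibc` Fhat3: per sample the mean over polymorphic, non-missing
#' variants of \eqn{[x^2 - (1+2p)x + 2p^2] / (2p(1-p))} with genotype
#' \eqn{x \in \{0,1,2\}} and allele frequency \eqn{p}.
#'
#' @inheritParams individual_heterozygosity
#' @return Named numeric vector of per-sample Fhat3 values.
#' @export
fhat3 <- function(gm, freq_samples = NULL) {
  p <- allele_freqs(gm, freq_samples)
  poly <- !is.nan(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic variants")
  p <- p[poly]
  calls <- gm$calls[, poly, drop = FALSE]
  denom <- 2 * p * (1 - p)
  out <- vapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    ok <- !is.na(x)
    if (!any(ok)) stop("sample with zero usable calls: ", gm$samples$id[i])
    mean((x[ok]^2 - (1 + 2 * p[ok]) * x[ok] + 2 * p[ok]^2) / denom[ok])
  }, 0)
  names(out) <- gm$samples$id
  out
}

#' Per-group diversity with pairwise Tukey-Kramer comparisons
#'
#' Summarises mean observed heterozygosity, expected heterozygosity (from
#' within-group allele frequencies, with the \eqn{n/(n-1)} small-sample
#' correction), and mean inbreeding F per group, then compares per-sample Ho
#' across groups with Levene's test (equality of variances) followed by
#' Tukey-Kramer pairwise tests on group means.
#'
#' @param gm a [genotype_matrix()].
#' @param group_labels character vector of group labels, one per sample
#'   (or the name of a sample-table column: `"breed"`, `"lineage"`, `"use"`).
#' @return list with `summary` (per-group table), `pairwise` (Tukey-Kramer
#'   p-values), and `levene` (statistic and p-value). Groups of size < 2 are
#'   excluded with a warning.
#' @export
group_diversity <- function(gm, group_labels) {
  if (length(group_labels) == 1L && group_labels %in% names(gm$samples))
    group_labels <- gm$samples[[group_labels]]
  stopifnot(length(group_labels) == nrow(gm$calls))
  group_labels <- as.character(group_labels)
  sizes <- table(group_labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups of size < 2: ", paste(small, collapse = ", "))
    keepers <- !(group_labels %in% small) & !is.na(group_labels)
    gm <- subset_genotypes(gm, samples = keepers)
    group_labels <- group_labels[keepers]
  }
  het <- individual_heterozygosity(gm)
  groups <- sort(unique(group_labels))
  summ <- do.call(rbind, lapply(groups, function(g) {
    idx <- group_labels == g
    sub <- subset_genotypes(gm, samples = idx)
    p <- allele_freqs(sub)
    nall <- 2L * colSums(!is.na(sub$calls))
    he_j <- 2 * p * (1 - p) * nall / pmax(nall - 1, 1)
    data.frame(group = g, n = sum(idx),
               mean_ho = mean(het$ho[idx]),
               he = mean(he_j[!is.nan(he_j)]),
               mean_f = mean(het$f[idx], na.rm = TRUE))
  }))
  if (length(groups) < 2L)
    return(list(summary = summ, pairwise = NULL, levene = NULL))
  list(summary = summ,
       pairwise = tukey_kramer(het$ho, group_labels),
       levene = levene_test(het$ho, group_labels))
}

#' Tukey-Kramer pairwise comparison of group means
#'
#' Studentized-range test for all group pairs with unequal sample sizes:
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{(s^2/2)(1/n_i + 1/n_j)}} against
#' the studentized range distribution with k groups and N - k df.
#'
#' @param y numeric response (e.g. per-sample Ho).
#' @param g group labels.
#' @return data.frame with columns `group1`, `group2`, `diff`, `q`, `p`.
#' @export
tukey_kramer <- function(y, g) {
  g <- as.character(g)
  groups <- sort(unique(g))
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  ns <- vapply(groups, function(gr) sum(g == gr), 0L)
  ms <- vapply(groups, function(gr) mean(y[g == gr]), 0)
  df <- length(y) - k
  s2 <- sum(vapply(groups, function(gr) sum((y[g == gr] - ms[gr])^2), 0)) / df
  pairs <- utils::combn(groups, 2)
  out <- vapply(seq_len(ncol(pairs)), function(cc) {
    i <- pairs[1, cc]; j <- pairs[2, cc]
    se <- sqrt((s2 / 2) * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(ms[[i]] - ms[[j]]) / se
    c(ms[[i]] - ms[[j]], q,
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  }, numeric(3))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             diff = out[1, ], q = out[2, ], p = out[3, ],
             row.names = NULL)
}

#' Levene's test for equality of group variances
#'
#' Classic (mean-centred) Levene: one-way ANOVA on absolute deviations from
#' group means.
#'
#' @inheritParams tukey_kramer
#' @return list with `statistic` (F), `df`, and `p`.
#' @export
levene_test <- function(y, g) {
  g <- as.character(g)
  groups <- unique(g)
  k <- length(groups)
  z <- abs(y - stats::ave(y, g, FUN = mean))
  n <- length(y)
  zbar <- mean(z)
  zg <- vapply(groups, function(gr) mean(z[g == gr]), 0)
  ng <- vapply(groups, function(gr) sum(g == gr), 0L)
  num <- sum(ng * (zg - zbar)^2) / (k - 1)
  den <- sum((z - stats::ave(z, g, FUN = mean))^2) / (n - k)
  f <- num / den
  list(statistic = f, df = c(k - 1, n - k),
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Pairwise identity-by-descent relatedness (PI_HAT)
#'
#' PLINK `--genome`-style method-of-moments estimation: per pair, observed
#' genome-wide identity-by-state counts are compared with their expectations
#' given allele frequencies to estimate P(IBD=0,1,2); probabilities are
#' clamped to [0,1] and renormalised, and
#' \eqn{\hat\pi = P(IBD{=}1)/2 + P(IBD{=}2)}.
#'
#' @param gm a [genotype_matrix()].
#' @param freq_samples optional sample ids for the frequency panel
#'   (default all samples).
#' @return Symmetric matrix of PI_HAT values with unit diagonal, sample ids
#'   as dimnames; class `relatedness_matrix`.
#' @export
pairwise_ibd <- function(gm, freq_samples = NULL) {
  p <- allele_freqs(gm, freq_samples)
  poly <- !is.nan(p) & p > 0 & p < 1
  p <- p[poly]
  q <- 1 - p
  calls <- gm$calls[, poly, drop = FALSE]
  # per-variant IBS expectations given IBD state
  e0_0 <- 2 * p^2 * q^2                      # P(IBS0 | IBD0)
  e1_0 <- 4 * p^3 * q + 4 * p * q^3          # P(IBS1 | IBD0)
  e2_0 <- p^4 + q^4 + 4 * p^2 * q^2          # P(IBS2 | IBD0)
  e1_1 <- 2 * p^2 * q + 2 * p * q^2          # P(IBS1 | IBD1)
  e2_1 <- p^2 + q^2                          # P(IBS2 | IBD1)
  n <- nrow(calls)
  out <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    xi <- calls[i, ]
    for (j in (i + 1L):n) {
      xj <- calls[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      if (!any(ok)) stop("pair with no jointly genotyped variants: ",
                         gm$samples$id[i], " / ", gm$samples$id[j])
      d <- abs(xi[ok] - xj[ok])
      ibs0 <- sum(d == 2L)        # opposite homozygotes
      ibs2 <- sum(d == 0L)        # identical genotypes (incl. double het)
      ibs1 <- sum(d == 1L)
      M <- sum(ok)
      P0 <- ibs0 / sum(e0_0[ok])
      P1 <- (ibs1 - P0 * sum(e1_0[ok])) / sum(e1_1[ok])
      P2 <- (ibs2 - P0 * sum(e2_0[ok]) - P1 * sum(e2_1[ok])) / M
      pr <- pmin(pmax(c(P0, P1, P2), 0), 1)
      pr <- pr / sum(pr)
      out[i, j] <- out[j, i] <- pr[2] / 2 + pr[3]
    }
  }
  dimnames(out) <- list(gm$samples$id, gm$samples$id)
  class(out) <- c("relatedness_matrix", class(out))
  out
}

#' Greedy relatedness filtering
#'
#' Repeatedly drops the sample participating in the most pairs with
#' PI_HAT at or above `ibd_max` (ties broken toward the later sample in
#' input order) until no such pair remains. Deterministic.
#'
#' @param rel square symmetric relatedness matrix (e.g. [pairwise_ibd()]).
#' @param ibd_max relatedness ceiling; default 0.25.
#' @return Character vector of retained sample ids (input order).
#' @export
relatedness_filter <- function(rel, ibd_max = 0.25) {
  rel <- unclass(rel)
  stopifnot(is.matrix(rel), nrow(rel) == ncol(rel),
            isTRUE(all.equal(rel, t(rel), tolerance = 1e-8)))
  ids <- rownames(rel)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rel)))
  adj <- rel >= ibd_max
  diag(adj) <- FALSE
  alive <- rep(TRUE, nrow(rel))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    drop <- max(which(deg == max(deg)))   # tie: later sample order
    alive[drop] <- FALSE
  }
  ids[alive]
}

#' Fhat3-based inbreeding outlier threshold
#'
#' The exclusion threshold used for cohort-level inbreeding filtering:
#' mean + `sd_mult` standard deviations of the cohort's Fhat3 values.
#'
#' @param fhat3_values numeric vector of per-sample Fhat3.
#' @param sd_mult number of standard deviations above the mean (default 2).
#' @return list with `threshold` and the ids/indices of samples exceeding it.
#' @export
fhat3_outliers <- function(fhat3_values, sd_mult = 2) {
  thr <- mean(fhat3_values) + sd_mult * stats::sd(fhat3_values)
  list(threshold = thr,
       outliers = names(fhat3_values)[fhat3_values > thr])
}
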