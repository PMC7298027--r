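#' Multi-locus Weir-Cockerham F_ST between two populations
#'
#' The Weir & Cockerham (1984) theta estimator: per-variant components
#' a (among populations), b (among individuals within populations) and
#' c (within individuals) are computed with missing-aware per-variant sample
#' sizes, and the multi-locus estimate is the ratio of sums
#' \eqn{\hat\theta = \sum_j a_j / \sum_j (a_j + b_j + c_j)} over polymorphic
#' variants.
#'
#' @param gm a [genotype_matrix()].
#' @param pop_labels character vector, one label per sample, taking exactly
#'   two values (or a sample-table column name).
#' @return The multi-locus theta (scalar).
#' @export
wc_fst <- function(gm, pop_labels) {
  if (length(pop_labels) == 1L && pop_labels %in% names(gm$samples))
    pop_labels <- gm$samples[[pop_labels]]
  pop_labels <- as.character(pop_labels)
  stopifnot(length(pop_labels) == nrow(gm$calls))
  pops <- sort(unique(pop_labels))
  if (length(pops) != 2L) stop("exactly 2 populations required")
  if (any(table(pop_labels) < 2L)) stop("each population needs >= 2 samples")
  comp <- .wc_components(gm$calls, pop_labels, pops)
  if (all(!comp$poly)) stop("no polymorphic variant")
  sum(comp$a[comp$poly]) / sum((comp$a + comp$b + comp$c)[comp$poly])
}

# Weir & Cockerham 1984 per-variant components for r = 2 populations.
.wc_components <- function(calls, pop_labels, pops) {
  r <- 2
  in1 <- pop_labels == pops[1]
  in2 <- pop_labels == pops[2]
  n1 <- colSums(!is.na(calls[in1, , drop = FALSE]))
  n2 <- colSums(!is.na(calls[in2, , drop = FALSE]))
  p1 <- colSums(calls[in1, , drop = FALSE], na.rm = TRUE) / (2 * n1)
  p2 <- colSums(calls[in2, , drop = FALSE], na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(calls[in1, , drop = FALSE] == 1L, na.rm = TRUE)
  h2 <- colMeans(calls[in2, , drop = FALSE] == 1L, na.rm = TRUE)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1 & nc > 0
  poly <- usable & pbar > 0 & pbar < 1
  a[!usable] <- b[!usable] <- c[!usable] <- 0
  list(a = a, b = b, c = c, poly = poly)
}

#' Permutation test for F_ST
#'
#' Sample labels are permuted over individuals; significance is
#' \eqn{p = (1 + \#\{\theta_{perm} \ge \theta_{obs}\}) / (1 + n_{perm})}.
#'
#' @inheritParams wc_fst
#' @param n_perm number of permutations (default 20000).
#' @param seed RNG seed.
#' @return list with `theta` (observed), `p` and `n_perm`.
#' @export
fst_permutation <- function(gm, pop_labels, n_perm = 20000, seed = NULL) {
  if (length(pop_labels) == 1L && pop_labels %in% names(gm$samples))
    pop_labels <- gm$samples[[pop_labels]]
  pop_labels <- as.character(pop_labels)
  theta <- wc_fst(gm, pop_labels)
  if (!is.null(seed)) set.seed(seed)
  pops <- sort(unique(pop_labels))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(pop_labels)
    comp <- .wc_components(gm$calls, perm, pops)
    tp <- if (any(comp$poly))
      sum(comp$a[comp$poly]) / sum((comp$a + comp$b + comp$c)[comp$poly])
    else -Inf
    if (tp >= theta) exceed <- exceed + 1L
  }
  list(theta = theta, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Four-level hierarchical AMOVA
#'
#' Allele-level analysis of molecular variance in the Excoffier et al. (1992)
#' nested design extended to diploid data: variance is decomposed among
#' groups (sigma2_a), among populations within groups (sigma2_b), among
#' individuals within populations (sigma2_c) and within individuals
#' (sigma2_d), from nested sums of squares of per-variant allele indicators
#' summed over variants. Phi statistics and per-level permutation p-values
#' accompany the components.
#'
#' Permutation schemes per level: alleles among individuals within
#' populations (tests Phi_IS), individuals among populations within groups
#' (tests Phi_SC), whole populations among groups (tests Phi_CT). P-values
#' carry the +1 correction and are never exactly zero.
#'
#' Variants with missing calls are excluded (the decomposition requires a
#' single complete design).
#'
#' @param gm a [genotype_matrix()].
#' @param hierarchy data.frame with columns `sample`, `population`, `group`
#'   covering every sample (see [read_hierarchy()]).
#' @param n_perm permutations per level (default 20000); 0 skips testing.
#' @param seed RNG seed.
#' @return An object of class `amova_result`: variance components,
#'   percentages, Phi statistics, permutation p-values, df table.
#' @export
amova <- function(gm, hierarchy, n_perm = 20000, seed = NULL) {
  stopifnot(all(c("sample", "population", "group") %in% names(hierarchy)))
  m <- match(gm$samples$id, hierarchy$sample)
  if (anyNA(m)) stop("hierarchy missing samples: ",
                     paste(gm$samples$id[is.na(m)], collapse = ", "))
  pop <- hierarchy$population[m]
  grp <- hierarchy$group[m]
  pg <- unique(data.frame(pop, grp))
  if (anyDuplicated(pg$pop)) stop("a population maps to more than one group")
  if (length(unique(grp)) < 2L) stop("need >= 2 groups")
  if (any(table(pop) < 2L)) stop("each population needs >= 2 individuals")

  complete <- colSums(is.na(gm$calls)) == 0L
  if (!all(complete)) {
    message("amova: excluding ", sum(!complete), " variants with missing calls")
    gm <- subset_genotypes(gm, variants = complete)
  }
  if (ncol(gm$calls) == 0L) stop("no complete variants for AMOVA")

  obs <- .amova_fit(gm$calls, pop, grp)
  pvals <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_is = NA_real_)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(gm$calls)
    ex <- c(ct = 0L, sc = 0L, is = 0L)
    # level a: permute whole populations among groups
    pops_u <- unique(pop)
    grp_of_pop <- pg$grp[match(pops_u, pg$pop)]
    for (b in seq_len(n_perm)) {
      g_perm <- sample(grp_of_pop)
      fit <- .amova_fit(gm$calls, pop, g_perm[match(pop, pops_u)])
      if (fit$phi["phi_ct"] >= obs$phi["phi_ct"]) ex["ct"] <- ex["ct"] + 1L
    }
    # level b: permute individuals among populations within groups
    for (b in seq_len(n_perm)) {
      pop_perm <- pop
      for (g in unique(grp)) {
        idx <- which(grp == g)
        pop_perm[idx] <- pop[sample(idx)]
      }
      fit <- .amova_fit(gm$calls, pop_perm, grp)
      if (fit$phi["phi_sc"] >= obs$phi["phi_sc"]) ex["sc"] <- ex["sc"] + 1L
    }
    # level c/d: permute alleles among individuals within populations
    hapA <- .pseudo_haplotypes(gm$calls)
    for (b in seq_len(n_perm)) {
      perm_calls <- .permute_alleles_within_pops(hapA, pop)
      fit <- .amova_fit(perm_calls, pop, grp)
      if (fit$phi["phi_is"] >= obs$phi["phi_is"]) ex["is"] <- ex["is"] + 1L
    }
    pvals <- c(phi_ct = (1 + ex[["ct"]]) / (1 + n_perm),
               phi_sc = (1 + ex[["sc"]]) / (1 + n_perm),
               phi_is = (1 + ex[["is"]]) / (1 + n_perm))
  }
  structure(c(obs, list(p_values = pvals, n_perm = n_perm,
                        levels = c("among groups",
                                   "among populations within groups",
                                   "among individuals within populations",
                                   "within individuals"))),
            class = "amova_result")
}

# Split diploid dosages into two allele indicator matrices. Unphased split:
# hets contribute one 0 and one 1 (which physical haplotype is irrelevant to
# the allele-level sums of squares).
.pseudo_haplotypes <- function(calls) {
  h1 <- (calls == 2L) + (calls == 1L) * 1L
  h2 <- (calls == 2L) * 1L
  list(h1 = h1, h2 = h2)
}

.permute_alleles_within_pops <- function(haps, pop) {
  n <- nrow(haps$h1)
  out <- matrix(0L, n, ncol(haps$h1))
  for (pp in unique(pop)) {
    idx <- which(pop == pp)
    # pool the 2*length(idx) allele rows, reassign in pairs
    allele_rows <- rbind(haps$h1[idx, , drop = FALSE],
                         haps$h2[idx, , drop = FALSE])
    perm <- sample(nrow(allele_rows))
    k <- length(idx)
    out[idx, ] <- allele_rows[perm[seq_len(k)], , drop = FALSE] +
                  allele_rows[perm[k + seq_len(k)], , drop = FALSE]
  }
  out
}

# Core nested sums-of-squares decomposition on allele indicators.
# Strata: group > population > individual > allele copy, complete data,
# exactly two allele copies per individual.
.amova_fit <- function(calls, pop, grp) {
  n <- nrow(calls)
  pops_u <- unique(pop); P <- length(pops_u)
  grps_u <- unique(grp); G <- length(grps_u)
  M <- 2 * n
  pop_of <- match(pop, pops_u)                     # per individual
  grp_of <- match(grp, grps_u)                     # per individual
  grp_of_pop <- grp_of[match(pops_u, pop)]         # per population
  pop_n <- tabulate(pop_of, P)
  grp_n <- tabulate(grp_of, G)

  ind_mean <- calls / 2                            # n x m
  tot_mean <- colMeans(calls) / 2                  # m
  pop_mean <- rowsum(calls, pop_of) / (2 * pop_n)  # P x m
  grp_mean <- rowsum(calls, grp_of) / (2 * grp_n)  # G x m

  # within individuals: sum over the two 0/1 allele copies of (y - mean)^2;
  # a heterozygote contributes 2 * 0.25 per variant, homozygotes 0
  ss_d <- sum(calls == 1L) * 0.5
  ss_c <- 2 * sum((ind_mean - pop_mean[pop_of, , drop = FALSE])^2)
  ss_b <- sum((2 * pop_n) *
                (pop_mean - grp_mean[grp_of_pop, , drop = FALSE])^2)
  ss_a <- sum((2 * grp_n) * sweep(grp_mean, 2, tot_mean)^2)

  df_a <- G - 1; df_b <- P - G; df_c <- n - P; df_d <- n
  ms_a <- ss_a / df_a
  ms_b <- if (df_b > 0) ss_b / df_b else 0
  ms_c <- ss_c / df_c
  ms_d <- ss_d / df_d

  m_pop <- 2 * pop_n                 # allele copies per population
  m_grp <- 2 * grp_n                 # allele copies per group
  sum_pop2_by_grp <- sum(tapply(m_pop^2, grp_of_pop, sum) / m_grp)
  # nested-ANOVA expected-mean-square coefficients (2 copies per individual)
  n_b <- if (df_b > 0) (M - sum_pop2_by_grp) / df_b else NA_real_
  n_b2 <- (sum_pop2_by_grp - sum(m_pop^2) / M) / df_a
  n_a <- (M - sum(m_grp^2) / M) / df_a

  s_d <- ms_d
  s_c <- (ms_c - s_d) / 2
  s_b <- if (df_b > 0) (ms_b - s_d - 2 * s_c) / n_b else 0
  s_a <- (ms_a - s_d - 2 * s_c - n_b2 * s_b) / n_a
  comp <- c(sigma2_a = s_a, sigma2_b = s_b, sigma2_c = s_c, sigma2_d = s_d)
  total <- sum(comp)
  phi <- c(phi_ct = s_a / total,
           phi_sc = s_b / (s_b + s_c + s_d),
           phi_is = s_c / (s_c + s_d),
           phi_it = (s_a + s_b + s_c) / total)
  list(ss = c(a = ss_a, b = ss_b, c = ss_c, d = ss_d),
       df = c(a = df_a, b = df_b, c = df_c, d = df_d),
       components = comp,
       percent = 100 * comp / total,
       phi = phi,
       degenerate = c(b = df_b == 0))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA\n")
  tab <- data.frame(level = x$levels,
                    df = unname(x$df),
                    SS = unname(x$ss),
                    sigma2 = unname(x$components),
                    percent = unname(x$percent))
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("Phi_CT=%.4f Phi_SC=%.4f Phi_IS=%.4f Phi_IT=%.4f\n",
              x$phi["phi_ct"], x$phi["phi_sc"], x$phi["phi_is"],
              x$phi["phi_it"]))
  if (!all(is.na(x$p_values)))
    cat(sprintf("permutation p (n=%d): CT=%.4g SC=%.4g IS=%.4g\n",
                x$n_perm, x$p_values["phi_ct"], x$p_values["phi_sc"],
                x$p_values["phi_is"]))
  invisible(x)
}
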