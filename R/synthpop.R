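#' Balding-Nichols per-population allele frequencies
#'
#' Around a global frequency p, each population's frequency is an
#' independent draw from Beta(p(1-F)/F, (1-p)(1-F)/F), so that the expected
#' among-population variance is F p(1-p) — the standard generator of
#' population structure at a target differentiation level. F = 0 copies the
#' global frequency exactly.
#'
#' @param n_variants number of variants.
#' @param F per-population differentiation, scalar or length `n_pops`,
#'   each in [0, 1).
#' @param n_pops number of populations.
#' @param p_global optional vector of global frequencies; by default drawn
#'   Uniform(0.05, 0.95).
#' @param seed RNG seed.
#' @return matrix (n_pops x n_variants) of frequencies, with `p_global`
#'   attached as an attribute.
#' @export
bn_frequencies <- function(n_variants, F, n_pops = length(F),
                           p_global = NULL, seed = NULL) {
  F <- rep_len(F, n_pops)
  if (any(F < 0) || any(F >= 1)) stop("F must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p_global)) p_global <- stats::runif(n_variants, 0.05, 0.95)
  stopifnot(length(p_global) == n_variants)
  out <- matrix(NA_real_, n_pops, n_variants)
  for (k in seq_len(n_pops)) {
    if (F[k] == 0) {
      out[k, ] <- p_global
    } else {
      shape <- (1 - F[k]) / F[k]
      out[k, ] <- stats::rbeta(n_variants, p_global * shape,
                               (1 - p_global) * shape)
    }
  }
  attr(out, "p_global") <- p_global
  out
}

#' Evenly spread variant positions with jitter
#' @param n_variants number of positions.
#' @param chrom_length chromosome length in bp.
#' @param seed RNG seed.
#' @return strictly increasing integer positions in [1, chrom_length].
#' @export
make_positions <- function(n_variants, chrom_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  step <- chrom_length / n_variants
  pos <- round((seq_len(n_variants) - 0.5) * step +
                 stats::runif(n_variants, -0.4, 0.4) * step)
  pos <- sort(as.integer(pmin(pmax(pos, 1), chrom_length)))
  while (any(dup <- diff(pos) <= 0))           # enforce strict increase
    pos[which(dup)[1] + 1L] <- pos[which(dup)[1]] + 1L
  pos
}

#' Draw independent haplotypes from allele frequencies
#'
#' Linkage-free panel mode: independent Bernoulli alleles per site per
#' haplotype.
#'
#' @param freqs per-variant alternate-allele frequencies.
#' @param n_haps number of haplotypes (2 per sample; must be even).
#' @param positions variant positions (default 10 kb spacing).
#' @param chrom chromosome id.
#' @param sample_prefix prefix for generated sample ids.
#' @param seed RNG seed.
#' @return A [haplotype_matrix()].
#' @export
draw_haplotypes <- function(freqs, n_haps, positions = NULL, chrom = "1",
                            sample_prefix = "S", seed = NULL) {
  stopifnot(all(freqs >= 0), all(freqs <= 1), n_haps %% 2 == 0)
  if (!is.null(seed)) set.seed(seed)
  m <- length(freqs)
  if (is.null(positions)) positions <- as.integer(seq_len(m) * 1e4)
  al <- matrix(stats::rbinom(n_haps * m, 1L, rep(freqs, each = n_haps)),
               n_haps, m)
  haplotype_matrix(al, paste0(sample_prefix, seq_len(n_haps / 2)),
                   data.frame(chrom = chrom, pos = positions,
                              id = paste0(chrom, ":", positions),
                              a1 = "A", a2 = "T"))
}

#' Simulate admixed haplotypes as reference-panel mosaics
#'
#' Each admixed haplotype is a mosaic of tracts copied from reference
#' haplotypes: recombination breakpoints follow a Poisson process with rate
#' G x recombination rate along the chromosome (Morgans), each tract's
#' source population is drawn from `proportions`, and tract alleles are
#' copied verbatim from a uniformly chosen haplotype of that population's
#' panel. The realised tracts are recorded as truth.
#'
#' @param ref_haps_by_pop named list of [haplotype_matrix()] reference
#'   panels over one shared variant set (one chromosome).
#' @param proportions named numeric vector of admixture proportions
#'   (must sum to 1; names match the panels).
#' @param G generations since admixture (default 9).
#' @param recomb_rate_cM_per_Mb uniform recombination rate (default 1).
#' @param n_samples number of admixed diploid samples.
#' @param sample_prefix prefix for admixed sample ids.
#' @param seed RNG seed.
#' @return list with `haps` (admixed [haplotype_matrix()]) and `truth`
#'   (data.frame: hap, sample, chrom, start, end, source population,
#'   source haplotype row).
#' @export
simulate_admixed <- function(ref_haps_by_pop, proportions, G = 9,
                             recomb_rate_cM_per_Mb = 1, n_samples = 10,
                             sample_prefix = "ADM", seed = NULL) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9, G >= 1,
            all(names(proportions) %in% names(ref_haps_by_pop)))
  if (any(vapply(ref_haps_by_pop, function(h) nrow(h$alleles), 0L) == 0L))
    stop("empty reference panel")
  if (!is.null(seed)) set.seed(seed)
  va <- ref_haps_by_pop[[1]]$variants
  chrom <- unique(va$chrom)
  stopifnot(length(chrom) == 1L)
  L <- max(va$pos)
  first <- min(va$pos)
  morgans <- G * recomb_rate_cM_per_Mb * (L - first) / 1e6 / 100
  n_h <- 2L * n_samples
  al <- matrix(0L, n_h, nrow(va))
  truth <- list()
  pops <- names(proportions)
  for (r in seq_len(n_h)) {
    n_bp <- stats::rpois(1, morgans)
    bks <- sort(stats::runif(n_bp, first, L))
    lo <- c(first, ceiling(bks))
    hi <- c(ceiling(bks) - 1, L)
    keep <- lo <= hi
    lo <- lo[keep]; hi <- hi[keep]
    src_pop <- sample(pops, length(lo), replace = TRUE, prob = proportions)
    src_hap <- integer(length(lo))
    for (t in seq_along(lo)) {
      panel <- ref_haps_by_pop[[src_pop[t]]]
      src_hap[t] <- sample.int(nrow(panel$alleles), 1)
      cols <- which(va$pos >= lo[t] & va$pos <= hi[t])
      if (length(cols)) al[r, cols] <- panel$alleles[src_hap[t], cols]
    }
    truth[[r]] <- data.frame(
      hap = paste0(sample_prefix, (r + 1L) %/% 2L, "_h", 2L - (r %% 2L)),
      sample = paste0(sample_prefix, (r + 1L) %/% 2L),
      chrom = chrom, start = lo, end = hi,
      pop = src_pop, source_hap = src_hap)
  }
  haps <- haplotype_matrix(al, paste0(sample_prefix, seq_len(n_samples)), va)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(haps = haps, truth = truth)
}

#' Implant a hard selective sweep into a haplotype panel
#'
#' One donor haplotype is chosen; for each selected carrier, alleles within
#' [position - l_left, position + l_right] (l ~ independent
#' Exponential(mean_tract_bp)) are overwritten by the donor's — producing a
#' shared core haplotype with decaying extent, the classic hard-sweep
#' signature (elevated H and H12, depressed diversity).
#'
#' @param haps a [haplotype_matrix()] on one chromosome.
#' @param position sweep locus (bp, within the variant span).
#' @param carrier_fraction fraction of haplotypes carrying the sweep
#'   (floor(fraction x n) carriers; at least 2).
#' @param mean_tract_bp mean one-sided tract length (default 5e5).
#' @param seed RNG seed.
#' @return list with `haps` (modified matrix) and `truth` (donor row,
#'   carrier rows, per-carrier tract bounds).
#' @export
implant_sweep <- function(haps, position, carrier_fraction = 0.6,
                          mean_tract_bp = 5e5, seed = NULL) {
  va <- haps$variants
  stopifnot(length(unique(va$chrom)) == 1L,
            position >= min(va$pos), position <= max(va$pos),
            carrier_fraction > 0, carrier_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(haps$alleles)
  n_car <- floor(carrier_fraction * n)
  if (n_car < 2L) stop("carrier count < 2: no sweep signal possible")
  donor <- sample.int(n, 1)
  carriers <- sample.int(n, n_car)
  lo <- pmax(min(va$pos), position - stats::rexp(n_car, 1 / mean_tract_bp))
  hi <- pmin(max(va$pos), position + stats::rexp(n_car, 1 / mean_tract_bp))
  al <- haps$alleles
  for (k in seq_len(n_car)) {
    cols <- which(va$pos >= lo[k] & va$pos <= hi[k])
    if (length(cols)) al[carriers[k], cols] <- al[donor, cols]
  }
  out <- haplotype_matrix(al, haps$sample_ids, va)
  list(haps = out,
       truth = list(position = position, donor = donor, carriers = carriers,
                    tract_start = as.integer(floor(lo)),
                    tract_end = as.integer(ceiling(hi))))
}

#' Neutral site-frequency-spectrum haplotypes
#'
#' Independent sites whose derived-allele count i is drawn with probability
#' proportional to 1/i (i in 1..n-1), derived alleles placed on a uniform
#' random haplotype subset — the standard neutral calibration for Tajima's
#' D, under which E[pi] = E[theta_W] = 1/a1 per site.
#'
#' @param n_haps number of haplotypes (>= 4, even).
#' @param n_sites number of sites.
#' @param positions variant positions (default 1 kb spacing).
#' @param chrom chromosome id.
#' @param seed RNG seed.
#' @return A [haplotype_matrix()]; every site is polymorphic.
#' @export
neutral_sfs_sites <- function(n_haps, n_sites, positions = NULL,
                              chrom = "1", seed = NULL) {
  stopifnot(n_haps >= 4, n_haps %% 2 == 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- as.integer(seq_len(n_sites) * 1e3)
  i_prob <- 1 / seq_len(n_haps - 1)
  cnt <- sample.int(n_haps - 1, n_sites, replace = TRUE,
                    prob = i_prob / sum(i_prob))
  al <- matrix(0L, n_haps, n_sites)
  for (j in seq_len(n_sites))
    al[sample.int(n_haps, cnt[j]), j] <- 1L
  haplotype_matrix(al, paste0("N", seq_len(n_haps / 2)),
                   data.frame(chrom = chrom, pos = positions,
                              id = paste0(chrom, ":", positions),
                              a1 = "A", a2 = "T"))
}

#' Array-style minor-allele-frequency ascertainment
#'
#' Removes variants whose realised MAF is at or below `maf_min`, emulating
#' SNP chip site selection (an exclusive floor: a singleton among 100
#' haplotypes is dropped at `maf_min = 0.01`). `maf_min = 0` is the
#' identity. Positions are preserved.
#'
#' @param x a [genotype_matrix()] or [haplotype_matrix()].
#' @param maf_min MAF floor in [0, 0.5].
#' @return Same type as `x`.
#' @export
ascertain <- function(x, maf_min) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  if (inherits(x, "genotype_matrix")) {
    mafs <- maf(x)
  } else if (inherits(x, "haplotype_matrix")) {
    p <- colMeans(x$alleles)
    mafs <- pmin(p, 1 - p)
  } else stop("x must be a genotype_matrix or haplotype_matrix")
  keep <- if (maf_min == 0) rep(TRUE, length(mafs)) else mafs > maf_min
  keep[is.na(keep)] <- FALSE
  if (inherits(x, "genotype_matrix")) subset_genotypes(x, variants = keep)
  else subset_haplotypes(x, variants = keep)
}

#' Standard sweep-scan fixture
#'
#' One population of `n_haps` haplotypes over a 6 Mb chromosome with
#' `n_snps` array-like sites (global frequencies Uniform(0.05, 0.95)) and a
#' hard sweep implanted at mid-chromosome (carrier fraction 0.6, mean
#' one-sided tract 500 kb).
#'
#' @param seed RNG seed.
#' @param n_haps haplotypes (default 60).
#' @param n_snps sites (default 7020, i.e. 20 windows of 351).
#' @param chrom_length chromosome length (default 6e6).
#' @param sweep_pos sweep locus (default mid-chromosome).
#' @param carrier_fraction,mean_tract_bp sweep parameters (0.6, 5e5).
#' @return list: `haps`, `truth`, `sweep_pos`.
#' @export
sim_sweep_fixture <- function(seed, n_haps = 60, n_snps = 7020,
                              chrom_length = 6e6,
                              sweep_pos = chrom_length / 2,
                              carrier_fraction = 0.6, mean_tract_bp = 5e5) {
  set.seed(seed)
  pos <- make_positions(n_snps, chrom_length)
  freqs <- stats::runif(n_snps, 0.05, 0.95)
  base <- draw_haplotypes(freqs, n_haps, positions = pos, chrom = "1",
                          sample_prefix = "SW")
  sw <- implant_sweep(base, sweep_pos, carrier_fraction, mean_tract_bp)
  list(haps = sw$haps, truth = sw$truth, sweep_pos = sweep_pos)
}

#' Arabian-like end-to-end fixture
#'
#' Four reference populations under the Balding-Nichols model with
#' per-population F spanning roughly the 0.02-0.23 pairwise differentiation
#' range of strongly structured horse breeds, one admixed group (30% donor,
#' G = 9 generations), and one hard sweep at mid-chromosome in the recipient
#' population. Sites are array-ascertained at MAF 0.01. Group labels follow
#' the reference-group roles of a local-ancestry analysis: recipient
#' ("arabian"), donor ("thoroughbred"), a related outgroup ("turkemen") and
#' a diverged negative control ("icelandic").
#'
#' @param seed RNG seed.
#' @param n_variants sites before ascertainment (default 4000).
#' @param chrom_length chromosome length (default 5e7).
#' @param n_per_pop diploid samples per reference population (default 25).
#' @param n_admixed admixed diploid samples (default 10).
#' @param donor_prop donor admixture proportion (default 0.3).
#' @param G generations since admixture (default 9).
#' @return list: `ref_haps` (named list of panels), `admixed` (haps +
#'   truth), `sweep` (truth), `genotypes` (combined genotype_matrix with
#'   breed labels), `hierarchy` (sample/population/group table), `config`.
#' @export
sim_arabian_like <- function(seed, n_variants = 4000, chrom_length = 5e7,
                             n_per_pop = 25, n_admixed = 10,
                             donor_prop = 0.3, G = 9) {
  set.seed(seed)
  Fs <- c(arabian = 0.02, thoroughbred = 0.12, turkemen = 0.10,
          icelandic = 0.30)
  pos <- make_positions(n_variants, chrom_length)
  fr <- bn_frequencies(n_variants, F = unname(Fs), n_pops = 4)
  ref_haps <- list()
  for (k in seq_along(Fs))
    ref_haps[[names(Fs)[k]]] <-
      draw_haplotypes(fr[k, ], 2L * n_per_pop, positions = pos,
                      sample_prefix = paste0(toupper(substr(names(Fs)[k], 1, 2)), "_"))
  adm <- simulate_admixed(ref_haps[c("arabian", "thoroughbred")],
                          proportions = c(arabian = 1 - donor_prop,
                                          thoroughbred = donor_prop),
                          G = G, n_samples = n_admixed,
                          sample_prefix = "RACING")
  sw <- implant_sweep(ref_haps$arabian, position = chrom_length / 2,
                      carrier_fraction = 0.6, mean_tract_bp = 5e5)
  ref_haps$arabian <- sw$haps
  gms <- lapply(names(ref_haps), function(g) {
    gm <- haplotypes_to_genotypes(ref_haps[[g]])
    gm$samples$breed <- g
    gm
  })
  gm_adm <- haplotypes_to_genotypes(adm$haps)
  gm_adm$samples$breed <- "racing_arabian"
  calls <- do.call(rbind, c(lapply(gms, function(g) g$calls),
                            list(gm_adm$calls)))
  samples <- do.call(rbind, c(lapply(gms, function(g) g$samples),
                              list(gm_adm$samples)))
  gm <- genotype_matrix(calls, gms[[1]]$variants, samples)
  gm <- ascertain(gm, 0.01)
  hierarchy <- data.frame(
    sample = samples$id,
    population = samples$breed,
    group = ifelse(samples$breed %in% c("arabian", "racing_arabian"),
                   "arabian_lineages", "outgroups"))
  list(ref_haps = ref_haps, admixed = adm, sweep = sw$truth,
       genotypes = gm, hierarchy = hierarchy,
       config = list(seed = seed, F = Fs, n_variants = n_variants,
                     chrom_length = chrom_length, donor_prop = donor_prop,
                     G = G))
}
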