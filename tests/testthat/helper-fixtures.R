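# Fixture builders and independent oracles used across the suite.

rand_gm <- function(n, m, seed, miss_rate = 0, chrom = "1") {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  if (miss_rate > 0)
    calls[runif(n * m) < miss_rate] <- NA_integer_
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos = seq_len(m) * 100L,
                             id = paste0("v", seq_len(m)),
                             a1 = "A", a2 = "G"),
                  data.frame(id = paste0("s", seq_len(n))))
}

rand_haps <- function(n_haps, m, seed, chrom = "1", spacing = 1000L) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  al <- matrix(rbinom(n_haps * m, 1L, rep(p, each = n_haps)), n_haps, m)
  haplotype_matrix(al, paste0("s", seq_len(n_haps / 2)),
                   data.frame(chrom = chrom, pos = seq_len(m) * spacing,
                              id = paste0("v", seq_len(m)),
                              a1 = "A", a2 = "T"))
}

make_haps <- function(allele_rows, pos, chrom = "1") {
  al <- do.call(rbind, allele_rows)
  stopifnot(nrow(al) %% 2 == 0)
  haplotype_matrix(al, paste0("s", seq_len(nrow(al) / 2)),
                   data.frame(chrom = chrom, pos = as.integer(pos),
                              id = paste0("v", seq_along(pos)),
                              a1 = "A", a2 = "T"))
}

# Exhaustive O(n^2 m^2) H-scan oracle: literal tract-boundary definition.
oracle_h_scan <- function(al, pos) {
  n <- nrow(al); m <- ncol(al)
  vals <- numeric(m)
  for (x in seq_len(m)) {
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (al[i, x] != al[j, x]) next
      L <- pos[1]
      for (k in x:1) if (al[i, k] != al[j, k]) { L <- pos[k]; break }
      R <- pos[m]
      for (k in x:m) if (al[i, k] != al[j, k]) { R <- pos[k]; break }
      tot <- tot + (R - L)
    }
    vals[x] <- tot * 2 / (n * (n - 1))
  }
  vals
}

# Independent HWE evaluation from expected genotype counts.
oracle_hwe <- function(aa, ab, bb) {
  n <- aa + ab + bb
  p <- (ab + 2 * bb) / (2 * n)
  if (p <= 0 || p >= 1) return(1.0)
  e <- c(n * (1 - p)^2, 2 * n * p * (1 - p), n * p^2)
  stats::pchisq(sum((c(aa, ab, bb) - e)^2 / e), 1, lower.tail = FALSE)
}

# Quadratic greedy LD-pruning oracle over explicit window sweeps.
oracle_ld_prune <- function(calls, pos_order, window, step, r2_max) {
  m <- ncol(calls)
  keep <- rep(TRUE, m)
  s <- 1L
  repeat {
    win <- seq(s, min(s + window - 1L, m))
    repeat {
      act <- win[keep[win]]
      if (length(act) < 2L) break
      best <- c(0, NA, NA)
      for (a in seq_len(length(act) - 1L)) for (b in (a + 1L):length(act)) {
        r2 <- suppressWarnings(
          stats::cor(calls[, act[a]], calls[, act[b]],
                     use = "pairwise.complete.obs"))^2
        if (is.finite(r2) && r2 > best[1]) best <- c(r2, act[a], act[b])
      }
      if (best[1] <= r2_max) break
      keep[max(best[2:3])] <- FALSE
    }
    if (s + window - 1L >= m) break
    s <- s + step
  }
  which(keep)
}

# Exhaustive minimal-removal search for relatedness filtering (n <= 12).
oracle_min_removal <- function(adj) {
  n <- nrow(adj)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(pairs)) return(integer())
  for (k in 1:n) {
    cmb <- utils::combn(n, k)
    for (cc in seq_len(ncol(cmb))) {
      rm <- cmb[, cc]
      if (all(pairs[, 1] %in% rm | pairs[, 2] %in% rm)) return(rm)
    }
  }
  seq_len(n)
}

# All-pairs interval overlap oracle (1-based inclusive regions vs 0-based
# half-open features).
oracle_annotate <- function(regions, bed) {
  lapply(seq_len(nrow(regions)), function(i) {
    hits <- character()
    for (j in seq_len(nrow(bed))) {
      if (bed$chrom[j] != regions$chrom[i]) next
      if (bed$start[j] < regions$end[i] && bed$end[j] > regions$start[i] - 1)
        hits <- c(hits, bed$name[j])
    }
    hits
  })
}

tmp_path <- function(ext) tempfile(fileext = ext)
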