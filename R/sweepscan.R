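#' Construct a scan track
#'
#' Per-position values of one selection statistic for one sample group.
#' @param chrom chromosome ids (recycled if scalar).
#' @param pos evaluation positions (bp), strictly increasing per chromosome.
#' @param raw raw statistic values.
#' @param stat statistic name: `"H"`, `"H12"` or `"D"`.
#' @param group sample-group name.
#' @param window_snps window size in SNPs (NA for per-SNP statistics).
#' @param scaled optional 0-1 scaled values (see [scale_track()]).
#' @return An object of class `scan_track` (a data.frame with attributes).
#' @export
scan_track <- function(chrom, pos, raw, stat, group = "all",
                       window_snps = NA_integer_, scaled = NULL) {
  stopifnot(stat %in% c("H", "H12", "D"))
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   raw = as.numeric(raw))
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", ch)
  }
  if (!is.null(scaled)) df$scaled <- scaled
  structure(df, stat = stat, group = group,
            window_snps = as.integer(window_snps),
            class = c("scan_track", "data.frame"))
}

#' @export
print.scan_track <- function(x, ...) {
  cat(sprintf("scan_track: %s statistic, group '%s', %d positions%s\n",
              attr(x, "stat"), attr(x, "group"), nrow(x),
              if ("scaled" %in% names(x)) " (scaled)" else ""))
  invisible(x)
}

#' SNP-density pruning for window-based scans
#'
#' Tiles each chromosome into non-overlapping 0.1 Mb bins anchored at
#' position 1; any bin containing more than `max_per_bin` SNPs keeps exactly
#' `keep_per_bin`, chosen evenly spaced by rank within the bin (the bin's
#' first and last SNP are always kept). Idempotent and deterministic.
#'
#' @param positions sorted positions (bp) of one chromosome.
#' @param bin_bp bin width (default 1e5).
#' @param max_per_bin density trigger (default 16).
#' @param keep_per_bin SNPs retained in a dense bin (default 13).
#' @return Integer indices of retained positions.
#' @export
density_prune <- function(positions, bin_bp = 1e5, max_per_bin = 16,
                          keep_per_bin = 13) {
  if (is.unsorted(positions)) stop("positions must be sorted")
  bin <- (positions - 1) %/% bin_bp
  keep <- logical(length(positions))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    if (length(idx) > max_per_bin) {
      sel <- unique(round(seq(1, length(idx), length.out = keep_per_bin)))
      keep[idx[sel]] <- TRUE
    } else keep[idx] <- TRUE
  }
  which(keep)
}

#' H statistic: average pairwise haplotype homozygosity tract length
#'
#' At each SNP position x, \eqn{H(x) = \frac{2}{n(n-1)} \sum_{i<j}
#' \ell_{ij}(x)} where \eqn{\ell_{ij}(x)} is the base-pair length of the
#' homozygosity tract shared by haplotypes i and j around x: it runs from
#' the nearest SNP at or left of x where they differ (or the chromosome's
#' first SNP if none) to the nearest differing SNP at or right of x (or the
#' last SNP). If i and j differ at x itself the tract length is 0.
#'
#' @param haps a [haplotype_matrix()].
#' @param chromosome chromosome to scan (default: the only one present).
#' @param group group name recorded on the track.
#' @return A `scan_track` with one H value (bp) per SNP position.
#' @export
h_scan <- function(haps, chromosome = NULL, group = "all") {
  va <- haps$variants
  if (is.null(chromosome)) {
    chromosome <- unique(va$chrom)
    if (length(chromosome) > 1L)
      stop("multiple chromosomes present; pick one")
  }
  sel <- which(va$chrom == chromosome)
  if (length(sel) < 2L) stop("need >= 2 variants on chromosome ", chromosome)
  al <- haps$alleles[, sel, drop = FALSE]
  pos <- va$pos[sel]
  n <- nrow(al)
  if (n < 2L) stop("need >= 2 haplotypes")
  m <- length(pos)
  first <- pos[1]; last <- pos[m]
  acc <- numeric(m)
  focal <- seq_len(m)
  for (i in seq_len(n - 1L)) {
    xi <- al[i, ]
    for (j in (i + 1L):n) {
      mis <- which(xi != al[j, ])
      if (!length(mis)) {
        acc <- acc + (last - first)
        next
      }
      # nearest mismatch at or left / at or right of each focal SNP (by rank)
      li <- findInterval(focal, mis)               # last mismatch rank <= focal
      ri <- findInterval(focal - 1L, mis) + 1L     # first mismatch rank >= focal
      L <- ifelse(li >= 1L, pos[mis[pmax(li, 1L)]], first)
      R <- ifelse(ri <= length(mis), pos[mis[pmin(ri, length(mis))]], last)
      len <- R - L
      len[focal %in% mis] <- 0
      acc <- acc + len
    }
  }
  scan_track(chromosome, pos, acc * 2 / (n * (n - 1)), "H", group)
}

#' H12 haplotype-frequency-spectrum statistic in fixed-SNP windows
#'
#' Non-overlapping consecutive windows of `window_snps` SNPs (any trailing
#' remainder is dropped). Within a window, haplotypes are grouped by exact
#' allele-string identity into frequency classes \eqn{p_1 \ge p_2 \ge ...},
#' and \eqn{H12 = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2}. Values are reported
#' at the window's centre SNP position.
#'
#' @inheritParams h_scan
#' @param window_snps SNPs per window (default 351).
#' @return A `scan_track`; empty (with a warning) if the chromosome has
#'   fewer SNPs than one window.
#' @export
h12_windows <- function(haps, window_snps = 351, chromosome = NULL,
                        group = "all") {
  w <- .hap_windows(haps, chromosome, window_snps)
  if (!length(w$starts)) {
    warning("fewer SNPs than one window; empty track")
    return(scan_track(character(), integer(), numeric(), "H12", group,
                      window_snps))
  }
  vals <- vapply(seq_along(w$starts), function(k) {
    cols <- w$starts[k]:w$ends[k]
    key <- apply(w$al[, cols, drop = FALSE], 1, paste, collapse = "")
    p <- sort(tabulate(factor(key)) / length(key), decreasing = TRUE)
    if (length(p) == 1L) return(1)
    (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
  }, 0)
  scan_track(w$chromosome, w$center_pos, vals, "H12", group, window_snps)
}

#' Windowed variance-normalised Tajima's D
#'
#' Per window of `window_snps` SNPs with S segregating sites among n
#' haplotypes: \eqn{\pi} is the mean pairwise difference computed from
#' derived-allele counts, \eqn{\theta_W = S/a_1}, and
#' \eqn{D = (\pi - \theta_W)/\sqrt{e_1 S + e_2 S(S-1)}} with Tajima's (1989)
#' constants. Windows with S = 0 emit no value. Values are reported at the
#' window's centre SNP position.
#'
#' @inheritParams h12_windows
#' @return A `scan_track` of D values.
#' @export
tajimas_d_windows <- function(haps, window_snps = 351, chromosome = NULL,
                              group = "all") {
  n <- nrow(haps$alleles)
  if (n < 4L) stop("need >= 4 haplotypes")
  w <- .hap_windows(haps, chromosome, window_snps)
  if (!length(w$starts)) {
    warning("fewer SNPs than one window; empty track")
    return(scan_track(character(), integer(), numeric(), "D", group,
                      window_snps))
  }
  cst <- tajima_constants(n)
  keep <- logical(length(w$starts))
  vals <- numeric(length(w$starts))
  for (k in seq_along(w$starts)) {
    cols <- w$starts[k]:w$ends[k]
    cnt <- colSums(w$al[, cols, drop = FALSE])
    seg <- cnt > 0L & cnt < n
    S <- sum(seg)
    if (S == 0L) next
    pi_w <- sum(2 * cnt[seg] * (n - cnt[seg])) / (n * (n - 1))
    theta_w <- S / cst$a1
    vals[k] <- (pi_w - theta_w) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    keep[k] <- TRUE
  }
  scan_track(w$chromosome, w$center_pos[keep], vals[keep], "D",
             group, window_snps)
}

#' Tajima (1989) normalisation constants for n sequences
#' @param n number of haplotypes (>= 2).
#' @return list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.hap_windows <- function(haps, chromosome, window_snps) {
  va <- haps$variants
  if (is.null(chromosome)) {
    chromosome <- unique(va$chrom)
    if (length(chromosome) > 1L)
      stop("multiple chromosomes present; pick one")
  }
  sel <- which(va$chrom == chromosome)
  al <- haps$alleles[, sel, drop = FALSE]
  pos <- va$pos[sel]
  m <- length(pos)
  n_win <- m %/% window_snps
  if (n_win == 0L)
    return(list(al = al, starts = integer(), ends = integer(),
                center_pos = integer(), chromosome = chromosome))
  starts <- (seq_len(n_win) - 1L) * window_snps + 1L
  ends <- starts + window_snps - 1L
  centers <- starts + (window_snps - 1L) %/% 2L
  list(al = al, starts = starts, ends = ends, center_pos = pos[centers],
       chromosome = chromosome)
}

#' Scale a scan track to 0-1
#'
#' Min-max scaling over the whole track (genome-wide for one statistic and
#' one group). Tajima's D is negated ("reflected") first so that sweep-like
#' signals appear as peaks; H and H12 are scaled directly.
#'
#' @param track a `scan_track` with at least two distinct raw values.
#' @return The track with a `scaled` column added.
#' @export
scale_track <- function(track) {
  raw <- track$raw
  if (attr(track, "stat") == "D") raw <- -raw
  rng <- range(raw)
  if (diff(rng) == 0) stop("constant track cannot be scaled")
  track$scaled <- (raw - rng[1]) / (rng[2] - rng[1])
  track
}

#' Call peaks on a scaled scan track
#'
#' Thresholds at the given percentile of the track's scaled values; maximal
#' runs of consecutive evaluation positions at or above threshold become
#' intervals. Intervals closer than `merge_gap_bp` are merged; intervals
#' spanning more than `max_span_bp` are discarded (broad regions where the
#' signal is unspecific); single-position runs are widened to +/- half the
#' median inter-position spacing.
#'
#' @param track a scaled `scan_track` (see [scale_track()]).
#' @param percentile threshold percentile of scaled values (default 99).
#' @param max_span_bp broad-peak exclusion span (default 5e6).
#' @param merge_gap_bp merge distance for nearby peaks (default 1e5).
#' @return An object of class `peak_set`: data.frame (chrom, start, end,
#'   max_scaled) with attributes `stat`, `group`, `threshold`.
#' @export
call_peaks <- function(track, percentile = 99, max_span_bp = 5e6,
                       merge_gap_bp = 1e5) {
  if (!"scaled" %in% names(track)) stop("track must be scaled first")
  thr <- stats::quantile(track$scaled, percentile / 100, names = FALSE)
  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    above <- t$scaled >= thr
    if (!any(above)) next
    r <- rle(above)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    runs <- which(r$values)
    iv <- data.frame(start = t$pos[starts_idx[runs]],
                     end = t$pos[ends_idx[runs]],
                     max_scaled = vapply(runs, function(k)
                       max(t$scaled[starts_idx[k]:ends_idx[k]]), 0))
    half <- if (nrow(t) > 1) stats::median(diff(t$pos)) / 2 else 1
    deg <- iv$end == iv$start
    iv$start[deg] <- pmax(1, floor(iv$start[deg] - half))
    iv$end[deg] <- ceiling(iv$end[deg] + half)
    # merge intervals separated by < merge_gap_bp
    if (nrow(iv) > 1) {
      merged <- iv[1, ]
      for (k in 2:nrow(iv)) {
        if (iv$start[k] - merged$end[nrow(merged)] < merge_gap_bp) {
          merged$end[nrow(merged)] <- iv$end[k]
          merged$max_scaled[nrow(merged)] <-
            max(merged$max_scaled[nrow(merged)], iv$max_scaled[k])
        } else merged <- rbind(merged, iv[k, ])
      }
      iv <- merged
    }
    iv <- iv[iv$end - iv$start <= max_span_bp, , drop = FALSE]
    if (nrow(iv)) out[[ch]] <- data.frame(chrom = ch, iv)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               max_scaled = numeric())
  rownames(res) <- NULL
  structure(res, stat = attr(track, "stat"), group = attr(track, "group"),
            threshold = thr, class = c("peak_set", "data.frame"))
}

#' Intersect peak sets from several scans
#'
#' Counts, over the genome, how many of the input peak sets overlap each
#' interval; candidate regions are the maximal intervals with count at or
#' above `min_count`. The headline region is the interval with the highest
#' count (ties broken toward the smallest interval).
#'
#' @param peaksets list of `peak_set` objects (length >= 2).
#' @param min_count minimum overlap count for a candidate region (default 2).
#' @return list with `regions` (data.frame chrom/start/end/count, provenance
#'   of contributing scans) and `top` (the headline region, or NULL).
#' @export
intersect_peaks <- function(peaksets, min_count = 2) {
  stopifnot(length(peaksets) >= 2)
  all_iv <- do.call(rbind, lapply(peaksets, function(p)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               stat = attr(p, "stat"), group = attr(p, "group"))))
  if (is.null(all_iv) || !nrow(all_iv))
    return(list(regions = data.frame(chrom = character(), start = integer(),
                                     end = integer(), count = integer()),
                top = NULL))
  regions <- list()
  for (ch in unique(all_iv$chrom)) {
    iv <- all_iv[all_iv$chrom == ch, ]
    ir <- IRanges::IRanges(start = iv$start, end = iv$end)
    cov <- IRanges::coverage(ir)
    sl <- IRanges::slice(cov, lower = max(min_count, 1L))
    if (!length(sl)) next
    vr <- IRanges::ranges(sl)
    counts <- vapply(seq_along(sl), function(k) max(sl[[k]]), 0L)
    regions[[ch]] <- data.frame(chrom = ch,
                                start = IRanges::start(vr),
                                end = IRanges::end(vr),
                                count = counts)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               count = integer())
  rownames(regions) <- NULL
  top <- NULL
  if (nrow(regions)) {
    best <- which(regions$count == max(regions$count))
    widths <- regions$end[best] - regions$start[best]
    top <- regions[best[which.min(widths)], ]
  }
  list(regions = regions, top = top)
}

#' Annotate regions with features from a BED file
#'
#' Interval intersection against a (0-based half-open) BED annotation:
#' features overlapping a region by at least 1 bp are reported. Regions use
#' the in-memory 1-based inclusive convention.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param bed_path path to a BED file of features.
#' @return list, one character vector of feature names per region row.
#' @export
annotate_regions <- function(regions, bed_path) {
  bed <- read_bed(bed_path)
  lapply(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    # region in 0-based half-open: [start-1, end)
    rs <- regions$start[i] - 1L
    re <- regions$end[i]
    hit <- bed$chrom == ch & bed$start < re & bed$end > rs
    bed$name[hit]
  })
}
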