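#' Demo pipeline configuration
#'
#' A complete configuration running every stage on the Arabian-like
#' synthetic fixture. All thresholds surface the pipeline defaults:
#' maf 0.01, missingness ceiling 0.2 (0 for PCA/AMOVA), HWE alpha 0.005,
#' LD pruning 50/5/0.5, IBD ceiling 0.25, window 351 SNPs, 99th percentile,
#' posterior 0.99, G = 9.
#'
#' @param outdir output directory.
#' @param seed master seed (default 1).
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(outdir, seed = 1) {
  list(
    seed = seed,
    outdir = outdir,
    simulate = list(fixture = "arabian_like", n_variants = 2000,
                    chrom_length = 2e7, n_per_pop = 15, n_admixed = 6),
    filters = list(maf = 0.01, max_missing_rate = 0.2, hwe_alpha = 0.005,
                   ld = list(window = 50, step = 5, r2 = 0.5)),
    diversity = list(ibd_max = 0.25, fhat3_sd_mult = 2),
    fst = list(permutations = 200),
    amova = list(permutations = 200),
    pca = list(components = 4),
    scan = list(stats = c("H", "H12", "D"), window_snps = 60,
                percentile = 99, group = "arabian"),
    ancestry = list(query = "racing_arabian",
                    refs = c("arabian", "thoroughbred", "turkemen",
                             "icelandic"),
                    window = 50, threshold = 0.99)
  )
}

#' Run the analysis pipeline from a single configuration
#'
#' Executes the stage graph — simulate (or load) -> variant QC -> diversity
#' and relatedness -> pairwise F_ST -> AMOVA -> PCA on genotypes, and
#' selection scans -> local ancestry on phased haplotypes — writing TSV/BED
#' outputs plus a JSON run manifest recording parameters, seeds and counts.
#' Stages are deterministic given the config seed; re-running reproduces
#' byte-identical outputs and regenerates any deleted output.
#'
#' @param config a config list (see [demo_config()]) or path to a YAML file.
#' @return The run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  cat(sprintf("[%s] pipeline start seed=%d\n", format(Sys.time()),
              config$seed), file = log_path)
  logmsg <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[stage] %s\n", msg), file = log_path, append = TRUE)
    message(msg)
  }
  manifest <- list(config = config, stages = list())
  outputs <- character()
  add_output <- function(path) outputs <<- c(outputs, path)

  # --- stage: simulate / load -------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim <- sim_arabian_like(
      seed = config$seed,
      n_variants = sim_cfg$n_variants %||% 4000,
      chrom_length = sim_cfg$chrom_length %||% 5e7,
      n_per_pop = sim_cfg$n_per_pop %||% 25,
      n_admixed = sim_cfg$n_admixed %||% 10)
    gm <- sim$genotypes
    haps <- sim$ref_haps
    query_haps <- sim$admixed$haps
    hierarchy <- sim$hierarchy
    write_ped_map(gm, file.path(outdir, "genotypes.ped"),
                  file.path(outdir, "genotypes.map"))
    add_output(file.path(outdir, "genotypes.ped"))
    add_output(file.path(outdir, "genotypes.map"))
    utils::write.table(hierarchy, file.path(outdir, "hierarchy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(file.path(outdir, "hierarchy.tsv"))
    truth_bed <- sim$admixed$truth
    write_bed(data.frame(chrom = truth_bed$chrom, start = truth_bed$start,
                         end = truth_bed$end, name = truth_bed$hap,
                         label = truth_bed$pop),
              file.path(outdir, "ancestry_truth.bed"))
    add_output(file.path(outdir, "ancestry_truth.bed"))
    logmsg("simulate: %d samples x %d variants", nrow(gm$calls),
           ncol(gm$calls))
    manifest$stages$simulate <- list(
      seed = config$seed, n_samples = nrow(gm$calls),
      n_variants = ncol(gm$calls))
  } else {
    gm <- read_ped_map(config$inputs$ped, config$inputs$map)
    hierarchy <- read_hierarchy(config$inputs$hierarchy)
    gm$samples$breed <- hierarchy$population[
      match(gm$samples$id, hierarchy$sample)]
    haps <- NULL
    query_haps <- if (!is.null(config$inputs$phased_vcf))
      read_vcf_phased(config$inputs$phased_vcf) else NULL
    logmsg("load: %d samples x %d variants", nrow(gm$calls), ncol(gm$calls))
    manifest$stages$load <- list(n_samples = nrow(gm$calls),
                                 n_variants = ncol(gm$calls))
  }

  # --- stage: variant QC -------------------------------------------------
  f <- config$filters
  fl <- filter_variants(gm, maf_min = f$maf %||% 0.01,
                        max_missing_rate = f$max_missing_rate %||% 0.2,
                        hwe_alpha = f$hwe_alpha %||% 0.005)
  gmf <- fl$genotypes
  utils::write.table(fl$report$stages,
                     file.path(outdir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_output(file.path(outdir, "filter_report.tsv"))
  keep <- ld_prune(gmf, window_snps = f$ld$window %||% 50,
                   step_snps = f$ld$step %||% 5, r2_max = f$ld$r2 %||% 0.5)
  gm_pruned <- subset_genotypes(gmf, variants = keep)
  logmsg("filter: %d -> %d variants (LD-pruned %d)", ncol(gm$calls),
         ncol(gmf$calls), ncol(gm_pruned$calls))
  manifest$stages$filter <- list(params = f, retained = ncol(gmf$calls),
                                 ld_pruned = ncol(gm_pruned$calls))

  # --- stage: diversity --------------------------------------------------
  het <- individual_heterozygosity(gmf)
  het$fhat3 <- fhat3(gmf)
  utils::write.table(het, file.path(outdir, "diversity_per_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_output(file.path(outdir, "diversity_per_sample.tsv"))
  gd <- group_diversity(gmf, gmf$samples$breed)
  utils::write.table(gd$summary, file.path(outdir, "diversity_by_group.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_output(file.path(outdir, "diversity_by_group.tsv"))
  rel <- pairwise_ibd(gm_pruned)
  utils::write.table(round(unclass(rel), 6),
                     file.path(outdir, "pi_hat.tsv"),
                     sep = "\t", quote = FALSE)
  add_output(file.path(outdir, "pi_hat.tsv"))
  unrelated <- relatedness_filter(rel, config$diversity$ibd_max %||% 0.25)
  writeLines(unrelated, file.path(outdir, "unrelated_samples.txt"))
  add_output(file.path(outdir, "unrelated_samples.txt"))
  logmsg("diversity: %d samples, %d unrelated", nrow(het), length(unrelated))
  manifest$stages$diversity <- list(
    n_unrelated = length(unrelated),
    fhat3_threshold = fhat3_outliers(
      het$fhat3, config$diversity$fhat3_sd_mult %||% 2)$threshold)

  # --- stage: F_ST -------------------------------------------------------
  pops <- unique(gmf$samples$breed)
  pairs <- utils::combn(pops, 2)
  fst_rows <- lapply(seq_len(ncol(pairs)), function(k) {
    pr <- pairs[, k]
    sub <- subset_genotypes(gmf, samples = gmf$samples$breed %in% pr)
    res <- fst_permutation(sub, sub$samples$breed,
                           n_perm = config$fst$permutations %||% 20000,
                           seed = config$seed + k)
    data.frame(pop1 = pr[1], pop2 = pr[2], fst = res$theta, p = res$p)
  })
  fst_tab <- do.call(rbind, fst_rows)
  utils::write.table(fst_tab, file.path(outdir, "fst_pairwise.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_output(file.path(outdir, "fst_pairwise.tsv"))
  logmsg("fst: %d pairs, range %.3f-%.3f", nrow(fst_tab),
         min(fst_tab$fst), max(fst_tab$fst))
  manifest$stages$fst <- list(pairs = nrow(fst_tab),
                              permutations = config$fst$permutations %||% 20000)

  # --- stage: AMOVA ------------------------------------------------------
  am_gm <- subset_genotypes(gmf, variants = colSums(is.na(gmf$calls)) == 0L)
  am <- amova(am_gm, hierarchy,
              n_perm = config$amova$permutations %||% 20000,
              seed = config$seed + 100)
  am_tab <- data.frame(level = am$levels, sigma2 = unname(am$components),
                       percent = unname(am$percent))
  utils::write.table(am_tab, file.path(outdir, "amova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_output(file.path(outdir, "amova.tsv"))
  logmsg("amova: within-individual %.1f%%", am$percent["sigma2_d"])
  manifest$stages$amova <- list(percent = as.list(am$percent),
                                p_values = as.list(am$p_values))

  # --- stage: PCA --------------------------------------------------------
  pc <- pca(gm_pruned, k = min(config$pca$components %||% 4,
                               nrow(gm_pruned$calls) - 1L),
            impute_mean = TRUE)
  sc <- data.frame(id = rownames(pc$scores), pc$scores,
                   breed = gm_pruned$samples$breed)
  utils::write.table(sc, file.path(outdir, "pca_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_output(file.path(outdir, "pca_scores.tsv"))
  utils::write.table(
    data.frame(component = paste0("PC", seq_along(pc$percent_variance)),
               percent_variance = pc$percent_variance),
    file.path(outdir, "pca_scree.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  add_output(file.path(outdir, "pca_scree.tsv"))
  logmsg("pca: PC1 %.1f%%, PC2 %.1f%%", pc$percent_variance[1],
         pc$percent_variance[2])
  manifest$stages$pca <- list(percent_variance = pc$percent_variance)

  # --- stage: selection scan --------------------------------------------
  if (!is.null(haps)) {
    scan_grp <- config$scan$group %||% names(haps)[1]
    h <- haps[[scan_grp]]
    keep_idx <- density_prune(h$variants$pos)
    h <- subset_haplotypes(h, variants = keep_idx)
    w <- config$scan$window_snps %||% 351
    tracks <- list(
      H = scale_track(h_scan(h, group = scan_grp)),
      H12 = scale_track(h12_windows(h, window_snps = w, group = scan_grp)),
      D = scale_track(tajimas_d_windows(h, window_snps = w,
                                        group = scan_grp)))
    peaks <- lapply(tracks, call_peaks,
                    percentile = config$scan$percentile %||% 99)
    for (nm in names(tracks)) {
      utils::write.table(
        as.data.frame(tracks[[nm]]),
        file.path(outdir, sprintf("scan_%s.tsv", nm)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      add_output(file.path(outdir, sprintf("scan_%s.tsv", nm)))
      if (nrow(peaks[[nm]]))
        write_bed(data.frame(peaks[[nm]][c("chrom", "start", "end")],
                             stat = nm, group = scan_grp),
                  file.path(outdir, sprintf("peaks_%s.bed", nm)))
      else writeLines(character(),
                      file.path(outdir, sprintf("peaks_%s.bed", nm)))
      add_output(file.path(outdir, sprintf("peaks_%s.bed", nm)))
    }
    inter <- intersect_peaks(peaks, min_count = 2)
    if (nrow(inter$regions))
      write_bed(inter$regions, file.path(outdir, "candidate_regions.bed"))
    else writeLines(character(), file.path(outdir, "candidate_regions.bed"))
    add_output(file.path(outdir, "candidate_regions.bed"))
    logmsg("scan: %d candidate regions", nrow(inter$regions))
    manifest$stages$scan <- list(group = scan_grp, window = w,
                                 n_candidates = nrow(inter$regions))
  } else logmsg("scan: skipped (no phased haplotypes in config)")

  # --- stage: ancestry ---------------------------------------------------
  if (!is.null(haps) && !is.null(query_haps)) {
    refs <- config$ancestry$refs %||% names(haps)
    rf <- reference_freqs(haps[refs])
    seg <- assign_windows(query_haps, rf,
                          window_snps = config$ancestry$window %||% 50,
                          threshold = config$ancestry$threshold %||% 0.99)
    write_bed(data.frame(chrom = seg$chrom, start = seg$start,
                         end = seg$end, name = seg$hap, label = seg$label,
                         posterior = round(seg$posterior, 4)),
              file.path(outdir, "ancestry_segments.bed"))
    add_output(file.path(outdir, "ancestry_segments.bed"))
    fr <- ancestry_fractions(seg)
    utils::write.table(fr, file.path(outdir, "ancestry_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(file.path(outdir, "ancestry_fractions.tsv"))
    logmsg("ancestry: %d query haplotypes", length(unique(seg$hap)))
    manifest$stages$ancestry <- list(refs = refs,
                                     n_haps = length(unique(seg$hap)))
  } else logmsg("ancestry: skipped (no phased query/reference input)")

  manifest$outputs <- outputs
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.check_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or YAML path")
  if (is.null(config$outdir)) stop("config$outdir is required")
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config must provide either a simulate spec or inputs")
  if (!is.null(config$inputs) && is.null(config$simulate)) {
    for (f in c("ped", "map", "hierarchy"))
      if (is.null(config$inputs[[f]]) || !file.exists(config$inputs[[f]]))
        stop("missing input file for '", f, "'")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
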