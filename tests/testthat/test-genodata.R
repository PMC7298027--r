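test_that("container invariants are enforced", {
  va <- data.frame(chrom = "1", pos = c(100L, 50L), id = c("a", "b"),
                   a1 = "A", a2 = "G")
  expect_error(genotype_matrix(matrix(0L, 2, 2), va,
                               data.frame(id = c("s1", "s2"))),
               "strictly increasing")
  va$pos <- c(50L, 100L)
  expect_error(genotype_matrix(matrix(3L, 2, 2), va,
                               data.frame(id = c("s1", "s2"))),
               "0, 1, 2 or NA")
  expect_error(genotype_matrix(matrix(0L, 2, 2), va,
                               data.frame(id = c("s1", "s1"))),
               "duplicate sample")
  expect_error(haplotype_matrix(matrix(NA_integer_, 2, 2), "s1", va),
               "missing")
  h <- haplotype_matrix(matrix(c(0L, 1L, 1L, 1L), 2, 2), "s1", va)
  gm <- haplotypes_to_genotypes(h)
  expect_equal(unname(gm$calls), matrix(c(1L, 2L), 1, 2))
})

test_that("PED/MAP reading maps alleles and missing calls as specified", {
  map <- c("1\tv1\t0\t100", "1\tv2\t0\t200", "1\tv3\t0\t300")
  ped <- c("f1 s1 0 0 0 -9 A A A G G G",
           "f2 s2 0 0 0 -9 G G A G A A")
  mp <- tmp_path(".map"); pp <- tmp_path(".ped")
  writeLines(map, mp); writeLines(ped, pp)
  gm <- read_ped_map(pp, mp)
  # first-observed allele becomes a1, calls count copies of a2: at v3 the
  # first sample is G G, so a1 = G and its call is 0
  expect_equal(unname(gm$calls), rbind(c(0L, 1L, 0L), c(2L, 1L, 2L)))
  expect_equal(gm$variants$a1, c("A", "A", "G"))
  expect_equal(gm$variants$a2, c("G", "G", "A"))
  # one missing genotype
  ped2 <- c("f1 s1 0 0 0 -9 A A 0 0 G G", "f2 s2 0 0 0 -9 G G A G A A")
  writeLines(ped2, pp)
  gm2 <- read_ped_map(pp, mp)
  expect_equal(sum(is.na(gm2$calls)), 1L)
  expect_true(is.na(gm2$calls[1, 2]))
  # ragged row and duplicate ids are errors
  writeLines(c(ped[1], "f2 s2 0 0 0 -9 A A"), pp)
  expect_error(read_ped_map(pp, mp), "line 2")
  writeLines(c(ped[1], sub("s2", "s1", ped[2])), pp)
  expect_error(read_ped_map(pp, mp), "duplicate sample")
})

test_that("PED/MAP round-trips random matrices (up to allele labelling)", {
  for (seed in 1:5) {
    gm <- rand_gm(8, 30, seed, miss_rate = 0.05)
    pp <- tmp_path(".ped"); mp <- tmp_path(".map")
    write_ped_map(gm, pp, mp)
    gm2 <- read_ped_map(pp, mp)
    flip <- gm2$variants$a1 != gm$variants$a1 & gm2$variants$a1 != "0"
    calls2 <- gm2$calls
    calls2[, flip] <- 2L - calls2[, flip]
    expect_equal(unname(calls2), unname(gm$calls))
    expect_equal(gm2$variants$pos, gm$variants$pos)
  }
})

test_that("phased VCF round-trips and collapses consistently", {
  h <- rand_haps(10, 40, seed = 3)
  vp <- tmp_path(".vcf")
  write_vcf_phased(h, vp)
  h2 <- read_vcf_phased(vp)
  expect_equal(unname(h2$alleles), unname(h$alleles))
  expect_equal(h2$variants$pos, h$variants$pos)
  expect_equal(h2$sample_ids, h$sample_ids)
  # collapse-to-genotype equals direct genotype view
  expect_equal(unname(haplotypes_to_genotypes(h2)$calls),
               unname(haplotypes_to_genotypes(h)$calls))
  # one-sample single-site file
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0|1"), vp)
  h3 <- read_vcf_phased(vp)
  expect_equal(unname(h3$alleles), matrix(c(0L, 1L), 2, 1))
  # unphased separator is an error naming the record
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0/1"), vp)
  expect_error(read_vcf_phased(vp), "unphased")
  # multi-allelic record is an error
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\tv1\tA\tT,G\t.\tPASS\t.\tGT\t0|1"), vp)
  expect_error(read_vcf_phased(vp), "multi-allelic")
})

test_that("merge intersects variants, reconciles swapped alleles, drops the rest", {
  va <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                   id = paste0("v", 1:4), a1 = c("A", "A", "A", "A"),
                   a2 = c("G", "G", "G", "T"))
  a <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), 1, 4), va,
                       data.frame(id = "s1"))
  # b: v2 swapped alleles, v3 mismatching pair, v4 strand-ambiguous (A/T)
  vb <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                   id = paste0("w", 1:4), a1 = c("A", "G", "A", "T"),
                   a2 = c("G", "A", "C", "A"))
  b <- genotype_matrix(matrix(c(2L, 2L, 0L, 0L), 1, 4), vb,
                       data.frame(id = "s2"))
  res <- merge_genotypes(a, b)
  expect_equal(res$genotypes$variants$pos, c(100L, 200L))
  expect_equal(unname(res$genotypes$calls),
               rbind(c(0L, 1L), c(2L, 0L)))  # b's v2 call recoded 2-x
  st <- res$report$stages
  expect_equal(st$removed[st$stage == "strand_ambiguous"], 1L)
  expect_equal(st$removed[st$stage == "allele_mismatch"], 1L)
  # self-merge under renamed samples doubles samples, keeps variants
  a2 <- a; a2$samples$id <- "s9"; a2 <- genotype_matrix(a$calls, va,
                                                        a2$samples)
  res2 <- merge_genotypes(a, a2)
  expect_equal(nrow(res2$genotypes$calls), 2L)
  expect_equal(res2$genotypes$variants$pos, c(100L, 200L, 300L))
  expect_error(merge_genotypes(a, a), "shared sample")
  # symmetry up to sample order and per-variant allele coding
  res_ab <- merge_genotypes(a, b)$genotypes
  res_ba <- merge_genotypes(b, a)$genotypes
  expect_equal(res_ab$variants$pos, res_ba$variants$pos)
  ba_calls <- res_ba$calls[c("s1", "s2"), , drop = FALSE]
  flip <- res_ba$variants$a2 != res_ab$variants$a2
  ba_calls[, flip] <- 2L - ba_calls[, flip]
  expect_equal(unname(res_ab$calls[c("s1", "s2"), ]), unname(ba_calls))
})

test_that("HWE chi-square test matches hand values and the enumeration oracle", {
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_lt(hwe_test(30, 30, 40), 0.005)
  expect_equal(hwe_test(50, 0, 0), 1)
  expect_error(hwe_test(0, 0, 0), "zero")
  # exhaustive agreement on all triples with total <= 30
  for (n in 1:30) for (aa in 0:n) for (ab in 0:(n - aa)) {
    bb <- n - aa - ab
    expect_equal(hwe_test(aa, ab, bb), oracle_hwe(aa, ab, bb),
                 tolerance = 1e-12)
  }
})

test_that("filter_variants applies thresholds with fixed precedence", {
  gm <- rand_gm(40, 50, seed = 8, miss_rate = 0)
  # identity configuration
  res <- filter_variants(gm, maf_min = 0, max_missing_rate = 1,
                         hwe_alpha = 0)
  expect_equal(ncol(res$genotypes$calls), 50L)
  # monomorphic variant removed by MAF floor
  calls <- gm$calls; calls[, 7] <- 0L
  gm2 <- genotype_matrix(calls, gm$variants, gm$samples)
  res2 <- filter_variants(gm2, maf_min = 0.01, max_missing_rate = 1,
                          hwe_alpha = 0)
  expect_false("v7" %in% res2$genotypes$variants$id)
  # forced HWE failure is removed iff below the Bonferroni threshold
  calls3 <- gm$calls
  calls3[, 3] <- c(rep(0L, 12), rep(1L, 12), rep(2L, 16))  # (12,12,16)/40
  gm3 <- genotype_matrix(calls3, gm$variants, gm$samples)
  res3 <- filter_variants(gm3, maf_min = 0, max_missing_rate = 1,
                          hwe_alpha = 0.005)
  p3 <- hwe_test(12, 12, 16)
  expect_equal(!("v3" %in% res3$genotypes$variants$id), p3 < 0.005 / 50)
  # report conservation: removed + retained = input at every stage
  st <- res3$report$stages
  input <- 50L
  for (k in seq_len(nrow(st))) {
    expect_equal(st$removed[k] + st$retained[k], input)
    input <- st$retained[k]
  }
  # missingness precedence: an all-missing variant counts only once,
  # at the missingness stage, even though it would also fail MAF
  calls4 <- gm$calls; calls4[, 5] <- NA_integer_
  gm4 <- genotype_matrix(calls4, gm$variants, gm$samples)
  res4 <- filter_variants(gm4, maf_min = 0.05, max_missing_rate = 0.5,
                          hwe_alpha = 0)
  expect_equal(res4$report$stages$removed[1], 1L)
  expect_false("v5" %in% res4$genotypes$variants$id)
  # HWE subgroup parameter must name known samples
  expect_error(filter_variants(gm, hwe_test_samples = "nope"), "subset")
})

test_that("ld_prune matches the greedy oracle and basic contracts", {
  gm <- rand_gm(30, 12, seed = 5)
  # uncorrelated variants: keep all (r2_max = 1 means nothing exceeds)
  expect_equal(ld_prune(gm, 6, 2, r2_max = 1), 1:12)
  # duplicated column: exactly one removed
  calls <- gm$calls; calls[, 4] <- calls[, 3]
  gmd <- genotype_matrix(calls, gm$variants, gm$samples)
  kept <- ld_prune(gmd, 6, 2, r2_max = 0.5)
  expect_equal(sum(c(3, 4) %in% kept), 1L)
  expect_true(3 %in% kept)  # later-positioned member removed
  # random 20-variant instances vs oracle
  for (seed in 11:16) {
    g <- rand_gm(25, 20, seed)
    # correlate some columns to create prunable structure
    cl <- g$calls
    cl[, 2] <- cl[, 1]; cl[, 10] <- pmin(2L, cl[, 9] + rbinom(25, 1, 0.1))
    cl[, 15] <- cl[, 14]
    g <- genotype_matrix(cl, g$variants, g$samples)
    expect_equal(ld_prune(g, 8, 3, 0.5),
                 oracle_ld_prune(g$calls, order(g$variants$pos), 8, 3, 0.5))
  }
})
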