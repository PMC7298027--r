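test_that("individual heterozygosity matches hand-computable cases", {
  # sample 1: calls [0,1,1,2,missing] -> 2 het of 4 non-missing
  calls <- rbind(c(0L, 1L, 1L, 2L, NA),
                 c(0L, 1L, 2L, 0L, 1L),
                 c(1L, 0L, 1L, 2L, 2L))
  gm <- genotype_matrix(calls,
                        data.frame(chrom = "1", pos = (1:5) * 10L,
                                   id = paste0("v", 1:5), a1 = "A", a2 = "G"),
                        data.frame(id = paste0("s", 1:3)))
  het <- individual_heterozygosity(gm)
  expect_equal(het$ho[1], 0.5)
  expect_equal(het$n_nonmissing, c(4L, 5L, 5L))
  # fully heterozygous sample: Ho = 1, F < 0
  calls2 <- rbind(rep(1L, 6), rbind(c(0L, 2L, 0L, 2L, 1L, 0L),
                                    c(2L, 0L, 1L, 0L, 1L, 2L)))
  gm2 <- genotype_matrix(calls2,
                         data.frame(chrom = "1", pos = (1:6) * 10L,
                                    id = paste0("v", 1:6), a1 = "A",
                                    a2 = "G"),
                         data.frame(id = paste0("s", 1:3)))
  het2 <- individual_heterozygosity(gm2)
  expect_equal(het2$ho[1], 1)
  expect_lt(het2$f[1], 0)
  # Ho in [0,1] everywhere on random fixtures
  gmr <- rand_gm(30, 200, seed = 2, miss_rate = 0.05)
  hr <- individual_heterozygosity(gmr)
  expect_true(all(hr$ho >= 0 & hr$ho <= 1))
})

test_that("mean F and Fhat3 are near zero for outbred panmictic samples", {
  gm <- rand_gm(200, 2000, seed = 31)
  het <- individual_heterozygosity(gm)
  f3 <- fhat3(gm)
  se_f <- sd(het$f) / sqrt(nrow(het))
  se_3 <- sd(f3) / sqrt(length(f3))
  expect_lt(abs(mean(het$f)), 3 * se_f + 1e-3)
  expect_lt(abs(mean(f3)), 3 * se_3 + 1e-3)
})

test_that("Fhat3 reproduces hand-evaluated genotype terms", {
  # x = 1 at p = 0.5 gives term -1; all-homozygous at p = 0.5 gives +1.
  # Construct a cohort whose frequency at every variant is exactly 0.5 and
  # check the focal samples' means.
  m <- 40
  half1 <- matrix(rep(c(0L, 2L), each = m / 2), 10, m, byrow = TRUE)
  half2 <- 2L - half1
  focal_het <- matrix(1L, 1, m)
  focal_hom <- matrix(rep(c(0L, 2L), m / 2), 1, m)
  # frequencies estimated on the balanced panel s1..s20 are exactly 0.5
  calls <- rbind(half1, half2, focal_het, focal_hom)
  gm <- genotype_matrix(calls,
                        data.frame(chrom = "1", pos = (1:m) * 10L,
                                   id = paste0("v", 1:m), a1 = "A",
                                   a2 = "G"),
                        data.frame(id = paste0("s", 1:22)))
  panel <- paste0("s", 1:20)
  expect_equal(unname(allele_freqs(gm, panel)), rep(0.5, m))
  f3 <- fhat3(gm, freq_samples = panel)
  expect_equal(unname(f3["s21"]), -1)
  expect_equal(unname(f3["s22"]), 1)
})

test_that("group diversity separates differentiated groups and handles clones", {
  # Balding-Nichols-style: inbred group (within-group correlation) has
  # lower Ho than an outbred group at shared global frequencies
  set.seed(44)
  m <- 1500
  p <- runif(m, 0.2, 0.8)
  # outbred: HWE draws; "inbred": excess homozygosity via F = 0.3
  Fin <- 0.3
  n <- 30
  outb <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  hom_extra <- matrix(runif(n * m) < Fin, n, m)
  a1 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  a2 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  inb <- ifelse(hom_extra, 2L * a1, a1 + a2)
  gm <- genotype_matrix(rbind(outb, inb),
                        data.frame(chrom = "1", pos = (1:m) * 10L,
                                   id = paste0("v", 1:m), a1 = "A",
                                   a2 = "G"),
                        data.frame(id = paste0("s", 1:(2 * n))))
  labs <- rep(c("outbred", "inbred"), each = n)
  gd <- group_diversity(gm, labs)
  s <- gd$summary
  expect_lt(s$mean_ho[s$group == "inbred"], s$mean_ho[s$group == "outbred"])
  expect_lt(gd$pairwise$p[1], 0.001)
  # two identical groups: comparison p ~ 1
  gm_same <- genotype_matrix(rbind(outb, outb),
                             gm$variants,
                             data.frame(id = paste0("s", 1:(2 * n))))
  gd_same <- group_diversity(gm_same, labs)
  expect_gt(gd_same$pairwise$p[1], 0.99)
  # clone group: mean Ho equals the clone's own Ho
  clone <- outb[rep(1, 5), ]
  gm_cl <- genotype_matrix(rbind(outb, clone),
                           gm$variants,
                           data.frame(id = paste0("s", 1:(n + 5))))
  gd_cl <- group_diversity(gm_cl, c(rep("out", n), rep("clone", 5)))
  ho1 <- individual_heterozygosity(gm_cl)$ho[n + 1]
  expect_equal(gd_cl$summary$mean_ho[gd_cl$summary$group == "clone"], ho1)
  # undersized groups excluded with warning
  expect_warning(group_diversity(gm_cl, c(rep("out", n + 4), "solo")),
                 "size < 2")
})

test_that("PI_HAT recovers duplicates, parent-offspring and unrelated pairs", {
  set.seed(7)
  m <- 2000
  frq <- runif(m, 0.1, 0.9)
  h <- draw_haplotypes(frq, 20, sample_prefix = "U", seed = 71)
  g <- haplotypes_to_genotypes(h)
  child <- h$alleles[1, ] + rbinom(m, 1L, frq)  # one transmitted haplotype
  calls <- rbind(g$calls, g$calls[1, , drop = FALSE],
                 matrix(as.integer(child), 1))
  gm <- genotype_matrix(calls, g$variants,
                        data.frame(id = c(g$samples$id, "DUP", "CHILD")))
  rel <- pairwise_ibd(gm)
  expect_true(isSymmetric(unclass(rel)))
  expect_equal(unname(diag(unclass(rel))), rep(1, nrow(rel)))
  expect_gte(rel["U1", "DUP"], 0.95)
  expect_equal(rel["U1", "CHILD"], 0.5, tolerance = 0.1)
  off <- unclass(rel)[2:10, 2:10]; diag(off) <- NA
  expect_lt(max(off, na.rm = TRUE), 0.15)
})

test_that("relatedness filter is conflict-free and near the brute-force optimum", {
  # duplicate pair: exactly one member removed
  rel <- diag(1, 4)
  rel[1, 2] <- rel[2, 1] <- 0.99
  rownames(rel) <- colnames(rel) <- paste0("s", 1:4)
  kept <- relatedness_filter(rel, 0.25)
  expect_equal(length(kept), 3L)
  expect_true(xor("s1" %in% kept, "s2" %in% kept))
  expect_true("s1" %in% kept)  # tie removes the later sample
  # no pair above threshold: identity
  expect_equal(relatedness_filter(diag(1, 3)), c("1", "2", "3"))
  # random instances: retained set conflict-free; size vs exhaustive optimum
  excess <- 0L
  for (seed in 21:28) {
    set.seed(seed)
    n <- 9
    r <- matrix(runif(n * n, 0, 0.35), n)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    rownames(r) <- colnames(r) <- paste0("x", 1:n)
    kept <- relatedness_filter(r, 0.25)
    sub <- r[kept, kept, drop = FALSE]
    diag(sub) <- 0
    expect_true(all(sub < 0.25))
    opt <- n - length(oracle_min_removal(r >= 0.25 & upper.tri(r) |
                                           t(r >= 0.25 & upper.tri(r))))
    expect_lte(length(kept), n)
    excess <- excess + (opt - length(kept))
  }
  # greedy may exceed the optimum, but not grossly across instances
  expect_lte(excess, 8L)
})

test_that("fhat3 outlier threshold is mean + k sd", {
  x <- c(a = 0.0, b = 0.1, c = 0.05, d = 0.5)
  res <- fhat3_outliers(x, sd_mult = 2)
  expect_equal(res$threshold, mean(x) + 2 * sd(x))
  expect_equal(res$outliers, character(0))
  res1 <- fhat3_outliers(x, sd_mult = 1)
  expect_equal(res1$outliers, "d")
})
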