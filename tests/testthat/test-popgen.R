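# scalar-loop Weir-Cockerham oracle (two or more populations, one pass per
# locus), kept deliberately naive
wc_oracle <- function(genotypes, populations) {
  pops <- sort(unique(populations))
  r <- length(pops)
  A <- B <- C <- 0
  for (l in seq_len(ncol(genotypes))) {
    n <- p <- h <- numeric(r)
    for (k in seq_len(r)) {
      g <- genotypes[populations == pops[k], l]
      g <- g[!is.na(g)]
      n[k] <- length(g); p[k] <- mean(g) / 2; h[k] <- mean(g == 1)
    }
    if (any(n < 1)) next
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    A <- A + a; B <- B + b; C <- C + hbar / 2
  }
  A / (A + B + C)
}

test_that("locus filters apply sequentially with a faithful report", {
  set.seed(21)
  g <- random_genotypes(10, 5)
  meta <- data.frame(locus_id = colnames(g),
                     reproducibility = c(0.99, 0.97, 0.98, 0.95, 1.0),
                     call_rate = 1)
  fl <- filter_loci(g, meta, repro_min = 0.98, callrate_min = 0,
                    maf_min = 0)
  expect_identical(colnames(fl$genotypes), colnames(g)[c(1, 3, 5)])

  # the three passes happen in the stated order on survivors only
  g2 <- random_genotypes(20, 6)
  g2[, 6] <- 0L; g2[1:2, 6] <- 1L        # MAF = 0.05
  g2[, 5] <- 0L                          # monomorphic
  meta2 <- data.frame(locus_id = colnames(g2),
                      reproducibility = c(0.5, rep(1, 5)),
                      call_rate = c(1, 0.5, rep(1, 4)))
  fl2 <- filter_loci(g2, meta2, 0.98, 0.95, 0.02)
  expect_equal(fl2$report$removed, c(0, 1, 1, 1))
  expect_identical(colnames(fl2$genotypes), colnames(g2)[c(3, 4, 6)])
  expect_match(attr(fl2$report, "maf_note"), "frequency")

  expect_error(filter_loci(g, meta, repro_min = 1.1), "not TRUE")
  meta$reproducibility <- 0
  expect_error(filter_loci(g, meta), "all loci removed")
})

test_that("heterozygosities use the sample-size corrected gene diversity", {
  g <- matrix(c(0L, 1L, 1L, 2L), 4, 1, dimnames = list(paste0("i", 1:4), "L1"))
  het <- heterozygosities(g, rep("A", 4))
  expect_equal(het$Ho, 0.5)
  # p = 0.5, n = 4: Hs = 4/3 * (1 - 0.5 - 0.5/8) = 7/12
  expect_equal(het$He, 7 / 12)
  expect_equal(het$Fis, 1 - 0.5 / (7 / 12))

  g0 <- matrix(c(0L, 0L, 2L, 2L), 4, 1)
  het0 <- heterozygosities(g0, rep("A", 4))
  expect_equal(het0$Ho, 0)
  expect_true(het0$He > 0)
  expect_equal(het0$Fis, 1)

  # monomorphic-only population: He = 0, Fis undefined
  gm <- matrix(0L, 4, 2)
  hetm <- heterozygosities(gm, rep("A", 4))
  expect_equal(hetm$He, 0)
  expect_true(is.na(hetm$Fis))

  # identity F_IS = 1 - Ho/He on random data
  set.seed(3)
  g <- random_genotypes(30, 40, miss = 0.05)
  het <- heterozygosities(g, rep(c("A", "B"), 15))
  expect_equal(het$Fis, 1 - het$Ho / het$He, tolerance = 1e-12)
})

test_that("pairwise Weir-Cockerham theta hits its boundary cases", {
  # opposite fixation: theta exactly 1
  g <- rbind(matrix(0L, 6, 10), matrix(2L, 6, 10))
  rownames(g) <- paste0("i", 1:12)
  pf <- pairwise_fst(g, rep(c("A", "B"), each = 6), n_boot = 0)
  expect_equal(pf$fst["A", "B"], 1)
  expect_equal(diag(pf$fst), c(A = 0, B = 0))

  # same frequencies, large n: theta near 0 (and can go negative -- no clip)
  set.seed(31)
  p <- runif(300, 0.2, 0.8)
  g2 <- matrix(rbinom(200 * 300, 2, rep(p, each = 200)), 200, 300)
  rownames(g2) <- paste0("i", 1:200)
  pf2 <- pairwise_fst(g2, rep(c("A", "B"), 100), n_boot = 200, seed = 4)
  expect_lt(abs(pf2$fst["A", "B"]), 0.01)
  expect_gt(pf2$p["A", "B"], 0.05)

  # agreement with the scalar-loop oracle, including missing data
  set.seed(32)
  g3 <- random_genotypes(15, 20, miss = 0.08)
  pops3 <- rep(c("A", "B", "C"), each = 5)
  pf3 <- pairwise_fst(g3, pops3, n_boot = 0)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    keep <- pops3 %in% pair
    expect_equal(pf3$fst[pair[1], pair[2]],
                 wc_oracle(g3[keep, ], pops3[keep]))
  }
  # a population of one individual is excluded with a warning
  expect_warning(pairwise_fst(g3[c(1:5, 6:10, 11), ],
                              c(pops3[1:10], "C"), n_boot = 0), "size 1")
})

test_that("population-specific beta recovers the simulated island model", {
  cfg <- simulation_config(populations = data.frame(
    population = paste0("P", 1:5), n_pairs = 0, n_genotyped = 15,
    lat = -35 - (1:5) / 10, lon = 150 + (1:5) / 10),
    n_loci = 5000, F = 0.2, missing_beta = c(1e-6, 1))
  snp <- simulate_snps(cfg, seed = 9)
  beta <- population_specific_fst(snp$genotypes, snp$populations)
  expect_true(all(abs(beta - 0.2) < 0.05))
  expect_error(population_specific_fst(snp$genotypes,
                                       rep("P1", nrow(snp$genotypes))),
               "at least 2")

  # a deme sitting at the ancestral frequencies is the least drifted
  set.seed(33)
  L <- 3000
  p_anc <- runif(L, 0.2, 0.8)
  drift <- function(F) rbeta(L, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  freqs <- rbind(p_anc, drift(0.2), drift(0.2), drift(0.2))
  g <- do.call(rbind, lapply(1:4, function(k)
    matrix(rbinom(12 * L, 2, rep(freqs[k, ], each = 12)), 12, L)))
  rownames(g) <- paste0("i", seq_len(48))
  beta2 <- population_specific_fst(g, rep(paste0("P", 1:4), each = 12))
  expect_equal(which.min(beta2), c(P1 = 1))
})

test_that("AMOVA components match the explicit-haplotype oracle", {
  # tiny fixed instance: 6 individuals, 2 loci, 2 populations
  g <- matrix(c(0L, 1L, 2L, 0L, 2L, 1L,
                1L, 1L, 0L, 2L, 2L, 0L), 6, 2)
  rownames(g) <- paste0("i", 1:6)
  pops <- rep(c("A", "B"), each = 3)
  am <- amova(g, pops, n_perm = 99, seed = 1)
  oracle <- brute_amova_components(g, pops)
  expect_equal(am$table$sigma2[1:3], unname(oracle), tolerance = 1e-12)
  expect_equal(sum(am$table$percent[1:3]), 100, tolerance = 1e-9)

  # randomized instances with missing data
  set.seed(41)
  for (i in 1:3) {
    gr <- random_genotypes(9, 12, miss = 0.1)
    pr <- sample(rep(c("A", "B", "C"), each = 3))
    amr <- amova(gr, pr, n_perm = 99, seed = i)
    expect_equal(amr$table$sigma2[1:3],
                 unname(brute_amova_components(gr, pr)), tolerance = 1e-10)
    expect_gte(amr$p_value, 1 / 100)
    expect_lte(amr$p_value, 1)
  }
  expect_error(amova(g, pops, n_perm = 50), "at least 99")
  expect_error(amova(g, rep("A", 6), n_perm = 99), "at least 2")
})

test_that("Nei distance follows the summed gene-identity formula", {
  g <- rbind(matrix(0L, 4, 6), matrix(2L, 4, 6))
  rownames(g) <- paste0("i", 1:8)
  pops <- rep(c("A", "B"), each = 4)
  expect_equal(nei_distance(g, pops)["A", "B"], Inf)
  expect_equal(nei_distance(rbind(g[1:4, ], g[1:4, ]), pops)["A", "B"], 0)

  set.seed(51)
  g2 <- random_genotypes(16, 25)
  pops2 <- rep(c("A", "B"), each = 8)
  f <- courtpop:::pop_freqs(g2, pops2)
  expect_equal(nei_distance(g2, pops2)["A", "B"],
               unname(brute_nei(f$P["A", ], f$P["B", ])))
})

test_that("Kosman distance counts unshared alleles and is a metric", {
  expect_equal(kosman_distance(rbind(c(0L, 2L), c(0L, 2L)))[1, 2], 0)
  expect_equal(kosman_distance(rbind(c(0L, 0L), c(2L, 2L)))[1, 2], 1)
  expect_equal(kosman_distance(rbind(0L, 1L))[1, 2], 0.5)

  set.seed(61)
  g <- random_genotypes(8, 15)
  D <- kosman_distance(g)
  expect_equal(D, brute_kosman(g))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)

  # no jointly genotyped loci: flagged missing
  g2 <- rbind(c(0L, NA), c(NA, 2L))
  expect_true(is.na(kosman_distance(g2)[1, 2]))
})

test_that("private alleles are credited to exactly one population", {
  # engineered: 4 private alleles across 3 populations
  g <- matrix(1L, 6, 5)
  pops <- rep(c("A", "B", "C"), each = 2)
  # L1: alt only in A; L2: ref only in B; L3: alt only in C; L4: ref only
  # in A; L5: everything everywhere
  g[, 1] <- c(1L, 1L, 0L, 0L, 0L, 0L)
  g[, 2] <- c(2L, 2L, 1L, 2L, 2L, 2L)
  g[, 3] <- c(0L, 0L, 0L, 0L, 0L, 1L)
  g[, 4] <- c(1L, 2L, 2L, 2L, 2L, 2L)
  priv <- private_alleles(g, pops)
  expect_equal(priv, c(A = 2L, B = 1L, C = 1L))
  # an allele in two populations is private to neither
  g2 <- matrix(c(1L, 0L, 1L, 0L, 0L, 0L), 6, 1)
  expect_equal(unname(private_alleles(g2, pops)), c(0L, 0L, 0L))
})

test_that("genotype PCA separates duplicated clusters and matches SVD", {
  g <- rbind(matrix(0L, 5, 20), matrix(2L, 5, 20))
  g[, 1] <- c(rep(0L, 5), rep(2L, 4), 1L)  # tiny wobble to avoid exact ties
  rownames(g) <- paste0("i", 1:10)
  pca <- genotype_pca(g)
  expect_gt(pca$var_frac[1], 0.95)
  expect_gt(min(abs(diff(sort(pca$scores[, 1])[c(5, 6)]))), 1)

  set.seed(71)
  g2 <- random_genotypes(12, 30)
  pca2 <- genotype_pca(g2)
  X <- scale(g2, center = TRUE, scale = FALSE)
  sv <- svd(X)$d
  expect_equal(pca2$var_frac, sv^2 / sum(sv^2), tolerance = 1e-10)

  g2[, 3] <- NA
  expect_warning(genotype_pca(g2), "all-missing")
})

test_that("Mantel statistics match vegan and exhaustive enumeration", {
  set.seed(81)
  n <- 5
  co <- matrix(runif(2 * n, 0, 10), n, 2)
  geo <- as.matrix(dist(co))
  gen <- 0.3 + 1.7 * geo  # exact affine relation: r = 1
  diag(gen) <- 0
  mt <- mantel_test(gen, geo, n_perm = 199, seed = 1)
  expect_equal(mt$r, 1)

  gen2 <- gen + matrix(runif(n * n), n, n)
  gen2 <- (gen2 + t(gen2)) / 2; diag(gen2) <- 0
  mt2 <- mantel_test(gen2, geo, n_perm = 999, seed = 2)
  vg <- vegan::mantel(as.dist(gen2), as.dist(geo), permutations = 99)
  expect_equal(mt2$r, unname(vg$statistic), tolerance = 1e-12)

  # 4 items: p against full enumeration of the 24 relabelings
  n <- 4
  m1 <- as.matrix(dist(matrix(runif(8), 4, 2)))
  m2 <- as.matrix(dist(matrix(runif(8), 4, 2)))
  lt <- lower.tri(m1)
  r_obs <- cor(m1[lt], m2[lt])
  rs <- c()
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4) {
    pp <- c(a, b, cc, d)
    if (length(unique(pp)) < 4) next
    mp <- m2[pp, pp]
    rs <- c(rs, cor(m1[lt], mp[lt]))
  }
  p_exact <- mean(rs >= r_obs - 1e-12)
  ex <- mantel_test(m1, m2, exact = TRUE)
  expect_equal(ex$p, p_exact)
  mc <- mantel_test(m1, m2, n_perm = 9999, seed = 3)
  expect_lt(abs(mc$p - p_exact), 0.03)
})

test_that("isolation by distance is detected on spatially drifting demes", {
  cfg <- simulation_config(populations = data.frame(
    population = paste0("P", 1:6), n_pairs = 0, n_genotyped = 12,
    lat = seq(-35, -37.5, length.out = 6), lon = rep(150, 6)),
    n_loci = 1500, F = 0.06, spatial = TRUE)
  snp <- simulate_snps(cfg, seed = 13)
  ibd <- mantel_ibd(snp$genotypes, snp$populations, snp$coordinates,
                    n_perm = 999, seed = 14)
  expect_gt(ibd$r, 0.5)
  expect_lt(ibd$p, 0.05)
  expect_error(mantel_ibd(snp$genotypes[1:24, ], snp$populations[1:24],
                          snp$coordinates, n_perm = 99), "at least 3")
})

test_that("the population summary table assembles all per-population stats", {
  cfg <- simulation_config(populations = data.frame(
    population = c("A", "B"), n_pairs = 0, n_genotyped = c(10, 8),
    lat = c(-35, -36), lon = c(150, 151)), n_loci = 300)
  snp <- simulate_snps(cfg, seed = 15)
  s <- summarize_populations(snp$genotypes, snp$populations,
                             snp$coordinates)
  expect_setequal(s$population, c("A", "B"))
  expect_equal(s$n, c(10, 8))
  expect_true(all(c("Ho", "He", "Fis", "Fst", "snp_priv", "lat") %in%
                    names(s)))
  expect_true(all(s$Ho >= 0 & s$Ho <= 1))
})
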