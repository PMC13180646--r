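#' Read a dosage genotype matrix from CSV
#'
#' Rows are individuals (first column `id`), remaining columns are biallelic
#' loci coded as copies of the alternate allele (0/1/2; empty or `NA` for
#' missing calls).
#'
#' @param path CSV path.
#' @return integer matrix individuals x loci with `NA` for missing.
#' @export
read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(d)) stop("genotype CSV must have an 'id' column")
  g <- as.matrix(d[, setdiff(names(d), "id"), drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- d$id
  bad <- !(g %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or missing")
  g
}

#' Read biallelic genotypes from a VCF into a dosage matrix
#'
#' Thin wrapper over vcfR: keeps biallelic sites, converts GT fields to
#' alternate-allele dosages.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @return integer matrix individuals x loci with `NA` for missing.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- t(map[gt])
  dos
}

#' Read a population map CSV
#' @param path CSV with columns `individual_id`, `population`, `lat`, `lon`.
#' @return list with `populations` (named character vector, individual to
#'   population) and `coordinates` (data.frame `population`, `lat`, `lon`).
#' @export
read_population_map <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "population")
  if (!all(need %in% names(d))) stop("population map needs columns ",
                                     paste(need, collapse = ", "))
  pops <- stats::setNames(d$population, d$individual_id)
  coords <- NULL
  if (all(c("lat", "lon") %in% names(d)))
    coords <- unique(d[, c("population", "lat", "lon")])
  list(populations = pops, coordinates = coords)
}

#' Read per-locus metadata
#' @param path CSV with columns `locus_id`, `reproducibility`, `call_rate`.
#' @return data.frame of metadata.
#' @export
read_locus_metadata <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "reproducibility", "call_rate")
  if (!all(need %in% names(d))) stop("locus metadata needs columns ",
                                     paste(need, collapse = ", "))
  d
}

#' Sequential locus filtering by reproducibility, call rate and MAF
#'
#' Applies the three marker-quality filters in order: (1) reproducibility
#' (the proportion of technical replicate assay pairs with a consistent
#' marker score) at `repro_min`; (2) call rate (the proportion of samples
#' with a non-missing genotype call) at `callrate_min`; (3) minor-allele
#' frequency at `maf_min` -- the published threshold of 0.02 is stated as a
#' minor-allele *count*, which is treated here as a frequency since a
#' fractional count is not meaningful (the report notes this). Loci at or
#' above each threshold are kept. MAF is computed from the genotypes
#' surviving the first two steps.
#'
#' @param genotypes dosage matrix individuals x loci.
#' @param metadata data.frame with `locus_id`, `reproducibility`,
#'   `call_rate` matching the matrix columns (by `locus_id` when column
#'   names exist, else by position).
#' @param repro_min,callrate_min,maf_min thresholds in `[0, 1]`
#'   (defaults 0.98, 0.95, 0.02).
#' @return list with `genotypes` (filtered matrix) and `report` (data.frame
#'   `step`, `removed`, `remaining`, plus attributes `missing_pct` and
#'   `maf_note`).
#' @export
filter_loci <- function(genotypes, metadata,
                        repro_min = 0.98, callrate_min = 0.95,
                        maf_min = 0.02) {
  stopifnot(repro_min >= 0, repro_min <= 1,
            callrate_min >= 0, callrate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  L0 <- ncol(genotypes)
  if (!is.null(colnames(genotypes)) && "locus_id" %in% names(metadata)) {
    metadata <- metadata[match(colnames(genotypes), metadata$locus_id), ]
  }
  if (nrow(metadata) != L0)
    stop("metadata does not match the genotype matrix loci")
  keep1 <- metadata$reproducibility >= repro_min
  g1 <- genotypes[, keep1, drop = FALSE]
  keep2 <- metadata$call_rate[keep1] >= callrate_min
  g2 <- g1[, keep2, drop = FALSE]
  p <- colMeans(g2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep3 <- !is.na(maf) & maf >= maf_min
  g3 <- g2[, keep3, drop = FALSE]
  if (ncol(g3) == 0)
    stop("all loci removed; attrition: reproducibility -", sum(!keep1),
         ", call rate -", sum(!keep2), ", MAF -", sum(!keep3))
  report <- data.frame(
    step = c("input", "reproducibility", "call_rate", "maf"),
    threshold = c(NA, repro_min, callrate_min, maf_min),
    removed = c(0L, sum(!keep1), sum(!keep2), sum(!keep3)),
    remaining = c(L0, ncol(g1), ncol(g2), ncol(g3)))
  attr(report, "missing_pct") <- 100 * mean(is.na(g3))
  attr(report, "maf_note") <-
    "minor-allele count threshold interpreted as minor-allele frequency"
  list(genotypes = g3, report = report)
}

# per-population allele frequencies, sample sizes and observed het
# returns r x L matrices P (alt freq), N (individuals genotyped), H (obs het)
pop_freqs <- function(genotypes, populations) {
  pops <- sort(unique(populations))
  P <- N <- H <- matrix(NA_real_, length(pops), ncol(genotypes),
                        dimnames = list(pops, colnames(genotypes)))
  for (k in seq_along(pops)) {
    g <- genotypes[populations == pops[k], , drop = FALSE]
    n <- colSums(!is.na(g))
    N[k, ] <- n
    P[k, ] <- ifelse(n > 0, colMeans(g, na.rm = TRUE) / 2, NA)
    H[k, ] <- ifelse(n > 0, colMeans(g == 1L, na.rm = TRUE), NA)
  }
  list(pops = pops, P = P, N = N, H = H)
}

#' Per-population heterozygosities and inbreeding coefficients
#'
#' Observed heterozygosity H_O is the proportion of heterozygous calls among
#' non-missing genotypes. Expected heterozygosity uses the sample-size
#' corrected gene-diversity estimator
#' `Hs = n/(n-1) * (1 - p^2 - q^2 - Ho/(2n))` per locus, averaged over loci.
#' The inbreeding coefficient is `F_IS = 1 - Ho/Hs` on the per-population
#' averages (NA when Hs is 0, i.e. a population monomorphic at every usable
#' locus). Loci with fewer than two genotyped individuals in a population
#' are skipped for that population.
#'
#' @param genotypes dosage matrix.
#' @param populations named vector mapping individual id to population (or
#'   a vector aligned with matrix rows).
#' @return data.frame `population`, `n`, `Ho`, `He`, `Fis`, `n_loci`.
#' @export
heterozygosities <- function(genotypes, populations) {
  populations <- align_pops(genotypes, populations)
  f <- pop_freqs(genotypes, populations)
  out <- lapply(seq_along(f$pops), function(k) {
    n <- f$N[k, ]; p <- f$P[k, ]; ho <- f$H[k, ]
    use <- n >= 2
    n <- n[use]; p <- p[use]; ho <- ho[use]
    hs <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
    Ho <- mean(ho); He <- mean(hs)
    data.frame(population = f$pops[k],
               n = sum(populations == f$pops[k]),
               Ho = Ho, He = He,
               Fis = if (He > 0) 1 - Ho / He else NA_real_,
               n_loci = sum(use))
  })
  do.call(rbind, out)
}

align_pops <- function(genotypes, populations) {
  if (!is.null(names(populations)) && !is.null(rownames(genotypes))) {
    if (!all(rownames(genotypes) %in% names(populations)))
      stop("population assignment missing for some individuals")
    populations <- populations[rownames(genotypes)]
  }
  if (length(populations) != nrow(genotypes))
    stop("populations must align with the genotype matrix rows")
  as.character(populations)
}

# Weir-Cockerham (1984) variance components per locus for a set of
# populations; returns per-locus a, b, c vectors
wc_components <- function(P, N, H) {
  r <- nrow(P)
  ok <- colSums(N >= 1) == r & colSums(!is.na(P)) == r
  P <- P[, ok, drop = FALSE]; N <- N[, ok, drop = FALSE]
  H <- H[, ok, drop = FALSE]
  nbar <- colMeans(N)
  nc <- (colSums(N) - colSums(N^2) / colSums(N)) / (r - 1)
  pbar <- colSums(N * P) / colSums(N)
  s2 <- colSums(N * sweep(P, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(N * H) / colSums(N)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c, ok = ok)
}

wc_theta <- function(P, N, H) {
  w <- wc_components(P, N, H)
  sum(w$a) / sum(w$a + w$b + w$c)
}

#' Pairwise Weir-Cockerham F_ST between populations
#'
#' Per-locus theta components (Weir & Cockerham 1984) are combined across
#' loci as the ratio of summed variance components; the multilocus estimate
#' can be negative and is reported as computed. Significance per pair comes
#' from bootstrapping loci: the p-value is the (add-one corrected)
#' proportion of bootstrap estimates at or below zero, a one-sided test of
#' differentiation.
#'
#' @param genotypes dosage matrix.
#' @param populations population assignment (see [heterozygosities()]).
#' @param n_boot bootstrap replicates over loci (0 skips p-values;
#'   default 1000).
#' @param seed optional seed for the bootstrap.
#' @return list with `fst` (symmetric matrix, zero diagonal) and `p`
#'   (matrix of bootstrap p-values, NA when `n_boot = 0`).
#' @export
pairwise_fst <- function(genotypes, populations, n_boot = 1000, seed = NULL) {
  populations <- align_pops(genotypes, populations)
  if (!is.null(seed)) set.seed(seed)
  tab <- table(populations)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding population(s) of size 1: ",
            paste(small, collapse = ", "))
    keep <- !(populations %in% small)
    genotypes <- genotypes[keep, , drop = FALSE]
    populations <- populations[keep]
  }
  f <- pop_freqs(genotypes, populations)
  r <- length(f$pops)
  if (r < 2) stop("need at least 2 populations of size >= 2")
  fst <- matrix(0, r, r, dimnames = list(f$pops, f$pops))
  pmat <- matrix(NA_real_, r, r, dimnames = list(f$pops, f$pops))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    idx <- c(i, j)
    w <- wc_components(f$P[idx, , drop = FALSE], f$N[idx, , drop = FALSE],
                       f$H[idx, , drop = FALSE])
    theta <- sum(w$a) / sum(w$a + w$b + w$c)
    fst[i, j] <- fst[j, i] <- theta
    if (n_boot > 0) {
      L <- length(w$a)
      abc <- w$a + w$b + w$c
      le0 <- 0L
      done <- 0L
      while (done < n_boot) {  # chunked to bound memory
        nb <- min(1000L, n_boot - done)
        idx <- matrix(sample.int(L, L * nb, replace = TRUE), L, nb)
        th <- colSums(matrix(w$a[idx], L, nb)) /
          colSums(matrix(abc[idx], L, nb))
        le0 <- le0 + sum(!is.na(th) & th <= 0)
        done <- done + nb
      }
      pmat[i, j] <- pmat[j, i] <- (1 + le0) / (n_boot + 1)
    }
  }
  list(fst = fst, p = pmat)
}

#' Population-specific F_ST (allele-matching beta estimates)
#'
#' The Weir-Goudet population-specific estimator: for each population the
#' within-population allele-matching proportion `M_i` (the probability that
#' two distinct alleles drawn from the population match, unbiased for
#' sample size) is compared with the mean between-population matching `M_B`
#' over all population pairs, `beta_i = (M_i - M_B) / (1 - M_B)` with
#' multilocus averaging of the matching proportions before the ratio.
#' Values can be negative (a population less inbred than the average
#' between-population comparison).
#'
#' @param genotypes dosage matrix.
#' @param populations population assignment.
#' @return named numeric vector of per-population beta estimates.
#' @export
population_specific_fst <- function(genotypes, populations) {
  populations <- align_pops(genotypes, populations)
  f <- pop_freqs(genotypes, populations)
  r <- length(f$pops)
  if (r < 2) stop("need at least 2 populations")
  # within-population matching, unbiased: x alt alleles of 2n total
  X <- f$P * 2 * f$N
  tot <- 2 * f$N
  Mw <- (X * (X - 1) + (tot - X) * (tot - X - 1)) / (tot * (tot - 1))
  Mw[f$N < 1] <- NA
  # between-population matching averaged over pairs, per locus
  Mb <- matrix(0, 1, ncol(f$P))
  npair <- matrix(0, 1, ncol(f$P))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    m <- f$P[i, ] * f$P[j, ] + (1 - f$P[i, ]) * (1 - f$P[j, ])
    use <- !is.na(m)
    Mb[use] <- Mb[use] + m[use]
    npair[use] <- npair[use] + 1
  }
  MB <- as.numeric(Mb / npair)
  MBbar <- mean(MB, na.rm = TRUE)
  beta <- vapply(seq_len(r), function(k) {
    (mean(Mw[k, ], na.rm = TRUE) - MBbar) / (1 - MBbar)
  }, numeric(1))
  stats::setNames(beta, f$pops)
}

# squared-distance summaries for AMOVA: for each pair of individuals the
# sum of squared allele differences over all four cross-haplotype pairs
# (phase-free: 2g_u + 2g_v - 2 g_u g_v per locus), pairwise-deleting
# missing loci; and per individual the heterozygous-locus count (the
# squared distance between its own two haplotypes)
amova_distances <- function(genotypes) {
  N <- nrow(genotypes)
  G <- genotypes
  C <- matrix(0, N, N)
  for (u in seq_len(N - 1)) {
    gu <- G[u, ]
    for (v in (u + 1):N) {
      gv <- G[v, ]
      ok <- !is.na(gu) & !is.na(gv)
      C[u, v] <- C[v, u] <- sum(2 * gu[ok] + 2 * gv[ok] - 2 * gu[ok] * gv[ok])
    }
  }
  w <- rowSums(G == 1L, na.rm = TRUE)
  list(C = C, w = as.numeric(w))
}

amova_components <- function(C, w, populations) {
  N <- length(w)
  pops <- unique(populations)
  r <- length(pops)
  nk <- as.numeric(table(factor(populations, levels = pops)))
  # haplotype-level sums of squared distances
  ssd_t <- (sum(C) / 2 + sum(w)) / (2 * N)
  ssd_wp <- 0
  for (k in seq_len(r)) {
    idx <- populations == pops[k]
    ssd_wp <- ssd_wp + (sum(C[idx, idx]) / 2 + sum(w[idx])) / (2 * nk[k])
  }
  ssd_wi <- sum(w) / 2
  ssd_ai <- ssd_wp - ssd_wi
  ssd_ap <- ssd_t - ssd_wp
  df_ap <- r - 1; df_ai <- N - r; df_wi <- N
  ms_wi <- ssd_wi / df_wi
  ms_ai <- ssd_ai / df_ai
  ms_ap <- ssd_ap / df_ap
  nc_hap <- 2 * (N - sum(nk^2) / N) / (r - 1)
  sig_w <- ms_wi
  sig_b <- (ms_ai - ms_wi) / 2
  sig_a <- (ms_ap - ms_ai) / nc_hap
  list(ssd = c(among_pops = ssd_ap, among_ind = ssd_ai, within_ind = ssd_wi,
               total = ssd_t),
       df = c(df_ap, df_ai, df_wi),
       sigma2 = c(among_pops = sig_a, among_ind = sig_b, within_ind = sig_w))
}

#' Distance-based AMOVA on SNP dosages
#'
#' Hierarchical analysis of molecular variance with three strata: among
#' populations, among individuals within populations, and within
#' individuals. Squared Euclidean distances between allele vectors are
#' computed from dosages without requiring phase (the sum of squared allele
#' differences over the four cross-haplotype pairs of two individuals is
#' phase-invariant for biallelic loci); missing loci are pairwise-deleted.
#' The within-individuals component comes from heterozygous-locus counts.
#' Significance of population structure is assessed by permuting individuals
#' among populations and recomputing the among-population component,
#' `p = (1 + #(permuted >= observed)) / (n_perm + 1)`. Negative variance
#' components are reported as computed.
#'
#' @param genotypes dosage matrix.
#' @param populations population assignment.
#' @param n_perm permutations for the randomization test (>= 99;
#'   default 1000).
#' @param seed optional seed.
#' @return object of class `amova`: list with `table` (df, SSD, MS, sigma2,
#'   percent per stratum), `phi` (`phi_st`, `phi_is`, `phi_it`),
#'   `p_value`, `n_perm`.
#' @export
amova <- function(genotypes, populations, n_perm = 1000, seed = NULL) {
  populations <- align_pops(genotypes, populations)
  if (length(unique(populations)) < 2) stop("need at least 2 populations")
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  d <- amova_distances(genotypes)
  obs <- amova_components(d$C, d$w, populations)
  sig <- obs$sigma2
  total <- sum(sig)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- amova_components(d$C, d$w, sample(populations))
    if (perm$sigma2[["among_pops"]] >= sig[["among_pops"]]) ge <- ge + 1L
  }
  p <- (1 + ge) / (n_perm + 1)
  tab <- data.frame(
    stratum = c("among_populations", "among_individuals", "within_individuals",
                "total"),
    df = c(obs$df, sum(obs$df)),
    SSD = as.numeric(obs$ssd),
    sigma2 = c(sig, total),
    percent = 100 * c(sig, total) / total)
  phi <- c(phi_st = sig[["among_pops"]] / total,
           phi_is = sig[["among_ind"]] / (sig[["among_ind"]] + sig[["within_ind"]]),
           phi_it = (sig[["among_pops"]] + sig[["among_ind"]]) / total)
  structure(list(table = tab, phi = phi, p_value = p, n_perm = n_perm),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA (", x$n_perm, "permutations )\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Phi_ST = %.4f (p = %.4g)\n", x$phi[["phi_st"]], x$p_value))
  invisible(x)
}

#' Nei (1972) standard genetic distance between populations
#'
#' `D = -ln( Jxy / sqrt(Jx * Jy) )` where the gene-identity terms `Jx`,
#' `Jy`, `Jxy` are summed over loci (and both alleles) *before* the ratio.
#' Populations sharing no alleles give `Inf`.
#'
#' @param genotypes dosage matrix.
#' @param populations population assignment.
#' @return symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(genotypes, populations) {
  populations <- align_pops(genotypes, populations)
  f <- pop_freqs(genotypes, populations)
  r <- length(f$pops)
  if (r < 2) stop("need at least 2 populations")
  D <- matrix(0, r, r, dimnames = list(f$pops, f$pops))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    px <- f$P[i, ]; py <- f$P[j, ]
    ok <- !is.na(px) & !is.na(py)
    if (!any(ok)) stop("populations ", f$pops[i], " and ", f$pops[j],
                       " share no genotyped loci")
    jx <- sum(px[ok]^2 + (1 - px[ok])^2)
    jy <- sum(py[ok]^2 + (1 - py[ok])^2)
    jxy <- sum(px[ok] * py[ok] + (1 - px[ok]) * (1 - py[ok]))
    D[i, j] <- D[j, i] <- if (jxy == 0) Inf else -log(jxy / sqrt(jx * jy))
  }
  D
}

#' Kosman inter-individual genetic distance
#'
#' Per locus, the distance between two diploid genotypes is one minus half
#' the number of shared alleles: 0 for identical genotypes, 0.5 for a
#' heterozygote vs either homozygote, 1 for opposite homozygotes (for
#' biallelic dosages this is `|g_u - g_v| / 2`). The individual distance is
#' the average over loci genotyped in both individuals; pairs with no
#' jointly genotyped locus are `NA`.
#'
#' @param genotypes dosage matrix.
#' @return symmetric matrix of distances in `[0, 1]` with zero diagonal.
#' @export
kosman_distance <- function(genotypes) {
  N <- nrow(genotypes)
  if (N < 2) stop("need at least 2 individuals")
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(N))
  D <- matrix(0, N, N, dimnames = list(ids, ids))
  for (u in seq_len(N - 1)) {
    gu <- genotypes[u, ]
    for (v in (u + 1):N) {
      gv <- genotypes[v, ]
      ok <- !is.na(gu) & !is.na(gv)
      D[u, v] <- D[v, u] <-
        if (any(ok)) mean(abs(gu[ok] - gv[ok]) / 2) else NA_real_
    }
  }
  D
}

#' Mean of an individual distance matrix over population pairs
#'
#' @param distances symmetric (or symmetrized) individual matrix.
#' @param populations named vector individual -> population.
#' @return data.frame `pop_a`, `pop_b`, `mean`, `se`, `n_pairs`
#'   (within-population rows have `pop_a == pop_b`).
#' @export
population_pair_means <- function(distances, populations) {
  ids <- rownames(distances)
  pop <- populations[ids]
  if (anyNA(pop)) stop("population assignment missing for some individuals")
  pops <- sort(unique(pop))
  rows <- list()
  for (i in seq_along(pops)) for (j in i:length(pops)) {
    ia <- which(pop == pops[i]); ib <- which(pop == pops[j])
    if (i == j) {
      sub <- distances[ia, ia, drop = FALSE]
      vals <- sub[upper.tri(sub)]
    } else {
      vals <- as.numeric(distances[ia, ib, drop = FALSE])
    }
    vals <- vals[!is.na(vals)]
    rows[[length(rows) + 1]] <- data.frame(
      pop_a = pops[i], pop_b = pops[j],
      mean = if (length(vals)) mean(vals) else NA_real_,
      se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
      n_pairs = length(vals), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Private-allele counts per population
#'
#' For each locus and each allele (reference and alternate), the allele is
#' private to a population when it is observed (on non-missing genotypes) in
#' that population only. The per-population count is the number of loci
#' carrying at least one allele private to it; a locus contributes at most
#' once per allele.
#'
#' @param genotypes dosage matrix.
#' @param populations population assignment.
#' @return named integer vector of counts per population.
#' @export
private_alleles <- function(genotypes, populations) {
  populations <- align_pops(genotypes, populations)
  pops <- sort(unique(populations))
  if (length(pops) < 2) stop("need at least 2 populations")
  hasRef <- hasAlt <- matrix(FALSE, length(pops), ncol(genotypes))
  for (k in seq_along(pops)) {
    g <- genotypes[populations == pops[k], , drop = FALSE]
    hasRef[k, ] <- colSums(g < 2L, na.rm = TRUE) > 0
    hasAlt[k, ] <- colSums(g > 0L, na.rm = TRUE) > 0
  }
  counts <- stats::setNames(integer(length(pops)), pops)
  for (mat in list(hasRef, hasAlt)) {
    priv <- colSums(mat) == 1
    if (any(priv)) {
      owner <- apply(mat[, priv, drop = FALSE], 2, which)
      tab <- table(factor(pops[owner], levels = pops))
      counts <- counts + as.integer(tab)
    }
  }
  counts
}

#' Principal component analysis of genotypes
#'
#' Missing dosages are mean-imputed per locus, columns centered, and the
#' decomposition done by SVD. Loci that are entirely missing (or constant
#' after imputation) are dropped with a warning.
#'
#' @param genotypes dosage matrix.
#' @param n_comp number of components to return scores for (default 10).
#' @return list with `scores` (individuals x components), `var_frac`
#'   (per-component fraction of total variance), `sdev`.
#' @export
genotype_pca <- function(genotypes, n_comp = 10) {
  if (nrow(genotypes) < 3) stop("need at least 3 individuals")
  G <- genotypes
  mu <- colMeans(G, na.rm = TRUE)
  allmiss <- !is.finite(mu)
  if (any(allmiss)) {
    warning("dropping ", sum(allmiss), " all-missing locus/loci")
    G <- G[, !allmiss, drop = FALSE]
    mu <- mu[!allmiss]
  }
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- mu[j]
  }
  pc <- stats::prcomp(G, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_comp, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_frac = var_frac, sdev = pc$sdev)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles, with significance from
#' permuting the rows/columns of the second matrix. For small matrices
#' `exact = TRUE` enumerates all permutations instead of sampling.
#'
#' @param m1,m2 symmetric distance matrices with matching dimensions.
#' @param n_perm random permutations (default 10000).
#' @param seed optional seed.
#' @param exact enumerate all `n!` permutations (requires `n <= 8`).
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 10000, seed = NULL, exact = FALSE) {
  stopifnot(identical(dim(m1), dim(m2)))
  n <- nrow(m1)
  if (n < 3) stop("need at least 3 items")
  lt <- lower.tri(m1)
  r_obs <- stats::cor(m1[lt], m2[lt])
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_perms(n)
    rs <- vapply(perms, function(pp) {
      mp <- m2[pp, pp]
      stats::cor(m1[lt], mp[lt])
    }, numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, n_perm = length(perms)))
  }
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    pp <- sample.int(n)
    mp <- m2[pp, pp]
    if (stats::cor(m1[lt], mp[lt]) >= r_obs - 1e-12) ge <- ge + 1L
  }
  list(r = r_obs, p = (1 + ge) / (n_perm + 1), n_perm = n_perm)
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos)
  }
  out
}

#' Isolation by distance: Mantel test of linearized F_ST vs geography
#'
#' Genetic distances between populations are pairwise Weir-Cockerham F_ST
#' linearized as `F/(1-F)`; geographic distances are great-circle
#' (haversine) kilometers from population latitude/longitude (a planar
#' Euclidean option on the raw coordinates is available for strict
#' replication of toolchains that treat degrees as planar).
#'
#' @param genotypes dosage matrix.
#' @param populations population assignment.
#' @param coordinates data.frame `population`, `lat`, `lon`.
#' @param n_perm Mantel permutations (default 10000).
#' @param seed optional seed.
#' @param method `"haversine"` (default) or `"euclidean"`.
#' @return list with `r`, `p`, `genetic` and `geographic` distance matrices.
#' @export
mantel_ibd <- function(genotypes, populations, coordinates,
                       n_perm = 10000, seed = NULL,
                       method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  populations <- align_pops(genotypes, populations)
  pops <- sort(unique(populations))
  if (length(pops) < 3) stop("need at least 3 populations")
  pf <- pairwise_fst(genotypes, populations, n_boot = 0)
  lin <- pf$fst / (1 - pf$fst)
  co <- coordinates[match(pops, coordinates$population), ]
  if (anyNA(co$lat)) stop("coordinates missing for some populations")
  r <- length(pops)
  geo <- matrix(0, r, r, dimnames = list(pops, pops))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    geo[i, j] <- geo[j, i] <- if (method == "haversine") {
      geosphere::distHaversine(c(co$lon[i], co$lat[i]),
                               c(co$lon[j], co$lat[j])) / 1000
    } else {
      sqrt((co$lat[i] - co$lat[j])^2 + (co$lon[i] - co$lon[j])^2)
    }
  }
  mt <- mantel_test(lin, geo, n_perm = n_perm, seed = seed)
  list(r = mt$r, p = mt$p, n_perm = n_perm, genetic = lin, geographic = geo)
}

#' Per-population summary table
#'
#' Combines sample sizes, heterozygosities, F_IS, population-specific F_ST
#' and private-allele counts into one table per population, mirroring the
#' usual population-genetics summary layout.
#'
#' @param genotypes dosage matrix.
#' @param populations population assignment.
#' @param coordinates optional data.frame `population`, `lat`, `lon`.
#' @return data.frame, one row per population.
#' @export
summarize_populations <- function(genotypes, populations, coordinates = NULL) {
  het <- heterozygosities(genotypes, populations)
  beta <- population_specific_fst(genotypes, populations)
  priv <- private_alleles(genotypes, populations)
  out <- het
  out$Fst <- beta[out$population]
  out$snp_priv <- priv[out$population]
  if (!is.null(coordinates)) {
    m <- match(out$population, coordinates$population)
    out$lat <- coordinates$lat[m]
    out$lon <- coordinates$lon[m]
  }
  out
}
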