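#' Recompute the field-study statistics from a local copy of its data
#'
#' Runs the complete analysis against a locally downloaded copy of the
#' deposited dune-fly dataset (figshare DOI 10.6084/m9.figshare.31669183,
#' converted to this package's CSV dialects) and returns the headline
#' quantities: locus-filter attrition and residual missingness, the
#' per-population summary table, AMOVA percentages and Phi_ST, the pairwise
#' F_ST range, the PCA variance explained by the first two components, the
#' interaction-time summaries, the number of composite behavioral states,
#' the prevalence-filtered behavior set, the mean between-population KL
#' divergences and the courtship-vs-genetic R^2. Nothing is downloaded:
#' the data directory must already contain `genotypes.csv` (raw dosage
#' matrix), `locus_metadata.csv`, `population_map.csv` and `events.csv`
#' (scored behavior logs for the three filmed populations).
#'
#' @param dir directory holding the four CSV files.
#' @param edge_B permutations for the transition edge test.
#' @param seed seed for all resampling.
#' @return list of computed quantities (see Details).
#' @export
reproduce_study <- function(dir, edge_B = 1000, seed = 1) {
  need <- c("genotypes.csv", "locus_metadata.csv", "population_map.csv",
            "events.csv")
  paths <- file.path(dir, need)
  if (!all(file.exists(paths)))
    stop("deposited-data directory is missing: ",
         paste(need[!file.exists(paths)], collapse = ", "))
  g <- read_genotypes_csv(paths[1])
  meta <- read_locus_metadata(paths[2])
  pm <- read_population_map(paths[3])
  fl <- filter_loci(g, meta)
  gf <- fl$genotypes
  summ <- summarize_populations(gf, pm$populations, pm$coordinates)
  am <- amova(gf, pm$populations, n_perm = 1000, seed = seed)
  pf <- pairwise_fst(gf, pm$populations, n_boot = 1000, seed = seed)
  pca <- genotype_pca(gf)
  ibd <- mantel_ibd(gf, pm$populations, pm$coordinates,
                    n_perm = 10000, seed = seed)
  kos <- kosman_distance(gf)

  # behavior side: the three filmed populations
  vocab <- state_vocabulary("full")
  ev <- load_event_log(paths[4], ethogram = attr(vocab, "ethogram"))
  metrics <- courtship_metrics(ev)
  totals <- unique(metrics[, c("pair_id", "total_duration_s")])
  occ <- occurrence_proportions(ev)
  prevalent <- prevalence_filter(occ, threshold = 0.5,
                                 exclude = c("Face-off", "Chasing"))
  mats <- pair_transition_matrices(ev)
  n_states <- nrow(mats[[1]])
  pair_pops <- stats::setNames(
    ev$population[match(names(mats), ev$pair_id)], names(mats))
  D <- pairwise_courtship_distances(mats, pseudocount = 1)
  kl_means <- population_divergence_summary((D + t(D)) / 2, pair_pops)
  fit <- courtship_vs_genetic(D, kos, pair_pops, pm$populations)

  list(n_loci_raw = ncol(g), n_loci_filtered = ncol(gf),
       missing_pct = attr(fl$report, "missing_pct"),
       population_summary = summ,
       amova_among_pct = am$table$percent[1],
       amova_phi_st = unname(am$phi["phi_st"]),
       amova_p = am$p_value,
       pairwise_fst_range = range(pf$fst[upper.tri(pf$fst)]),
       pca_var_frac_12 = sum(pca$var_frac[1:2]),
       mantel_r = ibd$r, mantel_p = ibd$p,
       median_interaction_s = stats::median(totals$total_duration_s),
       mean_interaction_s = mean(totals$total_duration_s),
       n_states = n_states,
       prevalent_behaviors = prevalent,
       kl_means = kl_means,
       r_squared = fit$r_squared)
}
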