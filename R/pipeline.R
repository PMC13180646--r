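#' Per-pair transition-count matrices from an event log
#'
#' Derives the male and female composite-state sequences of every courting
#' pair and counts within-individual transitions, returning one matrix per
#' pair on a shared state order. Two modes reflect two readings of how a
#' pair's chain should be assembled: `"separate"` (default) counts
#' transitions within each actor's own sequence and sums the two actors'
#' matrices, so no male-to-female transitions exist; `"interleaved"` merges
#' the two actors' states by onset time into one chain before counting, so
#' cross-sex transitions appear.
#'
#' @param events validated event data.frame.
#' @param states optional fixed state order (default: union over pairs,
#'   sentinels included).
#' @param mode `"separate"` or `"interleaved"`.
#' @return named list of transition-count matrices, one per pair.
#' @export
pair_transition_matrices <- function(events, states = NULL,
                                     mode = c("separate", "interleaved")) {
  mode <- match.arg(mode)
  pairs <- unique(events$pair_id)
  seqs <- lapply(pairs, function(p) {
    m <- derive_state_sequence(events, p, "male")
    f <- derive_state_sequence(events, p, "female")
    if (mode == "interleaved") list(interleave_pair(m, f)) else list(m, f)
  })
  names(seqs) <- pairs
  if (is.null(states))
    states <- sort(unique(unlist(lapply(seqs, function(x)
      unlist(lapply(x, `[[`, "states"))))), method = "radix")
  out <- lapply(seqs, function(x) count_transitions(x, states = states))
  names(out) <- pairs
  out
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.character(h), basename(paths))
}

#' Run the analysis pipeline
#'
#' Desk-scale orchestration of the full analysis: simulate paired behavior
#' and SNP data, filter loci, compute the population-genetic statistics,
#' the courtship metrics, the transition networks and the
#' courtship-vs-genetic comparison, writing tidy CSV outputs plus a run
#' manifest (JSON with the seed, the parameters of every stochastic stage
#' and an md5 checksum of every file written). Later stages read the
#' in-memory results of earlier ones; `stages` must therefore be a prefix-
#' closed subset of the full order.
#'
#' @param out_dir output directory (created if needed).
#' @param stages character vector among `simulate`, `filter`, `popgen`,
#'   `ethogram`, `transitions`, `divergence`, `report` (default: all).
#' @param config a [simulation_config()].
#' @param seed integer seed for every stochastic stage.
#' @param edge_B permutations for the transition edge test (default 1000).
#' @param amova_perm AMOVA randomization permutations (default 1000).
#' @param fst_boot bootstrap replicates for pairwise F_ST p-values
#'   (default 1000).
#' @param mantel_perm Mantel permutations (default 10000).
#' @param alpha edge-retention significance level (default 0.05).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("simulate", "filter", "popgen",
                                    "ethogram", "transitions", "divergence",
                                    "report"),
                         config = simulation_config(),
                         seed = 1,
                         edge_B = 1000, amova_perm = 1000,
                         fst_boot = 1000, mantel_perm = 10000,
                         alpha = 0.05) {
  known <- c("simulate", "filter", "popgen", "ethogram", "transitions",
             "divergence", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  files <- character()
  put <- function(name) file.path(out_dir, name)

  if ("simulate" %in% stages) {
    beh <- simulate_behavior(config, seed = seed)
    snp <- simulate_snps(config, seed = seed + 1)
    write_event_log(beh$events, put("events.csv"))
    write_genotypes_csv(snp$genotypes, put("genotypes.csv"))
    utils::write.csv(snp$metadata, put("locus_metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(individual_id = names(snp$populations),
                 population = snp$populations,
                 lat = snp$coordinates$lat[match(snp$populations,
                                                 snp$coordinates$population)],
                 lon = snp$coordinates$lon[match(snp$populations,
                                                 snp$coordinates$population)]),
      put("population_map.csv"), row.names = FALSE)
    files <- c(files, put(c("events.csv", "genotypes.csv",
                            "locus_metadata.csv", "population_map.csv")))
    res$behavior <- beh; res$snps <- snp
  }
  if ("filter" %in% stages) {
    fl <- filter_loci(res$snps$genotypes, res$snps$metadata)
    utils::write.csv(fl$report, put("filter_report.csv"), row.names = FALSE)
    write_genotypes_csv(fl$genotypes, put("genotypes_filtered.csv"))
    files <- c(files, put(c("filter_report.csv", "genotypes_filtered.csv")))
    res$filtered <- fl
  }
  if ("popgen" %in% stages) {
    g <- res$filtered$genotypes
    pop <- res$snps$populations
    coords <- res$snps$coordinates
    summ <- summarize_populations(g, pop, coords)
    pf <- pairwise_fst(g, pop, n_boot = fst_boot, seed = seed + 2)
    am <- amova(g, pop, n_perm = amova_perm, seed = seed + 3)
    nei <- nei_distance(g, pop)
    ibd <- mantel_ibd(g, pop, coords, n_perm = mantel_perm, seed = seed + 4)
    pca <- genotype_pca(g)
    kos <- kosman_distance(g)
    utils::write.csv(summ, put("population_summary.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(pf$fst), put("pairwise_fst.csv"))
    utils::write.csv(as.data.frame(pf$p), put("pairwise_fst_p.csv"))
    utils::write.csv(am$table, put("amova.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(nei), put("nei_distance.csv"))
    jsonlite::write_json(
      list(mantel_r = ibd$r, mantel_p = ibd$p,
           amova_phi_st = unname(am$phi["phi_st"]), amova_p = am$p_value,
           pca_var_frac_12 = sum(pca$var_frac[1:2])),
      put("popgen_summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, put(c("population_summary.csv", "pairwise_fst.csv",
                            "pairwise_fst_p.csv", "amova.csv",
                            "nei_distance.csv", "popgen_summary.json")))
    res$popgen <- list(summary = summ, fst = pf, amova = am, nei = nei,
                       ibd = ibd, pca = pca, kosman = kos)
  }
  if ("ethogram" %in% stages) {
    ev <- res$behavior$events
    metrics <- courtship_metrics(ev)
    occ <- occurrence_proportions(ev)
    prev <- prevalence_filter(occ, threshold = 0.5)
    utils::write.csv(metrics, put("courtship_metrics.csv"), row.names = FALSE)
    utils::write.csv(occ, put("occurrence_proportions.csv"))
    utils::write.csv(data.frame(behavior = prev),
                     put("prevalent_behaviors.csv"), row.names = FALSE)
    files <- c(files, put(c("courtship_metrics.csv",
                            "occurrence_proportions.csv",
                            "prevalent_behaviors.csv")))
    res$ethogram <- list(metrics = metrics, occurrence = occ,
                         prevalent = prev)
  }
  if ("transitions" %in% stages) {
    ev <- res$behavior$events
    pair_pops <- res$behavior$pair_populations
    mats <- pair_transition_matrices(ev)
    states <- rownames(mats[[1]])
    nets <- list()
    for (p in unique(pair_pops)) {
      pids <- names(pair_pops)[pair_pops == p]
      seqs <- unlist(lapply(pids, function(pid) list(
        derive_state_sequence(ev, pid, "male"),
        derive_state_sequence(ev, pid, "female"))), recursive = FALSE)
      net <- permutation_edge_test(seqs, B = edge_B, alpha = alpha,
                                   states = states, seed = seed + 5)
      write_transition_matrix(net$counts,
                              put(sprintf("transitions_%s.csv", p)))
      write_edge_list(net, put(sprintf("edges_%s.csv", p)))
      files <- c(files, put(sprintf(c("transitions_%s.csv", "edges_%s.csv"), p)))
      nets[[p]] <- net
    }
    res$transitions <- list(pair_matrices = mats, networks = nets)
  }
  if ("divergence" %in% stages) {
    D <- pairwise_courtship_distances(res$transitions$pair_matrices)
    summ <- population_divergence_summary((D + t(D)) / 2,
                                          res$behavior$pair_populations)
    geno_pops <- res$snps$populations
    fit <- courtship_vs_genetic(D, res$popgen$kosman,
                                res$behavior$pair_populations, geno_pops)
    utils::write.csv(summ, put("courtship_divergence.csv"), row.names = FALSE)
    write_divergence_link(fit, put("divergence_link.csv"),
                          put("divergence_fit.json"))
    files <- c(files, put(c("courtship_divergence.csv",
                            "divergence_link.csv", "divergence_fit.json")))
    res$divergence <- list(distances = D, summary = summ, fit = fit)
  }
  if ("report" %in% stages) {
    # Table-1-like population summary, occurrence table, per-pair metric
    # table restricted to prevalent behaviors, and the divergence records
    prev <- res$ethogram$prevalent
    tab3 <- res$ethogram$metrics[res$ethogram$metrics$behavior %in% prev, ]
    utils::write.csv(tab3, put("report_metric_table.csv"), row.names = FALSE)
    files <- c(files, put("report_metric_table.csv"))
  }
  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    stages = stages,
    parameters = list(edge_B = edge_B, amova_perm = amova_perm,
                      fst_boot = fst_boot, mantel_perm = mantel_perm,
                      alpha = alpha, eps = config$eps,
                      n_loci = config$n_loci, F = config$F),
    attrition = if (!is.null(res$filtered)) res$filtered$report else NULL,
    files = as.list(md5_of(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$manifest <- manifest
  invisible(res)
}
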