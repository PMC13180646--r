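#' Composite-state vocabularies for the behavior simulator
#'
#' Composite behavioral states are simulated directly as atoms; a
#' decomposition table maps each state back to its constituent behaviors so
#' that simulated sequences can be written out as ordinary behavior event
#' logs. Two presets are provided: `"reduced"`, a 12-state vocabulary (6
#' male, 6 female states) for fast tests; and `"full"`, the 41-state
#' vocabulary of the dune-fly display (including the sentinels and two
#' female wing states outside the core 18-behavior ethogram). State labels
#' are canonical: alphabetically sorted behavior sets joined by `-` plus an
#' actor tag.
#'
#' @param preset `"reduced"` or `"full"`.
#' @return data.frame with columns `state`, `actor` (`"male"`/`"female"`);
#'   attribute `decomposition` (named list state -> behavior vector) and
#'   attribute `ethogram` (an [ethogram_definition()] covering all
#'   constituent behaviors).
#' @export
state_vocabulary <- function(preset = c("reduced", "full")) {
  preset <- match.arg(preset)
  if (preset == "reduced") {
    decomp <- list(
      male = list(c("Face-off"), c("Face-off", "Wing-sweep"),
                  c("Orient"), c("Orient", "Wing-vibrate"),
                  c("Orient", "Wing-flash"), c("Wing-flap")),
      female = list(c("Standing"), c("Walking"),
                    c("Walking", "Wing-flap"), c("Turn"),
                    c("Kick"), c("Standing", "Wing-flap")))
  } else {
    decomp <- list(
      male = list(
        c("Chasing"), c("Chasing", "Wing-flap"),
        c("Face-off"), c("Face-off", "Single-wing"),
        c("Face-off", "Wing-flap"), c("Face-off", "Wing-flash"),
        c("Face-off", "Wing-sweep"), c("Face-off", "Wing-touch"),
        c("Face-off", "Wing-vibrate"),
        c("Orient"), c("Orient", "Single-wing"), c("Orient", "Wing-flap"),
        c("Orient", "Wing-flash"), c("Orient", "Wing-sweep"),
        c("Orient", "Wing-touch"), c("Orient", "Wing-vibrate"),
        c("Single-wing"),
        c("Straddle"), c("Single-wing", "Straddle"),
        c("Straddle", "Wing-flap"), c("Straddle", "Wing-flash"),
        c("Straddle", "Wing-sweep"), c("Straddle", "Wing-touch"),
        c("Straddle", "Wing-vibrate"),
        c("Wing-flap"), c("Wing-vibrate")),
      female = list(
        c("Copulation"), c("Kick"),
        c("Single-wing", "Standing"), c("Single-wing", "Turn"),
        c("Single-wing", "Walking"),
        c("Standing"), c("Turn"), c("Walking"),
        c("Standing", "Wing-flap"), c("Turn", "Wing-flap"),
        c("Walking", "Wing-flap"),
        c("Standing", "Wing-swing"), c("Walking", "Wing-swing")))
  }
  rows <- list()
  dec <- list()
  for (actor in c("male", "female")) {
    for (b in decomp[[actor]]) {
      lab <- state_label(b, actor)
      rows[[length(rows) + 1]] <- data.frame(state = lab, actor = actor,
                                             stringsAsFactors = FALSE)
      dec[[lab]] <- sort(b, method = "radix")
    }
  }
  out <- do.call(rbind, rows)
  eth <- ethogram_definition()
  extra <- setdiff(unique(unlist(dec)), eth$behavior)
  if (length(extra)) {
    eth <- ethogram_definition(rbind(
      as.data.frame(eth),
      data.frame(behavior = extra, sex = "F", stringsAsFactors = FALSE)))
  }
  attr(out, "decomposition") <- dec
  attr(out, "ethogram") <- eth
  out
}

#' Deterministic baseline transition matrix
#'
#' A fixed, heterogeneous row-stochastic matrix with zero diagonal used as
#' the shared population baseline: neighboring states (in vocabulary order)
#' are preferred and a periodic term adds asymmetric structure, so the
#' chain has strongly nonuniform transition probabilities without any
#' randomness in its construction.
#'
#' @param states character vector of state labels.
#' @return row-stochastic matrix with zero diagonal and state dimnames.
#' @export
default_base_matrix <- function(states) {
  S <- length(states)
  i <- matrix(seq_len(S), S, S)
  j <- t(i)
  w <- 1 + 4 * (abs(i - j) == 1) + 2 * ((i + 2 * j) %% 3 == 0)
  diag(w) <- 0
  m <- w / rowSums(w)
  dimnames(m) <- list(states, states)
  m
}

random_stochastic <- function(S, states = NULL) {
  m <- matrix(stats::rexp(S * S), S, S)
  diag(m) <- 0
  m <- m / rowSums(m)
  if (!is.null(states)) dimnames(m) <- list(states, states)
  m
}

#' Simulation configuration
#'
#' Bundles the study-design parameters of the paired behavior/SNP
#' simulators. Defaults mirror the dune-fly study design: seven beach
#' populations with the study's sample sizes and coordinates, courtship
#' filmed in three of them (15 male-female pairs each), gamma-distributed
#' bout durations, a divergence knob `eps` mixing a population-specific
#' perturbation into the shared baseline transition matrix, and a
#' Balding-Nichols SNP model whose differentiation parameter `F` matches
#' the study-wide differentiation.
#'
#' @param populations data.frame with `population`, `n_pairs` (filmed
#'   courting pairs), `n_genotyped`, `lat`, `lon`.
#' @param preset state vocabulary preset for the behavior model.
#' @param eps divergence knob in `[0, 1]`: population transition matrices
#'   are `(1 - eps) * P_base + eps * P_perturb(pop)`.
#' @param bout_shape,bout_scale gamma parameters of bout durations
#'   (seconds).
#' @param gap_shape,gap_scale gamma parameters of inter-state gaps
#'   (seconds); gaps must be positive so composite states never touch.
#' @param p_end per-step probability of ending the interaction.
#' @param max_states hard cap on states per actor sequence.
#' @param n_loci number of simulated SNP loci.
#' @param F Balding-Nichols differentiation, scalar in (0, 1) or named
#'   per-population vector; `spatial = TRUE` instead drifts allele
#'   frequencies sequentially along the latitude-ordered populations so
#'   differentiation decays with distance (isolation by distance).
#' @param ancestral_range range of ancestral allele frequencies.
#' @param missing_beta shape parameters of the Beta distribution of
#'   per-locus missingness rates.
#' @param repro_beta shape parameters of the Beta distribution of locus
#'   reproducibility scores.
#' @param spatial logical, see `F`.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(populations = NULL,
                              preset = "reduced",
                              eps = 0.1,
                              bout_shape = 1.8, bout_scale = 1.2,
                              gap_shape = 1.5, gap_scale = 0.5,
                              p_end = 0.03, max_states = 200,
                              n_loci = 5000,
                              F = 0.2,
                              ancestral_range = c(0.1, 0.9),
                              missing_beta = c(0.8, 40),
                              repro_beta = c(60, 0.9),
                              spatial = FALSE) {
  if (is.null(populations)) {
    populations <- data.frame(
      population = c("GR", "WA", "HA", "BE", "ME", "MI", "SE"),
      n_pairs = c(15L, 0L, 0L, 0L, 0L, 15L, 15L),
      n_genotyped = c(23L, 9L, 12L, 11L, 19L, 10L, 10L),
      lat = c(-35.1365, -35.4276, -36.4053, -36.4324, -36.9033,
              -36.8915, -36.9526),
      lon = c(150.72346, 150.41645, 150.06543, 150.07836, 149.91,
              149.92931, 149.90857),
      stringsAsFactors = FALSE)
  }
  stopifnot(eps >= 0, eps <= 1, all(F > 0), all(F < 1))
  vocab <- state_vocabulary(preset)
  base <- default_base_matrix(vocab$state)
  structure(list(populations = populations, vocab = vocab,
                 base_matrix = base, eps = eps,
                 bout_shape = bout_shape, bout_scale = bout_scale,
                 gap_shape = gap_shape, gap_scale = gap_scale,
                 p_end = p_end, max_states = max_states,
                 n_loci = n_loci, F = F,
                 ancestral_range = ancestral_range,
                 missing_beta = missing_beta, repro_beta = repro_beta,
                 spatial = spatial),
            class = "simulation_config")
}

# one semi-Markov realization over the actor's states of P (renormalized
# submatrix); returns states with start/end times
simulate_chain <- function(P, states_actor, bout_shape, bout_scale,
                           gap_shape, gap_scale, p_end, max_states) {
  sub <- P[states_actor, states_actor, drop = FALSE]
  sub <- sub / rowSums(sub)
  S <- length(states_actor)
  idx <- integer(max_states)
  cur <- sample.int(S, 1)
  idx[1] <- cur
  n <- 1L
  while (n < max_states && stats::runif(1) > p_end) {
    cur <- sample.int(S, 1, prob = sub[cur, ])
    n <- n + 1L
    idx[n] <- cur
  }
  idx <- idx[seq_len(n)]
  dur <- stats::rgamma(n, shape = bout_shape, scale = bout_scale)
  gap <- stats::rgamma(n, shape = gap_shape, scale = gap_scale)
  end <- cumsum(dur + gap)
  start <- end - dur
  list(states = states_actor[idx], start = start, end = end)
}

#' Simulate per-pair courtship behavior event logs
#'
#' Semi-Markov realization of the courtship display for every filmed pair
#' of every population with `n_pairs > 0`: composite states are drawn from
#' the population transition matrix
#' `P_pop = (1 - eps) * P_base + eps * P_perturb(pop)` (the perturbation
#' matrices are random row-stochastic matrices drawn once per population
#' from the seed), bout durations and inter-state gaps from the gamma
#' models, and each composite state is decomposed back into overlapping
#' behavior bout records. Male and female chains of a pair are simulated
#' independently over their actor's states.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; all randomness derives from it.
#' @return list with `events` (data.frame `pair_id`, `population`, `actor`,
#'   `behavior`, `start_s`, `end_s`), `sequences` (named list of true
#'   `state_sequence` objects per pair and actor), `matrices` (per-pop
#'   transition matrices) and `pair_populations` (named vector).
#' @export
simulate_behavior <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  vocab <- config$vocab
  dec <- attr(vocab, "decomposition")
  base <- config$base_matrix
  if (any(abs(rowSums(base) - 1) > 1e-9) || any(diag(base) != 0))
    stop("base matrix must be row-stochastic with zero diagonal")
  S <- nrow(base)
  pops <- config$populations[config$populations$n_pairs > 0, , drop = FALSE]
  matrices <- list()
  for (p in pops$population) {
    pert <- random_stochastic(S, vocab$state)
    matrices[[p]] <- (1 - config$eps) * base + config$eps * pert
  }
  events <- list(); sequences <- list(); pair_pops <- character()
  for (k in seq_len(nrow(pops))) {
    p <- pops$population[k]
    for (i in seq_len(pops$n_pairs[k])) {
      pid <- sprintf("%s_%02d", p, i)
      pair_pops[pid] <- p
      for (actor in c("male", "female")) {
        sa <- vocab$state[vocab$actor == actor]
        ch <- simulate_chain(matrices[[p]], sa,
                             config$bout_shape, config$bout_scale,
                             config$gap_shape, config$gap_scale,
                             config$p_end, config$max_states)
        t0 <- min(ch$start); t1 <- max(ch$end)
        sequences[[paste(pid, actor, sep = ".")]] <- structure(
          list(pair_id = pid, actor = actor,
               states = c("Bout-start", ch$states, "Bout-end"),
               start = c(t0, ch$start, t1), end = c(t0, ch$end, t1)),
          class = "state_sequence")
        nb <- lengths(dec[ch$states])
        events[[length(events) + 1]] <- data.frame(
          pair_id = pid, population = p, actor = actor,
          behavior = unlist(dec[ch$states], use.names = FALSE),
          start_s = rep(ch$start, nb), end_s = rep(ch$end, nb),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(events = do.call(rbind, events), sequences = sequences,
       matrices = matrices, pair_populations = pair_pops)
}

#' Per-pair transition matrices from simulated state sequences
#'
#' Shortcut for simulator output: sums the male and female
#' within-individual transition-count matrices of every pair on a shared
#' state order, skipping the event-log round trip (the result is identical
#' to [pair_transition_matrices()] on the emitted events).
#'
#' @param behavior result of [simulate_behavior()] (or the `behavior`
#'   element of [simulate_coupled_study()]).
#' @return named list of transition-count matrices, one per pair.
#' @export
pair_matrices_from_sequences <- function(behavior) {
  states <- sort(unique(unlist(lapply(behavior$sequences, `[[`, "states"))),
                 method = "radix")
  pids <- names(behavior$pair_populations)
  out <- lapply(pids, function(pid)
    count_transitions(
      behavior$sequences[paste(pid, c("male", "female"), sep = ".")],
      states = states))
  names(out) <- pids
  out
}

#' Write a behavior event log CSV
#' @param events event data.frame.
#' @param path output CSV path.
#' @export
write_event_log <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Simulate a structured biallelic SNP panel
#'
#' Balding-Nichols model: ancestral allele frequencies are uniform on
#' `ancestral_range`; each population's frequency is Beta-distributed
#' around the ancestral value with differentiation parameter `F`
#' (`Beta(p(1-F)/F, (1-p)(1-F)/F)`); genotypes are binomial draws of two
#' alleles. With `spatial = TRUE` the populations are ordered by latitude
#' and frequencies drift sequentially (each population perturbs its
#' neighbor's), producing isolation by distance. Missingness is masked at
#' per-locus rates drawn from the configured Beta distribution;
#' reproducibility scores are sampled likewise, so the marker-quality
#' filters have realistic bite. Call rate is the realized per-locus
#' proportion of non-missing calls.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `genotypes` (dosage matrix), `metadata` (data.frame
#'   `locus_id`, `reproducibility`, `call_rate`), `populations` (named
#'   vector individual -> population), `coordinates` (data.frame
#'   `population`, `lat`, `lon`).
#' @export
simulate_snps <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  pops <- config$populations
  L <- config$n_loci
  r <- nrow(pops)
  p_anc <- stats::runif(L, config$ancestral_range[1], config$ancestral_range[2])
  Fv <- config$F
  if (length(Fv) == 1) Fv <- rep(Fv, r)
  if (!is.null(names(config$F)) && length(config$F) > 1)
    Fv <- config$F[pops$population]
  freq <- matrix(NA_real_, r, L)
  if (config$spatial) {
    ord <- order(pops$lat)
    prev <- p_anc
    for (k in ord) {
      a <- prev * (1 - Fv[k]) / Fv[k]
      b <- (1 - prev) * (1 - Fv[k]) / Fv[k]
      freq[k, ] <- stats::rbeta(L, a, b)
      prev <- pmin(pmax(freq[k, ], 1e-6), 1 - 1e-6)
    }
  } else {
    for (k in seq_len(r)) {
      a <- p_anc * (1 - Fv[k]) / Fv[k]
      b <- (1 - p_anc) * (1 - Fv[k]) / Fv[k]
      freq[k, ] <- stats::rbeta(L, a, b)
    }
  }
  ids <- unlist(lapply(seq_len(r), function(k)
    sprintf("%s_%03d", pops$population[k], seq_len(pops$n_genotyped[k]))))
  populations <- stats::setNames(
    rep(pops$population, pops$n_genotyped), ids)
  N <- length(ids)
  G <- matrix(NA_integer_, N, L,
              dimnames = list(ids, sprintf("L%05d", seq_len(L))))
  row0 <- 0L
  for (k in seq_len(r)) {
    nk <- pops$n_genotyped[k]
    if (nk == 0) next
    G[row0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * L, 2, rep(freq[k, ], each = nk)), nk, L)
    row0 <- row0 + nk
  }
  miss_rate <- stats::rbeta(L, config$missing_beta[1], config$missing_beta[2])
  mask <- matrix(stats::runif(N * L) < rep(miss_rate, each = N), N, L)
  G[mask] <- NA_integer_
  metadata <- data.frame(
    locus_id = colnames(G),
    reproducibility = stats::rbeta(L, config$repro_beta[1],
                                   config$repro_beta[2]),
    call_rate = colMeans(!is.na(G)))
  list(genotypes = G, metadata = metadata, populations = populations,
       coordinates = pops[, c("population", "lat", "lon")])
}

#' Write a dosage genotype matrix as CSV
#' @param genotypes dosage matrix.
#' @param path output CSV path.
#' @export
write_genotypes_csv <- function(genotypes, path) {
  d <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Coupled behavior/SNP simulation with a shared divergence driver
#'
#' Places populations along a divergence axis `z` in `[0, 1]` and scales
#' both sides of the analysis from it: population `k` gets courtship
#' divergence knob `eps_k = eps_max * z_k` and Balding-Nichols
#' differentiation `F_k = F_min + (F_max - F_min) * z'_k`, where
#' `z' = coupling * z + (1 - coupling) * shuffle(z)`. With full coupling,
#' population pairs that diverge in
#' courtship also diverge genetically, so the courtship-vs-genetic R^2
#' rises with `coupling`; at zero coupling the two axes are unrelated.
#'
#' @param n_pops number of populations (>= 4 recommended).
#' @param n_pairs filmed pairs per population.
#' @param n_genotyped genotyped individuals per population.
#' @param coupling coupling strength in `[0, 1]`.
#' @param eps_max maximal courtship divergence knob.
#' @param F_range range of the genetic differentiation parameter.
#' @param n_loci SNP loci.
#' @param max_states,p_end chain-length controls (long chains keep the
#'   finite-sequence noise floor of the KL estimator below the signal).
#' @param seed integer seed.
#' @return list with `behavior` (from [simulate_behavior()]), `snps` (from
#'   [simulate_snps()]) and `z` (the divergence axis).
#' @export
simulate_coupled_study <- function(n_pops = 6, n_pairs = 8,
                                   n_genotyped = 12, coupling = 1,
                                   eps_max = 0.8, F_range = c(0.02, 0.35),
                                   n_loci = 1000, max_states = 300,
                                   p_end = 0.002, seed = 1) {
  stopifnot(coupling >= 0, coupling <= 1)
  set.seed(seed)
  z <- seq(0, 1, length.out = n_pops)
  zg <- coupling * z + (1 - coupling) * z[sample(n_pops)]
  popnames <- sprintf("P%02d", seq_len(n_pops))
  pops <- data.frame(population = popnames, n_pairs = n_pairs,
                     n_genotyped = n_genotyped,
                     lat = -35 - z, lon = 150 + z,
                     stringsAsFactors = FALSE)
  behavior <- NULL; snps <- NULL
  # per-population eps: simulate each population separately at its own knob
  beh_list <- lapply(seq_len(n_pops), function(k) {
    cfg <- simulation_config(populations = pops[k, , drop = FALSE],
                             eps = eps_max * z[k], n_loci = n_loci,
                             max_states = max_states, p_end = p_end)
    simulate_behavior(cfg, seed = seed + k)
  })
  events <- do.call(rbind, lapply(beh_list, `[[`, "events"))
  sequences <- do.call(c, lapply(beh_list, `[[`, "sequences"))
  pair_pops <- do.call(c, lapply(beh_list, `[[`, "pair_populations"))
  Fv <- stats::setNames(F_range[1] + (F_range[2] - F_range[1]) * zg, popnames)
  cfg_g <- simulation_config(populations = pops, F = Fv, n_loci = n_loci)
  snps <- simulate_snps(cfg_g, seed = seed + 1000)
  list(behavior = list(events = events, sequences = sequences,
                       pair_populations = pair_pops),
       snps = snps, z = z, z_genetic = zg, coupling = coupling)
}
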