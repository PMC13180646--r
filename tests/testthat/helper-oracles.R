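# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct route (fine time grids, explicit haplotypes,
# scalar loops) so they share no code path with the package internals.

# fine-grid state labeling: events must have times on a lattice of step `dt`
grid_states <- function(events, pair_id, actor, dt = 0.25) {
  ev <- events[events$pair_id == pair_id & events$actor == actor, ]
  if (nrow(ev) == 0) return(c("Bout-start", "Bout-end"))
  t0 <- min(ev$start_s); t1 <- max(ev$end_s)
  mids <- seq(t0 + dt / 2, t1 - dt / 2, by = dt)
  tag <- if (actor == "male") "(M)" else "(F)"
  labs <- vapply(mids, function(tm) {
    act <- ev$behavior[ev$start_s <= tm & ev$end_s >= tm]
    if (!length(act)) return(NA_character_)
    paste(c(sort(unique(act), method = "radix"), tag), collapse = "-")
  }, character(1))
  labs <- labs[!is.na(labs)]
  labs <- labs[c(TRUE, labs[-1] != labs[-length(labs)])]
  c("Bout-start", labs, "Bout-end")
}

# random event log on a quarter-second lattice
random_event_log <- function(n_events, behaviors, actor = "male",
                             pair_id = "p1", t_max = 40) {
  start <- sample(seq(0, t_max, by = 0.25), n_events, replace = TRUE)
  len <- sample(seq(0.25, 5, by = 0.25), n_events, replace = TRUE)
  data.frame(pair_id = pair_id, population = "X", actor = actor,
             behavior = sample(behaviors, n_events, replace = TRUE),
             start_s = start, end_s = start + len,
             stringsAsFactors = FALSE)
}

brute_count_transitions <- function(seqs, states) {
  m <- matrix(0L, length(states), length(states),
              dimnames = list(states, states))
  for (s in seqs) {
    s <- if (inherits(s, "state_sequence")) s$states else s
    if (length(s) < 2) next
    for (k in seq_len(length(s) - 1)) {
      m[s[k], s[k + 1]] <- m[s[k], s[k + 1]] + 1L
    }
  }
  m
}

# allele-multiset Kosman distance (shared-allele counting, scalar loops)
brute_kosman <- function(genotypes) {
  N <- nrow(genotypes)
  D <- matrix(0, N, N, dimnames = list(rownames(genotypes),
                                       rownames(genotypes)))
  for (u in seq_len(N)) for (v in seq_len(N)) {
    if (u == v) next
    num <- 0; nloc <- 0
    for (l in seq_len(ncol(genotypes))) {
      gu <- genotypes[u, l]; gv <- genotypes[v, l]
      if (is.na(gu) || is.na(gv)) next
      shared <- min(gu, gv) + min(2 - gu, 2 - gv)
      num <- num + (1 - shared / 2)
      nloc <- nloc + 1
    }
    D[u, v] <- if (nloc) num / nloc else NA_real_
  }
  D
}

brute_nei <- function(freq_x, freq_y) {
  jx <- 0; jy <- 0; jxy <- 0
  for (l in seq_along(freq_x)) {
    for (p in list(c(freq_x[l], freq_y[l]),
                   c(1 - freq_x[l], 1 - freq_y[l]))) {
      jx <- jx + p[1]^2; jy <- jy + p[2]^2; jxy <- jxy + p[1] * p[2]
    }
  }
  -log(jxy / sqrt(jx * jy))
}

# AMOVA oracle: explicit haplotypes (arbitrary phase -- the statistics are
# phase-invariant), full pairwise squared distances, literal group sums
brute_amova_components <- function(genotypes, populations) {
  N <- nrow(genotypes); L <- ncol(genotypes)
  hap <- matrix(NA_real_, 2 * N, L)
  for (i in seq_len(N)) {
    g <- genotypes[i, ]
    hap[2 * i - 1, ] <- ifelse(is.na(g), NA, as.numeric(g >= 1))
    hap[2 * i, ] <- ifelse(is.na(g), NA, as.numeric(g == 2))
  }
  ind_of <- rep(seq_len(N), each = 2)
  pop_of <- populations[ind_of]
  H <- 2 * N
  d2 <- matrix(0, H, H)
  for (u in seq_len(H)) for (v in seq_len(H)) {
    ok <- !is.na(hap[u, ]) & !is.na(hap[v, ])
    d2[u, v] <- sum((hap[u, ok] - hap[v, ok])^2)
  }
  ssd_group <- function(idx) sum(d2[idx, idx]) / (2 * length(idx))
  ssd_t <- ssd_group(seq_len(H))
  ssd_wp <- sum(vapply(unique(pop_of), function(p)
    ssd_group(which(pop_of == p)), numeric(1)))
  ssd_wi <- sum(vapply(seq_len(N), function(i)
    ssd_group(which(ind_of == i)), numeric(1)))
  r <- length(unique(populations))
  nk <- as.numeric(table(populations)[unique(populations)])
  ms_wi <- ssd_wi / N
  ms_ai <- (ssd_wp - ssd_wi) / (N - r)
  ms_ap <- (ssd_t - ssd_wp) / (r - 1)
  nc_hap <- 2 * (N - sum(nk^2) / N) / (r - 1)
  sig_w <- ms_wi
  sig_b <- (ms_ai - ms_wi) / 2
  sig_a <- (ms_ap - ms_ai) / nc_hap
  c(among_pops = sig_a, among_ind = sig_b, within_ind = sig_w)
}

# small genotype panel with no missing data
random_genotypes <- function(n, L, miss = 0) {
  g <- matrix(sample(0:2, n * L, replace = TRUE), n, L,
              dimnames = list(paste0("i", seq_len(n)),
                              paste0("L", seq_len(L))))
  if (miss > 0) g[runif(n * L) < miss] <- NA_integer_
  g
}
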