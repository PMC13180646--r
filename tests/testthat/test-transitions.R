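test_that("transition counting matches direct tallies", {
  m <- count_transitions(list(c("A", "B", "A", "B")))
  expect_equal(m["A", "B"], 2L)
  expect_equal(m["B", "A"], 1L)
  expect_equal(sum(m), 3L)

  set.seed(11)
  states <- LETTERS[1:6]
  seqs <- lapply(1:8, function(i)
    sample(states, sample(2:30, 1), replace = TRUE))
  expect_equal(count_transitions(seqs, states = states),
               brute_count_transitions(seqs, states))
  # per-individual matrices sum to the aggregate
  ind <- count_transitions(seqs, states = states, scope = "individual")
  expect_equal(Reduce(`+`, ind), count_transitions(seqs, states = states))
  # aggregate is invariant to the order individuals are concatenated in
  expect_equal(count_transitions(rev(seqs), states = states),
               count_transitions(seqs, states = states))
})

test_that("degenerate sequences give empty matrices and networks", {
  expect_warning(m <- count_transitions(list("A", "B")), "all-zero")
  expect_true(all(m == 0))
  net <- suppressWarnings(
    permutation_edge_test(list(c("A")), B = 100, seed = 1))
  expect_equal(nrow(net$edges), 0)
})

test_that("a strict alternation is maximally nonrandom", {
  s <- rep(c("A", "B"), 10)
  net <- permutation_edge_test(list(s), B = 999, seed = 1)
  expect_equal(net$pvals["A", "B"], 1 / 1000)
  expect_true(all(net$edges$p >= 1 / 1000))
  expect_error(permutation_edge_test(list(s), B = 50), "at least 100")
})

test_that("permutation p-values agree with exhaustive enumeration", {
  s <- c("A", "B", "A", "B", "A", "B")
  obs <- count_transitions(list(s))["A", "B"]
  perms <- courtpop:::all_perms(6)
  counts <- vapply(perms, function(pp)
    count_transitions(list(s[pp]))["A", "B"], integer(1))
  p_exact <- mean(counts >= obs)
  net <- permutation_edge_test(list(s), B = 4999, seed = 3)
  expect_lt(abs(net$pvals["A", "B"] - p_exact), 0.01)
})

test_that("Dirichlet-smoothed KL has its closed-form values and properties", {
  expect_equal(kl_dirichlet(c(3, 1, 7), c(3, 1, 7)), 0)
  expect_equal(kl_dirichlet(c(1, 0), c(0, 1), a = 1), log(2) / 3)
  expect_error(kl_dirichlet(c(1, 0), c(1, 0, 0)), "length")
  expect_error(kl_dirichlet(c(-1, 2), c(1, 0)), "negative")
  expect_error(kl_dirichlet(c(1, 0), c(0, 1), a = 0), "positive")
  set.seed(4)
  for (i in 1:25) {
    y1 <- rpois(6, 3); y2 <- rpois(6, 3)
    d <- kl_dirichlet(y1, y2, a = runif(1, 0.1, 2))
    expect_gte(d, 0)
    if (!identical(y1, y2)) {
      # zero iff the smoothed distributions coincide
      p <- (y1 + 1) / (sum(y1) + 6); q <- (y2 + 1) / (sum(y2) + 6)
      if (max(abs(p - q)) > 1e-12) expect_gt(kl_dirichlet(y1, y2, 1), 0)
    }
  }
})

test_that("pairwise courtship distances compose from single KL calls", {
  set.seed(5)
  states <- c("A", "B", "C")
  mats <- lapply(1:3, function(i) {
    m <- matrix(rpois(9, 4), 3, 3, dimnames = list(states, states))
    diag(m) <- 0L
    m
  })
  names(mats) <- paste0("ind", 1:3)
  D <- pairwise_courtship_distances(mats, pseudocount = 1)
  expect_equal(diag(D), setNames(rep(0, 3), names(mats)))
  expect_equal(sum(D > 0), 6)
  for (i in 1:3) for (j in 1:3) if (i != j)
    expect_equal(D[i, j],
                 kl_dirichlet(as.vector(t(mats[[i]])),
                              as.vector(t(mats[[j]])), a = 1))
  # identical individuals at distance 0 in both directions
  D2 <- pairwise_courtship_distances(list(a = mats[[1]], b = mats[[1]]))
  expect_equal(D2, matrix(0, 2, 2), ignore_attr = TRUE)
  # mismatched state order is refused
  bad <- mats[[2]][c(2, 1, 3), c(2, 1, 3)]
  expect_error(pairwise_courtship_distances(list(mats[[1]], bad)),
               "state order")
  Ds <- pairwise_courtship_distances(mats, symmetrize = TRUE)
  expect_equal(Ds, (D + t(D)) / 2, ignore_attr = TRUE)
})

test_that("population divergence summary averages the right cells", {
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- 1; D["b", "a"] <- 3
  D["a", "c"] <- 2; D["c", "a"] <- 2
  pops <- setNames(c("X", "X", "Y", "Z"), letters[1:4])
  s <- population_divergence_summary(D, pops)
  expect_equal(s$mean_kl[s$pop_a == "X" & s$pop_b == "X"], 2)   # (1+3)/2
  expect_equal(s$mean_kl[s$pop_a == "X" & s$pop_b == "Y"], 1)   # (2+2+0+0)/4
  # single-individual population: within-mean undefined
  expect_true(is.na(s$mean_kl[s$pop_a == "Y" & s$pop_b == "Y"]))
  # all-identical individuals: all means 0
  D0 <- matrix(0, 4, 4, dimnames = dimnames(D))
  s0 <- population_divergence_summary(D0, pops)
  expect_true(all(s0$mean_kl[s0$n_pairs > 0] == 0))
})

test_that("interleaving merges a pair's chains by onset time", {
  ev <- data.frame(
    pair_id = "p1", population = "GR",
    actor = c("male", "female", "male"),
    behavior = c("Orient", "Walking", "Wing-flash"),
    start_s = c(0, 2, 5), end_s = c(1, 3, 6))
  m <- derive_state_sequence(ev, "p1", "male")
  f <- derive_state_sequence(ev, "p1", "female")
  pa <- interleave_pair(m, f)
  expect_equal(pa$states, c("Bout-start", "Orient-(M)", "Walking-(F)",
                            "Wing-flash-(M)", "Bout-end"))
})
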