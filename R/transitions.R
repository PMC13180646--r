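#' Extract the state labels of a sequence
#' @keywords internal
#' @noRd
seq_states <- function(x) {
  if (inherits(x, "state_sequence")) x$states else as.character(x)
}

#' Count within-individual state transitions
#'
#' Builds the S x S transition-count matrix of a set of state sequences:
#' cell (i, j) is the number of times state i was immediately followed by
#' state j within the *same* individual's sequence. Because adjacent
#' identical states are merged when sequences are derived, the diagonal of
#' observed sequences is zero. The matrix is the adjacency representation of
#' the courtship display used for the network and divergence analyses.
#'
#' @param sequences list of [derive_state_sequence()] results or plain
#'   character vectors of states; all share one state universe.
#' @param states optional character vector fixing the state order (default:
#'   sorted union of observed states).
#' @param scope `"all"` (one aggregate matrix) or `"individual"` (a named
#'   list, one matrix per sequence, all on the shared state order).
#' @return integer matrix (or list of matrices) with state dimnames.
#' @export
count_transitions <- function(sequences, states = NULL,
                              scope = c("all", "individual")) {
  scope <- match.arg(scope)
  if (inherits(sequences, "state_sequence")) sequences <- list(sequences)
  seqs <- lapply(sequences, seq_states)
  if (is.null(states)) states <- sort(unique(unlist(seqs)))
  S <- length(states)
  count_one <- function(s) {
    idx <- match(s, states)
    if (anyNA(idx)) stop("sequence contains states outside the state universe")
    m <- matrix(0L, S, S, dimnames = list(states, states))
    if (length(idx) >= 2) {
      from <- idx[-length(idx)]; to <- idx[-1]
      tab <- tabulate((to - 1L) * S + from, nbins = S * S)
      m[] <- as.integer(tab)
    }
    m
  }
  if (scope == "individual") {
    out <- lapply(seqs, count_one)
    names(out) <- names(sequences)
    return(out)
  }
  agg <- Reduce(`+`, lapply(seqs, count_one))
  if (all(agg == 0)) warning("fewer than 2 states in every sequence: all-zero matrix")
  agg
}

#' Interleave the male and female sequences of a courting pair
#'
#' Merges two actors' state sequences into one chain ordered by state onset
#' time, so that transitions between the sexes' behaviors can be counted in
#' a single network. Each input's sentinels are dropped and a shared
#' `Bout-start`/`Bout-end` added.
#'
#' @param male,female `state_sequence` objects for the two actors.
#' @return a `state_sequence` for the pair (actor `"pair"`).
#' @export
interleave_pair <- function(male, female) {
  strip <- function(x) {
    keep <- !(x$states %in% c("Bout-start", "Bout-end"))
    list(states = x$states[keep], start = x$start[keep], end = x$end[keep])
  }
  m <- strip(male); f <- strip(female)
  states <- c(m$states, f$states)
  start <- c(m$start, f$start)
  end <- c(m$end, f$end)
  o <- order(start, end)
  t0 <- if (length(start)) min(start) else 0
  t1 <- if (length(end)) max(end) else 0
  structure(list(pair_id = male$pair_id, actor = "pair",
                 states = c("Bout-start", states[o], "Bout-end"),
                 start = c(t0, start[o], t1),
                 end = c(t0, end[o], t1)),
            class = "state_sequence")
}

shuffle_within <- function(s) {
  n <- length(s)
  pin_head <- n >= 1 && s[1] == "Bout-start"
  pin_tail <- n >= 1 && s[n] == "Bout-end"
  lo <- 1 + pin_head; hi <- n - pin_tail
  if (hi - lo < 1) return(s)
  mid <- s[lo:hi]
  s[lo:hi] <- mid[sample.int(length(mid))]
  s
}

#' Permutation test for nonrandom transitions
#'
#' Identifies the transitions that occur more often than expected by chance,
#' i.e. the nonrandom backbone of the display. The null distribution is
#' built by independently shuffling the order of states within each
#' individual sequence (sentinels stay pinned at the ends, so per-sequence
#' state multisets are preserved), recounting the aggregate matrix, and
#' repeating `B` times. For each cell with a positive observed count the
#' one-sided p-value is `(1 + #(permuted >= observed)) / (B + 1)`; cells
#' with `p <= alpha` form the significant-transition network.
#'
#' @param sequences list of state sequences (see [count_transitions()]).
#' @param B number of permutations, at least 100 (default 1000).
#' @param alpha significance level for edge retention (default 0.05; no
#'   multiple-testing correction is applied).
#' @param states optional fixed state order.
#' @param seed optional integer seed for the permutations.
#' @return An object of class `transition_network`: list with `states`,
#'   `counts`, `prob` (row-normalized transition probabilities), `pvals`
#'   (NA where the observed count is 0), `edges` (data.frame `from`, `to`,
#'   `count`, `prob`, `p` of retained edges), `centrality` (percentage of
#'   all state occurrences per state), `alpha`, `B`.
#' @export
permutation_edge_test <- function(sequences, B = 1000, alpha = 0.05,
                                  states = NULL, seed = NULL) {
  if (B < 100) stop("B must be at least 100 for stable p-values")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(sequences, "state_sequence")) sequences <- list(sequences)
  seqs <- lapply(sequences, seq_states)
  if (is.null(states)) states <- sort(unique(unlist(seqs)))
  obs <- count_transitions(seqs, states = states)
  S <- length(states)
  testable <- obs > 0
  ge <- matrix(0L, S, S)
  for (b in seq_len(B)) {
    perm <- count_transitions(lapply(seqs, shuffle_within), states = states)
    ge <- ge + (perm >= obs)
  }
  pvals <- (1 + ge) / (B + 1)
  pvals[!testable] <- NA_real_
  rs <- rowSums(obs)
  prob <- obs / ifelse(rs > 0, rs, 1)
  occ <- table(factor(unlist(seqs), levels = states))
  centrality <- 100 * as.numeric(occ) / sum(occ)
  names(centrality) <- states
  sig <- which(testable & pvals <= alpha, arr.ind = TRUE)
  edges <- data.frame(from = states[sig[, 1]], to = states[sig[, 2]],
                      count = obs[sig], prob = prob[sig], p = pvals[sig],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$p, -edges$count), ]
  rownames(edges) <- NULL
  structure(list(states = states, counts = obs, prob = prob, pvals = pvals,
                 edges = edges, centrality = centrality,
                 alpha = alpha, B = B),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat("Transition network:", length(x$states), "states,",
      sum(x$counts > 0), "observed transitions,",
      nrow(x$edges), "significant at alpha =", x$alpha,
      paste0("(B = ", x$B, ")\n"))
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}

#' Dirichlet-smoothed Kullback-Leibler divergence between count vectors
#'
#' Estimates the KL divergence between the multinomial distributions
#' underlying two count vectors, with a symmetric Dirichlet prior: each
#' count gets pseudocount `a` added before normalization,
#' `p_i = (y1_i + a) / (n1 + a*S)` and likewise for `q`, and the divergence
#' is `sum(p * log(p / q))` in nats. With `a > 0` both estimates have full
#' support, so the divergence is always finite.
#'
#' @param y1,y2 nonnegative count vectors of equal length `S >= 2`.
#' @param a pseudocount, positive (default 1, Laplace smoothing).
#' @return divergence in nats (nonnegative scalar).
#' @export
#' @examples
#' kl_dirichlet(c(1, 0), c(0, 1))  # log(2) / 3
kl_dirichlet <- function(y1, y2, a = 1) {
  if (length(y1) != length(y2)) stop("count vectors differ in length")
  if (length(y1) < 2) stop("need at least 2 categories")
  if (any(y1 < 0) || any(y2 < 0)) stop("negative counts")
  if (a <= 0) stop("pseudocount must be positive")
  S <- length(y1)
  p <- (y1 + a) / (sum(y1) + a * S)
  q <- (y2 + a) / (sum(y2) + a * S)
  sum(p * log(p / q))
}

#' Pairwise courtship distances between individuals
#'
#' Flattens each individual's transition-count matrix to an S^2 count vector
#' (row-major over the shared state order) and applies [kl_dirichlet()] to
#' every ordered pair of individuals. KL divergence is asymmetric; an
#' optional symmetrized variant averages the two directions.
#'
#' @param matrices named list of per-individual transition-count matrices on
#'   identical state orders (e.g. `count_transitions(..., scope =
#'   "individual")`).
#' @param pseudocount Dirichlet pseudocount (default 1).
#' @param symmetrize return `(D + t(D)) / 2` (default `FALSE`).
#' @return numeric matrix with zero diagonal and individual dimnames;
#'   attribute `pseudocount`.
#' @export
pairwise_courtship_distances <- function(matrices, pseudocount = 1,
                                         symmetrize = FALSE) {
  n <- length(matrices)
  if (n < 2) stop("need at least 2 individuals")
  dn <- dimnames(matrices[[1]])
  ok <- vapply(matrices, function(m)
    identical(dimnames(m), dn), logical(1))
  if (!all(ok)) stop("transition matrices differ in state order")
  vecs <- lapply(matrices, function(m) as.vector(t(m)))
  ids <- names(matrices)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    D[i, j] <- kl_dirichlet(vecs[[i]], vecs[[j]], a = pseudocount)
  if (symmetrize) D <- (D + t(D)) / 2
  attr(D, "pseudocount") <- pseudocount
  D
}

#' Mean within- and between-population courtship divergence
#'
#' Averages inter-individual KL divergences over all ordered pairs of
#' distinct individuals within each population and across each population
#' pair, with the standard error over contributing pairs.
#'
#' @param distances matrix from [pairwise_courtship_distances()].
#' @param populations named character vector mapping individual id to
#'   population.
#' @return data.frame `pop_a`, `pop_b`, `mean_kl`, `se_kl`, `n_pairs`;
#'   rows with `pop_a == pop_b` are within-population summaries (`NA` when a
#'   population has a single individual).
#' @export
population_divergence_summary <- function(distances, populations) {
  ids <- rownames(distances)
  if (!all(ids %in% names(populations)))
    stop("every individual needs a population assignment")
  pop <- populations[ids]
  pops <- sort(unique(pop))
  rows <- list()
  for (i in seq_along(pops)) for (j in i:length(pops)) {
    a <- pops[i]; b <- pops[j]
    ia <- which(pop == a); ib <- which(pop == b)
    if (a == b) {
      if (length(ia) < 2) {
        vals <- numeric(0)
      } else {
        sub <- distances[ia, ia, drop = FALSE]
        vals <- sub[row(sub) != col(sub)]
      }
    } else {
      vals <- c(distances[ia, ib, drop = FALSE],
                distances[ib, ia, drop = FALSE])
    }
    rows[[length(rows) + 1]] <- data.frame(
      pop_a = a, pop_b = b,
      mean_kl = if (length(vals)) mean(vals) else NA_real_,
      se_kl = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
      n_pairs = length(vals), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a transition matrix as CSV with state headers
#' @param m transition matrix.
#' @param path output CSV path.
#' @export
write_transition_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Write the significant-edge list of a network as CSV
#' @param network a `transition_network`.
#' @param path output CSV path.
#' @export
write_edge_list <- function(network, path) {
  utils::write.csv(network$edges, path, row.names = FALSE)
  invisible(path)
}

#' Export a significant-transition network as GraphML
#'
#' Node attributes carry degree centrality (percentage of all state
#' occurrences); edge attributes carry count, transition probability and
#' permutation p-value. Requires the igraph package.
#'
#' @param network a `transition_network`.
#' @param path output GraphML path.
#' @export
write_graphml <- function(network, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for GraphML export")
  g <- igraph::graph_from_data_frame(
    network$edges,
    vertices = data.frame(name = network$states,
                          centrality = network$centrality),
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
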