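#' Ethogram definition
#'
#' An ethogram is the closed scoring vocabulary of discrete behaviors, each
#' tagged with the sex that can perform it. The default vocabulary is the
#' 18-behavior courtship ethogram of the dancing dune fly (wing displays,
#' orienting, straddling and female responses), plus the two sentinel states
#' `Bout-start` and `Bout-end` that delimit every state sequence.
#'
#' @param behaviors data.frame with columns `behavior` and `sex`
#'   (`"M"`, `"F"` or `"MF"`). Defaults to the 18-behavior courtship
#'   vocabulary.
#' @return An object of class `ethogram`: a data.frame of behaviors with a
#'   `sentinels` attribute `c(start, end)`.
#' @export
#' @examples
#' eth <- ethogram_definition()
#' nrow(eth)  # 18
ethogram_definition <- function(behaviors = NULL) {
  if (is.null(behaviors)) {
    behaviors <- data.frame(
      behavior = c("Chasing", "Face-off", "Foraging", "Foreleg-touch",
                   "Kick", "Orient", "Preening", "Proboscis-touch",
                   "Single-wing", "Standing", "Straddle", "Turn",
                   "Walking", "Wing-flap", "Wing-flash", "Wing-sweep",
                   "Wing-touch", "Wing-vibrate"),
      sex = c("M", "M", "MF", "M",
              "F", "M", "MF", "M",
              "MF", "F", "M", "F",
              "F", "MF", "M", "M",
              "M", "M"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(behaviors),
            all(c("behavior", "sex") %in% names(behaviors)))
  if (anyDuplicated(behaviors$behavior))
    stop("ethogram behavior labels must be unique")
  if (!all(behaviors$sex %in% c("M", "F", "MF")))
    stop("ethogram 'sex' must be one of 'M', 'F', 'MF'")
  structure(behaviors,
            sentinels = c(start = "Bout-start", end = "Bout-end"),
            class = c("ethogram", "data.frame"))
}

#' Load and validate a behavior event log
#'
#' Reads a CSV of time-stamped behavior bouts (one row per bout per actor per
#' courting pair) and validates it against an ethogram: behavior labels must
#' belong to the vocabulary, intervals must have positive length, and by
#' default a behavior scored for the wrong sex (e.g. a female `Straddle`) is
#' rejected, which catches scoring errors.
#'
#' @param path path to a CSV with header columns `pair_id`, `population`,
#'   `actor` (`"male"`/`"female"`), `behavior`, `start_s`, `end_s` (seconds).
#' @param ethogram an [ethogram_definition()].
#' @param check_sex reject behaviors scored for a sex the ethogram does not
#'   allow (default `TRUE`).
#' @return data.frame of validated events with the columns above.
#' @export
load_event_log <- function(path, ethogram = ethogram_definition(),
                           check_sex = TRUE) {
  if (!file.exists(path)) stop("event log not found: ", path)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("pair_id", "actor", "behavior", "start_s", "end_s")
  missing_cols <- setdiff(required, names(ev))
  if (length(missing_cols))
    stop("event log format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!"population" %in% names(ev)) ev$population <- NA_character_
  validate_events(ev, ethogram, check_sex = check_sex)
}

#' Validate behavior events against an ethogram
#'
#' @param events data.frame of events (see [load_event_log()]).
#' @param ethogram an [ethogram_definition()].
#' @param check_sex reject wrong-sex behaviors.
#' @return the validated events, invisibly unchanged.
#' @export
validate_events <- function(events, ethogram = ethogram_definition(),
                            check_sex = TRUE) {
  if (!all(events$actor %in% c("male", "female")))
    stop("actor must be 'male' or 'female'; offending rows: ",
         paste(which(!events$actor %in% c("male", "female")), collapse = ", "))
  unknown <- !(events$behavior %in% ethogram$behavior)
  if (any(unknown))
    stop("unknown behavior label(s) ",
         paste(unique(events$behavior[unknown]), collapse = ", "),
         " in rows: ", paste(which(unknown), collapse = ", "))
  bad_t <- !(is.finite(events$start_s) & is.finite(events$end_s) &
               events$start_s >= 0 & events$end_s > events$start_s)
  if (any(bad_t))
    stop("invalid intervals (need 0 <= start_s < end_s) in rows: ",
         paste(which(bad_t), collapse = ", "))
  if (check_sex) {
    sex_of <- stats::setNames(ethogram$sex, ethogram$behavior)
    actor_code <- ifelse(events$actor == "male", "M", "F")
    allowed <- sex_of[events$behavior]
    bad_sex <- allowed != "MF" & allowed != actor_code
    if (any(bad_sex))
      stop("behavior scored for the wrong sex in rows: ",
           paste(which(bad_sex), collapse = ", "))
  }
  events
}

state_label <- function(behaviors, actor) {
  tag <- if (actor %in% c("male", "M")) "(M)" else "(F)"
  paste(c(sort(behaviors, method = "radix"), tag), collapse = "-")
}

#' Derive the composite-state sequence of one actor
#'
#' Behaviors of one fly may overlap in time (a male can orient and
#' wing-vibrate simultaneously), so the behavioral state at any instant is
#' the *set* of concurrently active behaviors. The timeline is partitioned at
#' every bout boundary (a sweep line over interval endpoints), each segment
#' is labeled with its active set (sorted alphabetically, joined by `-`, with
#' an actor tag, e.g. `Orient-Wing-vibrate-(M)`), consecutive identical
#' segments are merged, segments with no active behavior are dropped (they
#' are inter-bout gaps, not states), and the sentinels `Bout-start` /
#' `Bout-end` are prepended/appended.
#'
#' @param events validated event data.frame.
#' @param pair_id the courting pair to extract.
#' @param actor `"male"` or `"female"`.
#' @return An object of class `state_sequence`: list with `pair_id`, `actor`,
#'   `states` (character), `start`, `end` (numeric, seconds).
#' @export
derive_state_sequence <- function(events, pair_id, actor) {
  stopifnot(actor %in% c("male", "female"))
  ev <- events[events$pair_id == pair_id & events$actor == actor, , drop = FALSE]
  sent <- c("Bout-start", "Bout-end")
  if (nrow(ev) == 0) {
    return(structure(list(pair_id = pair_id, actor = actor,
                          states = sent, start = numeric(2), end = numeric(2)),
                     class = "state_sequence"))
  }
  bounds <- sort(unique(c(ev$start_s, ev$end_s)))
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  labels <- character(length(seg_start))
  for (k in seq_along(seg_start)) {
    active <- ev$behavior[ev$start_s <= seg_start[k] & ev$end_s >= seg_end[k]]
    labels[k] <- if (length(active)) state_label(unique(active), actor) else NA_character_
  }
  keep <- !is.na(labels)
  labels <- labels[keep]; seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  # merge runs of identical adjacent labels
  if (length(labels)) {
    run <- cumsum(c(TRUE, labels[-1] != labels[-length(labels)]))
    states <- tapply(labels, run, `[`, 1)
    start <- tapply(seg_start, run, min)
    end <- tapply(seg_end, run, max)
    states <- as.character(states); start <- as.numeric(start); end <- as.numeric(end)
  } else {
    states <- character(); start <- numeric(); end <- numeric()
  }
  t0 <- min(ev$start_s); t1 <- max(ev$end_s)
  structure(list(pair_id = pair_id, actor = actor,
                 states = c("Bout-start", states, "Bout-end"),
                 start = c(t0, start, t1),
                 end = c(t0, end, t1)),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("State sequence for pair", x$pair_id, "/", x$actor, ":",
      length(x$states), "states\n")
  cat(paste(utils::head(x$states, 10), collapse = " -> "),
      if (length(x$states) > 10) "..." else "", "\n")
  invisible(x)
}

# merge a behavior's raw intervals into maximal bouts (gap tolerance 0:
# touching or overlapping intervals merge, disjoint ones stay separate)
merge_bouts <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  for (k in seq_along(start)[-1]) {
    if (start[k] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], end[k])
    } else {
      out_s <- c(out_s, start[k]); out_e <- c(out_e, end[k])
    }
  }
  cbind(start = out_s, end = out_e)
}

#' Proportional courtship metrics per pair
#'
#' For every behavior of every actor in a courting pair, computes the three
#' proportional metrics used to compare courtship effort across interactions
#' of different length: (i) `duration_prop`, the mean bout duration divided
#' by the total interaction duration; (ii) `frequency_prop`, the number of
#' bouts of the behavior divided by the total number of bouts of all
#' behaviors in the pair; (iii) `interval_prop`, the mean gap between
#' consecutive bouts of the behavior divided by the total interaction
#' duration (`NA` when the behavior has a single bout). The total interaction
#' duration is the span from the first event start to the last event end.
#'
#' @param events validated event data.frame.
#' @param pair_ids pairs to include (default: all pairs present).
#' @return data.frame with columns `pair_id`, `population`, `actor`,
#'   `behavior`, `n_bouts`, `duration_prop`, `frequency_prop`,
#'   `interval_prop`, `total_duration_s`.
#' @export
courtship_metrics <- function(events, pair_ids = unique(events$pair_id)) {
  out <- lapply(pair_ids, function(p) {
    ev <- events[events$pair_id == p, , drop = FALSE]
    if (nrow(ev) == 0) stop("no events for pair ", p)
    total <- max(ev$end_s) - min(ev$start_s)
    if (total <= 0) stop("zero-duration interaction for pair ", p)
    key <- paste(ev$actor, ev$behavior, sep = "\r")
    rows <- lapply(unique(key), function(k) {
      sub <- ev[key == k, , drop = FALSE]
      b <- merge_bouts(sub$start_s, sub$end_s)
      n <- nrow(b)
      gaps <- if (n > 1) b[-1, "start"] - b[-n, "end"] else NA_real_
      data.frame(pair_id = p,
                 population = sub$population[1],
                 actor = sub$actor[1],
                 behavior = sub$behavior[1],
                 n_bouts = n,
                 duration_prop = mean(b[, "end"] - b[, "start"]) / total,
                 interval_prop = if (n > 1) mean(gaps) / total else NA_real_,
                 total_duration_s = total,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$frequency_prop <- res$n_bouts / sum(res$n_bouts)
    res
  })
  res <- do.call(rbind, out)
  res[, c("pair_id", "population", "actor", "behavior", "n_bouts",
          "duration_prop", "frequency_prop", "interval_prop",
          "total_duration_s")]
}

#' Proportion of pairs exhibiting each behavior, by population
#'
#' For each behavior and population, the fraction of assayed courting pairs
#' in which the behavior was observed at least once. Behaviors never seen in
#' a population report 0, not `NA`.
#'
#' @param events validated event data.frame with a `population` column, or a
#'   metrics table from [courtship_metrics()].
#' @param populations optional named vector mapping `pair_id` to population,
#'   used when the events carry no population column.
#' @return data.frame behavior x population of proportions in `[0, 1]`.
#' @export
occurrence_proportions <- function(events, populations = NULL) {
  if (!is.null(populations))
    events$population <- populations[as.character(events$pair_id)]
  if (any(is.na(events$population)))
    stop("every pair must have a population assignment")
  pops <- sort(unique(events$population))
  behaviors <- sort(unique(events$behavior))
  n_pairs <- vapply(pops, function(pp)
    length(unique(events$pair_id[events$population == pp])), integer(1))
  if (any(n_pairs == 0)) stop("empty population")
  mat <- sapply(pops, function(pp) {
    sub <- events[events$population == pp, ]
    vapply(behaviors, function(b)
      length(unique(sub$pair_id[sub$behavior == b])) / n_pairs[[pp]],
      numeric(1))
  })
  mat <- matrix(mat, nrow = length(behaviors),
                dimnames = list(behaviors, pops))
  as.data.frame(mat)
}

#' Prevalence filter for quantitative analysis
#'
#' Retains the behaviors whose occurrence proportion exceeds `threshold` in
#' *every* population, minus an explicit exclusion list (behaviors that pass
#' the threshold but are not active display elements, e.g. a precondition
#' like face-off or locomotion like chasing, are excluded via `exclude`
#' rather than hard-coded).
#'
#' @param occurrence behavior x population table from
#'   [occurrence_proportions()].
#' @param threshold prevalence threshold in (0, 1); default 0.5.
#' @param exclude character vector of behaviors to drop regardless.
#' @return character vector of retained behavior labels.
#' @export
prevalence_filter <- function(occurrence, threshold = 0.5,
                              exclude = character()) {
  stopifnot(threshold >= 0, threshold < 1)
  keep <- apply(as.matrix(occurrence), 1, function(x) all(x > threshold))
  setdiff(rownames(occurrence)[keep], exclude)
}
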