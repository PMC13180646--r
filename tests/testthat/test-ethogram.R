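test_that("event logs are parsed and validated against the ethogram", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "pair_id,population,actor,behavior,start_s,end_s",
    "p1,GR,male,Orient,0,5",
    "p1,GR,male,Wing-vibrate,2,5",
    "p1,GR,female,Standing,0,4",
    "p2,GR,male,Face-off,1,3"), csv)
  ev <- load_event_log(csv)
  expect_equal(nrow(ev), 4)

  writeLines(c("pair_id,population,actor,behavior,start_s,end_s",
               "p1,GR,male,Orient,0,5",
               "p1,GR,male,Pirouette,1,2"), csv)
  expect_error(load_event_log(csv), "Pirouette.*rows: 2")

  writeLines(c("pair_id,actor,behavior,start_s",
               "p1,male,Orient,0"), csv)
  expect_error(load_event_log(csv), "missing column")

  writeLines(c("pair_id,population,actor,behavior,start_s,end_s",
               "p1,GR,male,Orient,5,5"), csv)
  expect_error(load_event_log(csv), "intervals.*rows: 1")

  # a female cannot straddle: wrong-sex scoring is rejected
  writeLines(c("pair_id,population,actor,behavior,start_s,end_s",
               "p1,GR,female,Straddle,0,2"), csv)
  expect_error(load_event_log(csv), "wrong sex")
  expect_equal(nrow(load_event_log(csv, check_sex = FALSE)), 1)
})

test_that("the default ethogram has 18 behaviors and the two sentinels", {
  eth <- ethogram_definition()
  expect_equal(nrow(eth), 18)
  expect_false(anyDuplicated(eth$behavior) > 0)
  expect_equal(unname(attr(eth, "sentinels")),
               c("Bout-start", "Bout-end"))
})

test_that("overlapping bouts produce composite states with sentinels", {
  ev <- data.frame(pair_id = "p1", population = "GR", actor = "male",
                   behavior = c("Orient", "Wing-vibrate"),
                   start_s = c(0, 2), end_s = c(5, 5))
  ss <- derive_state_sequence(ev, "p1", "male")
  expect_equal(ss$states, c("Bout-start", "Orient-(M)",
                            "Orient-Wing-vibrate-(M)", "Bout-end"))
  expect_equal(ss$start[2:3], c(0, 2))
  expect_equal(ss$end[2:3], c(2, 5))

  empty <- derive_state_sequence(ev, "p1", "female")
  expect_equal(empty$states, c("Bout-start", "Bout-end"))
})

test_that("sweep-line state derivation matches fine-grid labeling", {
  set.seed(42)
  behaviors <- c("Orient", "Wing-vibrate", "Wing-flash", "Face-off",
                 "Wing-sweep")
  for (rep in 1:10) {
    ev <- random_event_log(sample(3:10, 1), behaviors)
    got <- derive_state_sequence(ev, "p1", "male")$states
    expect_equal(got, grid_states(ev, "p1", "male"))
  }
})

test_that("courtship metrics are definitional proportions", {
  # one 10 s bout of Orient in a 100 s interaction; 5 Face-off bouts of the
  # 20 total bouts
  mk <- function(b, s, e) data.frame(pair_id = "p1", population = "GR",
                                     actor = "male", behavior = b,
                                     start_s = s, end_s = e)
  ev <- rbind(mk("Orient", 0, 10),
              mk("Face-off", 20 + 0:4 * 3, 21 + 0:4 * 3),
              mk("Wing-flash", 40 + 0:13 * 4, 41 + 0:13 * 4),
              mk("Wing-sweep", 99, 100))
  m <- courtship_metrics(ev)
  expect_equal(sum(m$n_bouts), 21)
  ev <- ev[-nrow(ev), ]  # 20 bouts, ending at 96; stretch last to 100
  ev$end_s[nrow(ev)] <- 100
  m <- courtship_metrics(ev)
  expect_equal(m$duration_prop[m$behavior == "Orient"], 0.10)
  expect_equal(m$frequency_prop[m$behavior == "Face-off"], 5 / 20)
  expect_equal(sum(m$frequency_prop), 1, tolerance = 1e-12)
  # single-bout behavior: inter-bout interval undefined
  expect_true(is.na(m$interval_prop[m$behavior == "Orient"]))
  expect_false(is.na(m$interval_prop[m$behavior == "Face-off"]))
})

test_that("metrics are invariant under uniform time rescaling", {
  set.seed(7)
  ev <- random_event_log(12, c("Orient", "Wing-flash", "Face-off"))
  m1 <- courtship_metrics(ev)
  ev2 <- transform(ev, start_s = start_s * 3.7, end_s = end_s * 3.7)
  m2 <- courtship_metrics(ev2)
  for (col in c("duration_prop", "frequency_prop", "interval_prop"))
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-12)
  ev$end_s <- ev$start_s <- 0
  expect_error(courtship_metrics(transform(ev, end_s = start_s)),
               "invalid|zero-duration")
})

test_that("occurrence proportions and the prevalence filter behave", {
  mk <- function(pair, pop, b) data.frame(
    pair_id = pair, population = pop, actor = "male", behavior = b,
    start_s = 0, end_s = 1, stringsAsFactors = FALSE)
  ev <- do.call(rbind, c(
    lapply(sprintf("a%02d", 1:15), function(p) mk(p, "A", "Orient")),
    lapply(sprintf("a%02d", 1:3), function(p) mk(p, "A", "Wing-sweep")),
    lapply(sprintf("b%02d", 1:15), function(p) mk(p, "B", "Orient")),
    lapply(sprintf("b%02d", 1:8), function(p) mk(p, "B", "Wing-sweep"))))
  occ <- occurrence_proportions(ev)
  expect_equal(occ["Wing-sweep", "A"], 3 / 15)
  expect_equal(occ["Orient", "A"], 1)
  expect_equal(occ["Orient", "B"], 1)
  # behaviors absent from a population report 0, not NA
  ev2 <- rbind(ev, mk("a01", "A", "Kick"))
  ev2$actor[nrow(ev2)] <- "female"
  occ2 <- occurrence_proportions(ev2)
  expect_identical(occ2["Kick", "B"], 0)

  # exactly the behaviors above the threshold in EVERY population pass
  expect_setequal(prevalence_filter(occ, 0.5), "Orient")
  expect_setequal(prevalence_filter(occ, 0), c("Orient", "Wing-sweep"))
  expect_setequal(prevalence_filter(occ, 0.5, exclude = "Orient"),
                  character(0))
  # 8/15 everywhere passes 0.5, <=7/15 anywhere does not
  ev3 <- rbind(ev, do.call(rbind, lapply(sprintf("a%02d", 1:8), function(p)
    mk(p, "A", "Wing-flash"))), do.call(rbind, lapply(
      sprintf("b%02d", 1:8), function(p) mk(p, "B", "Wing-flash"))))
  occ3 <- occurrence_proportions(ev3)
  expect_setequal(prevalence_filter(occ3, 0.5), c("Orient", "Wing-flash"))
})
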