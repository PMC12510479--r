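test_that("load_event_tables validates, sorts, and reports bad rows", {
  dir <- withr::local_tempdir()
  reg <- toy_registry()
  det <- data.frame(bird_id = c("J11", "J12", "F1"),
                    timestamp = c("100", "oops", "50"),
                    site_id = "s1", source = "network_feeder")
  puz <- data.frame(bird_id = c("F1", "J11"), timestamp = c(200, 150),
                    site_id = "s1", action = c("solve_left", "visit"))
  paths <- write_event_csvs(dir, reg, det, puz)
  out <- load_event_tables(paths$registry, paths$detections, paths$puzzle)
  expect_equal(nrow(out$detections), 2)
  expect_equal(nrow(out$rejects), 1)
  expect_equal(out$rejects$line, 3L) # header is line 1
  expect_match(out$rejects$reason, "timestamp")
  # time-sorted
  expect_false(is.unsorted(out$detections$timestamp))
  expect_false(is.unsorted(out$puzzle_events$timestamp))
})

test_that("empty event files with valid headers load as empty streams", {
  dir <- withr::local_tempdir()
  paths <- write_event_csvs(
    dir, toy_registry(),
    data.frame(bird_id = character(), timestamp = numeric(),
               site_id = character(), source = character()),
    data.frame(bird_id = character(), timestamp = numeric(),
               site_id = character(), action = character()))
  out <- load_event_tables(paths$registry, paths$detections, paths$puzzle)
  expect_equal(nrow(out$detections), 0)
  expect_equal(nrow(out$puzzle_events), 0)
  expect_equal(nrow(out$rejects), 0)
})

test_that("schema and referential errors are raised", {
  dir <- withr::local_tempdir()
  reg_bad <- toy_registry()
  reg_bad$mother_id[5] <- "GHOST"
  sub <- file.path(dir, "bad_reg")
  dir.create(sub)
  paths_bad <- write_event_csvs(
    sub, reg_bad,
    data.frame(bird_id = "J11", timestamp = 1, site_id = "s1",
               source = "network_feeder"),
    data.frame(bird_id = "J11", timestamp = 1, site_id = "s1",
               action = "visit"))
  expect_error(read_bird_registry(paths_bad$registry), "referential")
  paths <- write_event_csvs(
    dir, toy_registry(),
    data.frame(bird_id = "J11", timestamp = 1, site_id = "s1",
               source = "network_feeder"),
    data.frame(bird_id = "J11", timestamp = 1, site_id = "s1",
               action = "visit"))
  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(bird_id = "x", when = 1), bad, row.names = FALSE)
  expect_error(
    load_event_tables(paths$registry, bad, paths$puzzle),
    "schema error")
})

test_that("generator output round-trips through the CSV readers", {
  cfg <- small_config(seed = 21)
  scen <- simulate_scenario(cfg)
  dir <- withr::local_tempdir()
  paths <- write_event_csvs(dir, scen$registry, scen$detections,
                            scen$puzzle_events)
  out <- load_event_tables(paths$registry, paths$detections, paths$puzzle)
  expect_equal(nrow(out$rejects), 0)
  expect_equal(out$detections$bird_id, scen$detections$bird_id)
  expect_equal(out$detections$timestamp, scen$detections$timestamp)
  expect_equal(out$puzzle_events$action, scen$puzzle_events$action)
  expect_equal(out$registry$bird_id, scen$registry$bird_id)
})

test_that("derive_scrounges applies the 2-s same-site different-bird rule", {
  base <- data.frame(
    bird_id = c("A", "B", "A", "A", "C"),
    timestamp = c(100, 101.5, 101, 300, 302.5),
    site_id = c("s1", "s1", "s1", "s1", "s1"),
    action = c("solve_left", "visit", "visit", "solve_right", "visit"))
  sc <- derive_scrounges(base)
  # B within 1.5 s of A's solve scrounges; A's own visit does not;
  # C at 2.5 s is outside the window
  expect_equal(nrow(sc), 1)
  expect_equal(sc$bird_id, "B")
  expect_equal(sc$solver_id, "A")
  # different site never scrounges
  base2 <- base
  base2$site_id[2] <- "s2"
  expect_equal(nrow(derive_scrounges(base2)), 0)
})

test_that("derive_scrounges matches an exhaustive pairwise scan and is order-invariant", {
  set.seed(31)
  n <- 500
  ev <- data.frame(
    bird_id = sample(LETTERS[1:8], n, replace = TRUE),
    timestamp = round(cumsum(rexp(n, 0.4)), 2),
    site_id = sample(c("s1", "s2"), n, replace = TRUE),
    action = sample(c("solve_left", "solve_right", "visit"), n,
                    replace = TRUE, prob = c(0.3, 0.3, 0.4)))
  got <- derive_scrounges(ev)
  # oracle: double loop over all (solve, visit) pairs, most recent solve wins
  expected <- list()
  for (v in which(ev$action == "visit")) {
    cand <- which(ev$action %in% c("solve_left", "solve_right") &
                    ev$site_id == ev$site_id[v] &
                    ev$bird_id != ev$bird_id[v] &
                    ev$timestamp < ev$timestamp[v] &
                    ev$timestamp[v] - ev$timestamp <= 2)
    if (!length(cand)) next
    s <- cand[which.max(ev$timestamp[cand])]
    expected[[length(expected) + 1L]] <-
      c(ev$bird_id[v], ev$timestamp[v], ev$bird_id[s])
  }
  expect_equal(nrow(got), length(expected))
  exp_df <- as.data.frame(do.call(rbind, expected))
  o <- order(as.numeric(exp_df$V2))
  expect_equal(got$bird_id, exp_df$V1[o])
  expect_equal(got$solver_id, exp_df$V3[o])
  # permuted input gives the identical result
  got2 <- derive_scrounges(ev[sample(n), ])
  expect_equal(got, got2)
})

test_that("knowledge_states applies the 10-solve and third-solve rules", {
  reg <- toy_registry()
  mk <- function(id, times, action = "solve_left")
    data.frame(bird_id = id, timestamp = times, site_id = "s1",
               action = action)
  ev <- rbind(mk("J11", seq(5, 5 + 3 * 8, by = 3)),   # 9 solves
              mk("J12", seq(5, 5 + 3 * 11, by = 3)),  # 12 solves, 3rd at 11
              mk("F1", seq(1000, 1000 + 5 * 14, by = 5))) # adult, 15 solves
  ks <- knowledge_states(ev, reg, diffusion_start = 2000)
  expect_false(ks$knowledgeable[ks$bird_id == "J11"])
  expect_true(is.na(ks$acquisition_time[ks$bird_id == "J11"]))
  expect_true(ks$knowledgeable[ks$bird_id == "J12"])
  expect_equal(ks$acquisition_time[ks$bird_id == "J12"], 11)
  # adult with third solve before the diffusion start is a demonstrator
  expect_true(ks$demonstrator[ks$bird_id == "F1"])
  expect_false(ks$filtered[ks$bird_id == "F1"])
  # same adult is filtered when the diffusion starts earlier
  ks2 <- knowledge_states(ev, reg, diffusion_start = 500)
  expect_false(ks2$demonstrator[ks2$bird_id == "F1"])
  expect_true(ks2$filtered[ks2$bird_id == "F1"])
  # juveniles never demonstrator/filtered
  expect_false(any(ks$demonstrator[ks$bird_id %in% c("J11", "J12")]))
  expect_false(any(ks2$filtered[ks2$bird_id %in% c("J11", "J12")]))
  # idempotent
  expect_identical(ks, knowledge_states(ev, reg, diffusion_start = 2000))
  # unknown solver
  expect_error(knowledge_states(rbind(ev, mk("GHOST", 1)), reg, 0),
               "referential")
})

test_that("knowledge_states recovers the generator's schedule exactly", {
  cfg <- small_config(seed = 8)
  scen <- simulate_scenario(cfg)
  ks <- knowledge_states(scen$puzzle_events, scen$registry,
                         diffusion_start = 0)
  juv_known <- ks$bird_id[ks$knowledgeable &
                            ks$bird_id %in%
                            scen$registry$bird_id[
                              scen$registry$age_class == "juvenile"]]
  expect_setequal(juv_known, scen$sim$schedule$bird_id)
  # acquisition time <= time of 10th solve for every knowledgeable bird
  solves <- scen$puzzle_events[
    scen$puzzle_events$action %in% c("solve_left", "solve_right"), ]
  for (id in sample(juv_known, min(10, length(juv_known)))) {
    t10 <- sort(solves$timestamp[solves$bird_id == id])[10]
    expect_lte(ks$acquisition_time[ks$bird_id == id], t10)
  }
})
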