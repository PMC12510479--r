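test_that("parental strategy classification follows the 90% rule", {
  expect_equal(classify_parental_strategy(0, 0), "none")
  expect_equal(classify_parental_strategy(1, 19), "nonconflicting_right")
  expect_equal(classify_parental_strategy(19, 1), "nonconflicting_left")
  expect_equal(classify_parental_strategy(8, 12), "conflicting")
  # exactly 90% is not "more than 90%"
  expect_equal(classify_parental_strategy(2, 18), "conflicting")
})

test_that("side-choice covariates match hand counts", {
  t0 <- 30 * DAY
  ev <- data.frame(
    bird_id = c("A", "A", "B", "J", "J"),
    timestamp = c(t0 - 200, t0 - 100, t0 - 50, t0 - 1800, t0),
    site_id = "s1",
    action = c("solve_right", "solve_right", "solve_left", "solve_left",
               "solve_right"))
  reg <- toy_registry()
  reg$bird_id[reg$bird_id == "J11"] <- "J"
  rec <- build_side_choice_records(ev, reg)
  r <- rec[rec$solve_time == t0, ]
  # others' solves in 5 min: R, R, L
  expect_equal(r$social_prop_right, 2 / 3)
  expect_equal(r$social_count, 3L)
  # own prior solve within the hour: one left
  expect_equal(r$personal_prop_right, 0)
  expect_equal(r$cumulative_solves, 1L)
  expect_true(r$has_social && r$has_personal)
  # the first-ever solve has no personal information
  r1 <- rec[rec$solve_time == t0 - 1800, ]
  expect_true(is.na(r1$personal_prop_right))
  expect_false(r1$has_personal)
})

test_that("record builder matches a brute-force double loop on a 200-event fixture", {
  set.seed(41)
  reg <- toy_registry()
  juv_ids <- reg$bird_id[reg$age_class == "juvenile"]
  n <- 200
  ev <- data.frame(
    bird_id = sample(reg$bird_id, n, TRUE),
    timestamp = sort(30 * DAY + runif(n, 0, 3 * DAY)),
    site_id = sample(c("s1", "s2"), n, TRUE),
    action = sample(c("solve_left", "solve_right"), n, TRUE))
  rec <- build_side_choice_records(ev, reg)
  # oracle: double loop over juvenile solves and all events
  kept <- 0L
  for (r in seq_len(n)) {
    if (!(ev$bird_id[r] %in% juv_ids)) next
    kept <- kept + 1L
    t <- ev$timestamp[r]
    soc <- which(ev$bird_id != ev$bird_id[r] & ev$site_id == ev$site_id[r] &
                   ev$timestamp > t - 300 & ev$timestamp < t)
    own <- which(ev$bird_id == ev$bird_id[r] & ev$timestamp > t - 3600 &
                   ev$timestamp < t)
    row <- rec[rec$juvenile_id == ev$bird_id[r] & rec$solve_time == t, ]
    expect_equal(nrow(row), 1)
    expect_equal(row$social_count, length(soc))
    if (length(soc))
      expect_equal(row$social_prop_right,
                   mean(ev$action[soc] == "solve_right"))
    if (length(own))
      expect_equal(row$personal_prop_right,
                   mean(ev$action[own] == "solve_right"))
    expect_equal(row$cumulative_solves,
                 sum(ev$bird_id == ev$bird_id[r] & ev$timestamp < t))
  }
  expect_equal(nrow(rec), kept)
  # first-day flags: per-bird counts match an independent group-by
  for (id in unique(rec$juvenile_id)) {
    d <- rec[rec$juvenile_id == id, ]
    day1 <- floor(min(d$solve_time) / DAY)
    expect_equal(sum(d$first_day),
                 sum(floor(d$solve_time / DAY) == day1))
  }
})

test_that("exposure records use the learner/non-learner windows", {
  reg <- toy_registry()
  fledge <- unique(reg$fledge_date[reg$brood_id %in% "B1"])
  # parent F1 solves: 3 before J11's acquisition, 5 more after 15 d
  ev <- rbind(
    data.frame(bird_id = "F1", timestamp = fledge + c(1, 2, 3) * DAY,
               site_id = "s1", action = "solve_right"),
    data.frame(bird_id = "F1", timestamp = fledge + (16:20) * DAY,
               site_id = "s1", action = "solve_right"),
    # J11 becomes knowledgeable, third solve at fledge + 5 d
    data.frame(bird_id = "J11",
               timestamp = fledge + 5 * DAY + seq(0, 11) * 60,
               site_id = "s1", action = "solve_left"))
  ks <- knowledge_states(ev, reg, diffusion_start = 0)
  rec <- build_exposure_records(ev, reg, ks)
  r11 <- rec[rec$juvenile_id == "J11", ]
  expect_true(r11$learned)
  expect_equal(r11$n_parental_solves, 3) # only up to its acquisition
  expect_equal(r11$log_parental_solves, log10(4))
  # non-learner sibling: window is fledge + 15 d, so 3 solves count
  r12 <- rec[rec$juvenile_id == "J12", ]
  expect_false(r12$learned)
  expect_equal(r12$n_parental_solves, 3)
  # other brood: no parental solves at all
  expect_equal(rec$n_parental_solves[rec$juvenile_id == "J21"], 0)
  expect_equal(rec$parental_strategy[rec$juvenile_id == "J21"], "none")
})

test_that("exposure model covers a null effect and has coherent scaling", {
  set.seed(51)
  n <- 500
  solves <- rpois(n, 8)
  scrounges <- rpois(n, 5)
  eta <- -1.5 + 1.1 * log10(solves + 1) # scrounges truly null
  rec <- data.frame(
    juvenile_id = sprintf("J%03d", 1:n),
    learned = runif(n) < plogis(eta),
    log_parental_solves = log10(solves + 1),
    log_parental_scrounges = log10(scrounges + 1))
  fit <- fit_exposure_model(rec)
  sc <- fit$coefficients[fit$coefficients$term == "scrounges", ]
  expect_true(sc$lower <= 1 && sc$upper >= 1)
  so <- fit$coefficients[fit$coefficients$term == "solves", ]
  expect_true(so$lower <= exp(1.1) && so$upper >= exp(1.1))
  # with all-zero covariates the baseline equals the observed proportion
  rec0 <- rec
  rec0$log_parental_solves <- 0
  rec0$log_parental_scrounges <- 0
  fit0 <- fit_exposure_model(rec0)
  prop <- mean(rec0$learned)
  expect_true(fit0$baseline_prob["lower"] <= prop &&
                fit0$baseline_prob["upper"] >= prop)
  # doubling a covariate's scale halves its coefficient (weak priors)
  rec2 <- rec
  rec2$log_parental_solves <- 2 * rec2$log_parental_solves
  fit2 <- fit_exposure_model(rec2)
  expect_equal(fit2$coefficients$estimate[2],
               fit$coefficients$estimate[2] / 2, tolerance = 0.02)
})

test_that("side-choice estimators recover known effects and nulls", {
  rec <- simulate_side_choice_records(200, 4, or_social = 20,
                                      or_personal = 7.3, seed = 61)
  f <- fit_side_choice_models(rec, "all_days")
  gs <- f$table[f$table$term == "social_prop_right", ]
  expect_true(gs$lower <= 20 && gs$upper >= 20)
  expect_gt(gs$OR, 1)
  # no social signal: constant proportion at 0.5 (the term may be dropped
  # as rank-deficient, or estimated with an interval covering 1)
  rec0 <- rec
  rec0$social_prop_right <- 0.5
  f0 <- suppressMessages(fit_side_choice_models(rec0, "all_days"))
  g0 <- f0$table[f0$table$term == "social_prop_right", ]
  expect_true(nrow(g0) == 0 || isTRUE(is.na(g0$OR)) ||
                isTRUE(g0$lower <= 1 && g0$upper >= 1))
  # first-day social model runs on the first-day subset
  f1 <- fit_side_choice_models(rec, "first_day_social")
  expect_equal(f1$n_records, sum(rec$first_day))
  # single juvenile falls back to a fixed-effects GLM with a warning
  one <- rec[rec$juvenile_id == rec$juvenile_id[1], ]
  expect_warning(fit_side_choice_models(one, "all_days"), "fixed-effects")
})

test_that("the parental-strategy model contrasts strategies against none", {
  set.seed(72)
  juv <- sprintf("J%03d", 1:200)
  strat <- rep(c("none", "nonconflicting_right", "nonconflicting_left",
                 "conflicting"), 50)
  rows <- list()
  for (i in seq_along(juv)) {
    k <- sample(3:8, 1)
    # right-solve probability independent of strategy (the null the paper
    # found): all ORs should cover 1
    for (r in seq_len(k))
      rows[[length(rows) + 1L]] <- data.frame(
        juvenile_id = juv[i], solve_time = i * 1000 + r,
        site_id = "s1", choice_right = rbinom(1, 1, 0.5),
        social_prop_right = NA, social_count = 0L,
        personal_prop_right = NA, personal_count = 0L,
        cumulative_solves = r - 1L, first_day = TRUE,
        has_social = FALSE, has_personal = FALSE,
        parental_strategy = strat[i])
  }
  rec <- do.call(rbind, rows)
  f <- fit_side_choice_models(rec, "first_day_parental")
  or_rows <- f$table[-1, ]
  expect_true(all(or_rows$lower <= 1 & or_rows$upper >= 1))
})
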