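# Shared fixtures and independent oracles, built in code at test time.

DAY <- 86400

# 10-bird toy registry: 2 broods of 3 juveniles plus their 4 parents.
# Covers every dyad class (parents of the other brood are oblique).
toy_registry <- function() {
  data.frame(
    bird_id = c("F1", "M1", "F2", "M2",
                "J11", "J12", "J13", "J21", "J22", "J23"),
    age_class = c(rep("adult", 4), rep("juvenile", 6)),
    mother_id = c(rep(NA, 4), "F1", "F1", "F1", "F2", "F2", "F2"),
    father_id = c(rep(NA, 4), "M1", "M1", "M1", "M2", "M2", "M2"),
    brood_id = c(rep(NA, 4), "B1", "B1", "B1", "B2", "B2", "B2"),
    fledge_date = c(rep(NA, 4), rep(2 * DAY, 3), rep(3 * DAY, 3)),
    stringsAsFactors = FALSE)
}

# gathering-event list from a membership list
make_gatherings <- function(member_sets, site = "s1", day = 0) {
  lapply(seq_along(member_sets), function(i)
    list(site_id = site, day = day, members = member_sets[[i]],
         start = day * DAY + i * 1000, end = day * DAY + i * 1000 + 60))
}

# Hand-built diffusion fixture: 10 birds, 6 events, all four layers carrying
# weight, ILVs, a presence gap and staggered entry. Used by the likelihood
# and decomposition oracles.
make_site_fixture <- function(seed = 7, n_ilv = 2) {
  set.seed(seed)
  reg <- toy_registry()
  ids <- reg$bird_id
  n <- length(ids)
  masks <- layer_masks(reg)
  sri <- matrix(0, n, n, dimnames = list(ids, ids))
  sri[upper.tri(sri)] <- round(runif(n * (n - 1) / 2, 0.05, 0.9), 3)
  sri <- sri + t(sri)
  layers <- lapply(masks, function(m) sri * m)
  net <- network_layer_set(ids, layers)
  events <- data.frame(
    learner_id = c("J11", "J21", "J12", "J22", "J13", "J23"),
    time = c(2.5, 4.0, 7.25, 9.5, 11.0, 12.5))
  t_end <- 14
  S <- nrow(events) + 1L
  w <- matrix(rlnorm(S * n, log(4), 0.3), S, n)
  presence <- matrix(1L, S, n)
  presence[3, match("J22", ids)] <- 0L # temporary absence of a naive bird
  ilvs <- if (n_ilv > 0)
    array(round(rnorm(S * n * n_ilv, 0, 0.6), 3), dim = c(S, n, n_ilv))
  else NULL
  entry <- c(rep(0, 4), rep(1.0, 3), rep(1.5, 3))
  diffusion_site(
    ids = ids, learner_pool = reg$age_class == "juvenile",
    events = events, t_end = t_end, networks = net,
    demonstrators = c("F1", "F2"),
    filtered_acq = c(M2 = 6.0), # adult turning transmitter mid-diffusion
    w = w, presence = presence, entry = entry, ilvs = ilvs,
    brood = reg$brood_id, site_id = "s1")
}

make_fixture_data <- function(seed = 7, n_ilv = 2) {
  diffusion_data(list(make_site_fixture(seed, n_ilv)))
}

fixture_params <- function(weibull = FALSE) {
  list(s = list(vertical = 1.2, oblique = 0.7, sibling = 2.5, peer = 0.4),
       beta_a = c(0.3, -0.2), beta_s = c(-0.4, 0.25),
       theta = 9, kappa = if (weibull) 1.7 else 1)
}

fixture_spec <- function(weibull = FALSE) {
  tada_spec(networks = c("vertical", "oblique", "sibling", "peer"),
            ilv = c("both", "both"),
            baseline = if (weibull) "weibull" else "constant")
}

# Independent likelihood oracle: trapezoid quadrature of the pointwise
# hazard plus log-hazard at the event times.
quadrature_loglik <- function(data, params, spec, ngrid = 3000) {
  total <- 0
  for (site in data$sites) {
    S <- length(site$bounds) - 1L
    for (i in seq_along(site$ids)) {
      for (m in seq_len(S)) {
        if (!site$at_risk[m, i] || !site$presence[m, i]) next
        a <- max(site$bounds[m], site$entry[i])
        b <- site$bounds[m + 1]
        if (b <= a) next
        ts <- seq(a + 1e-9, b, length.out = ngrid)
        hs <- vapply(ts, function(t)
          hazard(site, site$ids[i], t, params, spec), numeric(1))
        total <- total - sum((hs[-1] + hs[-ngrid]) / 2 * diff(ts))
      }
    }
    for (e in seq_len(nrow(site$events)))
      total <- total + log(hazard(site, site$events$learner_id[e],
                                  site$events$time[e], params, spec))
  }
  total
}

# small helper: write the three event CSVs and return their paths
write_event_csvs <- function(dir, registry, detections, puzzle_events) {
  paths <- list(registry = file.path(dir, "registry.csv"),
                detections = file.path(dir, "detections.csv"),
                puzzle = file.path(dir, "puzzle_events.csv"))
  write.csv(registry[, c("bird_id", "age_class", "mother_id", "father_id",
                         "brood_id", "fledge_date")],
            paths$registry, row.names = FALSE, na = "")
  write.csv(detections, paths$detections, row.names = FALSE)
  write.csv(puzzle_events, paths$puzzle, row.names = FALSE)
  paths
}

# tiny scenario for fast end-to-end tests
small_config <- function(seed, ...) {
  scenario_config(seed = seed, n_sites = 2, pairs_per_site = 6,
                  duration = 42, ...)
}
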