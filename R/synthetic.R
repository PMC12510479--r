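#' Scenario configuration for the synthetic study system
#'
#' Defines a desk-scale version of the field system: breeding pairs at a few
#' puzzle-box sites, clutches of tagged juveniles fledging over a spring
#' window, family-biased co-feeding at RFID feeders, a diffusion of puzzle
#' solving with known pathway-specific transmission rates, and solve streams
#' with side choices and scrounging.
#'
#' Defaults give roughly 240 juveniles at 4 sites with sibling-dominant
#' transmission (s ordered sibling > oblique > vertical, peer 0), a weak
#' asocial rate, an 8-week diffusion, and side-choice rules with a conformist
#' social bias that fades with experience while personal information gains
#' weight.
#'
#' @param seed Integer seed (mandatory; governs every stochastic component).
#' @param n_sites,pairs_per_site,clutch_range Population structure.
#' @param fledge_spread Days over which broods fledge after diffusion start.
#' @param duration Diffusion length in days.
#' @param assoc_probs Named inclusion probabilities of birds in a gathering
#'   anchored on a brood: `sibling` (that brood's juveniles), `vertical`
#'   (its parents), `oblique` (other adults), `peer` (other juveniles).
#'   Must satisfy sibling > vertical > oblique/peer.
#' @param gatherings_per_day,visits_per_member,visit_sd Feeder-stream shape
#'   (events per feeder day; detections per included bird; within-event
#'   timestamp SD in seconds).
#' @param feeder_weekdays Integer weekdays (0-6) on which feeders run.
#' @param n_demonstrators Knowledgeable adults per site at diffusion start.
#' @param s Named true transmission rates per layer.
#' @param baseline,theta,kappa True baseline family and parameters (days).
#' @param beta_a,beta_s True ILV effects (length 2; defaults 0 — the
#'   diffusion simulator runs without ILV heterogeneity unless given a
#'   per-bird ILV matrix).
#' @param solve_rate_meanlog,solve_rate_sdlog Lognormal solve-rate
#'   distribution (solves per day) for knowledgeable birds.
#' @param scrounge_prob Probability a solve is followed by a scrounge.
#' @param side_or Named true side-choice odds ratios: `social`, `personal`,
#'   and their interactions with experience per 100 solves (`social_exp`,
#'   `personal_exp`).
#' @param demonstrator_fidelity Probability a demonstrator solves on its
#'   assigned side.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed,
                            n_sites = 4, pairs_per_site = 12,
                            clutch_range = c(4, 6), fledge_spread = 10,
                            duration = 56,
                            assoc_probs = c(sibling = 0.6, vertical = 0.35,
                                            oblique = 0.12, peer = 0.12),
                            gatherings_per_day = 8, visits_per_member = 2,
                            visit_sd = 60, feeder_weekdays = c(4, 5),
                            n_demonstrators = 2,
                            s = c(vertical = 8, oblique = 6,
                                  sibling = 600, peer = 0),
                            baseline = "constant", theta = 6000, kappa = 1,
                            beta_a = c(0, 0), beta_s = c(0, 0),
                            solve_rate_meanlog = log(6),
                            solve_rate_sdlog = 0.4,
                            scrounge_prob = 0.15,
                            side_or = c(social = 19.5, personal = 7.3,
                                        social_exp = 0.76,
                                        personal_exp = 1.22),
                            demonstrator_fidelity = 0.95) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(s >= 0), theta > 0, kappa > 0,
            all(assoc_probs >= 0 & assoc_probs <= 1),
            scrounge_prob >= 0 && scrounge_prob <= 1)
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate the synthetic population
#'
#' Breeding pairs per site, each with one brood of tagged juveniles sharing
#' a fledge date; deterministic under the config seed.
#'
#' @param config A [scenario_config()].
#' @return Registry data.frame (with an extra `site_id` column); fledge
#'   dates in seconds since diffusion start.
#' @export
generate_population <- function(config) {
  set.seed(config$seed)
  rows <- list()
  for (s in seq_len(config$n_sites)) {
    site <- sprintf("site%02d", s)
    for (p in seq_len(config$pairs_per_site)) {
      mom <- sprintf("%s_F%02d", site, p)
      dad <- sprintf("%s_M%02d", site, p)
      brood <- sprintf("%s_B%02d", site, p)
      for (id in c(mom, dad))
        rows[[length(rows) + 1L]] <- data.frame(
          bird_id = id, age_class = "adult", mother_id = NA_character_,
          father_id = NA_character_, brood_id = NA_character_,
          fledge_date = NA_real_, site_id = site, stringsAsFactors = FALSE)
      cl_vals <- seq(config$clutch_range[1], config$clutch_range[2])
      clutch <- cl_vals[sample.int(length(cl_vals), 1)]
      fledge <- stats::runif(1, 0, config$fledge_spread) * .DAY
      for (j in seq_len(clutch))
        rows[[length(rows) + 1L]] <- data.frame(
          bird_id = sprintf("%s_J%02d", brood, j), age_class = "juvenile",
          mother_id = mom, father_id = dad, brood_id = brood,
          fledge_date = fledge, site_id = site, stringsAsFactors = FALSE)
    }
  }
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  validate_registry(reg)
  reg
}

#' Simulate the RFID feeder detection stream
#'
#' Per site and feeder day, gathering events anchored on a cycling brood;
#' membership is family-biased (sibling inclusion > parental > other), so
#' downstream simple-ratio indices reproduce the configured ordering.
#' Juveniles appear only after their fledge date.
#'
#' @param registry Output of [generate_population()].
#' @param config A [scenario_config()].
#' @return Detection data.frame (`bird_id,timestamp,site_id,source`).
#' @export
simulate_associations <- function(registry, config) {
  set.seed(config$seed + 1L)
  p <- config$assoc_probs
  ids <- character()
  tss <- numeric()
  sites <- character()
  true_gat <- list()
  for (site in unique(registry$site_id)) {
    reg <- registry[registry$site_id == site, , drop = FALSE]
    broods <- unique(stats::na.omit(reg$brood_id))
    feeder_days <- which((seq_len(config$duration) - 1) %% 7 %in%
                           config$feeder_weekdays) - 1
    ev_counter <- 0L
    for (d in feeder_days) {
      centers <- d * .DAY + seq(8 * 3600, 16 * 3600,
                                length.out = config$gatherings_per_day) +
        stats::runif(config$gatherings_per_day, -600, 600)
      for (ct in centers) {
        ev_counter <- ev_counter + 1L
        anchor <- broods[(ev_counter - 1L) %% length(broods) + 1L]
        juv <- reg$age_class == "juvenile" & reg$fledge_date <= d * .DAY
        anchor_juv <- juv & reg$brood_id == anchor
        anchor_par <- reg$bird_id %in%
          c(reg$mother_id[which(anchor_juv)[1]],
            reg$father_id[which(anchor_juv)[1]])
        prob <- ifelse(anchor_juv, p["sibling"],
                ifelse(anchor_par, p["vertical"],
                ifelse(reg$age_class == "adult", p["oblique"],
                ifelse(juv, p["peer"], 0))))
        prob[is.na(prob)] <- 0
        members <- reg$bird_id[stats::runif(nrow(reg)) < prob]
        if (!length(members)) next
        nv <- sample(seq_len(max(1, config$visits_per_member)),
                     length(members), replace = TRUE)
        bird <- rep(members, nv)
        ts <- stats::rnorm(length(bird), ct, config$visit_sd)
        ids <- c(ids, bird)
        tss <- c(tss, ts)
        sites <- c(sites, rep(site, length(bird)))
        true_gat[[length(true_gat) + 1L]] <- list(
          site_id = site, day = d, members = members,
          start = min(ts), end = max(ts))
      }
    }
  }
  det <- data.frame(bird_id = ids, timestamp = tss, site_id = sites,
                    source = "network_feeder", stringsAsFactors = FALSE)
  det <- det[order(det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  # the generator's true gathering memberships, for truth-path networks
  attr(det, "gatherings") <- true_gat
  det
}

#' Static per-site networks from a detection stream
#'
#' Gathering events over the whole stream, simple-ratio indices, and layer
#' masks, one [network_layer_set()] per site over that site's birds. Used as
#' the ground-truth contact structure for diffusion simulation.
#'
#' @param detections Feeder detections.
#' @param registry Registry with `site_id`.
#' @param min_registrations Global feeder-registration filter (default 0:
#'   keep everyone for the generative truth).
#' @param gatherings Optional gathering-event list; defaults to the
#'   generator's true memberships when `detections` carries them (as the
#'   `"gatherings"` attribute from [simulate_associations()]), else the
#'   events are re-detected by mixture clustering.
#' @return Named list of `network_layer_set`, keyed by site.
#' @export
static_site_networks <- function(detections, registry, min_registrations = 0,
                                 gatherings = NULL) {
  if (is.null(gatherings)) gatherings <- attr(detections, "gatherings")
  out <- list()
  for (site in unique(registry$site_id)) {
    reg <- registry[registry$site_id == site, , drop = FALSE]
    det <- detections[detections$site_id == site, , drop = FALSE]
    nreg <- table(det$bird_id)
    ids <- reg$bird_id[reg$bird_id %in%
                         names(nreg)[nreg >= min_registrations] |
                         min_registrations == 0]
    gat <- if (!is.null(gatherings))
      Filter(function(g) g$site_id == site, gatherings)
    else if (nrow(det)) gathering_events(det) else list()
    sri <- .sri_matrix(gat, ids)
    masks <- layer_masks(registry, ids)
    out[[site]] <- network_layer_set(ids, lapply(masks, function(m) sri * m))
  }
  out
}

#' Simulate the diffusion of solving with known transmission truth
#'
#' Exact event-driven simulation of the TADA model on the supplied per-site
#' networks: each naive, fledged juvenile has hazard
#' `lambda0(t) (1 + sum_k s_k sum_j a_ij^k w_j z_j)`, next learner and
#' waiting time are drawn by time-rescaling (exact for both constant and
#' Weibull baselines), and the ground-truth pathway label is drawn
#' proportional to the learner's hazard components. Knowledge and
#' transmission weights update at each event; demonstrators are knowledgeable
#' from the start and never learn.
#'
#' @param registry Output of [generate_population()].
#' @param networks Named list of per-site [network_layer_set()]s (e.g. from
#'   [static_site_networks()]).
#' @param config A [scenario_config()].
#' @param max_events Stop after this many acquisition events per site
#'   (default unlimited; `1` draws just the next learner, e.g. for
#'   Monte-Carlo checks of the model-implied next-learner distribution).
#' @param rates Optional named per-bird solve rates, overriding the draw
#'   from the configured distribution.
#' @return A `diffusion_sim` list: `schedule` (bird, site, time in days,
#'   true pathway label), `rates` (solve rates per bird), `demonstrators`
#'   (with assigned sides), plus the inputs.
#' @export
simulate_diffusion <- function(registry, networks, config,
                               max_events = Inf, rates = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(rates)) rates <- stats::setNames(
    stats::rlnorm(nrow(registry), config$solve_rate_meanlog,
                  config$solve_rate_sdlog), registry$bird_id)
  theta <- config$theta
  kappa <- if (config$baseline == "weibull") config$kappa else 1
  Lam0 <- function(t) .Lambda0(t, theta, kappa, config$baseline)
  Lam0_inv <- function(L) theta * L^(1 / kappa)

  demos <- list()
  sched <- list()
  for (site in names(networks)) {
    net <- networks[[site]]
    reg <- registry[match(net$node_ids, registry$bird_id), , drop = FALSE]
    n <- nrow(reg)
    adults <- which(reg$age_class == "adult")
    dem <- adults[seq_len(min(config$n_demonstrators, length(adults)))]
    demos[[site]] <- data.frame(
      bird_id = reg$bird_id[dem], site_id = site,
      side = rep(c("right", "left"), length.out = length(dem)),
      stringsAsFactors = FALSE)
    z <- rep(0L, n)
    z[dem] <- 1L
    n_done <- 0L
    entry <- ifelse(is.na(reg$fledge_date), 0, reg$fledge_date / .DAY)
    naive <- reg$age_class == "juvenile"
    A <- lapply(.LAYERS, function(k) net$layers[[k]])
    names(A) <- .LAYERS
    w <- rates[reg$bird_id]
    t <- 0
    repeat {
      active <- naive & entry <= t
      comp <- matrix(0, n, 5,
                     dimnames = list(NULL, c("asocial", .LAYERS)))
      comp[active, "asocial"] <- 1
      for (k in .LAYERS) if (config$s[[k]] > 0)
        comp[active, k] <- config$s[[k]] *
          as.numeric(A[[k]][active, , drop = FALSE] %*% (w * z))
      R <- rowSums(comp)
      Rtot <- sum(R)
      next_cp <- min(c(entry[naive & entry > t], config$duration))
      if (Rtot <= 0) {
        if (next_cp >= config$duration) break
        t <- next_cp
        next
      }
      u <- stats::rexp(1)
      tau <- Lam0_inv(Lam0(t) + u / Rtot)
      if (tau > next_cp) {
        t <- next_cp
        if (t >= config$duration) break
        next
      }
      i <- sample.int(n, 1, prob = R)
      label <- sample(colnames(comp), 1, prob = comp[i, ])
      sched[[length(sched) + 1L]] <- data.frame(
        bird_id = reg$bird_id[i], site_id = site, time = tau,
        pathway = label, stringsAsFactors = FALSE)
      naive[i] <- FALSE
      z[i] <- 1L
      t <- tau
      n_done <- n_done + 1L
      if (n_done >= max_events || !any(naive)) break
    }
  }
  schedule <- if (length(sched)) do.call(rbind, sched)
    else data.frame(bird_id = character(), site_id = character(),
                    time = numeric(), pathway = character())
  schedule <- schedule[order(schedule$site_id, schedule$time), ]
  rownames(schedule) <- NULL
  structure(list(registry = registry, networks = networks, config = config,
                 schedule = schedule, rates = rates,
                 demonstrators = do.call(rbind, demos),
                 t_end = config$duration),
            class = "diffusion_sim")
}

#' Convert a simulated diffusion to TADA diffusion data
#'
#' Builds the exact [diffusion_data()] counterpart of the simulation: static
#' true networks, true solve rates as transmission weights, fledge dates as
#' entry times, no ILVs. Fitting this data tests the inferential machinery
#' free of network-estimation noise.
#'
#' @param sim A `diffusion_sim`.
#' @return A `diffusion_data` object.
#' @export
as_diffusion_data <- function(sim) {
  sites <- list()
  for (site in names(sim$networks)) {
    net <- sim$networks[[site]]
    reg <- sim$registry[match(net$node_ids, sim$registry$bird_id), ,
                        drop = FALSE]
    ev <- sim$schedule[sim$schedule$site_id == site, , drop = FALSE]
    events <- data.frame(learner_id = ev$bird_id, time = ev$time)
    dem <- sim$demonstrators$bird_id[sim$demonstrators$site_id == site]
    sites[[site]] <- diffusion_site(
      ids = reg$bird_id, learner_pool = reg$age_class == "juvenile",
      events = events, t_end = sim$t_end, networks = net,
      demonstrators = dem, w = sim$rates[reg$bird_id],
      entry = ifelse(is.na(reg$fledge_date), 0, reg$fledge_date / .DAY),
      brood = reg$brood_id, site_id = site)
  }
  diffusion_data(sites)
}

#' Simulate the puzzle-box event stream
#'
#' Knowledgeable birds emit solves at their individual rates from their
#' acquisition time on. Juvenile learners' first three solves fall at the
#' scheduled acquisition time (+0/60/120 s) and their totals are topped up to
#' the knowledgeable threshold, so [knowledge_states()] recovers the
#' schedule exactly. Side choices follow the configured conformity /
#' personal-information rule; scrounges (visits by another bird within 2 s)
#' are inserted with the configured probability.
#'
#' @param sim A `diffusion_sim`.
#' @param min_solves Minimum solves per learner (default 10).
#' @return Puzzle event data.frame (`bird_id,timestamp,site_id,action`),
#'   time-sorted.
#' @export
simulate_puzzle_stream <- function(sim, min_solves = 10) {
  config <- sim$config
  set.seed(config$seed + 3L)
  T_sec <- sim$t_end * .DAY
  solver_rows <- list()
  for (site in names(sim$networks)) {
    dem <- sim$demonstrators[sim$demonstrators$site_id == site, , drop = FALSE]
    ev <- sim$schedule[sim$schedule$site_id == site, , drop = FALSE]
    # demonstrator solves over the whole period
    for (r in seq_len(nrow(dem))) {
      rate <- sim$rates[dem$bird_id[r]]
      nsolve <- stats::rpois(1, rate * sim$t_end)
      if (!nsolve) next
      solver_rows[[length(solver_rows) + 1L]] <- data.frame(
        bird_id = dem$bird_id[r], timestamp = sort(stats::runif(nsolve, 0, T_sec)),
        site_id = site, role = "demonstrator", side_pref = dem$side[r],
        stringsAsFactors = FALSE)
    }
    # learner solves from acquisition on
    for (r in seq_len(nrow(ev))) {
      id <- ev$bird_id[r]
      acq_sec <- ev$time[r] * .DAY
      first3 <- acq_sec + c(0, 60, 120)
      rest_n <- stats::rpois(1, sim$rates[id] *
                               max(sim$t_end - ev$time[r], 0))
      rest_n <- max(rest_n, min_solves) - 3L
      rest <- if (rest_n > 0 && T_sec > acq_sec + 180)
        sort(stats::runif(rest_n, acq_sec + 180, T_sec)) else numeric()
      solver_rows[[length(solver_rows) + 1L]] <- data.frame(
        bird_id = id, timestamp = c(first3, rest), site_id = site,
        role = "learner", side_pref = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(solver_rows))
    return(data.frame(bird_id = character(), timestamp = numeric(),
                      site_id = character(), action = character()))
  solves <- do.call(rbind, solver_rows)
  solves <- solves[order(solves$site_id, solves$timestamp), ]
  rownames(solves) <- NULL

  lo <- log(config$side_or)
  out <- list()
  for (site in unique(solves$site_id)) {
    d <- solves[solves$site_id == site, , drop = FALSE]
    right <- logical(nrow(d))
    cum <- stats::setNames(rep(0L, length(unique(d$bird_id))),
                           unique(d$bird_id))
    for (r in seq_len(nrow(d))) {
      t <- d$timestamp[r]
      if (d$role[r] == "demonstrator") {
        pr <- if (d$side_pref[r] == "right") config$demonstrator_fidelity
              else 1 - config$demonstrator_fidelity
        right[r] <- stats::runif(1) < pr
      } else {
        id <- d$bird_id[r]
        win <- d$timestamp > t - 300 & d$timestamp < t & d$bird_id != id
        own <- d$timestamp > t - 3600 & d$timestamp < t & d$bird_id == id
        sprop <- if (any(win)) mean(right[win]) else 0.5
        pprop <- if (any(own)) mean(right[own]) else 0.5
        c100 <- cum[id] / 100
        eta <- (lo["social"] + lo["social_exp"] * c100) * (sprop - 0.5) +
          (lo["personal"] + lo["personal_exp"] * c100) * (pprop - 0.5)
        right[r] <- stats::runif(1) < stats::plogis(eta)
        cum[id] <- cum[id] + 1L
      }
    }
    d$action <- ifelse(right, "solve_right", "solve_left")
    out[[site]] <- d[, c("bird_id", "timestamp", "site_id", "action")]
  }
  puz <- do.call(rbind, out)

  # scrounges: another bird of the site visits within (0.5, 2] s of a solve
  site_birds <- split(sim$registry$bird_id, sim$registry$site_id)
  scr <- list()
  doscr <- which(stats::runif(nrow(puz)) < config$scrounge_prob)
  for (r in doscr) {
    pool <- setdiff(site_birds[[puz$site_id[r]]], puz$bird_id[r])
    if (!length(pool)) next
    scr[[length(scr) + 1L]] <- data.frame(
      bird_id = sample(pool, 1),
      timestamp = puz$timestamp[r] + stats::runif(1, 0.5, 2),
      site_id = puz$site_id[r], action = "visit", stringsAsFactors = FALSE)
  }
  res <- rbind(puz, if (length(scr)) do.call(rbind, scr))
  res <- res[order(res$timestamp), ]
  rownames(res) <- NULL
  res
}

#' Simulate the full scenario end-to-end
#'
#' Population, feeder associations, ground-truth networks, diffusion and
#' puzzle stream, in one call; the CSV schemas of the outputs are exactly
#' those consumed by [load_event_tables()].
#'
#' @param config A [scenario_config()].
#' @return List: `config`, `registry`, `detections`, `networks` (truth),
#'   `sim` (the `diffusion_sim`), `puzzle_events`.
#' @export
simulate_scenario <- function(config) {
  registry <- generate_population(config)
  detections <- simulate_associations(registry, config)
  networks <- static_site_networks(detections, registry)
  sim <- simulate_diffusion(registry, networks, config)
  puzzle_events <- simulate_puzzle_stream(sim)
  list(config = config, registry = registry, detections = detections,
       networks = networks, sim = sim, puzzle_events = puzzle_events)
}

#' Simulate side-choice records with known odds ratios
#'
#' Record-level generator for validating the side-choice estimators: social
#' and personal right-proportions are drawn from a U-shaped beta (mimicking
#' locally biased option use), experience accumulates within juveniles, and
#' choices follow a logistic rule with the supplied odds ratios (per 0-to-1
#' change of a proportion; interaction ORs per 100 solves of experience).
#'
#' @param n_juveniles,solves_each Records = `n_juveniles * solves_each`.
#' @param or_social,or_personal,or_social_exp,or_personal_exp True ORs.
#' @param experience_step Increase in cumulative solves between a juvenile's
#'   consecutive records.
#' @param sd_juvenile SD of the juvenile-level random intercept.
#' @param seed Integer seed.
#' @return data.frame shaped like [build_side_choice_records()] output
#'   (with `has_social`/`has_personal` all `TRUE` and `first_day` set for
#'   the first record of each juvenile).
#' @export
simulate_side_choice_records <- function(n_juveniles, solves_each,
                                         or_social = 19.5, or_personal = 7.3,
                                         or_social_exp = 1,
                                         or_personal_exp = 1,
                                         experience_step = 50,
                                         sd_juvenile = 0.3, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (j in seq_len(n_juveniles)) {
    a <- stats::rnorm(1, 0, sd_juvenile)
    for (r in seq_len(solves_each)) {
      sprop <- stats::rbeta(1, 0.7, 0.7)
      pprop <- stats::rbeta(1, 0.7, 0.7)
      cum <- (r - 1L) * experience_step
      c100 <- cum / 100
      eta <- a + (log(or_social) + log(or_social_exp) * c100) * (sprop - 0.5) +
        (log(or_personal) + log(or_personal_exp) * c100) * (pprop - 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        juvenile_id = sprintf("J%03d", j), solve_time = r * 600 + j,
        site_id = "site01",
        choice_right = stats::rbinom(1, 1, stats::plogis(eta)),
        social_prop_right = sprop, social_count = 1L + stats::rpois(1, 3),
        personal_prop_right = pprop, personal_count = 1L + stats::rpois(1, 5),
        cumulative_solves = cum, first_day = r == 1L,
        has_social = TRUE, has_personal = TRUE,
        parental_strategy = "none", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
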