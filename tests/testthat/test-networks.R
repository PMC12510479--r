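test_that("gathering detection separates well-spaced bursts and handles degenerate input", {
  set.seed(2)
  ts <- c(rnorm(8, 10 * 3600, 60), rnorm(8, 14 * 3600, 60))
  det <- data.frame(
    bird_id = c("A", "B", "C", "A", "B", "C", "A", "B",
                "A", "D", "A", "D", "A", "D", "A", "D"),
    timestamp = ts, site_id = "s1")
  gat <- detect_gathering_events(det)
  expect_length(gat, 2)
  members <- lapply(gat, `[[`, "members")
  expect_true(any(vapply(members, setequal, logical(1), c("A", "B", "C"))))
  expect_true(any(vapply(members, setequal, logical(1), c("A", "D"))))
  # all-identical timestamps collapse to one event
  det2 <- data.frame(bird_id = c("A", "B", "C"), timestamp = 100,
                     site_id = "s1")
  expect_length(detect_gathering_events(det2), 1)
  # single detection -> singleton event
  expect_length(detect_gathering_events(det2[1, ]), 1)
})

test_that("mixture clustering recovers a 3-component visiting schedule", {
  set.seed(5)
  means <- c(9, 12, 15) * 3600
  truth <- rep(1:3, each = 40)
  ts <- rnorm(120, means[truth], 90)
  det <- data.frame(bird_id = sprintf("B%02d", sample(1:20, 120, TRUE)),
                    timestamp = ts, site_id = "s1")
  gat <- detect_gathering_events(det)
  # assign each detection to the component whose span contains it (nearest
  # event center otherwise), then score against the generating labels
  centers <- vapply(gat, function(g) (g$start + g$end) / 2, numeric(1))
  assigned <- vapply(ts, function(t) which.min(abs(centers - t)), integer(1))
  # map each true component to its modal detected event
  correct <- 0
  for (k in 1:3) {
    modal <- as.integer(names(which.max(table(assigned[truth == k]))))
    correct <- correct + sum(assigned[truth == k] == modal)
  }
  expect_gte(correct / 120, 0.95)
})

test_that("simple-ratio index matches hand counts and its bounds", {
  g_all <- make_gatherings(rep(list(c("A", "B")), 5))
  expect_equal(simple_ratio_index(g_all, "A", "B"), 1)
  g_disj <- make_gatherings(list("A", "A", "B", "B"))
  expect_equal(simple_ratio_index(g_disj, "A", "B"), 0)
  g_half <- make_gatherings(list(c("A", "B"), c("A", "B"), "A", "B"))
  expect_equal(simple_ratio_index(g_half, "A", "B"), 0.5)
  # never observed at all
  expect_equal(simple_ratio_index(g_half, "X", "Y"), 0)
})

test_that("SRI is symmetric, bounded, and monotone under added sightings", {
  set.seed(11)
  ids <- LETTERS[1:6]
  sets <- replicate(20, sample(ids, sample(2:5, 1)), simplify = FALSE)
  g <- make_gatherings(sets)
  M <- tadanet:::.sri_matrix(g, ids)
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  # matrix path equals the pairwise op
  for (p in list(c("A", "B"), c("C", "F"), c("B", "E")))
    expect_equal(M[p[1], p[2]], simple_ratio_index(g, p[1], p[2]))
  # a joint sighting never decreases, a lone sighting never increases
  s0 <- simple_ratio_index(g, "A", "B")
  expect_gte(simple_ratio_index(c(g, make_gatherings(list(c("A", "B")))),
                                "A", "B"), s0)
  expect_lte(simple_ratio_index(c(g, make_gatherings(list("A"))),
                                "A", "B"), s0)
})

test_that("layer masks match a brute-force rule checker and partition dyads", {
  reg <- toy_registry()
  masks <- layer_masks(reg)
  expect_true(masks$vertical["J11", "F1"])  # own mother
  expect_true(masks$sibling["J11", "J12"])  # same brood
  expect_true(masks$oblique["J11", "F2"])   # unrelated adult
  expect_true(masks$peer["J11", "J21"])     # different brood
  ids <- reg$bird_id
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    bi <- reg[i, ]; bj <- reg[j, ]
    expected <-
      if (bi$age_class == "adult" && bj$age_class == "adult") "none"
      else if (bi$age_class == "juvenile" && bj$age_class == "juvenile") {
        if (identical(bi$brood_id, bj$brood_id)) "sibling" else "peer"
      } else {
        juvr <- if (bi$age_class == "juvenile") bi else bj
        ad <- if (bi$age_class == "juvenile") bj else bi
        if (ad$bird_id %in% c(juvr$mother_id, juvr$father_id)) "vertical"
        else "oblique"
      }
    hits <- vapply(masks, function(m) m[i, j], logical(1))
    if (expected == "none") expect_equal(sum(hits), 0L)
    else {
      expect_equal(sum(hits), 1L)
      expect_true(hits[[expected]])
    }
  }
})

test_that("dynamic networks route SRI weights into the right layers", {
  reg <- toy_registry()
  t0 <- 10 * DAY
  # one family (B1 + parents) always co-feeding within the window
  fam <- c("F1", "M1", "J11", "J12", "J13")
  det <- do.call(rbind, lapply(1:12, function(e)
    data.frame(bird_id = fam, timestamp = t0 - 3 * DAY + e * 3600,
               site_id = "s1", source = "network_feeder")))
  net <- dynamic_network(det, reg, event_time = t0, min_registrations = 10)
  expect_s3_class(net, "network_layer_set")
  expect_equal(net$layers$sibling["J11", "J12"], 1)
  expect_equal(net$layers$vertical["J11", "F1"], 1)
  expect_true(all(net$layers$oblique == 0))
  expect_true(all(net$layers$peer == 0))
  # empty window -> all-zero layers, flagged
  expect_message(
    net0 <- dynamic_network(det, reg, event_time = 200 * DAY,
                            min_registrations = 10),
    "empty network")
  expect_true(all(vapply(net0$layers, function(A) all(A == 0), logical(1))))
})

test_that("dynamic network weights equal an independent end-to-end recomputation", {
  set.seed(13)
  reg <- toy_registry()
  ids <- reg$bird_id
  t0 <- 20 * DAY
  # random bursts over 12 site-days within +/- 7 d, plus some outside
  det <- do.call(rbind, lapply(1:40, function(e) {
    d <- sample(seq(-10, 10), 1)
    members <- sample(ids, sample(2:6, 1))
    data.frame(bird_id = members,
               timestamp = t0 + d * DAY + e * 900 +
                 rnorm(length(members), 0, 20),
               site_id = "s1", source = "network_feeder")
  }))
  gat <- gathering_events(det)
  net <- dynamic_network(det, reg, event_time = t0, min_registrations = 1,
                         gatherings = gat)
  # oracle: filter gatherings by window by hand, count joint/either per dyad
  inwin <- Filter(function(g) g$start >= t0 - 7 * DAY &
                    g$start <= t0 + 7 * DAY, gat)
  masks <- layer_masks(reg, net$node_ids)
  for (a in net$node_ids) for (b in net$node_ids) {
    if (a >= b) next
    joint <- sum(vapply(inwin, function(g)
      a %in% g$members && b %in% g$members, logical(1)))
    either <- sum(vapply(inwin, function(g)
      a %in% g$members || b %in% g$members, logical(1)))
    sri <- if (either) joint / either else 0
    layer <- names(which(vapply(masks, function(m) m[a, b], logical(1))))
    for (k in names(net$layers)) {
      expect_equal(net$layers[[k]][a, b],
                   if (k %in% layer) sri else 0, tolerance = 1e-12)
    }
  }
  # bit-reproducible
  net2 <- dynamic_network(det, reg, event_time = t0, min_registrations = 1,
                          gatherings = gat)
  expect_identical(net$layers, net2$layers)
})

test_that("presence matrix matches a brute-force scan", {
  set.seed(17)
  ids <- toy_registry()$bird_id
  det <- data.frame(
    bird_id = sample(ids, 150, TRUE),
    timestamp = runif(150, 0, 30 * DAY),
    site_id = sample(c("s1", "s2"), 150, TRUE),
    source = "network_feeder")
  puz <- data.frame(
    bird_id = sample(ids, 60, TRUE),
    timestamp = runif(60, 0, 30 * DAY),
    site_id = sample(c("s1", "s2"), 60, TRUE),
    action = sample(c("visit", "solve_left"), 60, TRUE))
  acq <- data.frame(time = c(10, 17, 25) * DAY,
                    site_id = c("s1", "s2", "s1"))
  P <- presence_matrix(det, puz, acq, ids)
  for (i in seq_along(ids)) for (e in 1:3) {
    seen <- any(det$bird_id == ids[i] & det$site_id == acq$site_id[e] &
                  det$timestamp > acq$time[e] - 7 * DAY &
                  det$timestamp <= acq$time[e]) ||
      any(puz$bird_id == ids[i] & puz$site_id == acq$site_id[e] &
            puz$timestamp > acq$time[e] - 7 * DAY &
            puz$timestamp <= acq$time[e])
    expect_equal(unname(P[i, e]), as.integer(seen))
  }
  # simple cases: seen 3 days before at the site vs other site only
  det1 <- data.frame(bird_id = "J11", timestamp = 7 * DAY, site_id = "s1",
                     source = "network_feeder")
  puz0 <- puz[0, ]
  acq1 <- data.frame(time = 10 * DAY, site_id = c("s1", "s2"))
  P1 <- presence_matrix(det1, puz0, acq1, c("J11"))
  expect_equal(as.integer(P1), c(1L, 0L))
})
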