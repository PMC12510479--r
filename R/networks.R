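#' Detect gathering events at one site-day
#'
#' Fits 1-D Gaussian mixtures to the detection timestamps for K = 1..k_max
#' components, picks K by BIC, assigns each detection to its
#' maximum-responsibility component, and returns one gathering event per
#' component (the distinct birds assigned to it). This implements the
#' gambit-of-the-group grouping step for RFID feeder streams.
#'
#' @param detections data.frame of detections from a single site and day
#'   (`bird_id`, `timestamp` in seconds, `site_id`).
#' @param k_max Maximum number of mixture components (default 10); the number
#'   actually tried is capped at the number of detections.
#' @param seed Kept for interface stability; the mixture fit
#'   (model-based hierarchical initialisation) is deterministic.
#' @return List of gathering events, each a list with `site_id`, `day`
#'   (floor(timestamp / 86400)), `members` (character vector of distinct bird
#'   ids), `start`, `end` (seconds).
#' @export
detect_gathering_events <- function(detections, k_max = 10, seed = 1L) {
  stopifnot(nrow(detections) >= 1)
  ts <- detections$timestamp
  site <- detections$site_id[1]
  day <- floor(min(ts) / .DAY)
  n <- nrow(detections)
  if (n == 1 || diff(range(ts)) == 0) {
    cls <- rep(1L, n)
  } else {
    g_max <- min(k_max, n)
    set.seed(seed)
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(ts, G = seq_len(g_max),
                                      modelNames = c("E", "V"),
                                      verbose = FALSE)),
      error = function(e) NULL)
    cls <- if (is.null(fit)) rep(1L, n) else as.integer(fit$classification)
  }
  lapply(sort(unique(cls)), function(k) {
    sel <- cls == k
    list(site_id = site, day = day,
         members = unique(detections$bird_id[sel]),
         start = min(ts[sel]), end = max(ts[sel]))
  })
}

#' Gathering events for a whole detection stream
#'
#' Splits the stream by site and calendar day and runs
#' [detect_gathering_events()] on each slice.
#'
#' @inheritParams detect_gathering_events
#' @param detections Feeder detection data.frame across sites/days.
#' @return Flat list of gathering events.
#' @export
gathering_events <- function(detections, k_max = 10, seed = 1L) {
  if (!nrow(detections)) return(list())
  day <- floor(detections$timestamp / .DAY)
  keys <- split(seq_len(nrow(detections)),
                paste(detections$site_id, day, sep = "\r"))
  out <- list()
  for (idx in keys) {
    out <- c(out, detect_gathering_events(detections[idx, , drop = FALSE],
                                          k_max = k_max, seed = seed))
  }
  out
}

# events x birds incidence matrix over a gathering-event list
.incidence <- function(gatherings, ids) {
  M <- matrix(0L, nrow = length(gatherings), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (e in seq_along(gatherings)) {
    m <- intersect(gatherings[[e]]$members, ids)
    M[e, m] <- 1L
  }
  M
}

#' Simple-ratio association index for one dyad
#'
#' SRI = (events containing both) / (events containing a, b, or both), the
#' gambit-of-the-group association strength in \[0, 1\]: 0 = never seen
#' together, 1 = always observed in the same group.
#'
#' @param gatherings List of gathering events (see [gathering_events()]).
#' @param bird_a,bird_b Bird ids.
#' @return Numeric weight in \[0, 1\]; 0 when neither bird was ever observed.
#' @export
simple_ratio_index <- function(gatherings, bird_a, bird_b) {
  both <- either <- 0L
  for (g in gatherings) {
    a <- bird_a %in% g$members
    b <- bird_b %in% g$members
    if (a && b) both <- both + 1L
    if (a || b) either <- either + 1L
  }
  if (either == 0L) return(0)
  both / either
}

# Full SRI matrix over ids (vectorised; cross-checked against
# simple_ratio_index in the tests).
.sri_matrix <- function(gatherings, ids) {
  n <- length(ids)
  if (!length(gatherings) || !n)
    return(matrix(0, n, n, dimnames = list(ids, ids)))
  M <- .incidence(gatherings, ids)
  joint <- crossprod(M)
  seen <- diag(joint)
  either <- outer(seen, seen, "+") - joint
  sri <- ifelse(either > 0, joint / either, 0)
  diag(sri) <- 0
  dimnames(sri) <- list(ids, ids)
  sri
}

#' Dyad-to-layer masks from the pedigree
#'
#' Routes every dyad to at most one transmission layer: a juvenile and one of
#' its own parents form a vertical dyad; a juvenile and any other adult an
#' oblique dyad; two juveniles of the same brood a sibling dyad; two
#' juveniles of different broods a peer dyad. Adult-adult dyads belong to no
#' layer.
#'
#' @param registry Bird registry.
#' @param ids Optional subset/ordering of bird ids (default: registry order).
#' @return Named list of four symmetric logical matrices
#'   (`vertical`, `oblique`, `sibling`, `peer`) with `FALSE` diagonals.
#' @export
layer_masks <- function(registry, ids = registry$bird_id) {
  reg <- registry[match(ids, registry$bird_id), , drop = FALSE]
  if (anyNA(reg$bird_id))
    stop("referential error: id(s) not in registry", call. = FALSE)
  juv <- reg$age_class == "juvenile"
  if (any(juv & is.na(reg$brood_id)))
    stop("referential error: juvenile lacking brood_id", call. = FALSE)
  n <- length(ids)
  parent_of <- function(i, j) { # is j a parent of i
    !is.na(reg$mother_id[i]) & reg$mother_id[i] == ids[j] |
      !is.na(reg$father_id[i]) & reg$father_id[i] == ids[j]
  }
  P <- matrix(FALSE, n, n)
  for (i in which(juv)) P[i, ] <- vapply(seq_len(n), parent_of, i = i,
                                         FUN.VALUE = logical(1))
  P <- P | t(P)
  J <- outer(juv, juv, "&")
  JA <- outer(juv, !juv, "&") | outer(!juv, juv, "&")
  same_brood <- outer(reg$brood_id, reg$brood_id, "==")
  same_brood[is.na(same_brood)] <- FALSE
  masks <- list(
    vertical = JA & P,
    oblique  = JA & !P,
    sibling  = J & same_brood,
    peer     = J & !same_brood)
  masks <- lapply(masks, function(m) { diag(m) <- FALSE; m })
  lapply(masks, function(m) { dimnames(m) <- list(ids, ids); m })
}

#' Construct a four-layer network set
#'
#' @param node_ids Ordered node ids.
#' @param layers Named list of four numeric matrices
#'   (vertical/oblique/sibling/peer).
#' @param window Numeric length-2 `(start, end)` in seconds.
#' @return A `network_layer_set` object.
#' @export
network_layer_set <- function(node_ids, layers, window = c(NA_real_, NA_real_)) {
  stopifnot(setequal(names(layers), .LAYERS))
  layers <- layers[.LAYERS]
  for (k in .LAYERS) {
    A <- layers[[k]]
    stopifnot(is.matrix(A), nrow(A) == length(node_ids),
              ncol(A) == length(node_ids))
    if (any(A < 0) || any(A > 1)) stop("layer weights must lie in [0,1]")
    if (any(diag(A) != 0)) stop("layer diagonals must be zero")
    if (max(abs(A - t(A))) > 1e-12) stop("layer matrices must be symmetric")
    dimnames(layers[[k]]) <- list(node_ids, node_ids)
  }
  pos <- Reduce(`+`, lapply(layers, function(A) (A > 0) * 1L))
  if (any(pos > 1))
    stop("each dyad may have positive weight in at most one layer")
  structure(list(node_ids = node_ids, layers = layers, window = window),
            class = "network_layer_set")
}

#' @export
print.network_layer_set <- function(x, ...) {
  dens <- vapply(x$layers, function(A) mean(A[upper.tri(A)] > 0), numeric(1))
  cat("network_layer_set:", length(x$node_ids), "nodes\n")
  cat(sprintf("  %-8s edge density %.3f\n", names(dens), dens), sep = "")
  invisible(x)
}

#' Dynamic multi-layer network around an acquisition event
#'
#' Recomputes the association network from the gathering events in the week
#' before and after `event_time`, excludes birds with fewer than
#' `min_registrations` feeder detections over the whole stream (a global
#' transient-bird filter), computes the simple-ratio index per dyad, and
#' routes each dyad's weight to its layer.
#'
#' @param detections Full feeder detection stream (used for the global
#'   registration filter and, when `gatherings` is `NULL`, for clustering).
#' @param registry Bird registry.
#' @param event_time Acquisition-event timestamp (seconds).
#' @param window_days Half-width of the network window (default 7 days).
#' @param min_registrations Global minimum feeder-detection count (default 10).
#' @param k_max,seed Passed to [gathering_events()].
#' @param gatherings Optional precomputed gathering-event list (site-day
#'   clusters do not depend on the window, so precomputing them once is much
#'   cheaper when networks are rebuilt at every acquisition event).
#' @return A `network_layer_set`; all-zero layers (with a message) when the
#'   window holds no detections.
#' @export
dynamic_network <- function(detections, registry, event_time, window_days = 7,
                            min_registrations = 10, k_max = 10, seed = 1L,
                            gatherings = NULL) {
  nreg <- table(detections$bird_id)
  keep <- names(nreg)[nreg >= min_registrations]
  ids <- registry$bird_id[registry$bird_id %in% keep]
  w0 <- event_time - window_days * .DAY
  w1 <- event_time + window_days * .DAY
  if (is.null(gatherings)) {
    sel <- detections$timestamp >= w0 & detections$timestamp <= w1
    gat <- if (any(sel)) gathering_events(detections[sel, , drop = FALSE],
                                          k_max = k_max, seed = seed)
           else list()
  } else {
    gat <- Filter(function(g) g$start >= w0 & g$start <= w1, gatherings)
  }
  if (!length(gat))
    message("dynamic_network: no detections in window around ", event_time,
            "; returning empty network")
  sri <- .sri_matrix(gat, ids)
  masks <- layer_masks(registry, ids)
  layers <- lapply(masks, function(m) sri * m)
  network_layer_set(ids, layers, window = c(w0, w1))
}

#' Presence matrix for acquisition events
#'
#' A bird counts as present at an acquisition event if it was registered at
#' that event's site — on the network feeders or on the puzzle box — within
#' the `lookback_days` before the event (window `(t - lookback, t]`).
#'
#' @param detections Feeder detections.
#' @param puzzle_events Puzzle-box events.
#' @param acquisition_events data.frame with columns `time` (seconds) and
#'   `site_id`, one row per acquisition event.
#' @param ids Bird ids (rows of the output).
#' @param lookback_days Lookback window (default 7 days).
#' @return Binary matrix, birds x events.
#' @export
presence_matrix <- function(detections, puzzle_events, acquisition_events,
                            ids, lookback_days = 7) {
  E <- nrow(acquisition_events)
  P <- matrix(0L, nrow = length(ids), ncol = E,
              dimnames = list(ids, NULL))
  all_ev <- rbind(
    data.frame(bird_id = detections$bird_id,
               timestamp = detections$timestamp,
               site_id = detections$site_id),
    data.frame(bird_id = puzzle_events$bird_id,
               timestamp = puzzle_events$timestamp,
               site_id = puzzle_events$site_id))
  for (e in seq_len(E)) {
    t_e <- acquisition_events$time[e]
    sel <- all_ev$site_id == acquisition_events$site_id[e] &
      all_ev$timestamp > t_e - lookback_days * .DAY &
      all_ev$timestamp <= t_e
    P[unique(all_ev$bird_id[sel])[unique(all_ev$bird_id[sel]) %in% ids], e] <- 1L
  }
  P
}

#' Export a network layer set as a long edge list
#'
#' @param net A `network_layer_set`.
#' @return data.frame `layer,bird_a,bird_b,weight,window_start,window_end`
#'   with one row per positive-weight dyad.
#' @export
network_edge_list <- function(net) {
  out <- list()
  for (k in .LAYERS) {
    A <- net$layers[[k]]
    idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    out[[k]] <- data.frame(
      layer = k,
      bird_a = net$node_ids[idx[, 1]], bird_b = net$node_ids[idx[, 2]],
      weight = A[idx],
      window_start = net$window[1], window_end = net$window[2])
  }
  if (!length(out))
    return(data.frame(layer = character(), bird_a = character(),
                      bird_b = character(), weight = numeric(),
                      window_start = numeric(), window_end = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
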