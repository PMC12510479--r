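#' Build TADA diffusion data from raw event streams
#'
#' The full inferential data-preparation chain: knowledge states and
#' acquisition times from the puzzle log; learners assigned to the site of
#' their acquisition; dynamic four-layer networks recomputed from the
#' gathering events in the week before and after each acquisition event
#' (birds under the global feeder-registration threshold excluded);
#' presence from 7-day site lookback; transmission weights as each
#' knowledgeable bird's solves per experimental day since its acquisition;
#' and time-varying centered ILVs (log10 parental solves + 1, log10 own
#' scrounges + 1).
#'
#' @param registry,detections,puzzle_events Validated event tables (see
#'   [load_event_tables()]); `registry` needs a `site_id` column or juveniles
#'   are pooled by their primary detection site.
#' @param diffusion_start,t_end Diffusion window in seconds.
#' @param window_days Dynamic-network half-window (default 7).
#' @param lookback_days Presence lookback (default 7).
#' @param min_registrations Global feeder-registration filter (default 10).
#' @param knowledge_threshold,acq_solve Knowledge-state rules (10, 3).
#' @param nonlearner_window Days after fledging capping the parental-solve
#'   ILV for non-learners (default 15).
#' @param min_site_events Sites with fewer acquisition events are dropped
#'   (default 3).
#' @param ilvs Include the two ILVs? (default TRUE)
#' @param scrounge_window Scrounge attribution window in seconds (default 2).
#' @param k_max,seed Gathering-detection controls.
#' @return A [diffusion_data()] object.
#' @export
build_diffusion_data <- function(registry, detections, puzzle_events,
                                 diffusion_start, t_end,
                                 window_days = 7, lookback_days = 7,
                                 min_registrations = 10,
                                 knowledge_threshold = 10, acq_solve = 3,
                                 nonlearner_window = 15,
                                 min_site_events = 3, ilvs = TRUE,
                                 scrounge_window = 2, k_max = 10, seed = 1L) {
  ks <- knowledge_states(puzzle_events, registry, diffusion_start,
                         threshold = knowledge_threshold,
                         acq_solve = acq_solve)
  ev <- .dedup_solves(puzzle_events[order(puzzle_events$timestamp), ,
                                    drop = FALSE])
  solves <- ev[ev$action %in% c("solve_left", "solve_right"), , drop = FALSE]
  scrounges <- derive_scrounges(puzzle_events, window = scrounge_window)
  gat <- gathering_events(detections, k_max = k_max, seed = seed)
  nreg <- table(detections$bird_id)
  eligible <- names(nreg)[nreg >= min_registrations]

  juv <- registry$age_class == "juvenile"
  learners <- ks[ks$knowledgeable &
                   ks$bird_id %in% registry$bird_id[juv] &
                   ks$acquisition_time > diffusion_start &
                   ks$acquisition_time <= t_end, , drop = FALSE]
  # acquisition site = site of the acq_solve-th solve
  acq_site <- vapply(learners$bird_id, function(id) {
    st <- solves[solves$bird_id == id, , drop = FALSE]
    st$site_id[order(st$timestamp)][acq_solve]
  }, character(1))
  primary_site <- function(id) {
    d <- detections[detections$bird_id == id, , drop = FALSE]
    if (!nrow(d)) return(NA_character_)
    names(which.max(table(d$site_id)))
  }
  filt_adults <- ks[ks$filtered, , drop = FALSE]

  sites <- unique(acq_site)
  site_list <- list()
  for (site in sites) {
    lrn <- learners[acq_site == site, , drop = FALSE]
    lrn <- lrn[order(lrn$acquisition_time), , drop = FALSE]
    # tie separation: recorded order, +1 s
    tt <- lrn$acquisition_time
    if (nrow(lrn) > 1) for (r in 2:nrow(lrn))
      if (tt[r] <= tt[r - 1]) tt[r] <- tt[r - 1] + 1
    t_days <- (tt - diffusion_start) / .DAY
    # pool: eligible juveniles whose primary site is this one, plus learners
    pool_ids <- unique(c(
      lrn$bird_id,
      registry$bird_id[juv & registry$bird_id %in% eligible &
                         vapply(registry$bird_id, function(id)
                           identical(primary_site(id), site), logical(1))]))
    # adults seen at this site (feeders or puzzle)
    seen_here <- unique(c(
      detections$bird_id[detections$site_id == site],
      puzzle_events$bird_id[puzzle_events$site_id == site]))
    adult_ids <- registry$bird_id[!juv & registry$bird_id %in% seen_here]
    ids <- registry$bird_id[registry$bird_id %in% c(pool_ids, adult_ids)]
    reg <- registry[match(ids, registry$bird_id), , drop = FALSE]
    n <- length(ids)
    E <- nrow(lrn)
    Sl <- E + 1L

    nets <- lapply(tt, function(te)
      dynamic_network(detections, registry, te, window_days = window_days,
                      min_registrations = min_registrations,
                      gatherings = gat))
    acq_df <- data.frame(time = c(tt, t_end), site_id = site)
    P <- presence_matrix(detections, puzzle_events, acq_df, ids,
                         lookback_days = lookback_days)
    presence <- t(P) # (E+1) x n

    dem <- ks$bird_id[ks$demonstrator]
    facq <- stats::setNames(
      (filt_adults$acquisition_time - diffusion_start) / .DAY,
      filt_adults$bird_id)
    facq <- facq[names(facq) %in% ids]

    # transmission weights: solves since own acquisition per day since it
    acq_all <- stats::setNames(ks$acquisition_time, ks$bird_id)
    slice_t <- c(tt, t_end)
    w <- matrix(0, Sl, n, dimnames = list(NULL, ids))
    for (j in seq_len(n)) {
      aj <- acq_all[ids[j]]
      if (is.na(aj)) next
      for (m in seq_len(Sl)) {
        te <- slice_t[m]
        if (te <= aj) next
        cnt <- sum(solves$bird_id == ids[j] & solves$timestamp > aj &
                     solves$timestamp <= te)
        w[m, j] <- cnt / max((te - aj) / .DAY, 1)
      }
    }

    ilv_arr <- NULL
    if (ilvs) {
      ilv_arr <- array(0, dim = c(Sl, n, 2))
      fledge <- reg$fledge_date
      caps <- ifelse(ids %in% lrn$bird_id,
                     acq_all[ids], fledge + nonlearner_window * .DAY)
      for (i in which(reg$age_class == "juvenile")) {
        parents <- stats::na.omit(c(reg$mother_id[i], reg$father_id[i]))
        for (m in seq_len(Sl)) {
          to <- min(slice_t[m], caps[i], na.rm = TRUE)
          nps <- sum(solves$bird_id %in% parents &
                       solves$timestamp > fledge[i] & solves$timestamp <= to)
          nsc <- sum(scrounges$bird_id == ids[i] &
                       scrounges$timestamp <= slice_t[m])
          ilv_arr[m, i, ] <- c(log10(nps + 1), log10(nsc + 1))
        }
      }
      # center at the diffusion start over the learner pool
      pool_idx <- which(ids %in% pool_ids)
      for (p in 1:2)
        ilv_arr[, , p] <- ilv_arr[, , p] - mean(ilv_arr[1, pool_idx, p])
    }

    entry <- ifelse(is.na(reg$fledge_date), 0,
                    pmax((reg$fledge_date - diffusion_start) / .DAY, 0))
    site_list[[site]] <- diffusion_site(
      ids = ids, learner_pool = ids %in% pool_ids,
      events = data.frame(learner_id = lrn$bird_id, time = t_days),
      t_end = (t_end - diffusion_start) / .DAY,
      networks = nets, demonstrators = intersect(dem, ids),
      filtered_acq = facq, w = w, presence = presence, entry = entry,
      ilvs = ilv_arr, brood = reg$brood_id, site_id = site)
  }
  if (!length(site_list))
    stop("no acquisition events in the diffusion window", call. = FALSE)
  filter_sites(diffusion_data(site_list), min_events = min_site_events)
}
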