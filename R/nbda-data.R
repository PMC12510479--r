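#' Assemble per-site diffusion data for TADA
#'
#' Packages everything the time-of-acquisition likelihood needs for one
#' diffusion (one puzzle-box site): the ordered acquisition events, the
#' at-risk learner pool, demonstrators and filtered transmitters, the
#' multi-layer networks, presence, transmission weights and time-varying
#' individual-level variables (ILVs), all on a common time axis in
#' experimental days since the diffusion start.
#'
#' Covariates are piecewise-constant between acquisition events: slice
#' `m` covers `(t[m-1], t[m]]` and uses the values supplied for event `m`;
#' slice `E + 1` covers the censored tail `(t[E], t_end]`. The knowledgeable
#' indicator updates at event boundaries: the learner of event `m` transmits
#' from slice `m + 1` on, and a filtered adult transmits from the first slice
#' starting at or after its acquisition time.
#'
#' @param ids Character vector of bird ids at this site.
#' @param learner_pool Logical vector: which ids are juveniles at risk.
#' @param events data.frame with `learner_id` and `time` (days since
#'   diffusion start, strictly increasing; ties must be pre-separated).
#' @param t_end Censoring time (days) for birds that never learn.
#' @param networks A single [network_layer_set()] (static) or a list of
#'   `E + 1` of them (dynamic: one per event plus the tail; a list of length
#'   `E` is recycled by carrying the last event's network forward).
#' @param demonstrators Ids knowledgeable at time 0.
#' @param filtered_acq Named numeric vector: acquisition times (days) of
#'   filtered adults (transmitters that are not modelled as learners).
#' @param w Transmission weights: `(E+1) x n` matrix (behaviour performance
#'   rate per experimental day, per slice) or a length-`n` vector of constant
#'   rates.
#' @param presence `(E+1) x n` binary matrix (default: all present).
#' @param entry Length-`n` numeric entry times (days; e.g. fledge dates).
#'   Exposure before entry does not count; default 0.
#' @param ilvs `(E+1) x n x p` array of centered ILV values, or `NULL`.
#' @param brood Length-`n` character brood ids (`NA` for adults); used for
#'   the first-versus-subsequent sibling-learner split.
#' @param site_id Site label.
#' @return A `diffusion_site` object with precomputed per-slice social
#'   statistics.
#' @export
diffusion_site <- function(ids, learner_pool, events, t_end, networks,
                           demonstrators = character(),
                           filtered_acq = numeric(), w,
                           presence = NULL, entry = NULL, ilvs = NULL,
                           brood = NULL, site_id = "site") {
  n <- length(ids)
  E <- nrow(events)
  stopifnot(length(learner_pool) == n, E >= 0, t_end > 0)
  if (E > 0) {
    if (any(diff(events$time) <= 0))
      stop("event times must be strictly increasing", call. = FALSE)
    if (any(events$time <= 0) || any(events$time > t_end))
      stop("event times must lie in (0, t_end]", call. = FALSE)
    li <- match(events$learner_id, ids)
    if (anyNA(li)) stop("learner not among ids", call. = FALSE)
    if (any(!learner_pool[li]))
      stop("consistency error: event learner not in the at-risk pool",
           call. = FALSE)
    if (anyDuplicated(li)) stop("a bird can acquire only once", call. = FALSE)
  } else li <- integer()

  S <- E + 1L # slices
  if (inherits(networks, "network_layer_set")) networks <- list(networks)
  networks <- lapply(networks, function(nt) {
    if (!identical(nt$node_ids, ids)) {
      # align to site ids; missing nodes get zero rows/cols
      layers <- lapply(nt$layers, function(A) {
        B <- matrix(0, n, n, dimnames = list(ids, ids))
        common <- intersect(ids, nt$node_ids)
        B[common, common] <- A[common, common]
        B
      })
      network_layer_set(ids, layers, nt$window)
    } else nt
  })
  if (length(networks) == 1L) networks <- rep(networks, S)
  if (length(networks) == E) networks <- c(networks, networks[E])
  stopifnot(length(networks) == S)

  if (is.null(presence)) presence <- matrix(1L, S, n)
  if (is.vector(w) && !is.matrix(w)) w <- matrix(rep(w, each = S), S, n)
  stopifnot(all(dim(presence) == c(S, n)), all(dim(w) == c(S, n)),
            all(w >= 0))
  if (is.null(entry)) entry <- rep(0, n)
  if (!is.null(ilvs)) stopifnot(length(dim(ilvs)) == 3,
                                dim(ilvs)[1] == S, dim(ilvs)[2] == n,
                                all(is.finite(ilvs)))
  if (is.null(brood)) brood <- rep(NA_character_, n)

  bounds <- c(0, events$time, t_end)
  # knowledgeable indicator per slice (state at slice start)
  z <- matrix(0L, S, n)
  z[, match(intersect(demonstrators, ids), ids)] <- 1L
  if (E > 0) for (m in seq_len(E)) if (m < S) z[(m + 1L):S, li[m]] <- 1L
  if (length(filtered_acq)) {
    fi <- match(names(filtered_acq), ids)
    for (k in seq_along(fi)) {
      from <- which(bounds[seq_len(S)] >= filtered_acq[k])
      if (length(from)) z[from, fi[k]] <- 1L
    }
  }

  # at-risk: pool member that has not yet learned at slice start
  at_risk <- matrix(rep(learner_pool, each = S), S, n)
  if (E > 0) for (m in seq_len(E)) if (m < S) at_risk[(m + 1L):S, li[m]] <- FALSE

  # per-slice weighted knowledgeable-neighbour sums, per layer
  Tsoc <- array(0, dim = c(S, n, 4), dimnames = list(NULL, ids, .LAYERS))
  for (m in seq_len(S)) {
    zv <- z[m, ] * w[m, ] * presence[m, ]
    for (k in seq_along(.LAYERS))
      Tsoc[m, , k] <- as.numeric(networks[[m]]$layers[[.LAYERS[k]]] %*% zv)
  }

  structure(list(
    site_id = site_id, ids = ids, learner_pool = learner_pool,
    events = events, learner_idx = li, t_end = t_end, bounds = bounds,
    networks = networks, z = z, w = w, presence = presence, entry = entry,
    ilvs = ilvs, brood = brood, Tsoc = Tsoc, at_risk = at_risk,
    demonstrators = demonstrators, filtered_acq = filtered_acq),
    class = "diffusion_site")
}

#' Bundle diffusion sites into one multi-diffusion dataset
#'
#' @param sites List of [diffusion_site()] objects.
#' @param n_ilv Number of ILVs (checked against the sites).
#' @return A `diffusion_data` object. The TADA likelihood is the sum of the
#'   per-site likelihoods with shared parameters.
#' @export
diffusion_data <- function(sites, n_ilv = NULL) {
  stopifnot(length(sites) >= 1,
            all(vapply(sites, inherits, logical(1), "diffusion_site")))
  p <- vapply(sites, function(s) if (is.null(s$ilvs)) 0L else dim(s$ilvs)[3],
              integer(1))
  if (length(unique(p)) > 1)
    stop("all sites must carry the same number of ILVs", call. = FALSE)
  if (is.null(n_ilv)) n_ilv <- p[1]
  structure(list(sites = sites, n_ilv = n_ilv,
                 n_events = sum(vapply(sites, function(s) nrow(s$events),
                                       integer(1)))),
            class = "diffusion_data")
}

#' @export
print.diffusion_data <- function(x, ...) {
  cat("diffusion_data:", length(x$sites), "site(s),", x$n_events,
      "acquisition events,", x$n_ilv, "ILV(s)\n")
  for (s in x$sites)
    cat(sprintf("  %s: %d at risk, %d events, censored at %.1f d\n",
                s$site_id, sum(s$learner_pool), nrow(s$events), s$t_end))
  invisible(x)
}

#' Drop sites with too few acquisition events
#'
#' Sites with very few learners carry almost no information about the
#' transmission parameters and can destabilise the fit, so they are excluded
#' from modelling.
#'
#' @param data A `diffusion_data` object.
#' @param min_events Minimum acquisition events per site (default 3).
#' @return A `diffusion_data` object containing the retained sites.
#' @export
filter_sites <- function(data, min_events = 3) {
  keep <- vapply(data$sites, function(s) nrow(s$events) >= min_events,
                 logical(1))
  if (!any(keep)) stop("no site has enough acquisition events", call. = FALSE)
  if (!all(keep))
    message("filter_sites: dropping ",
            paste(vapply(data$sites[!keep], `[[`, "", "site_id"),
                  collapse = ", "))
  diffusion_data(data$sites[keep], n_ilv = data$n_ilv)
}
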