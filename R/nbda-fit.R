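#' Specify one TADA model
#'
#' A model is defined by which network layers carry social transmission,
#' where each ILV acts (on the asocial rate, the social rate, both, or not at
#' all — the "unconstrained" parameterisation), and the baseline-rate family.
#'
#' @param networks Character subset of
#'   `c("vertical","oblique","sibling","peer")`; empty means no social
#'   transmission (pure asocial model).
#' @param ilv Character vector (one entry per ILV) with values in
#'   `"absent"`, `"asocial_only"`, `"social_only"`, `"both"`.
#' @param baseline `"constant"` or `"weibull"`.
#' @return A `tada_spec` object; `K` is the free-parameter count (network
#'   s parameters + ILV coefficients + 1 scale, plus 1 shape for Weibull).
#' @export
tada_spec <- function(networks = character(), ilv = character(),
                      baseline = c("constant", "weibull")) {
  baseline <- match.arg(baseline)
  stopifnot(all(networks %in% .LAYERS),
            all(ilv %in% c("absent", "asocial_only", "social_only", "both")))
  networks <- .LAYERS[.LAYERS %in% networks]
  K <- length(networks) + sum(ilv %in% c("asocial_only", "both")) +
    sum(ilv %in% c("social_only", "both")) +
    if (baseline == "weibull") 2L else 1L
  structure(list(networks = networks, ilv = ilv, baseline = baseline, K = K),
            class = "tada_spec")
}

#' @export
print.tada_spec <- function(x, ...) {
  cat("tada_spec:",
      if (length(x$networks)) paste(x$networks, collapse = "+") else "asocial",
      "| ILVs:", if (length(x$ilv)) paste(x$ilv, collapse = ",") else "none",
      "|", x$baseline, "baseline | K =", x$K, "\n")
  invisible(x)
}

#' Enumerate the TADA model set
#'
#' All combinations of network subsets (including the empty, purely asocial
#' set) and per-ILV placements for one baseline family: with 4 networks and
#' 2 unconstrained ILVs this gives `2^4 * 4^2 = 256` model specifications.
#'
#' @param networks Candidate network layers.
#' @param n_ilv Number of ILVs.
#' @param baseline Baseline family for the whole set.
#' @return List of [tada_spec()] objects.
#' @export
enumerate_model_set <- function(networks = .LAYERS, n_ilv = 2,
                                baseline = c("constant", "weibull")) {
  baseline <- match.arg(baseline)
  placements <- c("absent", "asocial_only", "social_only", "both")
  subsets <- lapply(0:(2^length(networks) - 1), function(b)
    networks[bitwAnd(b, 2^(seq_along(networks) - 1)) > 0])
  ilv_grids <- if (n_ilv > 0)
    do.call(expand.grid, c(rep(list(placements), n_ilv),
                           stringsAsFactors = FALSE))
  else data.frame(row.names = 1)
  out <- list()
  for (s in subsets) for (r in seq_len(nrow(ilv_grids)))
    out[[length(out) + 1L]] <- tada_spec(
      networks = s,
      ilv = if (n_ilv > 0) as.character(ilv_grids[r, ]) else character(),
      baseline = baseline)
  out
}

# baseline hazard and cumulative hazard
.lambda0 <- function(t, theta, kappa, baseline) {
  if (baseline == "constant") rep(1 / theta, length(t))
  else (kappa / theta) * (t / theta)^(kappa - 1)
}
.Lambda0 <- function(t, theta, kappa, baseline) {
  if (baseline == "constant") t / theta else (t / theta)^kappa
}

# expand per-ILV coefficients to full-length vectors (0 where absent)
.beta_full <- function(params, spec, n_ilv) {
  ba <- bs <- rep(0, n_ilv)
  ia <- which(spec$ilv %in% c("asocial_only", "both"))
  is <- which(spec$ilv %in% c("social_only", "both"))
  if (length(ia)) ba[ia] <- params$beta_a
  if (length(is)) bs[is] <- params$beta_s
  list(ba = ba, bs = bs)
}

# linear predictors per slice x individual from the ILV array
.ilv_lin <- function(site, beta) {
  S <- length(site$bounds) - 1L
  n <- length(site$ids)
  if (is.null(site$ilvs) || all(beta == 0)) return(matrix(0, S, n))
  p <- dim(site$ilvs)[3]
  matrix(matrix(site$ilvs, S * n, p) %*% beta, S, n)
}

# rate multiplier R[m, i] = exp(bA x) + sum_k s_k exp(bS x) Tsoc_k
.rate_multiplier <- function(site, params, spec, n_ilv) {
  b <- .beta_full(params, spec, n_ilv)
  A <- exp(.ilv_lin(site, b$ba))
  Ssoc <- 0
  if (length(spec$networks)) {
    es <- exp(.ilv_lin(site, b$bs))
    for (k in spec$networks)
      Ssoc <- Ssoc + params$s[[k]] * es * site$Tsoc[, , k, drop = TRUE]
  }
  R <- A + Ssoc
  if (is.null(dim(R))) R <- matrix(R, nrow = length(site$bounds) - 1L)
  R
}

#' Individual acquisition hazard at a time point
#'
#' The modelled rate at which a naive individual acquires the behaviour:
#' `lambda_i(t) = lambda0(t) * [exp(bA x_i) + sum_k s_k exp(bS x_i) *
#' sum_j a_ij^k w_j z_j pi_j]`, with a constant (`1/theta`) or Weibull
#' (`(kappa/theta)(t/theta)^(kappa-1)`) baseline. Absent individuals (or
#' individuals before their entry time) have hazard 0.
#'
#' @param site A [diffusion_site()].
#' @param id Bird id.
#' @param time Time in days since diffusion start.
#' @param params List with `s` (named, per included network), `beta_a`,
#'   `beta_s`, `theta` (> 0) and, for Weibull, `kappa` (> 0).
#' @param spec A [tada_spec()].
#' @return Hazard rate (per day), a non-negative scalar.
#' @export
hazard <- function(site, id, time, params, spec) {
  if (any(unlist(params$s) < 0) || params$theta <= 0 ||
      (spec$baseline == "weibull" && params$kappa <= 0))
    stop("domain error: s >= 0, theta > 0, kappa > 0 required", call. = FALSE)
  i <- match(id, site$ids)
  stopifnot(!is.na(i))
  m <- findInterval(time, site$bounds, left.open = TRUE,
                    rightmost.closed = TRUE)
  m <- min(max(m, 1L), length(site$bounds) - 1L)
  if (site$presence[m, i] == 0 || time < site$entry[i]) return(0)
  n_ilv <- if (is.null(site$ilvs)) 0L else dim(site$ilvs)[3]
  b <- .beta_full(params, spec, n_ilv)
  x <- if (n_ilv) site$ilvs[m, i, ] else numeric()
  soc <- 0
  for (k in spec$networks)
    soc <- soc + params$s[[k]] * exp(sum(b$bs * x)) * site$Tsoc[m, i, k]
  .lambda0(time, params$theta,
           if (spec$baseline == "weibull") params$kappa else 1,
           spec$baseline) * (exp(sum(b$ba * x)) + soc)
}

#' TADA log-likelihood
#'
#' Continuous-time survival likelihood over all sites: each acquisition event
#' contributes `log lambda0(t_e) + log R_learner(t_e)`; each individual
#' contributes `-R_i * (Lambda0(end) - Lambda0(start))` for every inter-event
#' slice in which it is naive, present and past its entry time. Non-learners
#' are censored at the site end time.
#'
#' @param data A [diffusion_data()].
#' @param params Parameter list (see [hazard()]).
#' @param spec A [tada_spec()].
#' @return Log-likelihood (finite for admissible parameters; `-Inf` when an
#'   observed learner has zero modelled rate).
#' @export
tada_log_likelihood <- function(data, params, spec) {
  if (any(unlist(params$s) < 0) || params$theta <= 0 ||
      (spec$baseline == "weibull" && params$kappa <= 0))
    stop("domain error: s >= 0, theta > 0, kappa > 0 required", call. = FALSE)
  kappa <- if (spec$baseline == "weibull") params$kappa else 1
  ll <- 0
  for (site in data$sites) {
    S <- length(site$bounds) - 1L
    R <- .rate_multiplier(site, params, spec, data$n_ilv)
    # exposure per slice x individual, honouring entry times
    lo <- pmax(matrix(site$bounds[seq_len(S)], S, length(site$ids)),
               matrix(site$entry, S, length(site$ids), byrow = TRUE))
    hi <- matrix(site$bounds[-1], S, length(site$ids))
    dL <- .Lambda0(pmax(hi, 0), params$theta, kappa, spec$baseline) -
      .Lambda0(pmax(pmin(lo, hi), 0), params$theta, kappa, spec$baseline)
    expo <- R * site$at_risk * site$presence * dL
    ll <- ll - sum(expo)
    E <- nrow(site$events)
    if (E > 0) {
      tm <- site$events$time
      lam0 <- .lambda0(tm, params$theta, kappa, spec$baseline)
      Rl <- R[cbind(seq_len(E), site$learner_idx)]
      pres <- site$presence[cbind(seq_len(E), site$learner_idx)]
      Rl <- Rl * pres * (tm >= site$entry[site$learner_idx])
      if (any(Rl <= 0)) return(-Inf)
      ll <- ll + sum(log(lam0) + log(Rl))
    }
  }
  ll
}

# ---- parameter vector <-> list plumbing -----------------------------------

.par_names <- function(spec) {
  c(if (length(spec$networks)) paste0("s_", spec$networks),
    if (any(spec$ilv %in% c("asocial_only", "both")))
      paste0("beta_a", which(spec$ilv %in% c("asocial_only", "both"))),
    if (any(spec$ilv %in% c("social_only", "both")))
      paste0("beta_s", which(spec$ilv %in% c("social_only", "both"))),
    "log_theta",
    if (spec$baseline == "weibull") "log_kappa")
}

.vec_to_params <- function(par, spec) {
  nn <- length(spec$networks)
  na <- sum(spec$ilv %in% c("asocial_only", "both"))
  ns <- sum(spec$ilv %in% c("social_only", "both"))
  list(s = if (nn) stats::setNames(as.list(par[seq_len(nn)]), spec$networks)
           else list(),
       beta_a = if (na) par[nn + seq_len(na)] else numeric(),
       beta_s = if (ns) par[nn + na + seq_len(ns)] else numeric(),
       theta = exp(par[nn + na + ns + 1L]),
       kappa = if (spec$baseline == "weibull") exp(par[nn + na + ns + 2L])
               else 1)
}

.par_bounds <- function(spec) {
  nn <- length(spec$networks)
  nb <- sum(spec$ilv %in% c("asocial_only", "both")) +
    sum(spec$ilv %in% c("social_only", "both"))
  lower <- c(rep(0, nn), rep(-20, nb), log(1e-8),
             if (spec$baseline == "weibull") log(0.05))
  upper <- c(rep(1e7, nn), rep(20, nb), log(1e12),
             if (spec$baseline == "weibull") log(20))
  list(lower = lower, upper = upper)
}

# crude asocial scale: at-risk exposure days per acquisition event
.theta_init <- function(data) {
  expo <- 0
  for (site in data$sites) {
    S <- length(site$bounds) - 1L
    dt <- pmax(outer(site$bounds[-1],  site$entry, "-"), 0) -
      pmax(outer(site$bounds[seq_len(S)], site$entry, "-"), 0)
    expo <- expo + sum(site$at_risk * site$presence * pmax(dt, 0))
  }
  max(expo / max(data$n_events, 1), 1e-3)
}

#' Fit one TADA model by maximum likelihood
#'
#' Box-constrained quasi-Newton (`L-BFGS-B`) maximisation of
#' [tada_log_likelihood()] from several seeded starting points (social
#' transmission is scale-free, so starts span `s` over orders of magnitude).
#'
#' @param data A [diffusion_data()].
#' @param spec A [tada_spec()].
#' @param starts Number of starts (default 5: `s` in 0.1/1/10 plus two
#'   jittered).
#' @param seed Integer seed for the jittered starts.
#' @param fixed Optional named list of parameters to hold fixed (natural
#'   scale; names as in the fit's `estimates`, e.g. `s_sibling`, `theta`).
#'   Used by the profile-likelihood machinery.
#' @return A `tada_fit` with `params`, `estimates` (named vector on the
#'   natural scale), `loglik`, `K`, `n_events`, `aicc`, `convergence`.
#' @export
fit_tada <- function(data, spec, starts = 5, seed = 1L, fixed = list()) {
  if (data$n_events < 1) stop("need at least one acquisition event",
                              call. = FALSE)
  pn <- .par_names(spec)
  bounds <- .par_bounds(spec)
  to_internal <- function(name, value)
    if (name %in% c("theta", "kappa")) log(value) else value
  fixed_int <- list()
  for (nm in names(fixed)) {
    key <- if (nm %in% c("theta", "kappa")) paste0("log_", nm) else nm
    if (!key %in% pn) stop("unknown parameter: ", nm, call. = FALSE)
    fixed_int[[key]] <- to_internal(nm, fixed[[nm]])
  }
  free <- setdiff(pn, names(fixed_int))
  if (!length(free)) { # fully fixed: just evaluate
    full <- unlist(fixed_int)[pn]
    ll <- tada_log_likelihood(data, .vec_to_params(full, spec), spec)
    return(structure(list(spec = spec, params = .vec_to_params(full, spec),
                          loglik = ll, K = spec$K, n_events = data$n_events,
                          aicc = aicc(ll, spec$K, data$n_events),
                          convergence = 0L, estimates = .natural(full, spec)),
                     class = "tada_fit"))
  }
  fi <- match(names(fixed_int), pn)
  negll <- function(par_free) {
    full <- numeric(length(pn))
    full[match(free, pn)] <- par_free
    if (length(fi)) full[fi] <- unlist(fixed_int)
    ll <- tryCatch(tada_log_likelihood(data, .vec_to_params(full, spec), spec),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  theta0 <- .theta_init(data)
  nn <- length(spec$networks)
  base_start <- function(s0) {
    v <- stats::setNames(numeric(length(pn)), pn)
    if (nn) v[seq_len(nn)] <- s0
    v["log_theta"] <- log(theta0)
    if (spec$baseline == "weibull") v["log_kappa"] <- 0
    v
  }
  set.seed(seed)
  start_list <- lapply(c(0.1, 1, 10), base_start)
  extra <- max(0, starts - 3)
  for (j in seq_len(extra)) {
    v <- base_start(exp(stats::runif(1, log(0.05), log(50))))
    v["log_theta"] <- v["log_theta"] + stats::rnorm(1, 0, 0.5)
    if (spec$baseline == "weibull")
      v["log_kappa"] <- stats::rnorm(1, 0, 0.3)
    start_list[[3 + j]] <- v
  }

  best <- NULL
  diags <- character()
  for (st in start_list[seq_len(max(starts, 1))]) {
    par0 <- st[match(free, pn)]
    lw <- bounds$lower[match(free, pn)]
    up <- bounds$upper[match(free, pn)]
    res <- tryCatch(
      stats::optim(pmin(pmax(par0, lw), up), negll, method = "L-BFGS-B",
                   lower = lw, upper = up,
                   control = list(maxit = 500)),
      error = function(e) { diags <<- c(diags, conditionMessage(e)); NULL })
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("fit error: all starts failed: ",
         paste(unique(diags), collapse = "; "), call. = FALSE)

  full <- stats::setNames(numeric(length(pn)), pn)
  full[match(free, pn)] <- best$par
  if (length(fi)) full[fi] <- unlist(fixed_int)
  params <- .vec_to_params(full, spec)
  ll <- -best$value
  structure(list(spec = spec, params = params, loglik = ll, K = spec$K,
                 n_events = data$n_events,
                 aicc = aicc(ll, spec$K, data$n_events),
                 convergence = best$convergence,
                 estimates = .natural(full, spec)),
            class = "tada_fit")
}

# internal vector -> natural-scale named estimates
.natural <- function(full, spec) {
  out <- full
  nm <- names(full)
  out[nm == "log_theta"] <- exp(full[nm == "log_theta"])
  out[nm == "log_kappa"] <- exp(full[nm == "log_kappa"])
  names(out)[nm == "log_theta"] <- "theta"
  names(out)[nm == "log_kappa"] <- "kappa"
  out
}

#' @export
print.tada_fit <- function(x, ...) {
  print(x$spec)
  cat("  logLik:", format(x$loglik, digits = 6), " AICc:",
      format(x$aicc, digits = 6), " events:", x$n_events, "\n  ")
  cat(paste0(names(x$estimates), "=", signif(x$estimates, 4),
             collapse = "  "), "\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)` with `n` the number of
#' acquisition events.
#'
#' @param loglik Maximised log-likelihood.
#' @param K Number of free parameters.
#' @param n Sample size (acquisition events).
#' @return AICc value; `NA` (with a warning) when `n <= K + 1`.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) {
    warning("AICc undefined for n <= K + 1; model dropped")
    return(NA_real_)
  }
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights over a fitted model set
#'
#' @param fits List of `tada_fit` objects (or a numeric AICc vector).
#' @return Numeric weights summing to 1; models with undefined AICc get
#'   weight 0.
#' @export
akaike_weights <- function(fits) {
  a <- if (is.numeric(fits)) fits
       else vapply(fits, `[[`, numeric(1), "aicc")
  w <- rep(0, length(a))
  ok <- is.finite(a)
  d <- a[ok] - min(a[ok])
  w[ok] <- exp(-d / 2) / sum(exp(-d / 2))
  w
}

#' Summed Akaike support for a network or ILV
#'
#' The summed weight of all models containing the component: a network layer
#' among the model's social networks, or an ILV with any non-absent
#' placement (optionally a specific placement side).
#'
#' @param fits List of `tada_fit`s.
#' @param network Layer name, or `NULL`.
#' @param ilv ILV index, or `NULL`.
#' @param side For ILVs: `"any"`, `"asocial"` or `"social"`.
#' @return Summed Akaike weight in \[0, 1\].
#' @export
summed_support <- function(fits, network = NULL, ilv = NULL, side = "any") {
  w <- akaike_weights(fits)
  has <- vapply(fits, function(f) {
    if (!is.null(network)) return(network %in% f$spec$networks)
    pl <- f$spec$ilv[ilv]
    switch(side,
           any = pl != "absent",
           asocial = pl %in% c("asocial_only", "both"),
           social = pl %in% c("social_only", "both"))
  }, logical(1))
  sum(w[has])
}

#' Model table for a fitted set
#'
#' @param fits List of `tada_fit`s.
#' @return data.frame with model label, K, logLik, AICc, delta-AICc and
#'   Akaike weight, sorted by AICc.
#' @export
model_table <- function(fits) {
  w <- akaike_weights(fits)
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  df <- data.frame(
    model = vapply(fits, function(f)
      paste0(if (length(f$spec$networks))
        paste(f$spec$networks, collapse = "+") else "asocial",
        if (length(f$spec$ilv)) paste0(" | ", paste(f$spec$ilv, collapse = ","))
        else "",
        " | ", f$spec$baseline), character(1)),
    K = vapply(fits, `[[`, integer(1), "K"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = a, delta = a - min(a, na.rm = TRUE), weight = w)
  df[order(df$aicc), ]
}

#' Akaike-weighted median of a parameter across models
#'
#' One reading of "model-averaged medians": the weighted median of a
#' parameter's estimates across all models containing it, with the Akaike
#' weights renormalised over those models.
#'
#' @param fits List of `tada_fit`s.
#' @param param Estimate name (e.g. `"s_sibling"`, `"theta"`).
#' @return Weighted median (NA when no model contains the parameter).
#' @export
model_averaged_median <- function(fits, param) {
  w <- akaike_weights(fits)
  est <- vapply(fits, function(f)
    if (param %in% names(f$estimates)) unname(f$estimates[param]) else NA_real_,
    numeric(1))
  ok <- !is.na(est) & w > 0
  if (!any(ok)) return(NA_real_)
  ww <- w[ok] / sum(w[ok])
  o <- order(est[ok])
  cum <- cumsum(ww[o])
  est[ok][o][which(cum >= 0.5)[1]]
}

#' Fit every model in a set
#'
#' @param data A [diffusion_data()].
#' @param specs List of [tada_spec()]s (see [enumerate_model_set()]).
#' @param seed,starts Passed to [fit_tada()].
#' @return List of `tada_fit`s (failed fits are dropped with a warning).
#' @export
fit_model_set <- function(data, specs, seed = 1L, starts = 3) {
  fits <- list()
  for (i in seq_along(specs)) {
    f <- tryCatch(fit_tada(data, specs[[i]], starts = starts, seed = seed),
                  error = function(e) NULL)
    if (is.null(f)) warning("model ", i, " failed to fit; dropped")
    else fits[[length(fits) + 1L]] <- f
  }
  fits
}

# generic profile-likelihood interval search; pl(v) returns the profile
# log-likelihood, lmax its maximum at the MLE. Used on the real profile and,
# in the tests, on closed-form likelihoods.
.ci_from_profile <- function(pl, mle, lmax, level = 0.95,
                             lower_bound = -Inf, upper_bound = Inf,
                             max_doublings = 40) {
  crit <- stats::qchisq(level, df = 1) / 2
  g <- function(v) (lmax - pl(v)) - crit
  search <- function(dir) {
    step <- max(abs(mle), 0.5)
    prev <- mle
    for (i in seq_len(max_doublings)) {
      v <- mle + dir * step
      if (dir < 0 && v <= lower_bound) {
        if (g(lower_bound) <= 0) return(lower_bound)
        v <- lower_bound + 1e-12 * max(1, abs(lower_bound))
        gv <- g(v)
        if (gv <= 0) return(lower_bound)
        return(stats::uniroot(g, c(v, prev), tol = 1e-6)$root)
      }
      if (dir > 0 && v >= upper_bound) {
        if (g(upper_bound) <= 0) return(upper_bound)
        return(stats::uniroot(g, c(prev, upper_bound), tol = 1e-6)$root)
      }
      gv <- tryCatch(g(v), error = function(e) NA_real_)
      if (!is.na(gv) && gv > 0)
        return(stats::uniroot(g, sort(c(prev, v)), tol = 1e-6)$root)
      prev <- v
      step <- step * 2
    }
    dir * Inf # never crossed: open interval on this side
  }
  lower <- search(-1)
  upper <- search(+1)
  list(lower = lower, upper = upper, level = level,
       open_lower = is.infinite(lower), open_upper = is.infinite(upper))
}

#' Profile-likelihood confidence interval for one parameter
#'
#' The interval is the set of values whose profile log-likelihood (all other
#' parameters re-optimised) lies within `qchisq(level, 1) / 2` of the
#' maximum. If the profile never crosses the threshold on a side within
#' bounds the interval is reported open on that side (this happens e.g. for
#' weakly identified transmission parameters at sites with few learners).
#'
#' @param data A [diffusion_data()].
#' @param spec The model's [tada_spec()].
#' @param fit The converged `tada_fit` to profile around.
#' @param param Estimate name (`"s_<layer>"`, `"theta"`, `"kappa"`,
#'   `"beta_a<i>"`, `"beta_s<i>"`).
#' @param level Confidence level (default 0.95, threshold 3.841/2 on the
#'   log-likelihood scale).
#' @param seed Passed to the inner refits.
#' @return List with `lower`, `upper`, `level`, `open_lower`, `open_upper`.
#' @export
profile_ci <- function(data, spec, fit, param, level = 0.95, seed = 1L) {
  stopifnot(param %in% names(fit$estimates))
  mle <- unname(fit$estimates[param])
  is_s <- grepl("^s_", param)
  is_scale <- param %in% c("theta", "kappa")
  pl <- function(v) {
    fx <- stats::setNames(list(v), param)
    f <- tryCatch(fit_tada(data, spec, starts = 1, seed = seed, fixed = fx),
                  error = function(e) NULL)
    if (is.null(f)) return(-Inf)
    f$loglik
  }
  .ci_from_profile(pl, mle, fit$loglik, level = level,
                   lower_bound = if (is_s) 0 else if (is_scale) 1e-10 else -Inf,
                   upper_bound = if (is_s) 1e7 else if (is_scale) 1e12 else 20)
}
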