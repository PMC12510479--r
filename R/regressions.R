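#' Classify the parental side-choice strategy during dependence
#'
#' `none` when parents produced no solves; `nonconflicting_right` /
#' `nonconflicting_left` when more than 90% of parental solves fell on one
#' side; `conflicting` otherwise.
#'
#' @param n_left,n_right Parental solve counts per side over the dependence
#'   window.
#' @param threshold Majority threshold (default 0.9, strict).
#' @return One of `"none"`, `"nonconflicting_right"`, `"nonconflicting_left"`,
#'   `"conflicting"`.
#' @export
classify_parental_strategy <- function(n_left, n_right, threshold = 0.9) {
  tot <- n_left + n_right
  if (tot == 0) return("none")
  pr <- n_right / tot
  if (pr > threshold) "nonconflicting_right"
  else if (pr < 1 - threshold) "nonconflicting_left"
  else "conflicting"
}

# parental solve/scrounge counts for one juvenile over (from, to]
.parental_counts <- function(solves, scrounges, parents, from, to) {
  sel_s <- solves$bird_id %in% parents & solves$timestamp > from &
    solves$timestamp <= to
  sel_c <- scrounges$bird_id %in% parents & scrounges$timestamp > from &
    scrounges$timestamp <= to
  list(n_solves = sum(sel_s),
       n_right = sum(sel_s & solves$action == "solve_right"),
       n_left = sum(sel_s & solves$action == "solve_left"),
       n_scrounges = sum(sel_c))
}

#' Build parental-exposure records
#'
#' One record per juvenile: whether it learned to solve, and the
#' log10(count + 1) of parental solves and parental scrounges over its
#' exposure window — fledging to its own acquisition time for learners,
#' fledging to fledging + `window_days` for non-learners (15 days, the mean
#' latency until juveniles start to solve).
#'
#' @param puzzle_events Puzzle event data.frame.
#' @param registry Bird registry.
#' @param knowledge Output of [knowledge_states()].
#' @param window_days Non-learner exposure window (default 15).
#' @param scrounge_window Scrounge attribution window in seconds (default 2).
#' @return data.frame `juvenile_id, learned, log_parental_solves,
#'   log_parental_scrounges, n_parental_solves, n_parental_right,
#'   n_parental_left, parental_strategy`.
#' @export
build_exposure_records <- function(puzzle_events, registry, knowledge,
                                   window_days = 15, scrounge_window = 2) {
  solves <- puzzle_events[puzzle_events$action %in%
                            c("solve_left", "solve_right"), , drop = FALSE]
  scr <- derive_scrounges(puzzle_events, window = scrounge_window)
  juv <- registry[registry$age_class == "juvenile", , drop = FALSE]
  out <- lapply(seq_len(nrow(juv)), function(r) {
    id <- juv$bird_id[r]
    ks <- knowledge[knowledge$bird_id == id, ]
    learned <- nrow(ks) == 1 && isTRUE(ks$knowledgeable)
    from <- juv$fledge_date[r]
    to <- if (learned) ks$acquisition_time else from + window_days * .DAY
    parents <- stats::na.omit(c(juv$mother_id[r], juv$father_id[r]))
    pc <- .parental_counts(solves, scr, parents, from, to)
    data.frame(juvenile_id = id, learned = learned,
               log_parental_solves = log10(pc$n_solves + 1),
               log_parental_scrounges = log10(pc$n_scrounges + 1),
               n_parental_solves = pc$n_solves,
               n_parental_right = pc$n_right, n_parental_left = pc$n_left,
               parental_strategy = classify_parental_strategy(pc$n_left,
                                                              pc$n_right),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the parental-exposure model
#'
#' Penalised-likelihood (maximum a posteriori) logistic regression of
#' learned-or-not on the log parental solve and scrounge counts, under
#' independent normal priors N(0, 10) on the intercept and N(0, 5) on the
#' slopes; 95% intervals are Wald intervals from the curvature at the mode.
#' The priors regularise the fit under complete separation.
#'
#' @param records Output of [build_exposure_records()].
#' @param prior_sd Numeric length 2: prior SD for intercept and slopes.
#' @return List with `coefficients` (data.frame `term, estimate, OR, lower,
#'   upper` on the odds-ratio scale for slopes) and `baseline_prob`
#'   (probability of learning with both covariates at 0, with 95% interval).
#' @export
fit_exposure_model <- function(records, prior_sd = c(10, 5)) {
  stopifnot(nrow(records) >= 10, length(unique(records$learned)) == 2)
  y <- as.numeric(records$learned)
  X <- cbind(intercept = 1, solves = records$log_parental_solves,
             scrounges = records$log_parental_scrounges)
  sd_vec <- c(prior_sd[1], rep(prior_sd[2], ncol(X) - 1))
  negpost <- function(b) {
    eta <- X %*% b
    -sum(y * eta - log1p(exp(eta))) + sum(b^2 / (2 * sd_vec^2))
  }
  opt <- stats::optim(rep(0, ncol(X)), negpost, method = "BFGS",
                      hessian = TRUE)
  V <- solve(opt$hessian)
  se <- sqrt(diag(V))
  b <- opt$par
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = colnames(X), estimate = b,
                      OR = exp(b), lower = exp(b - z * se),
                      upper = exp(b + z * se))
  list(coefficients = coefs,
       baseline_prob = c(estimate = stats::plogis(b[1]),
                         lower = stats::plogis(b[1] - z * se[1]),
                         upper = stats::plogis(b[1] + z * se[1])),
       separation = any(abs(b[-1]) > 10))
}

#' Build side-choice records
#'
#' One record per juvenile solve, with the social and personal information
#' available at that moment: the proportion and count of right solves by
#' *other* birds at the same site in the 5 minutes strictly before the solve;
#' the proportion of the juvenile's *own* right solves in the previous hour;
#' its cumulative prior solve count; a first-solving-day flag; and the
#' parental strategy during dependence.
#'
#' @param puzzle_events Puzzle event data.frame.
#' @param registry Bird registry.
#' @param knowledge Optional [knowledge_states()] output (only used to pass
#'   through acquisition metadata; records are built for all juvenile solves).
#' @param social_window Social window in seconds (default 300).
#' @param personal_window Personal window in seconds (default 3600).
#' @param dependence_days Dependence window for the parental strategy
#'   (default 15 days after fledging).
#' @param scrounge_window Scrounge attribution window in seconds (default 2).
#' @return data.frame, one row per juvenile solve, with columns
#'   `juvenile_id, solve_time, site_id, choice_right, social_prop_right,
#'   social_count, personal_prop_right, personal_count, cumulative_solves,
#'   first_day, has_social, has_personal, parental_strategy`.
#' @export
build_side_choice_records <- function(puzzle_events, registry,
                                      knowledge = NULL,
                                      social_window = 300,
                                      personal_window = 3600,
                                      dependence_days = 15,
                                      scrounge_window = 2) {
  ev <- .dedup_solves(puzzle_events[order(puzzle_events$timestamp), ,
                                    drop = FALSE])
  solves <- ev[ev$action %in% c("solve_left", "solve_right"), , drop = FALSE]
  juv <- registry[registry$age_class == "juvenile", , drop = FALSE]
  strat <- stats::setNames(rep("none", nrow(juv)), juv$bird_id)
  scr <- derive_scrounges(puzzle_events, window = scrounge_window)
  for (r in seq_len(nrow(juv))) {
    parents <- stats::na.omit(c(juv$mother_id[r], juv$father_id[r]))
    pc <- .parental_counts(solves, scr, parents, juv$fledge_date[r],
                           juv$fledge_date[r] + dependence_days * .DAY)
    strat[juv$bird_id[r]] <- classify_parental_strategy(pc$n_left, pc$n_right)
  }
  out <- list()
  for (id in intersect(unique(solves$bird_id), juv$bird_id)) {
    own <- solves[solves$bird_id == id, , drop = FALSE]
    first_day <- floor(own$timestamp[1] / .DAY)
    for (r in seq_len(nrow(own))) {
      t <- own$timestamp[r]
      site <- own$site_id[r]
      soc <- solves$bird_id != id & solves$site_id == site &
        solves$timestamp > t - social_window & solves$timestamp < t
      pers <- own$timestamp > t - personal_window & own$timestamp < t
      n_soc <- sum(soc)
      n_pers <- sum(pers)
      out[[length(out) + 1L]] <- data.frame(
        juvenile_id = id, solve_time = t, site_id = site,
        choice_right = as.integer(own$action[r] == "solve_right"),
        social_prop_right = if (n_soc)
          sum(soc & solves$action == "solve_right") / n_soc else NA_real_,
        social_count = n_soc,
        personal_prop_right = if (n_pers)
          sum(pers & own$action == "solve_right") / n_pers else NA_real_,
        personal_count = n_pers,
        cumulative_solves = r - 1L,
        first_day = floor(t / .DAY) == first_day,
        has_social = n_soc >= 1, has_personal = n_pers >= 1,
        parental_strategy = unname(strat[id]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no juvenile solves in the stream", call. = FALSE)
  res <- do.call(rbind, out)
  res <- res[order(res$solve_time), ]
  rownames(res) <- NULL
  res
}

# Wald ORs from a (mixed) logistic fit
.or_table <- function(coefs, se) {
  z <- stats::qnorm(0.975)
  data.frame(term = names(coefs), OR = exp(coefs),
             lower = exp(coefs - z * se), upper = exp(coefs + z * se),
             row.names = NULL)
}

#' Fit the side-choice decision models
#'
#' Three estimator contracts over [build_side_choice_records()] output:
#' \describe{
#'   \item{`first_day_parental`}{per-juvenile first-day right/left solve
#'     counts modelled by a binomial GLM on the parental strategy category
#'     (reference `"none"`).}
#'   \item{`first_day_social`}{first-day solves with social information:
#'     mixed logistic regression of side on the 5-min proportion of right
#'     solves by others, its interaction with the number of observed solves,
#'     and a juvenile random intercept.}
#'   \item{`all_days`}{solves with both social and personal information:
#'     mixed logistic regression on the 5-min social proportion, the 1-h
#'     personal proportion, and their interactions with cumulative experience
#'     (scaled per 100 solves), with a juvenile random intercept.}
#' }
#' With a single juvenile the random intercept is degenerate and the model
#' falls back to a fixed-effects GLM with a warning.
#'
#' @param records Output of [build_side_choice_records()].
#' @param model One of `"first_day_parental"`, `"first_day_social"`,
#'   `"all_days"`.
#' @return List with `table` (term, OR, 95% Wald interval), `n_records`,
#'   `n_juveniles`, and the underlying `fit`.
#' @export
fit_side_choice_models <- function(records,
                                   model = c("all_days", "first_day_social",
                                             "first_day_parental")) {
  model <- match.arg(model)
  if (model == "first_day_parental") {
    d <- records[records$first_day, , drop = FALSE]
    agg <- do.call(rbind, lapply(split(d, d$juvenile_id), function(x)
      data.frame(juvenile_id = x$juvenile_id[1],
                 right = sum(x$choice_right), n = nrow(x),
                 parental_strategy = x$parental_strategy[1])))
    agg$parental_strategy <- factor(
      agg$parental_strategy,
      levels = c("none", "nonconflicting_left", "nonconflicting_right",
                 "conflicting"))
    agg$parental_strategy <- droplevels(agg$parental_strategy)
    fit <- stats::glm(cbind(right, n - right) ~ parental_strategy,
                      data = agg, family = stats::binomial())
    tab <- .or_table(stats::coef(fit), sqrt(diag(stats::vcov(fit))))
    return(list(table = tab, n_records = nrow(agg),
                n_juveniles = nrow(agg), fit = fit))
  }
  if (model == "first_day_social") {
    d <- records[records$first_day & records$has_social, , drop = FALSE]
    form <- choice_right ~ social_prop_right * social_count +
      (1 | juvenile_id)
    fallback <- choice_right ~ social_prop_right * social_count
  } else {
    d <- records[records$has_social & records$has_personal, , drop = FALSE]
    d$cum100 <- d$cumulative_solves / 100
    form <- choice_right ~ social_prop_right + personal_prop_right + cum100 +
      social_prop_right:cum100 + personal_prop_right:cum100 +
      (1 | juvenile_id)
    fallback <- choice_right ~ social_prop_right + personal_prop_right +
      cum100 + social_prop_right:cum100 + personal_prop_right:cum100
  }
  if (!nrow(d)) stop("no records satisfy the filters for model ", model,
                     call. = FALSE)
  single <- length(unique(d$juvenile_id)) < 2
  fit <- if (single) NULL else
    tryCatch(suppressWarnings(
      lme4::glmer(form, data = d, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE))),
      error = function(e) NULL)
  if (is.null(fit)) {
    warning("random intercept degenerate or fit failed; ",
            "falling back to fixed-effects GLM")
    fit <- stats::glm(fallback, data = d, family = stats::binomial())
    tab <- .or_table(stats::coef(fit), sqrt(diag(stats::vcov(fit))))
  } else {
    tab <- .or_table(lme4::fixef(fit),
                     sqrt(diag(as.matrix(stats::vcov(fit)))))
  }
  list(table = tab, n_records = nrow(d),
       n_juveniles = length(unique(d$juvenile_id)), fit = fit)
}
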