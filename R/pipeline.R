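#' Default pipeline configuration
#'
#' All analysis windows and thresholds exposed as named keys with the
#' field-protocol defaults: 7-day network and presence windows, 2-s scrounge
#' window, 5-min social and 1-h personal side-choice windows, 15-day
#' non-learner exposure window, 10-solve knowledge threshold, third-solve
#' acquisition time, 10-registration feeder filter, 90% parental-strategy
#' rule, and 3-event minimum per modelled site.
#'
#' @return Nested named list of defaults; override any key via the `config`
#'   argument of [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "tadanet_out",
    stages = c("simulate", "networks", "nbda", "decompose", "sidechoice",
               "report"),
    inputs = list(registry = NULL, detections = NULL, puzzle_events = NULL),
    scenario = list(), # overrides for scenario_config() when simulating
    diffusion = list(start_s = 0, end_s = NULL),
    windows = list(network_days = 7, presence_days = 7, social_s = 300,
                   personal_s = 3600, scrounge_s = 2, nonlearner_days = 15),
    thresholds = list(knowledge = 10, acq_solve = 3, min_registrations = 10,
                      strategy = 0.9, min_site_events = 3),
    nbda = list(networks = .LAYERS, n_ilv = 0, baseline = "constant",
                starts = 3))
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

.config_hash <- function(config) {
  config$outdir <- NULL
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

.write_stage <- function(df, outdir, name, manifest) {
  path <- file.path(outdir, name)
  utils::write.csv(df, path, row.names = FALSE)
  manifest$outputs[[name]] <- list(path = path, rows = nrow(df))
  manifest
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate` (synthetic scenario to CSV), `networks`
#' (knowledge states, gathering events, dynamic per-event networks, presence),
#' `nbda` (diffusion data, model-set fit, model table and summed supports),
#' `decompose` (per-event pathway probabilities and %ST), `sidechoice`
#' (exposure and side-choice records and model fits) and `report`
#' (aggregated `results.json` + `manifest.json`). Stage outputs are CSV/JSON
#' files under `outdir`; a single seed governs all randomness, and rerunning
#' with the same config and seed reproduces identical numeric outputs.
#'
#' @param config A nested list (see [default_pipeline_config()]) or the path
#'   to a YAML file of overrides. Provide `inputs` paths for field data or a
#'   `scenario` block (with the `simulate` stage) for synthetic data.
#' @param stages Optional stage subset, overriding `config$stages`. Stages
#'   depending on an earlier stage's in-memory results (e.g. `decompose`
#'   after `nbda`) raise a dependency error when run alone.
#' @return The run manifest (invisibly): config hash, seed, per-stage output
#'   files with row counts, package version.
#' @export
run_pipeline <- function(config = list(), stages = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("schema error: config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(default_pipeline_config(), config)
  if (!is.null(stages)) cfg$stages <- stages
  bad <- setdiff(cfg$stages, c("simulate", "networks", "nbda", "decompose",
                               "sidechoice", "report"))
  if (length(bad)) stop("schema error: unknown stage(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                   stages = cfg$stages,
                   version = as.character(utils::packageVersion("tadanet")),
                   outputs = list())
  state <- new.env(parent = emptyenv())

  if ("simulate" %in% cfg$stages) {
    sc <- do.call(scenario_config,
                  c(list(seed = cfg$seed), cfg$scenario))
    scen <- simulate_scenario(sc)
    state$scenario <- scen
    reg_out <- scen$registry
    manifest <- .write_stage(reg_out, cfg$outdir, "registry.csv", manifest)
    manifest <- .write_stage(scen$detections, cfg$outdir, "detections.csv",
                             manifest)
    manifest <- .write_stage(scen$puzzle_events, cfg$outdir,
                             "puzzle_events.csv", manifest)
    manifest <- .write_stage(scen$sim$schedule, cfg$outdir,
                             "ground_truth_schedule.csv", manifest)
    state$registry <- scen$registry
    state$detections <- scen$detections
    state$puzzle_events <- scen$puzzle_events
    if (is.null(cfg$diffusion$end_s)) cfg$diffusion$end_s <- sc$duration * .DAY
  } else if (!is.null(cfg$inputs$registry)) {
    tabs <- load_event_tables(cfg$inputs$registry, cfg$inputs$detections,
                              cfg$inputs$puzzle_events)
    state$registry <- tabs$registry
    state$detections <- tabs$detections
    state$puzzle_events <- tabs$puzzle_events
  } else if (length(intersect(cfg$stages,
                              c("networks", "nbda", "sidechoice")))) {
    stop("schema error: no inputs configured and 'simulate' not requested",
         call. = FALSE)
  }
  if (is.null(cfg$diffusion$end_s))
    cfg$diffusion$end_s <- max(state$puzzle_events$timestamp)

  if ("networks" %in% cfg$stages || "nbda" %in% cfg$stages) {
    state$data <- build_diffusion_data(
      state$registry, state$detections, state$puzzle_events,
      diffusion_start = cfg$diffusion$start_s, t_end = cfg$diffusion$end_s,
      window_days = cfg$windows$network_days,
      lookback_days = cfg$windows$presence_days,
      min_registrations = cfg$thresholds$min_registrations,
      knowledge_threshold = cfg$thresholds$knowledge,
      acq_solve = cfg$thresholds$acq_solve,
      nonlearner_window = cfg$windows$nonlearner_days,
      min_site_events = cfg$thresholds$min_site_events,
      ilvs = cfg$nbda$n_ilv > 0,
      scrounge_window = cfg$windows$scrounge_s, seed = cfg$seed)
    edges <- do.call(rbind, lapply(state$data$sites, function(s) {
      el <- do.call(rbind, lapply(seq_len(nrow(s$events)), function(e)
        cbind(site_id = s$site_id, event = e,
              network_edge_list(s$networks[[e]]))))
      el
    }))
    manifest <- .write_stage(edges, cfg$outdir, "networks_edges.csv",
                             manifest)
    pres <- do.call(rbind, lapply(state$data$sites, function(s)
      data.frame(site_id = s$site_id,
                 bird_id = rep(s$ids, each = nrow(s$presence)),
                 slice = rep(seq_len(nrow(s$presence)), length(s$ids)),
                 present = as.integer(s$presence))))
    manifest <- .write_stage(pres, cfg$outdir, "presence.csv", manifest)
    ksdf <- knowledge_states(state$puzzle_events, state$registry,
                             cfg$diffusion$start_s,
                             threshold = cfg$thresholds$knowledge,
                             acq_solve = cfg$thresholds$acq_solve)
    manifest <- .write_stage(ksdf, cfg$outdir, "knowledge_states.csv",
                             manifest)
  }

  if ("nbda" %in% cfg$stages) {
    specs <- enumerate_model_set(cfg$nbda$networks, cfg$nbda$n_ilv,
                                 cfg$nbda$baseline)
    fits <- fit_model_set(state$data, specs, seed = cfg$seed,
                          starts = cfg$nbda$starts)
    state$fits <- fits
    mt <- model_table(fits)
    manifest <- .write_stage(mt, cfg$outdir, "model_table.csv", manifest)
    supp <- data.frame(
      component = cfg$nbda$networks,
      summed_weight = vapply(cfg$nbda$networks, function(k)
        summed_support(fits, network = k), numeric(1)))
    if (cfg$nbda$n_ilv > 0)
      supp <- rbind(supp, data.frame(
        component = paste0("ilv", seq_len(cfg$nbda$n_ilv)),
        summed_weight = vapply(seq_len(cfg$nbda$n_ilv), function(i)
          summed_support(fits, ilv = i), numeric(1))))
    manifest <- .write_stage(supp, cfg$outdir, "summed_support.csv", manifest)
  }

  if ("decompose" %in% cfg$stages) {
    if (is.null(state$fits))
      stop("dependency error: 'decompose' requires the 'nbda' stage",
           call. = FALSE)
    best <- state$fits[[which.min(vapply(state$fits, `[[`, numeric(1),
                                         "aicc"))]]
    dec <- pathway_decomposition(state$data, best)
    state$decomposition <- dec
    manifest <- .write_stage(dec$table, cfg$outdir, "pathway_table.csv",
                             manifest)
    manifest <- .write_stage(
      data.frame(pathway = names(dec$pct_st), pct_st = dec$pct_st),
      cfg$outdir, "pct_st.csv", manifest)
    manifest <- .write_stage(dec$by_class, cfg$outdir,
                             "pathway_by_class.csv", manifest)
  }

  if ("sidechoice" %in% cfg$stages) {
    ksdf <- knowledge_states(state$puzzle_events, state$registry,
                             cfg$diffusion$start_s,
                             threshold = cfg$thresholds$knowledge,
                             acq_solve = cfg$thresholds$acq_solve)
    exp_rec <- build_exposure_records(state$puzzle_events, state$registry,
                                      ksdf,
                                      window_days = cfg$windows$nonlearner_days,
                                      scrounge_window = cfg$windows$scrounge_s)
    manifest <- .write_stage(exp_rec, cfg$outdir, "exposure_records.csv",
                             manifest)
    exp_fit <- tryCatch(fit_exposure_model(exp_rec), error = function(e) NULL)
    if (!is.null(exp_fit))
      manifest <- .write_stage(exp_fit$coefficients, cfg$outdir,
                               "exposure_model.csv", manifest)
    state$exposure <- exp_fit
    sc_rec <- build_side_choice_records(
      state$puzzle_events, state$registry,
      social_window = cfg$windows$social_s,
      personal_window = cfg$windows$personal_s,
      dependence_days = cfg$windows$nonlearner_days,
      scrounge_window = cfg$windows$scrounge_s)
    manifest <- .write_stage(sc_rec, cfg$outdir, "side_choice_records.csv",
                             manifest)
    sc_fit <- tryCatch(fit_side_choice_models(sc_rec, "all_days"),
                       error = function(e) NULL)
    if (!is.null(sc_fit))
      manifest <- .write_stage(sc_fit$table, cfg$outdir,
                               "side_choice_all_days.csv", manifest)
    state$sidechoice <- sc_fit
  }

  if ("report" %in% cfg$stages) {
    results <- list(seed = cfg$seed, config_hash = manifest$config_hash)
    if (!is.null(state$fits)) {
      best <- state$fits[[which.min(vapply(state$fits, `[[`, numeric(1),
                                           "aicc"))]]
      results$best_model <- model_table(state$fits)$model[1]
      results$n_events <- best$n_events
      results$summed_support <- stats::setNames(
        lapply(cfg$nbda$networks, function(k)
          summed_support(state$fits, network = k)), cfg$nbda$networks)
    }
    if (!is.null(state$decomposition))
      results$pct_st <- as.list(state$decomposition$pct_st)
    if (!is.null(state$sidechoice))
      results$side_choice_or <- stats::setNames(
        as.list(state$sidechoice$table$OR), state$sidechoice$table$term)
    jsonlite::write_json(results, file.path(cfg$outdir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$outputs[["results.json"]] <-
      list(path = file.path(cfg$outdir, "results.json"), rows = NA)
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
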