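#' Read and validate the bird registry (pedigree/brood table)
#'
#' The registry lists every PIT-tagged bird with its age class and, for
#' juveniles, its brood membership and fledge date. Parent references must
#' resolve within the registry and no bird may be its own parent.
#'
#' @param path CSV file with columns
#'   `bird_id,age_class,mother_id,father_id,brood_id,fledge_date`. Optional
#'   extra columns (e.g. `site_id`) are preserved. Empty strings are read as
#'   missing.
#' @return A `data.frame` registry, one row per bird.
#' @export
read_bird_registry <- function(path) {
  req <- c("bird_id", "age_class", "mother_id", "father_id", "brood_id",
           "fledge_date")
  df <- .read_checked(path, req)$data
  for (col in c("mother_id", "father_id", "brood_id"))
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA
  df$fledge_date <- suppressWarnings(as.numeric(df$fledge_date))
  validate_registry(df)
  df
}

#' @keywords internal
validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  if (anyDuplicated(registry$bird_id))
    stop("duplicate bird_id in registry", call. = FALSE)
  if (!all(registry$age_class %in% c("adult", "juvenile")))
    stop("age_class must be 'adult' or 'juvenile'", call. = FALSE)
  juv <- registry$age_class == "juvenile"
  if (any(juv & (is.na(registry$brood_id) | is.na(registry$fledge_date))))
    stop("juveniles must have brood_id and fledge_date", call. = FALSE)
  parents <- c(registry$mother_id, registry$father_id)
  parents <- parents[!is.na(parents)]
  unknown <- setdiff(parents, registry$bird_id)
  if (length(unknown))
    stop("referential error: parent id(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  own <- registry$bird_id == registry$mother_id |
    registry$bird_id == registry$father_id
  if (any(own, na.rm = TRUE))
    stop("a bird cannot be its own parent", call. = FALSE)
  invisible(registry)
}

# Shared CSV reader: checks header, reports unparseable rows with line
# numbers instead of failing.
.read_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  rejects <- data.frame(line = integer(), reason = character())
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad)) {
      # +1 for the header line
      rejects <- rbind(rejects,
                       data.frame(line = bad + 1L,
                                  reason = paste0("unparseable ", col)))
    }
    df[[col]] <- val
  }
  keep <- setdiff(seq_len(nrow(df)), rejects$line - 1L)
  list(data = df[keep, , drop = FALSE], rejects = rejects)
}

#' Load and validate all event tables
#'
#' Reads the registry, feeder detections and puzzle-box event log, rejects
#' unparseable rows (reported with their line numbers), validates categorical
#' fields and referential integrity, and returns time-sorted streams.
#'
#' @param registry_path,detections_path,puzzle_path CSV paths. Detections have
#'   columns `bird_id,timestamp,site_id,source`
#'   (source in `network_feeder`/`puzzle`); puzzle events have
#'   `bird_id,timestamp,site_id,action` (action in
#'   `solve_left`/`solve_right`/`visit`). Timestamps are seconds.
#' @return A list with `registry`, `detections`, `puzzle_events` (sorted by
#'   timestamp) and `rejects`, a data.frame of rejected rows
#'   (`file,line,reason`).
#' @export
load_event_tables <- function(registry_path, detections_path, puzzle_path) {
  registry <- read_bird_registry(registry_path)

  det <- .read_checked(detections_path,
                       c("bird_id", "timestamp", "site_id", "source"),
                       numeric_cols = "timestamp")
  puz <- .read_checked(puzzle_path,
                       c("bird_id", "timestamp", "site_id", "action"),
                       numeric_cols = "timestamp")
  rejects <- rbind(
    if (nrow(det$rejects)) cbind(file = detections_path, det$rejects),
    if (nrow(puz$rejects)) cbind(file = puzzle_path, puz$rejects))
  if (is.null(rejects))
    rejects <- data.frame(file = character(), line = integer(),
                          reason = character())

  detections <- det$data
  puzzle <- puz$data
  bad_src <- !(detections$source %in% c("network_feeder", "puzzle"))
  if (any(bad_src)) {
    rejects <- rbind(rejects, data.frame(
      file = detections_path, line = NA_integer_,
      reason = paste0("invalid source '", detections$source[bad_src], "'")))
    detections <- detections[!bad_src, , drop = FALSE]
  }
  bad_act <- !(puzzle$action %in% c("solve_left", "solve_right", "visit"))
  if (any(bad_act)) {
    rejects <- rbind(rejects, data.frame(
      file = puzzle_path, line = NA_integer_,
      reason = paste0("invalid action '", puzzle$action[bad_act], "'")))
    puzzle <- puzzle[!bad_act, , drop = FALSE]
  }

  detections <- detections[order(detections$timestamp), , drop = FALSE]
  puzzle <- puzzle[order(puzzle$timestamp), , drop = FALSE]
  rownames(detections) <- rownames(puzzle) <- NULL
  list(registry = registry, detections = detections, puzzle_events = puzzle,
       rejects = rejects)
}

# RFID double-reads: drop repeated (bird, timestamp, action) solves.
.dedup_solves <- function(puzzle_events) {
  solve <- puzzle_events$action %in% c("solve_left", "solve_right")
  key <- paste(puzzle_events$bird_id, puzzle_events$timestamp,
               puzzle_events$action)
  drop <- solve & duplicated(key)
  puzzle_events[!drop, , drop = FALSE]
}

#' Derive scrounge events from the puzzle-box log
#'
#' A scrounge is a visit by a different bird within 2 s after a solve at the
#' same site, while the sliding door is still open. A visit within range of
#' several solves is attached to the most recent preceding solve by another
#' bird.
#'
#' @param puzzle_events Puzzle event data.frame (see [load_event_tables()]).
#' @param window Scrounge window in seconds (default 2); the visit must fall
#'   in `(t_solve, t_solve + window]`.
#' @return data.frame with one row per scrounge: `bird_id`, `timestamp`,
#'   `site_id`, `solver_id`, `solve_time`.
#' @export
derive_scrounges <- function(puzzle_events, window = 2) {
  ev <- puzzle_events[order(puzzle_events$timestamp), , drop = FALSE]
  ev <- .dedup_solves(ev)
  out <- list()
  for (site in unique(ev$site_id)) {
    se <- ev[ev$site_id == site, , drop = FALSE]
    solves <- se[se$action %in% c("solve_left", "solve_right"), , drop = FALSE]
    visits <- se[se$action == "visit", , drop = FALSE]
    if (!nrow(solves) || !nrow(visits)) next
    for (v in seq_len(nrow(visits))) {
      tv <- visits$timestamp[v]
      ok <- which(solves$timestamp < tv &
                    tv - solves$timestamp <= window &
                    solves$bird_id != visits$bird_id[v])
      if (!length(ok)) next
      s <- ok[which.max(solves$timestamp[ok])]
      out[[length(out) + 1L]] <- data.frame(
        bird_id = visits$bird_id[v], timestamp = tv, site_id = site,
        solver_id = solves$bird_id[s], solve_time = solves$timestamp[s],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(bird_id = character(), timestamp = numeric(),
                      site_id = character(), solver_id = character(),
                      solve_time = numeric()))
  res <- do.call(rbind, out)
  res[order(res$timestamp), , drop = FALSE]
}

#' Knowledge states, demonstrators and filtered adults
#'
#' A bird counts as knowledgeable if it produced at least `threshold` solves
#' over the study; its acquisition time is the time of its `acq_solve`-th
#' solve (the third by default, to absorb occasional RFID misreads of the
#' solver's identity). Adults whose acquisition precedes the diffusion start
#' are demonstrators; adults acquiring during the diffusion are "filtered"
#' (excluded as learners, available as transmitters once knowledgeable).
#' Juveniles are never demonstrators or filtered.
#'
#' @param puzzle_events Puzzle event data.frame.
#' @param registry Bird registry.
#' @param diffusion_start Timestamp (seconds) at which the juvenile diffusion
#'   starts.
#' @param threshold Minimum solves to count as knowledgeable (default 10).
#' @param acq_solve Which solve defines the acquisition time (default 3).
#' @return data.frame: `bird_id, age_class, n_solves, knowledgeable,
#'   acquisition_time, demonstrator, filtered`. `acquisition_time` is `NA`
#'   for non-knowledgeable birds.
#' @export
knowledge_states <- function(puzzle_events, registry, diffusion_start,
                             threshold = 10, acq_solve = 3) {
  ev <- .dedup_solves(puzzle_events[order(puzzle_events$timestamp), ,
                                    drop = FALSE])
  solves <- ev[ev$action %in% c("solve_left", "solve_right"), , drop = FALSE]
  unknown <- setdiff(unique(solves$bird_id), registry$bird_id)
  if (length(unknown))
    stop("referential error: solver(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- registry[, c("bird_id", "age_class"), drop = FALSE]
  out$n_solves <- 0L
  out$acquisition_time <- NA_real_
  cnt <- table(solves$bird_id)
  out$n_solves[match(names(cnt), out$bird_id)] <- as.integer(cnt)
  out$knowledgeable <- out$n_solves >= threshold
  for (i in which(out$knowledgeable)) {
    ts <- solves$timestamp[solves$bird_id == out$bird_id[i]]
    out$acquisition_time[i] <- sort(ts)[acq_solve]
  }
  out$demonstrator <- out$age_class == "adult" & out$knowledgeable &
    !is.na(out$acquisition_time) & out$acquisition_time < diffusion_start
  out$filtered <- out$age_class == "adult" & out$knowledgeable &
    !out$demonstrator
  rownames(out) <- NULL
  out
}
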