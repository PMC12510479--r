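#' Per-event learning-pathway decomposition
#'
#' For every acquisition event, splits the learner's modelled rate into its
#' additive components: `p_k = s_k exp(bS x) T_i^(k) / R_i` for each network
#' layer and `p_asocial = exp(bA x) / R_i`, where `T_i^(k)` is the learner's
#' weighted knowledgeable-neighbour sum in layer k at the event. Rows sum to
#' one; the mean of `p_k` over events, times 100, is the estimated
#' percentage of acquisition events attributable to social transmission
#' through that layer (%ST).
#'
#' Each learner is classed `first_in_cohort` when no same-brood bird was
#' already knowledgeable at its acquisition time, else `subsequent`; per-class
#' summaries report both the mean and the median of the per-event
#' probabilities.
#'
#' @param data A [diffusion_data()].
#' @param fit A converged `tada_fit`.
#' @param spec The fit's [tada_spec()] (defaults to `fit$spec`).
#' @return A list of class `pathway_decomposition`: `table` (per-event
#'   probabilities and learner class), `pct_st` (named percentages incl.
#'   asocial, summing to 100), `by_class` (mean and median per pathway for
#'   first/subsequent learners).
#' @export
pathway_decomposition <- function(data, fit, spec = fit$spec) {
  params <- fit$params
  rows <- list()
  for (site in data$sites) {
    E <- nrow(site$events)
    if (!E) next
    n_ilv <- data$n_ilv
    b <- .beta_full(params, spec, n_ilv)
    for (e in seq_len(E)) {
      i <- site$learner_idx[e]
      x <- if (n_ilv) site$ilvs[e, i, ] else numeric()
      comp <- stats::setNames(numeric(4), .LAYERS)
      for (k in spec$networks)
        comp[k] <- params$s[[k]] * exp(sum(b$bs * x)) * site$Tsoc[e, i, k]
      asoc <- exp(sum(b$ba * x))
      R <- asoc + sum(comp)
      if (R <= 0) stop("degenerate rate at an observed event", call. = FALSE)
      # siblings knowledgeable at the event? (state at slice start)
      sibs <- which(!is.na(site$brood) & site$brood == site$brood[i] &
                      seq_along(site$ids) != i)
      first <- !any(site$z[e, sibs] > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = site$site_id, event = e, learner_id = site$ids[i],
        time = site$events$time[e],
        p_vertical = comp["vertical"] / R, p_oblique = comp["oblique"] / R,
        p_sibling = comp["sibling"] / R, p_peer = comp["peer"] / R,
        p_asocial = asoc / R,
        learner_class = if (first) "first_in_cohort" else "subsequent",
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pcols <- paste0("p_", c(.LAYERS, "asocial"))
  pct <- 100 * colMeans(tab[, pcols, drop = FALSE])
  names(pct) <- sub("^p_", "", pcols)
  by_class <- do.call(rbind, lapply(split(tab, tab$learner_class), function(d)
    data.frame(learner_class = d$learner_class[1], n = nrow(d),
               pathway = sub("^p_", "", pcols),
               mean = colMeans(d[, pcols]),
               median = apply(d[, pcols], 2, stats::median),
               row.names = NULL)))
  rownames(by_class) <- NULL
  structure(list(table = tab, pct_st = pct, by_class = by_class),
            class = "pathway_decomposition")
}

#' @export
print.pathway_decomposition <- function(x, ...) {
  cat("pathway_decomposition:", nrow(x$table), "acquisition events\n")
  cat("  %ST:", paste0(names(x$pct_st), "=",
                       sprintf("%.1f", x$pct_st), collapse = "  "), "\n")
  invisible(x)
}
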