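#' Run the full flicker/shimmer analysis pipeline
#'
#' One-shot driver: obtain a frame stack (synthetic scene or frames on
#' disk), pool it to square-level dlum series, mask shimmering episodes,
#' detect and filter flickering events, pool the wave trigger registry into
#' per-phase trigger maps and ts/nts partitions, and compute the cohort
#' statistics (relF, rate classes, exponential fits, Spearman, sign/chi2).
#' All outputs are written as CSV/JSON under \code{out_dir} and returned.
#' The run is deterministic given the config (including its seed).
#'
#' @param config a list (e.g. from \code{\link{read_run_config}}) with
#'   elements:
#'   \describe{
#'     \item{scene}{arguments for \code{\link{scene_config}} (synthetic
#'       mode), or NULL when \code{frames} is given.}
#'     \item{frames}{path to a PNG directory / TIFF stack plus
#'       \code{fps} and \code{square_px} (file mode); requires
#'       \code{registry} path.}
#'     \item{registry}{path of a trigger-registry CSV (file mode;
#'       synthetic mode uses the generator's ground truth).}
#'     \item{filter}{arguments for \code{\link{event_filter_config}}.}
#'     \item{shimmer}{\code{frac_threshold}, \code{min_len_frames} for
#'       \code{\link{detect_shimmer_episodes}}.}
#'     \item{phases}{named list of 0-based inclusive difference-series
#'       intervals \code{c(start, end)}; default one phase \code{all}
#'       covering the whole series. Intervals must not overlap.}
#'     \item{mask_squares}{data.frame of excluded squares (row, col);
#'       synthetic mouth-zone squares are excluded automatically.}
#'     \item{seed}{integer seed for the synthetic scene.}
#'   }
#' @param out_dir output directory; NULL skips writing.
#' @return (invisibly when writing) a list with \code{grid},
#'   \code{events}, \code{events_filtered}, \code{episodes},
#'   \code{phases} (per-phase list: \code{trigger_map},
#'   \code{partition}, \code{records}, \code{relF}, \code{class_table},
#'   \code{fits}, \code{spearman}, \code{comparison}) and \code{summary}
#'   (the JSON-ready summary list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  filter_args <- config$filter
  if (is.null(filter_args)) filter_args <- list()

  if (!is.null(config$scene)) {
    sc_args <- config$scene
    if (!is.null(config$seed)) sc_args$seed <- config$seed
    sc_args <- scene_args_from_yaml(sc_args)
    sc <- do.call(scene_config, sc_args)
    rendered <- render_frames(sc)
    stack <- rendered$stack
    grid <- rendered$grid
    registry <- rendered$ground_truth$trigger_registry
    fps <- sc$fps
    mask_sq <- if (!is.null(sc$mouth_zone)) sc$mouth_zone$squares else NULL
    ground_truth <- rendered$ground_truth
  } else if (!is.null(config$frames)) {
    fps <- config$frames$fps
    if (is.null(fps)) stop("missing input: frames$fps")
    if (is.null(config$frames$path)) stop("missing input: frames$path")
    if (is.null(config$registry)) stop("missing input: registry")
    stack <- read_frame_stack(config$frames$path, fps = fps)
    grid <- build_grid(dim(stack)[1:2], config$frames$square_px)
    registry <- read_trigger_registry(config$registry)
    mask_sq <- NULL
    ground_truth <- NULL
  } else {
    stop("missing input: either scene or frames must be configured")
  }
  if (!is.null(config$mask_squares)) {
    mask_sq <- rbind(mask_sq, as.data.frame(config$mask_squares))
  }
  filter_args$fps <- fps
  cfg <- do.call(event_filter_config, filter_args)

  series <- square_series(stack, grid)
  shim <- config$shimmer
  episodes <- detect_shimmer_episodes(
    activity_fraction(series, cfg$detect_threshold),
    frac_threshold = if (is.null(shim$frac_threshold)) 0.15
                     else shim$frac_threshold,
    min_len_frames = if (is.null(shim$min_len_frames)) 3L
                     else shim$min_len_frames)

  masks <- if (!is.null(mask_sq) && nrow(mask_sq) > 0) {
    list(region_mask(mask_sq, "mouth_zone"))
  } else list()
  active <- apply_mask(grid, masks)

  events <- detect_events_all(series, grid, cfg)
  events_f <- filter_events(events, episodes, active)

  phases <- config$phases
  n_series <- nrow(series)
  if (is.null(phases)) phases <- list(all = c(0L, n_series - 1L))
  check_phases(phases, n_series)

  per_phase <- lapply(names(phases), function(ph) {
    iv <- phases[[ph]]
    t_ref <- (iv[2] - iv[1] + 1) / fps
    ev <- events_f[events_f$onset_frame >= iv[1] &
                     events_f$onset_frame <= iv[2], , drop = FALSE]
    reg <- slice_registry(registry, ph, iv)
    tmap <- scale_map(pool_trigger_activity(reg, grid, phase_label = NULL))
    tmap$phase_label <- ph
    part <- partition_cohorts(tmap, active)
    records <- rate_intensity_records(ev, part, t_ref, phase_label = ph)
    relF <- relf_metrics(ev[, c("row", "col")], part, nrow(active))
    tab <- bin_rate_classes(records)
    fits <- list()
    for (co in c("ts", "nts")) {
      sub <- tab[tab$cohort == co & tab$mean_fI > 0, , drop = FALSE]
      fits[[co]] <- if (nrow(sub) >= 2) {
        fit_exponential(sub$rate_mid, sub$mean_fI)
      } else NULL
    }
    act_rec <- records[records$n_events > 0, , drop = FALSE]
    spear <- if (nrow(act_rec) >= 3) {
      spearman_rate_intensity(act_rec$rate_hz, act_rec$fI)
    } else NULL
    comparison <- if (length(intersect(tab$class_index[tab$cohort == "ts"],
                                       tab$class_index[tab$cohort == "nts"]))) {
      cohort_difference(tab)
    } else NULL
    list(phase = ph, interval = iv, t_ref = t_ref, trigger_map = tmap,
         partition = part, records = records, relF = relF,
         class_table = tab, fits = fits, spearman = spear,
         comparison = comparison)
  })
  names(per_phase) <- names(phases)

  summary <- list(
    grid = list(rows = grid$rows, cols = grid$cols,
                square_px = grid$square_px, n_squares = grid$rows * grid$cols,
                extent_cm = as.list(grid_extent_cm(grid))),
    fps = fps,
    n_frames = dim(stack)[3],
    n_active_squares = nrow(active),
    n_events_detected = nrow(events),
    n_events_filtered = nrow(events_f),
    n_shimmer_episodes = nrow(episodes),
    phases = lapply(per_phase, summarize_phase)
  )

  result <- list(grid = grid, series_dim = dim(series), events = events,
                 events_filtered = events_f, episodes = episodes,
                 phases = per_phase, summary = summary,
                 ground_truth = ground_truth, active = active)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(events, file.path(out_dir, "events_raw.csv"))
    write_events(events_f, file.path(out_dir, "events_filtered.csv"))
    utils::write.csv(episodes, file.path(out_dir, "episodes.csv"),
                     row.names = FALSE)
    for (ph in names(per_phase)) {
      p <- per_phase[[ph]]
      utils::write.csv(p$records,
                       file.path(out_dir, sprintf("records_%s.csv", ph)),
                       row.names = FALSE)
      utils::write.csv(p$class_table,
                       file.path(out_dir, sprintf("rate_classes_%s.csv", ph)),
                       row.names = FALSE)
      utils::write.table(p$trigger_map$activity,
                         file.path(out_dir, sprintf("trigger_map_%s.csv", ph)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      write_heatmap_png(p$trigger_map$scaled,
                        file.path(out_dir, sprintf("trigger_map_%s.png", ph)))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_lines <- c(
      sprintf("beeshimmer %s", as.character(utils::packageVersion("beeshimmer"))),
      sprintf("R %s", R.version.string),
      sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
      "config:", utils::capture.output(utils::str(config)))
    writeLines(log_lines, file.path(out_dir, "provenance.log"))
    return(invisible(result))
  }
  result
}

# YAML round-trips data.frames as lists; rebuild nested spec objects.
scene_args_from_yaml <- function(sc) {
  fix_df <- function(x) if (is.data.frame(x)) x else as.data.frame(x)
  if (!is.null(sc$cohorts)) {
    sc$cohorts <- lapply(sc$cohorts, function(co) {
      if (inherits(co, "cohort_spec")) return(co)
      co$squares <- fix_df(co$squares)
      do.call(cohort_spec, co)
    })
  }
  if (!is.null(sc$waves)) {
    sc$waves <- lapply(sc$waves, function(w) {
      if (inherits(w, "wave_spec")) return(w)
      do.call(wave_spec, w)
    })
  }
  if (!is.null(sc$mouth_zone)) sc$mouth_zone$squares <- fix_df(sc$mouth_zone$squares)
  if (!is.null(sc$events)) sc$events <- fix_df(sc$events)
  sc
}

check_phases <- function(phases, n_series) {
  iv <- do.call(rbind, phases)
  if (any(iv[, 1] > iv[, 2]) || any(iv[, 1] < 0) ||
      any(iv[, 2] > n_series - 1)) {
    stop("phase intervals must lie within the 0-based difference series")
  }
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
    stop("phase intervals must not overlap")
  }
}

# Registry rows for a phase: by explicit phase label when present,
# otherwise by the wave start_frame falling inside the interval.
slice_registry <- function(registry, phase_label, interval) {
  if (!is.null(registry$phase) && phase_label %in% registry$phase) {
    registry[registry$phase == phase_label, , drop = FALSE]
  } else if (!is.null(registry$start_frame)) {
    registry[registry$start_frame >= interval[1] &
               registry$start_frame <= interval[2], , drop = FALSE]
  } else {
    registry
  }
}

summarize_phase <- function(p) {
  list(
    interval = p$interval,
    t_ref_s = p$t_ref,
    n_ts_squares = nrow(p$partition$ts),
    n_nts_squares = nrow(p$partition$nts),
    n_trigger_entries = p$trigger_map$n_entries,
    relF = p$relF,
    fits = lapply(p$fits, function(f) if (is.null(f)) NULL else
      f[c("a", "b", "r_squared")]),
    spearman = p$spearman,
    comparison = if (is.null(p$comparison)) NULL else list(
      n_positive = p$comparison$n_positive,
      n_negative = p$comparison$n_negative,
      chi_square = p$comparison$chi_square,
      p_value = p$comparison$p_value)
  )
}
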