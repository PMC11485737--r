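#' Full pipeline configuration
#'
#' Gathers every knob of the real-time loop. Cadences follow the
#' multi-timescale design: traces every frame, indicator records at 2 Hz,
#' functional-network updates at 1 Hz, synchrony every 30 s, receptive-field
#' updates on trial completion.
#'
#' @param stream a [stream_config()] or a plain list of its fields.
#' @param centers_path cell-centres CSV.
#' @param out_dir output directory for the event log and exports.
#' @param roi list: `r_inner`, `r_outer` (px), `pixel_size_um`.
#' @param alpha neuropil coefficient.
#' @param baseline_window_s baseline window (s).
#' @param registration list: `enabled`, `upsample`, `max_shift`,
#'   `n_template_frames`.
#' @param network list: `method` (`"mst"` or `"threshold"`), `theta`,
#'   `min_samples`, `cadence_s`, `window` (`"cumulative"` or `"sliding"`),
#'   `sliding_s`.
#' @param indicators list: `cadence_hz`, `n_cells` displayed.
#' @param synchrony list: `enabled`, `cadence_s`, `n_surrogates`, `alpha`,
#'   `decay_s`, `threshold`, `seed`.
#' @param tuning list: `enabled`, `schedule_path`.
#' @param trigger list: `mode` (`"manual"`, `"top5"` or `"watch_group"`),
#'   `cells`, `dff_threshold`, `refractory_s`.
#' @param seed base seed for all randomized stages.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(stream, centers_path, out_dir = tempfile("calrun"),
                            roi = list(), alpha = 0.7, baseline_window_s = 10,
                            registration = list(), network = list(),
                            indicators = list(), synchrony = list(),
                            tuning = list(), trigger = list(), seed = 1) {
  defaults <- function(given, def) utils::modifyList(def, given)
  structure(list(
    stream = stream, centers_path = centers_path, out_dir = out_dir,
    roi = defaults(roi, list(r_inner = 2, r_outer = 6,
                             pixel_size_um = 370 / 512)),
    alpha = alpha, baseline_window_s = baseline_window_s,
    registration = defaults(registration,
      list(enabled = TRUE, upsample = 10, max_shift = 20,
           n_template_frames = 30)),
    network = defaults(network,
      list(method = "mst", theta = 0.5, min_samples = 30, cadence_s = 1,
           window = "cumulative", sliding_s = 30)),
    indicators = defaults(indicators, list(cadence_hz = 2, n_cells = 5)),
    synchrony = defaults(synchrony,
      list(enabled = TRUE, cadence_s = 30, n_surrogates = 200, alpha = 0.05,
           decay_s = 1.5, threshold = 3, seed = 7)),
    tuning = defaults(tuning, list(enabled = FALSE, schedule_path = NULL)),
    trigger = defaults(trigger,
      list(mode = "manual", cells = NULL, dff_threshold = 0.5,
           refractory_s = 3)),
    seed = seed), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Automatic selection of display / stimulation candidates
#'
#' The five neurons with the highest overall correlation to the rest of the
#' population, as measured by degree in the functional network. Sessions
#' with fewer than five cells return them all.
#'
#' @param ranking a [rank_by_degree()] result.
#' @return up to 5 cell ids.
#' @export
select_auto_cells <- function(ranking) utils::head(ranking$cell_id, 5L)

#' Evaluate the stimulation trigger rule
#'
#' In `"watch_group"` mode the rule fires when the mean current dF/F0 of the
#' watched cells exceeds the configured threshold, subject to a refractory
#' period; `"manual"` never fires from within the loop.
#'
#' @param state list with `mode`, `cells`, `dff_threshold`, `refractory_s`,
#'   `last_fire_s`.
#' @param dff_now named numeric vector of the current frame's dF/F0 (names =
#'   cell ids).
#' @param time_s current stream time.
#' @return list `fire` (logical) and the updated `state`.
#' @export
trigger_rule <- function(state, dff_now, time_s) {
  state$last_fire_s <- state$last_fire_s %||% -Inf
  if (!identical(state$mode, "watch_group") || is.null(state$cells))
    return(list(fire = FALSE, state = state))
  vals <- dff_now[as.character(state$cells)]
  fire <- is.finite(mean(vals)) && mean(vals) > state$dff_threshold &&
    (time_s - state$last_fire_s) >= state$refractory_s
  if (fire) state$last_fire_s <- time_s
  list(fire = fire, state = state)
}

#' Run the full real-time analysis loop
#'
#' Headless orchestration of the whole engine: per frame, registration
#' against the initial-batch template, ROI fluorescence extraction,
#' neuropil correction, sliding baseline and dF/F0; at 1 s cadence the
#' functional network and degree ranking; every 30 s the synchrony test; on
#' every completed tone trial the receptive-field update; the trigger rule
#' every frame. Every completed computation is appended to a JSONL event
#' log keyed by stream time, so replaying a movie and reading it live give
#' payload-identical logs. A failed downstream stage is logged as a warning
#' record and never stops trace extraction.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list: `event_log` path, `store` (trace store),
#'   `roiset`, `rankings` (list over network updates), `rfs` (per-cell
#'   receptive fields, if tuning), `n_frames`, export paths.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!inherits(cfg$stream, "stream_config"))
    cfg$stream <- do.call(stream_config, cfg$stream)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fr <- cfg$stream$frame_rate
  shape <- c(cfg$stream$height, cfg$stream$width)

  roiset <- build_roi_set(cfg$centers_path, shape,
                          geometry = list(r_inner = cfg$roi$r_inner,
                                          r_outer = cfg$roi$r_outer),
                          pixel_size_um = cfg$roi$pixel_size_um)
  cell_ids <- vapply(roiset$cells, `[[`, numeric(1), "cell_id")
  store <- trace_store(cell_ids, alpha = cfg$alpha,
                       window_s = cfg$baseline_window_s, frame_rate = fr)
  log <- event_log_open(file.path(cfg$out_dir, "events.jsonl"))

  schedule <- NULL; trials <- NULL; rfs <- NULL
  if (isTRUE(cfg$tuning$enabled) && !is.null(cfg$tuning$schedule_path)) {
    schedule <- load_schedule(cfg$tuning$schedule_path)
    trials <- assign_trials(schedule, fr, n_frames = .Machine$integer.max)
    grid_f <- attr(schedule, "freqs"); grid_l <- attr(schedule, "levels")
    rfs <- lapply(cell_ids, function(id) receptive_field(grid_f, grid_l))
    names(rfs) <- cell_ids
  }

  st <- open_stream(cfg$stream)
  on.exit({ st$close(); event_log_close(log) }, add = TRUE)

  # template from the initial batch (the cell-identification average image)
  n_tmpl <- cfg$registration$n_template_frames
  buf <- list()
  while (length(buf) < n_tmpl && !is.null(f <- st$next_frame()))
    buf[[length(buf) + 1L]] <- f
  if (length(buf) == 0) stop("stream yielded no frames")
  template <- build_template(buf)

  net_every <- max(1L, round(cfg$network$cadence_s * fr))
  syn_every <- max(1L, round(cfg$synchrony$cadence_s * fr))
  ind_every <- max(1L, round(fr / cfg$indicators$cadence_hz))
  rankings <- list()
  last_graph <- NULL
  trig_state <- list(mode = cfg$trigger$mode, cells = cfg$trigger$cells,
                     dff_threshold = cfg$trigger$dff_threshold,
                     refractory_s = cfg$trigger$refractory_s)
  syn_i <- 0L
  bufpos <- 0L

  next_frame <- function() {
    if (bufpos < length(buf)) {
      bufpos <<- bufpos + 1L
      return(buf[[bufpos]])
    }
    st$next_frame()
  }

  while (!is.null(f <- next_frame())) {
    t_now <- f$time_s
    if (isTRUE(cfg$registration$enabled)) {
      sh <- estimate_shift(f, template, cfg$registration$upsample,
                           cfg$registration$max_shift)
      f <- apply_shift(f, sh)
      log_event(log, t_now, "shift",
                list(dy = sh$dy, dx = sh$dx,
                     error = sh$registration_error,
                     degenerate = sh$degenerate, clamped = sh$clamped))
    }
    ext <- extract_fluorescence(f, roiset)
    dff_now <- ts_append(store, ext$F_soma, ext$F_NP)
    names(dff_now) <- cell_ids
    nfr <- store$n_frames
    log_event(log, t_now, "traces", list(frame = f$index, dff = dff_now))

    if (nfr %% ind_every == 0L) {
      show <- if (length(rankings))
        utils::head(rankings[[length(rankings)]]$cell_id,
                    cfg$indicators$n_cells)
      else utils::head(cell_ids, cfg$indicators$n_cells)
      log_event(log, t_now, "indicators",
                list(cells = show, dff = unname(dff_now[as.character(show)])))
    }

    if (nfr %% net_every == 0L) {
      res <- tryCatch({
        win <- if (identical(cfg$network$window, "sliding"))
          max(1L, nfr - round(cfg$network$sliding_s * fr) + 1L):nfr
        else seq_len(nfr)
        corr <- pairwise_correlations(ts_series(store, "dff", win),
                                      cfg$network$min_samples)
        if (is.null(corr)) {
          log_event(log, t_now, "warning",
                    list(stage = "network", msg = "window shorter than min_samples"))
        } else {
          g <- if (identical(cfg$network$method, "threshold"))
            threshold_network(corr, cfg$network$theta)
          else mst_network(corr)
          rk <- rank_by_degree(g)
          last_graph <- g
          rankings[[length(rankings) + 1L]] <- rk
          log_event(log, t_now, "network",
                    list(method = g$method, n_nodes = length(g$cell_ids),
                         n_edges = nrow(g$edges)))
          stab <- if (length(rankings) >= 2)
            list(set = ranking_stability(lapply(rankings, `[[`, "cell_id")),
                 positional = ranking_stability(
                   lapply(rankings, `[[`, "cell_id"), method = "positional"))
          else NULL
          log_event(log, t_now, "ranking",
                    list(method = g$method, ranking = rk$cell_id,
                         degrees = rk$degree,
                         top5 = select_auto_cells(rk),
                         stability_pct = stab))
        }
      }, error = function(e)
        log_event(log, t_now, "warning",
                  list(stage = "network", msg = conditionMessage(e))))
    }

    if (isTRUE(cfg$synchrony$enabled) && nfr %% syn_every == 0L &&
        nfr >= syn_every) {
      syn_i <- syn_i + 1L
      tryCatch({
        sp <- spike_matrix(ts_series(store, "dff"), frame_rate = fr,
                           decay_s = cfg$synchrony$decay_s,
                           threshold = cfg$synchrony$threshold)
        rep <- synchrony_test(sp, 2:4, cfg$synchrony$n_surrogates,
                              cfg$synchrony$alpha,
                              seed = cfg$synchrony$seed + syn_i)
        log_event(log, t_now, "synchrony",
                  list(k = rep$k, observed = rep$observed,
                       surr_mean = rep$surr_mean, verdict = rep$verdict))
      }, error = function(e)
        log_event(log, t_now, "warning",
                  list(stage = "synchrony", msg = conditionMessage(e))))
    }

    if (!is.null(trials)) {
      done <- which(vapply(trials, function(tr)
        length(tr$frames) > 0 && max(tr$frames) == f$index, logical(1)))
      for (e in done) {
        tr <- trials[[e]]
        frames1 <- tr$frames + 1L
        n_upd <- 0L
        for (ci in seq_along(cell_ids)) {
          dffw <- store$dff[ci, frames1]
          rfs[[ci]] <- update_receptive_field(rfs[[ci]], dffw,
                                              tr$frequency_hz, tr$level_db)
          if (!isTRUE(attr(rfs[[ci]], "skipped"))) n_upd <- n_upd + 1L
        }
        log_event(log, t_now, "rf_update",
                  list(event = e, frequency_hz = tr$frequency_hz,
                       level_db = tr$level_db, n_cells = n_upd))
      }
    }

    tg <- trigger_rule(trig_state, dff_now, t_now)
    trig_state <- tg$state
    if (tg$fire) {
      watch <- trig_state$cells
      targets <- lapply(watch, function(id) {
        cc <- roiset$cells[[as.character(id)]]
        target_spec(id, c(cc$x, cc$y), shape = "disk")
      })
      stimulate(log, t_now, targets)
    }
  }

  # exports
  paths <- list(traces = file.path(cfg$out_dir, "traces.csv"))
  ts_write_csv(store, paths$traces)
  if (!is.null(last_graph)) {
    paths$edges <- file.path(cfg$out_dir, "edges.csv")
    utils::write.csv(last_graph$edges, paths$edges, row.names = FALSE)
    rk <- rank_by_degree(last_graph)
    paths$ranking <- file.path(cfg$out_dir, "ranking.json")
    jsonlite::write_json(list(method = last_graph$method,
                              ranking = rk$cell_id, degrees = rk$degree,
                              top5 = select_auto_cells(rk)),
                         paths$ranking, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(rfs)) {
    paths$rf = file.path(cfg$out_dir, "receptive_fields.json")
    jsonlite::write_json(lapply(seq_along(rfs), function(i)
      list(cell_id = cell_ids[i],
           best_frequency_hz = best_frequency(rfs[[i]]),
           n_trials_total = sum(rfs[[i]]$n_trials))),
      paths$rf, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(event_log = log$path, store = store, roiset = roiset,
                 rankings = rankings, rfs = rfs, graph = last_graph,
                 n_frames = store$n_frames, paths = paths))
}
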