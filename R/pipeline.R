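#' Pipeline configuration
#'
#' One object drives the whole analysis; every under-specified methods
#' choice (filter phase, zone widths, quantile convention, anchoring-index
#' variant, momentum normalisation) is surfaced here and echoed into the
#' run metadata.
#'
#' @param alpha Primary Kruskal-Wallis threshold (default 0.05).
#' @param strict_alpha Stricter evidence flag threshold (0.01).
#' @param zones A [zone_spec()].
#' @param applicability Applicability table ([default_applicability()]).
#' @param filter_cutoff,filter_order Butterworth low-pass design (6 Hz, 4).
#' @param quantile_type Quantile convention for descriptive stats (7).
#' @param wbam_normalization `"mass_height_speed"` or `"none"`.
#' @param tandem_tolerance Tandem line tolerance (m, 0.05).
#' @param min_period Event-detector same-side separation (s, 0.6).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, strict_alpha = 0.01,
                            zones = zone_spec(),
                            applicability = default_applicability(),
                            filter_cutoff = 6, filter_order = 4,
                            quantile_type = 7,
                            wbam_normalization = "mass_height_speed",
                            tandem_tolerance = 0.05, min_period = 0.6) {
  stopifnot(alpha > 0, alpha < 1, strict_alpha > 0, strict_alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Names of the computed gait parameters
#' @return Character vector of the parameter battery.
#' @export
parameter_names <- function() {
  c("ML_CoM_rom", "MoS_ML", "MoS_AP", "WBAM_sag", "WBAM_cor", "WBAM_tra",
    "CoM_score", "Foot_score", "Step_width", "ML_step", "Step_number",
    "Walking_speed", "Double_support", "Task_time",
    "HeadAI_pitch", "HeadAI_roll", "HeadAI_yaw", "Head_AV", "Trunk_AV",
    "GaitSD")
}

# tasks where marker quality restricts the battery to a single parameter
single_parameter_tasks <- function() {
  c(tandem = "Step_number", backwards = "Task_time", steps = "Task_time")
}

#' Compute the parameter battery for one trial
#'
#' Runs preprocessing (gap fill as needed, 6 Hz zero-phase low-pass,
#' virtual joint centres), event detection (or uses supplied events), and
#' computes the dynamic-stability, spatial, temporal and kinematic
#' parameters. Tandem, backwards and stair trials yield their single
#' parameter; every other parameter is `NA` for those tasks. Failures of
#' individual parameters are caught and recorded as `NA`.
#'
#' @param trial A [trial_record()].
#' @param side Analysis side, `"left"` or `"right"`.
#' @param config A [pipeline_config()].
#' @param events Optional externally supplied/corrected event table;
#'   detected automatically when `NULL`.
#' @return Named list: `values` (named numeric vector over
#'   [parameter_names()]), `n_cycles`, `events`.
#' @export
compute_trial_parameters <- function(trial, side = "left",
                                     config = pipeline_config(),
                                     events = NULL) {
  vals <- stats::setNames(rep(NA_real_, length(parameter_names())),
                          parameter_names())
  single <- single_parameter_tasks()
  try_num <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  trial <- fill_gaps(trial)
  trial <- lowpass(trial, cutoff = config$filter_cutoff,
                   order = config$filter_order)
  trial <- add_virtual_markers(trial)
  if (is.null(events)) {
    # tandem strides are slow; widen the same-side separation accordingly
    mp <- if (trial$task == "tandem") max(config$min_period, 1.2)
          else config$min_period
    events <- suppressWarnings(detect_gait_events(trial, min_period = mp))
  }
  n_cycles <- max(0L, length(strike_times(events, side)) - 1L)

  if (trial$task %in% names(single)) {
    pm <- single[[trial$task]]
    vals[pm] <- switch(pm,
      Step_number = try_num(tandem_step_count(
        trial, events, line_tolerance = config$tandem_tolerance)),
      Task_time = try_num(task_time(trial, events)))
    return(list(values = vals, n_cycles = n_cycles, events = events))
  }

  pelvis <- marker(trial, "MIDPSIS")
  turny <- trial$task == "turn_pivot"
  dir <- if (turny) walking_direction_series(pelvis, trial$rate)
         else suppressWarnings(estimate_walking_direction(pelvis))
  # turn-pivot trials get one midline per straight leg
  leg_mask <- if (turny) dir[, 1] >= 0 else NULL
  leg_dev <- function(pos) {
    if (!turny) return(midline_deviation(pos))
    dev <- numeric(nrow(pos))
    for (s in c(TRUE, FALSE)) {
      idx <- which(leg_mask == s)
      if (length(idx) >= 20)
        dev[idx] <- as.numeric(midline_deviation(pos[idx, , drop = FALSE]))
    }
    dev
  }
  com <- try(compute_com(trial), silent = TRUE)
  if (!inherits(com, "try-error")) {
    xp <- xcom_params(com$mean_height)
    vals["ML_CoM_rom"] <- try_num(
      if (turny) {
        dev <- leg_dev(com$position)
        max(vapply(c(TRUE, FALSE), function(s) {
          idx <- which(leg_mask == s)
          if (length(idx) < 20) NA_real_ else diff(range(dev[idx]))
        }, numeric(1)), na.rm = TRUE)
      } else ml_com_rom(com, dir))
    vals["MoS_ML"] <- try_num(margin_of_stability(
      trial, events, com, xp, side, "ML", dir)$median)
    vals["MoS_AP"] <- try_num(margin_of_stability(
      trial, events, com, xp, side, "AP", dir)$median)
    pl <- tryCatch({
      w <- compute_wbam(trial, com = com,
                        normalize = config$wbam_normalization)
      wbam_planes(w, dir)
    }, error = function(e) NULL)
    if (!is.null(pl)) {
      vals["WBAM_sag"] <- wbam_range(pl, "sagittal")
      vals["WBAM_cor"] <- wbam_range(pl, "coronal")
      vals["WBAM_tra"] <- wbam_range(pl, "transverse")
    }
    vals["CoM_score"] <- try_num(com_zone_score(
      com, config$zones, ml_dev = leg_dev(com$position)))
    vals["Walking_speed"] <- try_num(walking_speed(com, events))
  }
  vals["Foot_score"] <- try_num(
    if (turny) foot_zone_score(trial, config$zones,
                               ml_dev_l = leg_dev(marker(trial, "LHEE")),
                               ml_dev_r = leg_dev(marker(trial, "RHEE")))
    else foot_zone_score(trial, config$zones))
  steps <- try(step_series(trial, events), silent = TRUE)
  if (!inherits(steps, "try-error") && !is.null(steps)) {
    sd_dir <- if (turny) {
      idx <- pmin(pmax(round(steps$time * trial$rate) + 1L, 1L), nrow(dir))
      dir[idx, , drop = FALSE]
    } else dir
    vals["Step_width"] <- try_num(step_width(steps, sd_dir))
    vals["ML_step"] <- try_num(ml_step_distance(steps, sd_dir, side))
  }
  vals["Double_support"] <- try_num(double_support_time(events, side)$median)
  vals["Task_time"] <- try_num(task_time(trial, events))

  ang <- try(segment_orientations(trial, dir), silent = TRUE)
  if (!inherits(ang, "try-error")) {
    vals["HeadAI_pitch"] <- try_num(head_anchoring_index(ang, "pitch"))
    vals["HeadAI_roll"] <- try_num(head_anchoring_index(ang, "roll"))
    vals["HeadAI_yaw"] <- try_num(head_anchoring_index(ang, "yaw"))
    st <- strike_times(events, side)
    cyc_dur <- if (length(st) >= 2) stats::median(diff(st)) else NA_real_
    vals["Head_AV"] <- try_num(angular_velocity_rms(ang, "head", cyc_dur))
    vals["Trunk_AV"] <- try_num(angular_velocity_rms(ang, "trunk", cyc_dur))
  }
  vals["GaitSD"] <- try_num(gait_sd(
    joint_angle_cycles(trial, events, side, dir)))
  list(values = vals, n_cycles = n_cycles, events = events)
}

#' Run the full analysis pipeline
#'
#' Generates or ingests a cohort of trials, computes the parameter battery
#' per trial, aggregates to one value per subject x task x parameter
#' (median over repeated trials), and runs the validity framework:
#' discriminant grid (Kruskal-Wallis + Dunn-Holm), convergent correlations
#' with the DHI, and the relevance synthesis. Deterministic given the
#' inputs and seed.
#'
#' @param trials List of [trial_record()]s (e.g. from [generate_cohort()]).
#' @param cohort Subject metadata (`subject_id`, `group`, `affected_side`,
#'   `dhi`).
#' @param config A [pipeline_config()].
#' @param verbose Print per-trial progress (default FALSE).
#' @return List: `parameters` (long-form table), `grid`, `correlations`,
#'   `relevance`, `report` (short-form test), `log` (per-trial cycle
#'   counts), `config`.
#' @export
run_pipeline <- function(trials, cohort, config = pipeline_config(),
                         verbose = FALSE) {
  rows <- list(); log_rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    meta <- cohort[cohort$subject_id == tr$subject_id, , drop = FALSE]
    if (!nrow(meta)) stop("trial subject not in cohort: ", tr$subject_id)
    side <- analysis_side(meta[1, ])
    res <- compute_trial_parameters(tr, side, config)
    if (verbose)
      message(sprintf("[%d/%d] %s %s: %d cycles", i, length(trials),
                      tr$subject_id, tr$task, res$n_cycles))
    rows[[i]] <- data.frame(subject = tr$subject_id,
                            group = meta$group[1], task = tr$task,
                            parameter = names(res$values),
                            value = unname(res$values),
                            stringsAsFactors = FALSE)
    log_rows[[i]] <- data.frame(subject = tr$subject_id, task = tr$task,
                                n_cycles = res$n_cycles,
                                stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  # median over repeated trials of the same subject x task x parameter
  agg <- stats::aggregate(value ~ subject + group + task + parameter,
                          data = long, FUN = stats::median,
                          na.action = stats::na.pass)
  # drop rows for parameters never computed for a task (NR cells keep one
  # NA row so the grid can mark them)
  grid <- build_discriminant_grid(agg, alpha = config$alpha,
                                  strict_alpha = config$strict_alpha)
  corr <- convergent_correlations(agg, cohort)
  relevance <- synthesize_relevance(grid, corr, config$applicability)
  report <- shortform_fga_report(relevance, agg, grid)
  list(parameters = agg, grid = grid, correlations = corr,
       relevance = relevance, report = report,
       log = do.call(rbind, log_rows), config = config)
}

#' Short-form FGA report
#'
#' Retains, per task, the parameters whose relevance tier is `relevant`,
#' with the direction of the patient effect derived from the group medians
#' (BV versus controls) and the strict-threshold flag of the underlying
#' comparison.
#'
#' @param relevance A relevance matrix ([synthesize_relevance()]).
#' @param parameters Long-form parameter table.
#' @param grid Discriminant grid (for the strict flag); optional.
#' @return Data frame: task, parameter, direction, strict. Empty (with a
#'   note attribute) when nothing is relevant.
#' @export
shortform_fga_report <- function(relevance, parameters, grid = NULL) {
  rel <- relevance[relevance$tier == "relevant", , drop = FALSE]
  if (!nrow(rel)) {
    out <- data.frame(task = character(), parameter = character(),
                      direction = character(), strict = logical())
    attr(out, "note") <- "no relevant task/parameter cells"
    return(out)
  }
  rows <- lapply(seq_len(nrow(rel)), function(i) {
    tk <- rel$task[i]; pm <- rel$parameter[i]
    sub <- parameters[parameters$task == tk & parameters$parameter == pm, ]
    med <- tapply(sub$value, sub$group, stats::median, na.rm = TRUE)
    dirn <- if (!all(c("BV", "HS") %in% names(med)) ||
                any(is.na(med[c("BV", "HS")]))) "unclear"
    else if (med[["BV"]] < med[["HS"]]) "lower for patients"
    else "higher for patients"
    strict <- if (is.null(grid)) NA else
      isTRUE(grid$strict[grid$task == tk & grid$parameter == pm])
    data.frame(task = tk, parameter = pm, direction = dirn,
               strict = strict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write pipeline outputs to CSV (and a relevance heatmap)
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @param heatmap Also render `relevance.png` (default TRUE).
#' @return Invisibly, the vector of written paths.
#' @export
write_outputs <- function(result, dir, heatmap = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in c("parameters", "grid", "correlations", "relevance", "report",
               "log")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(result[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- c(sprintf("alpha: %g", result$config$alpha),
            sprintf("strict_alpha: %g", result$config$strict_alpha),
            sprintf("filter: butterworth order %d, %g Hz, zero-phase",
                    result$config$filter_order, result$config$filter_cutoff),
            sprintf("zone_boundaries_m: %s",
                    paste(result$config$zones$boundaries, collapse = " ")),
            sprintf("zone_weights: %s",
                    paste(result$config$zones$weights, collapse = " ")),
            sprintf("quantile_type: %d", result$config$quantile_type),
            sprintf("wbam_normalization: %s (reference CoM: 9-segment model)",
                    result$config$wbam_normalization),
            "wbam_planes: sagittal/coronal/transverse ('frontal' = coronal)",
            "anchoring_index: SD of orientation angles (not velocities)",
            "angular_velocity_normalization: per percent of gait cycle")
  mp <- file.path(dir, "run_metadata.txt")
  writeLines(meta, mp)
  paths <- c(paths, mp)
  if (heatmap) {
    hp <- file.path(dir, "relevance.png")
    grDevices::png(hp, width = 1200, height = 800)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_relevance(result$relevance)
    paths <- c(paths, hp)
  }
  invisible(paths)
}

#' Heatmap of the relevance matrix
#'
#' Matrix view (tasks x parameters) of the relevance tiers - the
#' machine-readable counterpart of a circular synthesis plot.
#'
#' @param relevance A relevance matrix.
#' @return Invisibly, the tier matrix.
#' @export
plot_relevance <- function(relevance) {
  tasks <- unique(relevance$task)
  params <- unique(relevance$parameter)
  tiers <- c("not-relevant" = 1, "interesting" = 2, "relevant" = 3)
  m <- matrix(NA_real_, length(tasks), length(params),
              dimnames = list(tasks, params))
  for (i in seq_len(nrow(relevance)))
    m[relevance$task[i], relevance$parameter[i]] <-
      tiers[[relevance$tier[i]]]
  op <- graphics::par(mar = c(8, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_along(params), seq_along(tasks), t(m),
                  col = c("grey85", "palegreen", "forestgreen"),
                  zlim = c(1, 3), axes = FALSE, xlab = "", ylab = "",
                  main = "Relevance synthesis")
  graphics::axis(1, seq_along(params), params, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_along(tasks), tasks, las = 1, cex.axis = 0.8)
  invisible(m)
}
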