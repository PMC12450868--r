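#' Load cohort metadata from a CSV file
#'
#' Expects one row per subject with columns `subject_id`, `group` (BV, UV or
#' HS), `affected_side` (left/right/both/none), `dhi` (0-100, blank or `UN`
#' when unknown), the ten FGA item scores `fga_gait_level`,
#' `fga_change_speed`, `fga_horizontal_head`, `fga_vertical_head`,
#' `fga_turn_pivot`, `fga_step_obstacle`, `fga_tandem`, `fga_eyes_closed`,
#' `fga_backwards`, `fga_steps` (each 0-3) and `fga_total` (0-30).
#'
#' A missing Dizziness Handicap Inventory score is coded `NA`, never zero:
#' such subjects are kept everywhere except the convergent-validity
#' correlations. `fga_total` is validated against the item sum.
#'
#' @param path CSV file path.
#' @return A `data.frame` of subject metadata (class `subject_meta`).
#' @export
load_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "affected_side", "dhi",
            fga_item_columns(), "fga_total")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("cohort file missing column(s): ", paste(absent, collapse = ", "))
  df$dhi <- suppressWarnings(as.integer(ifelse(df$dhi %in% c("UN", "NA", ""),
                                               NA, df$dhi)))
  validate_cohort(df)
}

fga_item_columns <- function() {
  c("fga_gait_level", "fga_change_speed", "fga_horizontal_head",
    "fga_vertical_head", "fga_turn_pivot", "fga_step_obstacle",
    "fga_tandem", "fga_eyes_closed", "fga_backwards", "fga_steps")
}

validate_cohort <- function(df) {
  if (!all(df$group %in% c("BV", "UV", "HS")))
    stop("group must be BV, UV or HS")
  if (!all(df$affected_side %in% c("left", "right", "both", "none")))
    stop("affected_side must be left, right, both or none")
  bad_uv <- df$group == "UV" & !df$affected_side %in% c("left", "right")
  if (any(bad_uv))
    stop("UV subjects must have affected_side left or right: ",
         paste(df$subject_id[bad_uv], collapse = ", "))
  items <- as.matrix(df[, fga_item_columns()])
  if (any(items < 0 | items > 3))
    stop("FGA item scores must lie in 0..3")
  sums <- rowSums(items)
  bad <- which(sums != df$fga_total)
  if (length(bad))
    stop("fga_total disagrees with item sum for subject(s): ",
         paste(df$subject_id[bad], collapse = ", "))
  if (any(!is.na(df$dhi) & (df$dhi < 0 | df$dhi > 100)))
    stop("dhi must lie in 0..100")
  class(df) <- c("subject_meta", "data.frame")
  df
}

#' Path to the packaged clinical cohort table
#'
#' The transcribed per-subject table for the 30-subject study cohort
#' (10 bilateral-vestibulopathy, 10 unilateral-vestibulopathy, 10 controls):
#' affected side, DHI score, and FGA item/total scores. One BV subject's DHI
#' is unknown.
#'
#' @return Path to the installed CSV.
#' @export
cohort_table_path <- function() {
  system.file("extdata", "study_cohort.csv", package = "vestgait",
              mustWork = TRUE)
}

#' Side used for side-dependent parameters
#'
#' Lateralised parameters (margin of stability, step width, whole-body
#' angular momentum) are evaluated on the left side for BV patients and
#' controls, and on the pathological side for UV patients.
#'
#' @param meta_row One row of a subject-metadata table (or a list with
#'   `group` and `affected_side`).
#' @return `"left"` or `"right"`.
#' @export
analysis_side <- function(meta_row) {
  if (meta_row$group == "UV") {
    side <- meta_row$affected_side
    if (!side %in% c("left", "right"))
      stop("UV subject without lateralised affected_side")
    side
  } else "left"
}
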