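#' Shapiro-Wilk normality screen per group
#'
#' A screening report only: downstream comparisons are always nonparametric,
#' reflecting the small per-group samples and the prevailing non-normality.
#'
#' @param groups Named list of numeric vectors (one per group).
#' @return Data frame with group, n, W and p (NA when n < 3 or degenerate).
#' @export
shapiro_screen <- function(groups) {
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]][!is.na(groups[[g]])]
    if (length(x) < 3 || length(unique(x)) == 1L)
      return(data.frame(group = g, n = length(x), W = NA_real_, p = NA_real_,
                        note = if (length(x) < 3) "n < 3" else "constant"))
    sw <- stats::shapiro.test(x)
    data.frame(group = g, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, note = "")
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank test across the three groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution
#' (degrees of freedom = number of groups minus one).
#'
#' @param groups Named list of numeric vectors.
#' @return List with `H`, `p`, `df`, and per-group n.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(x) x[!is.na(x)])
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 non-missing values")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, 1L)))
  if (length(unique(values)) == 1L)   # fully degenerate: no evidence
    return(list(H = 0, p = 1, df = length(groups) - 1L,
                n = vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(values, labels)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter),
       n = vapply(groups, length, 1L))
}

#' Dunn's post-hoc test with Holm correction
#'
#' Pairwise z statistics from the pooled ranks with tie correction,
#' two-sided p values, Holm step-down adjustment over the comparisons.
#' By contract this is called only after a significant Kruskal-Wallis test.
#'
#' @param groups Named list of numeric vectors.
#' @param kw_p Optional Kruskal-Wallis p value; supplying a value > alpha
#'   raises a contract-violation error.
#' @param alpha Significance gate for the contract check (default 0.05).
#' @return Data frame with comparison, z, p_raw, p_adj.
#' @export
dunn_holm <- function(groups, kw_p = NULL, alpha = 0.05) {
  if (!is.null(kw_p) && kw_p > alpha)
    stop("dunn_holm called although the Kruskal-Wallis p (", signif(kw_p, 3),
         ") exceeds alpha = ", alpha)
  groups <- lapply(groups, function(x) x[!is.na(x)])
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- p_raw <- numeric(ncol(pairs))
  comp <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
    comp[j] <- paste0(a, "-", b)
  }
  data.frame(comparison = comp, z = z, p_raw = p_raw,
             p_adj = stats::p.adjust(p_raw, method = "holm"),
             stringsAsFactors = FALSE)
}

#' Categorise a discriminant p value or a convergent correlation
#'
#' Discriminant validity: excellent p <= 0.001, good p <= 0.01, moderate
#' p <= 0.05, fair 0.05 < p < 0.1, poor p >= 0.1. Convergent validity on
#' |r|: excellent > 0.8, good (0.6, 0.8], moderate (0.4, 0.6], fair
#' (0.2, 0.4], poor <= 0.2.
#'
#' @param x A p value (`kind = "discriminant"`) or a Pearson r
#'   (`kind = "convergent"`).
#' @param kind `"discriminant"` or `"convergent"`.
#' @return Ordered factor level as character: one of `"poor"`, `"fair"`,
#'   `"moderate"`, `"good"`, `"excellent"` (or `NA` for missing input).
#' @export
categorize <- function(x, kind = c("discriminant", "convergent")) {
  kind <- match.arg(kind)
  if (is.na(x)) return(NA_character_)
  if (kind == "discriminant") {
    if (x < 0 || x > 1) stop("p value out of [0, 1]")
    if (x <= 0.001) "excellent"
    else if (x <= 0.01) "good"
    else if (x <= 0.05) "moderate"
    else if (x < 0.1) "fair"
    else "poor"
  } else {
    if (abs(x) > 1) stop("correlation out of [-1, 1]")
    a <- abs(x)
    if (a > 0.8) "excellent"
    else if (a > 0.6) "good"
    else if (a > 0.4) "moderate"
    else if (a > 0.2) "fair"
    else "poor"
  }
}

category_rank <- function(cat) {
  match(cat, c("poor", "fair", "moderate", "good", "excellent"))
}

#' Default clinical-applicability ratings per parameter
#'
#' Encodes the study team's (subjective) clinic-floor ratings: parameters a
#' clinician can assess by eye or simple video are excellent; those needing
#' cameras/IMUs are moderate; model-based quantities needing full motion
#' capture are poor. Editable: pass your own two-column data frame wherever
#' an applicability table is accepted.
#'
#' @return Data frame with columns `parameter`, `applicability`.
#' @export
default_applicability <- function() {
  data.frame(
    parameter = c("ML_CoM_rom", "Foot_score", "Step_width", "ML_step",
                  "Walking_speed", "Step_number", "Task_time",
                  "CoM_score", "Double_support",
                  "MoS_ML", "MoS_AP", "WBAM_sag", "WBAM_cor", "WBAM_tra",
                  "HeadAI_pitch", "HeadAI_roll", "HeadAI_yaw",
                  "Head_AV", "Trunk_AV", "GaitSD"),
    applicability = c(rep("excellent", 7), rep("moderate", 2), rep("poor", 11)),
    stringsAsFactors = FALSE)
}

#' Build the discriminant-validity grid
#'
#' One cell per task-by-parameter combination: Kruskal-Wallis p across the
#' three groups, a strict flag at the 0.01 threshold, and - when the test is
#' significant at `alpha` - Dunn-Holm pairwise p values. Cells whose
#' parameter is not computed for a task are marked not-relevant (`NR`).
#'
#' @param table Long-form parameter table with columns `subject`, `group`,
#'   `task`, `parameter`, `value` (one row per subject x task x parameter).
#' @param alpha Primary significance threshold (default 0.05).
#' @param strict_alpha Stricter evidence threshold flagged per cell (0.01).
#' @return Data frame with one row per cell: task, parameter, n per group,
#'   kw_H, kw_p, strict flag, Dunn adjusted p per pair (NA when not run),
#'   and a status (`ok`, `NR`, or `insufficient`).
#' @export
build_discriminant_grid <- function(table, alpha = 0.05, strict_alpha = 0.01) {
  cells <- unique(table[, c("task", "parameter")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tk <- cells$task[i]; pm <- cells$parameter[i]
    sub <- table[table$task == tk & table$parameter == pm, ]
    out <- data.frame(task = tk, parameter = pm,
                      n_BV = NA_integer_, n_UV = NA_integer_, n_HS = NA_integer_,
                      kw_H = NA_real_, kw_p = NA_real_, strict = NA,
                      dunn_BV_HS = NA_real_, dunn_UV_HS = NA_real_,
                      dunn_BV_UV = NA_real_, status = "NR",
                      stringsAsFactors = FALSE)
    if (!nrow(sub) || all(is.na(sub$value))) return(out)
    gr <- split(sub$value, sub$group)
    for (g in c("BV", "UV", "HS"))
      out[[paste0("n_", g)]] <- sum(!is.na(gr[[g]]))
    if (any(vapply(c("BV", "UV", "HS"),
                   function(g) sum(!is.na(gr[[g]])) < 2, TRUE))) {
      out$status <- "insufficient"
      return(out)
    }
    kw <- kruskal_wallis(gr[c("BV", "UV", "HS")])
    out$kw_H <- kw$H; out$kw_p <- kw$p
    out$strict <- kw$p <= strict_alpha
    out$status <- "ok"
    if (!is.na(kw$p) && kw$p <= alpha) {
      dn <- dunn_holm(gr[c("BV", "UV", "HS")], kw_p = kw$p, alpha = alpha)
      out$dunn_BV_HS <- dn$p_adj[dn$comparison == "BV-HS"]
      out$dunn_UV_HS <- dn$p_adj[dn$comparison == "UV-HS"]
      out$dunn_BV_UV <- dn$p_adj[dn$comparison == "BV-UV"]
    }
    out
  })
  do.call(rbind, rows)
}

#' Convergent-validity correlations with the DHI score
#'
#' Pearson correlation between each task-by-parameter cell and the DHI,
#' computed separately within the BV and UV groups. Subjects with missing
#' DHI are excluded pairwise; a correlation is reported only when at least
#' three complete pairs remain and both variables vary.
#'
#' @param table Long-form parameter table (see [build_discriminant_grid()]).
#' @param cohort Subject metadata with `subject_id`, `group`, `dhi`.
#' @return Data frame: task, parameter, group, r, n.
#' @export
convergent_correlations <- function(table, cohort) {
  cells <- unique(table[, c("task", "parameter")])
  rows <- list()
  for (g in c("BV", "UV")) {
    meta <- cohort[cohort$group == g, c("subject_id", "dhi")]
    for (i in seq_len(nrow(cells))) {
      tk <- cells$task[i]; pm <- cells$parameter[i]
      sub <- table[table$task == tk & table$parameter == pm &
                     table$group == g, c("subject", "value")]
      m <- merge(sub, meta, by.x = "subject", by.y = "subject_id")
      ok <- !is.na(m$value) & !is.na(m$dhi)
      n <- sum(ok)
      r <- if (n >= 3 && stats::sd(m$value[ok]) > 0 && stats::sd(m$dhi[ok]) > 0)
        stats::cor(m$value[ok], m$dhi[ok]) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(task = tk, parameter = pm, group = g, r = r, n = n,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Synthesise the relevance matrix
#'
#' A task-by-parameter cell is `relevant` when its discriminant validity is
#' at least moderate, its convergent validity (best over the two patient
#' groups) is at least moderate, and its clinical applicability is
#' excellent; `interesting` when both validities are at least moderate but
#' applicability falls short; otherwise `not-relevant`.
#'
#' @param grid Output of [build_discriminant_grid()].
#' @param correlations Output of [convergent_correlations()].
#' @param applicability Two-column data frame (`parameter`,
#'   `applicability`); defaults to [default_applicability()].
#' @return Data frame: task, parameter, discriminant (category),
#'   convergent (category), applicability, tier.
#' @export
synthesize_relevance <- function(grid, correlations,
                                 applicability = default_applicability()) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tk <- grid$task[i]; pm <- grid$parameter[i]
    app <- applicability$applicability[applicability$parameter == pm]
    if (!length(app))
      stop("no applicability rating configured for parameter ", pm)
    disc <- if (grid$status[i] == "ok") categorize(grid$kw_p[i], "discriminant")
            else NA_character_
    rs <- correlations$r[correlations$task == tk &
                           correlations$parameter == pm]
    rs <- rs[!is.na(rs)]
    conv <- if (length(rs)) categorize(rs[which.max(abs(rs))], "convergent")
            else NA_character_
    both_moderate <- !is.na(disc) && !is.na(conv) &&
      category_rank(disc) >= 3 && category_rank(conv) >= 3
    tier <- if (both_moderate && app == "excellent") "relevant"
            else if (both_moderate) "interesting"
            else "not-relevant"
    data.frame(task = tk, parameter = pm,
               discriminant = disc %||% NA_character_,
               convergent = conv %||% NA_character_,
               applicability = app, tier = tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("relevance_matrix", "data.frame")
  out
}

#' Median and quartiles under a configurable quantile convention
#'
#' Default convention: linear interpolation between order statistics at
#' position (n - 1) q (R's type 7), which reproduces the study cohort's
#' printed medians and first quartiles.
#'
#' @param values Numeric vector; missing values dropped.
#' @param type Quantile type passed to [stats::quantile()] (default 7).
#' @return Named vector `c(median, q1, q3)`; all NA when empty.
#' @export
median_iqr <- function(values, type = 7) {
  x <- values[!is.na(values)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Monte-Carlo power of the Kruskal-Wallis test for three normal groups
#'
#' Draws `n_sim` cohorts of three independent normal groups with the given
#' means, standard deviations and per-group sizes, applies the tie-corrected
#' Kruskal-Wallis test to each, and returns the proportion of cohorts with
#' p at or below `alpha`.
#'
#' @param means,sds,ns Numeric vectors of length 3.
#' @param alpha Significance level (default 0.05).
#' @param n_sim Number of simulated cohorts (>= 1000).
#' @param seed Integer seed for reproducibility.
#' @return List with `power`, `n_sim`, `se` (binomial standard error).
#' @export
simulate_kw_power <- function(means, sds, ns, alpha = 0.05,
                              n_sim = 20000, seed = 1) {
  stopifnot(length(means) == 3, length(sds) == 3, length(ns) == 3)
  if (any(sds <= 0)) stop("standard deviations must be positive")
  if (n_sim < 1000) stop("n_sim must be at least 1000")
  set.seed(seed)
  g <- factor(rep(seq_len(3), ns))
  hits <- 0L
  ntot <- sum(ns)
  mu <- rep(means, ns)
  sigma <- rep(sds, ns)
  for (i in seq_len(n_sim)) {
    x <- stats::rnorm(ntot, mu, sigma)
    if (stats::kruskal.test(x, g)$p.value <= alpha) hits <- hits + 1L
  }
  p <- hits / n_sim
  list(power = p, n_sim = n_sim, se = sqrt(p * (1 - p) / n_sim))
}
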