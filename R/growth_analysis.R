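mouse_table <- function(metadata) {
  unique(metadata[, c("mouse_id", "colonization", "diet")])
}

#' Per-diet GF-vs-FMT body-weight contrast
#'
#' For one diet, contrasts the growth of FMT mice against GF mice:
#' * `delta_bw_abs` (g): mean FMT (final-week BW minus week-0 BW) minus the
#'   same mean in GF mice;
#' * `delta_bw_slope` (g/week): pooled-OLS growth slope of all FMT points
#'   minus the pooled GF slope (all mice's raw `(week, BW)` points within a
#'   colonization group fitted together);
#' * the ANCOVA line comparison of the two point clouds (slope homogeneity
#'   and elevation tests);
#' * weight gain per day for each colonization group.
#'
#' Mice missing the first- or final-week observation are excluded from
#' `delta_bw_abs` with a warning; a group emptied that way is an error.
#'
#' @param growth Data frame `mouse_id`, `week`, `bw_g`.
#' @param metadata Sample metadata carrying `mouse_id`, `colonization`,
#'   `diet` (see [make_metadata()]).
#' @param diet A diet label present in `metadata`.
#' @param end_week Week used as the endpoint of the absolute gain; defaults
#'   to week 8 (fixed even when feeding continued longer).
#' @return A list of class `"diet_contrast"`: `diet`, `delta_bw_abs`,
#'   `delta_bw_slope`, `slope_FMT`, `slope_GF`, `slope_se_FMT`,
#'   `slope_se_GF`, `ancova` (an [ancova_compare()] result) and
#'   `gain_per_day` (named by colonization, g/day).
#' @export
compute_diet_contrast <- function(growth, metadata, diet, end_week = 8) {
  mice <- mouse_table(metadata)
  mice <- mice[mice$diet == diet, ]
  if (nrow(mice) == 0) stop("diet not present in metadata: ", diet)
  if (!all(c("GF", "FMT") %in% mice$colonization))
    stop("both colonization groups are required for diet ", diet)
  g <- merge(growth, mice, by = "mouse_id")
  start_week <- min(g$week)
  pooled <- lapply(split(g, g$colonization), function(gg) {
    if (length(unique(gg$mouse_id)) < 2 || length(unique(gg$week)) < 2)
      stop("need >= 2 mice with >= 2 timepoints per group in diet ", diet)
    ols_line(gg$week, gg$bw_g)
  })
  gains <- lapply(split(g, g$colonization), function(gg) {
    per_mouse <- vapply(split(gg, gg$mouse_id), function(m) {
      b0 <- m$bw_g[m$week == start_week]
      b8 <- m$bw_g[m$week == end_week]
      if (length(b0) != 1 || length(b8) != 1) return(NA_real_)
      b8 - b0
    }, numeric(1))
    if (anyNA(per_mouse)) {
      warning("excluding mice without week-", start_week, " or week-", end_week,
              " observation in diet ", diet, ": ",
              paste(names(per_mouse)[is.na(per_mouse)], collapse = ", "))
      per_mouse <- per_mouse[!is.na(per_mouse)]
    }
    if (length(per_mouse) == 0) stop("no usable mice left in a group for diet ", diet)
    mean(per_mouse)
  })
  gf <- g[g$colonization == "GF", ]
  fmt <- g[g$colonization == "FMT", ]
  anc <- ancova_compare(fmt$week, fmt$bw_g, gf$week, gf$bw_g)
  structure(list(
    diet = diet,
    delta_bw_abs = gains$FMT - gains$GF,
    delta_bw_slope = pooled$FMT$slope - pooled$GF$slope,
    slope_FMT = pooled$FMT$slope, slope_GF = pooled$GF$slope,
    slope_se_FMT = pooled$FMT$slope_se, slope_se_GF = pooled$GF$slope_se,
    ancova = anc,
    gain_per_day = gain_per_day(growth, metadata, diets = diet)$gain_per_day_g
  ), class = "diet_contrast")
}

#' Weight gain per day by colonization and diet
#'
#' Per mouse, (last BW minus first BW) / days elapsed (7 days per
#' observation week), averaged within each colonization x diet group.
#' Single-timepoint mice are excluded with a warning.
#'
#' @inheritParams compute_diet_contrast
#' @param diets Diets to include; default all in `metadata`.
#' @return Data frame `diet`, `colonization`, `n`, `gain_per_day_g`, with
#'   `gain_per_day_g` named `diet.colonization` for direct lookup.
#' @export
gain_per_day <- function(growth, metadata, diets = NULL) {
  mice <- mouse_table(metadata)
  if (!is.null(diets)) mice <- mice[mice$diet %in% diets, ]
  g <- merge(growth, mice, by = "mouse_id")
  per_mouse <- do.call(rbind, lapply(split(g, g$mouse_id), function(m) {
    if (nrow(m) < 2) return(NULL)
    m <- m[order(m$week), ]
    days <- 7 * (m$week[nrow(m)] - m$week[1])
    data.frame(mouse_id = m$mouse_id[1], colonization = m$colonization[1],
               diet = m$diet[1], gpd = (m$bw_g[nrow(m)] - m$bw_g[1]) / days)
  }))
  dropped <- setdiff(unique(g$mouse_id), per_mouse$mouse_id)
  if (length(dropped))
    warning("excluding single-timepoint mice: ", paste(dropped, collapse = ", "))
  agg <- stats::aggregate(gpd ~ diet + colonization, data = per_mouse, FUN = mean)
  n <- stats::aggregate(gpd ~ diet + colonization, data = per_mouse, FUN = length)
  out <- data.frame(diet = agg$diet, colonization = agg$colonization,
                    n = n$gpd, gain_per_day_g = agg$gpd)
  names(out$gain_per_day_g) <- paste(out$diet, out$colonization, sep = ".")
  out
}

#' All per-diet contrasts as a table
#'
#' Runs [compute_diet_contrast()] over every diet (in the order given) and
#' assembles the per-diet contrast table that feeds the gene-weight
#' correlation screen.
#'
#' @inheritParams compute_diet_contrast
#' @param diets Diet order; defaults to order of appearance in `metadata`.
#' @return Data frame with one row per diet: `diet`, `delta_bw_abs`,
#'   `delta_bw_slope`, `slope_FMT`, `slope_GF`, `slope_se_FMT`,
#'   `slope_se_GF`, `F_slope`, `p_slope`, `F_elev`, `p_elev`. The full
#'   contrast objects are attached as attribute `"contrasts"`.
#' @export
diet_contrasts <- function(growth, metadata, diets = NULL, end_week = 8) {
  if (is.null(diets)) diets <- unique(metadata$diet)
  cl <- lapply(diets, function(d) compute_diet_contrast(growth, metadata, d, end_week))
  out <- data.frame(
    diet = diets,
    delta_bw_abs = vapply(cl, `[[`, numeric(1), "delta_bw_abs"),
    delta_bw_slope = vapply(cl, `[[`, numeric(1), "delta_bw_slope"),
    slope_FMT = vapply(cl, `[[`, numeric(1), "slope_FMT"),
    slope_GF = vapply(cl, `[[`, numeric(1), "slope_GF"),
    slope_se_FMT = vapply(cl, `[[`, numeric(1), "slope_se_FMT"),
    slope_se_GF = vapply(cl, `[[`, numeric(1), "slope_se_GF"),
    F_slope = vapply(cl, function(x) x$ancova$F_slope, numeric(1)),
    p_slope = vapply(cl, function(x) x$ancova$p_slope, numeric(1)),
    F_elev = vapply(cl, function(x) x$ancova$F_elev, numeric(1)),
    p_elev = vapply(cl, function(x) x$ancova$p_elev, numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "contrasts") <- stats::setNames(cl, diets)
  out
}
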