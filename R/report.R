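#' Grid-uniform mean slope of a derivative band
#' @param band a [derivative_band()].
#' @return mean derivative (ratio units / year).
#' @export
mean_slope <- function(band) {
  stopifnot(inherits(band, "derivative_band"))
  mean(band$estimate)
}

#' One-way ANOVA of parcel slopes across depth bins
#'
#' Parcels are the analysis units. Classic sums-of-squares F test with
#' `(bins - 1, N - bins)` degrees of freedom.
#'
#' @param slopes numeric vector of per-parcel slopes.
#' @param bins depth-bin label for each slope.
#' @return list with `F`, `p`, `df1`, `df2`, and per-bin means.
#' @export
depth_slope_anova <- function(slopes, bins) {
  if (length(slopes) != length(bins)) stop_invalid("slopes and bins lengths differ")
  bins <- factor(bins)
  counts <- table(bins)
  if (length(counts) < 2 || any(counts < 2))
    stop_invalid("need >= 2 bins with >= 2 parcels each")
  gm <- mean(slopes)
  means <- tapply(slopes, bins, mean)
  ss_b <- sum(counts * (means - gm)^2)
  ss_w <- sum((slopes - means[as.character(bins)])^2)
  df1 <- length(counts) - 1L
  df2 <- length(slopes) - length(counts)
  Fv <- if (ss_w == 0) {
    if (ss_b == 0) 0 else Inf
  } else (ss_b / df1) / (ss_w / df2)
  p <- if (is.infinite(Fv)) 0 else pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p, df1 = df1, df2 = df2, bin_means = means)
}

#' Smooth regression of per-parcel slopes on the hierarchy axis
#'
#' Regresses parcel slopes on hierarchy score with the same rank-3 smooth
#' machinery used for age trajectories (no sex term), returning the fit's
#' R-squared, a chi-squared significance p-value against the
#' intercept-only model, the fitted curve with a simultaneous 95% band,
#' and the grid-mean derivative (the sign of the gradient along the axis).
#'
#' @param slopes data.frame with columns `parcel_id` and `slope`.
#' @param axis a `hierarchy_axis` (scores merged by `parcel_id`).
#' @param k smooth complexity (default 3).
#' @param seed seed for the derivative band.
#' @return list with `r_squared`, `p`, `mean_derivative`, `fit` and `band`.
#' @export
slope_vs_hierarchy <- function(slopes, axis, k = 3L, seed = 1L) {
  stopifnot(inherits(axis, "hierarchy_axis"))
  df <- merge(slopes, as.data.frame(axis)[c("parcel_id", "score")], by = "parcel_id")
  if (nrow(df) < 10) stop_invalid("need >= 10 parcels with slopes and scores")
  if (var(df$score) == 0) stop_invalid("hierarchy axis is constant")
  d <- data.frame(value = df$slope, age = df$score)
  full <- fit_gam(d, k = k, include_sex = FALSE)
  red <- fit_gam(d, k = k, include_sex = FALSE, include_age = FALSE)
  band <- derivative_band(full, seed = seed)
  list(r_squared = full$r_squared, p = age_significance(full, red),
       mean_derivative = mean(band$estimate), fit = full, band = band)
}

#' Plateau proportions and timing across hierarchy groups
#'
#' Per hierarchy group (and per group x depth bin): the fraction of
#' parcels whose trajectory reached a detectable plateau, and a one-way
#' ANOVA of plateau ages across groups among plateaued parcels (censored
#' parcels are excluded from the timing ANOVA; the censoring fraction is
#' reported beside it). Groups with no plateaued parcel are dropped from
#' the timing ANOVA with a warning.
#'
#' @param results a [fit_trajectories()] result.
#' @param axis a tripartitioned `hierarchy_axis`.
#' @return list with `by_group`, `by_group_depth` (proportion tables) and
#'   `timing` (`F`, `p`, group means, `censored_fraction`; NULL when fewer
#'   than two groups have plateaued parcels).
#' @export
plateau_summaries <- function(results, axis) {
  stopifnot(inherits(axis, "hierarchy_axis"))
  df <- merge(as.data.frame(results),
              as.data.frame(axis)[c("parcel_id", "group")], by = "parcel_id")
  df$group <- factor(df$group, levels = c("sensorimotor", "middle", "association"))
  prop <- function(x) mean(x)
  by_group <- aggregate(plateau_reached ~ group, df, prop)
  names(by_group)[2] <- "proportion"
  by_gd <- aggregate(plateau_reached ~ group + depth_bin, df, prop)
  names(by_gd)[3] <- "proportion"
  pl <- df[df$plateau_reached, ]
  groups_with <- unique(pl$group)
  timing <- NULL
  if (length(groups_with) >= 2 && all(table(droplevels(pl$group)) >= 2)) {
    if (length(groups_with) < nlevels(df$group))
      warning("timing ANOVA excludes groups with no plateaued parcels: ",
              paste(setdiff(levels(df$group), as.character(groups_with)), collapse = ", "))
    an <- depth_slope_anova(pl$plateau_age, droplevels(pl$group))
    timing <- list(F = an$F, p = an$p, group_means = an$bin_means,
                   censored_fraction = 1 - mean(df$plateau_reached))
  } else if (nrow(pl) == 0) {
    warning("no plateaued parcels; timing ANOVA skipped")
  }
  list(by_group = by_group, by_group_depth = by_gd, timing = timing)
}

#' Deep-superficial slope gap and its hierarchy gradient
#'
#' Per-parcel difference between the deepest and most superficial retained
#' bins' mean slopes, regressed on the hierarchy axis with the same smooth
#' machinery as [slope_vs_hierarchy()]. Parcels missing either extreme bin
#' are skipped with a warning.
#'
#' @param results a [fit_trajectories()] result (multiple depth bins).
#' @param axis a `hierarchy_axis`.
#' @return list with `gaps` (data.frame `parcel_id`, `gap`) and `fit`
#'   (the gap-vs-hierarchy regression, see [slope_vs_hierarchy()]).
#' @export
deep_superficial_gap <- function(results, axis) {
  df <- as.data.frame(results)
  dmin <- min(df$depth_bin); dmax <- max(df$depth_bin)
  if (dmin == dmax) stop_invalid("results span a single depth bin")
  deep <- df[df$depth_bin == dmin, c("parcel_id", "mean_slope")]
  sup <- df[df$depth_bin == dmax, c("parcel_id", "mean_slope")]
  m <- merge(deep, sup, by = "parcel_id", suffixes = c("_deep", "_sup"))
  missing <- setdiff(unique(df$parcel_id), m$parcel_id)
  if (length(missing))
    warning("skipping parcels without both extreme bins: ",
            paste(missing, collapse = ", "))
  gaps <- data.frame(parcel_id = m$parcel_id,
                     gap = m$mean_slope_deep - m$mean_slope_sup)
  fit <- slope_vs_hierarchy(data.frame(parcel_id = gaps$parcel_id,
                                       slope = gaps$gap), axis)
  list(gaps = gaps, fit = fit)
}

#' Cross-species developmental age scaling
#'
#' Maps ages between macaque and human developmental time using the
#' conventional 4:1 ratio (1 macaque year is approximately 4 human years).
#'
#' @param age age(s), > 0.
#' @param factor scaling factor (> 0, default 4).
#' @param direction `"macaque_to_human"` (multiply) or
#'   `"human_to_macaque"` (divide).
#' @return scaled age(s).
#' @export
scale_age <- function(age, factor = 4,
                      direction = c("macaque_to_human", "human_to_macaque")) {
  direction <- match.arg(direction)
  if (any(age <= 0)) stop_invalid("age must be > 0")
  if (factor <= 0) stop_invalid("factor must be > 0")
  if (direction == "macaque_to_human") age * factor else age / factor
}
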