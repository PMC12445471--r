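#' Spatially contiguous random parcellation of a mesh
#'
#' Grows parcels from k-means centroids of the vertex coordinates: the
#' vertex nearest each centroid becomes a parcel seed and every vertex is
#' assigned to its nearest seed by weighted graph distance (a graph Voronoi
#' tessellation), followed by a contiguity repair pass that reassigns any
#' stray minority components to the most adjacent neighboring parcel.
#' Stands in for an anatomical atlas in synthetic pipelines.
#'
#' @param mesh a [surface_mesh()].
#' @param n_parcels number of parcels, in `[1, n_vertices]`.
#' @param seed RNG seed; the same seed reproduces the labeling exactly.
#' @return integer vector of per-vertex parcel labels in `1..n_parcels`.
#' @export
assign_parcels <- function(mesh, n_parcels, seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- mesh$n_vertices
  if (n_parcels < 1 || n_parcels > nv)
    stop_invalid("n_parcels must lie in [1, %d], got %s", nv, n_parcels)
  n_parcels <- as.integer(n_parcels)
  if (n_parcels == 1L) return(rep(1L, nv))
  if (n_parcels == nv) return(seq_len(nv))
  seeds <- with_seed(seed, {
    km <- kmeans(mesh$vertices, centers = n_parcels, nstart = 5, iter.max = 200)
    vapply(seq_len(n_parcels), function(cl) {
      members <- which(km$cluster == cl)
      ctr <- km$centers[cl, ]
      d2 <- rowSums((mesh$vertices[members, , drop = FALSE] -
                     matrix(ctr, length(members), 3, byrow = TRUE))^2)
      members[which.min(d2)]
    }, integer(1))
  })
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = seeds, weights = igraph::E(g)$length)
  d <- d[, order(as.integer(colnames(d))), drop = FALSE]
  labels <- apply(d, 2, which.min)  # ties -> lowest parcel id
  repair_contiguity(mesh, as.integer(labels), g)
}

# Reassign minority connected components of each parcel to the adjacent
# parcel they touch most, keeping the largest component.
repair_contiguity <- function(mesh, labels, g, max_iter = 10L) {
  edges <- mesh_edges(mesh)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (p in sort(unique(labels))) {
      vs <- which(labels == p)
      sub <- igraph::induced_subgraph(g, vs)
      comp <- igraph::components(sub)
      if (comp$no <= 1L) next
      keep <- which.max(comp$csize)
      for (cc in setdiff(seq_len(comp$no), keep)) {
        stray <- vs[comp$membership == cc]
        touching <- c(labels[edges$to[edges$from %in% stray]],
                      labels[edges$from[edges$to %in% stray]])
        touching <- touching[touching != p]
        if (length(touching) == 0) next
        labels[stray] <- as.integer(names(which.max(table(touching))))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

#' Ground-truth maturational trajectories
#'
#' Per-(parcel, depth bin) parameters of a saturating-exponential growth
#' curve `T(a) = B + A * (1 - exp(-r * (a - a0)))` for ages `a >= a0` (and
#' `B` before onset), the simplest monotone curve with a closed-form
#' plateau age. Global parameters give the residual noise sd, the
#' subject random-intercept sd, an additive sex effect, and the derivative
#' threshold `delta` below which the true trajectory counts as plateaued.
#'
#' @param params data.frame with columns `parcel_id`, `depth_bin`,
#'   `baseline` (B, ratio units), `amplitude` (A >= 0), `rate` (r > 0, per
#'   year), `onset` (a0, years).
#' @param sigma residual noise sd (>= 0), ratio units.
#' @param sigma_subject subject random-intercept sd (>= 0).
#' @param beta_sex additive effect of male sex, ratio units.
#' @param delta derivative threshold defining the true plateau age
#'   (ratio units / year); defaults to `sigma / 5`.
#' @return An object of class `trajectory_truth`.
#' @export
trajectory_truth <- function(params, sigma = 0.05, sigma_subject = 0,
                             beta_sex = 0.02,
                             delta = if (sigma > 0) sigma / 5 else 0.001) {
  need <- c("parcel_id", "depth_bin", "baseline", "amplitude", "rate", "onset")
  if (!all(need %in% names(params)))
    stop_invalid("params must have columns %s", paste(need, collapse = ", "))
  if (any(params$amplitude < 0)) stop_invalid("amplitude must be >= 0")
  if (any(params$rate <= 0)) stop_invalid("rate must be > 0")
  if (sigma < 0 || sigma_subject < 0) stop_invalid("noise sds must be >= 0")
  if (delta <= 0) stop_invalid("delta must be > 0")
  if (anyDuplicated(params[c("parcel_id", "depth_bin")]))
    stop_invalid("duplicate (parcel_id, depth_bin) rows in truth")
  structure(list(params = as.data.frame(params), sigma = sigma,
                 sigma_subject = sigma_subject, beta_sex = beta_sex,
                 delta = delta),
            class = "trajectory_truth")
}

truth_row <- function(truth, parcel, depth_bin) {
  i <- which(truth$params$parcel_id == parcel & truth$params$depth_bin == depth_bin)
  if (length(i) != 1L)
    stop_lookup("no truth entry for parcel %s, depth bin %s", parcel, depth_bin)
  truth$params[i, ]
}

#' Evaluate a ground-truth trajectory
#'
#' @param truth a [trajectory_truth()].
#' @param parcel,depth_bin cell identifiers (must exist in the truth).
#' @param age age(s) in years (>= 0); vectorized.
#' @return trajectory value(s), non-decreasing in age.
#' @export
true_trajectory <- function(truth, parcel, depth_bin, age) {
  stopifnot(inherits(truth, "trajectory_truth"))
  if (any(age < 0)) stop_invalid("age must be >= 0")
  p <- truth_row(truth, parcel, depth_bin)
  ifelse(age >= p$onset,
         p$baseline + p$amplitude * (1 - exp(-p$rate * (age - p$onset))),
         p$baseline)
}

#' Closed-form true plateau ages
#'
#' The age at which the true derivative `A * r * exp(-r * (a - a0))` falls
#' to `delta`: `a0 + log(A * r / delta) / r` when `A * r > delta`, else the
#' onset `a0`.
#'
#' @param truth a [trajectory_truth()].
#' @return the truth's parameter table with a `true_plateau` column added.
#' @export
true_plateau <- function(truth) {
  stopifnot(inherits(truth, "trajectory_truth"))
  p <- truth$params
  ar <- p$amplitude * p$rate
  p$true_plateau <- ifelse(ar > truth$delta,
                           p$onset + log(ar / truth$delta) / p$rate,
                           p$onset)
  p
}

#' Study design for synthetic cohorts
#'
#' Cross-sectional mode samples one visit per subject at a uniform random
#' age. Longitudinal mode gives each subject visits on an equally spaced
#' per-subject age grid with small uniform jitter; when `drop_one_visit`
#' is `TRUE` (default) the last subject loses its final visit, mirroring
#' cohorts where one animal has one fewer time point.
#'
#' @param mode `"cross_sectional"` or `"longitudinal"`.
#' @param n_subjects number of subjects (>= 1).
#' @param age_range length-2 numeric, years (positive length).
#' @param timepoints visits per subject (longitudinal only, >= 2).
#' @param sex_ratio proportion of female subjects in \[0, 1\].
#' @param species free-text species label carried into tables.
#' @param scanner_gain_sd,scanner_offset_sd sd of the per-subject
#'   multiplicative gain (around 1) and additive offset applied to raw
#'   values; both 0 disables the uncalibrated columns.
#' @param drop_one_visit logical, see above.
#' @param seed default RNG seed used by [generate_dataset()].
#' @return An object of class `study_design`.
#' @export
study_design <- function(mode = c("cross_sectional", "longitudinal"),
                         n_subjects, age_range, timepoints = NULL,
                         sex_ratio = 0.5, species = "human",
                         scanner_gain_sd = 0, scanner_offset_sd = 0,
                         drop_one_visit = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  if (length(age_range) != 2 || diff(age_range) <= 0)
    stop_invalid("age_range must be an increasing length-2 vector")
  if (mode == "longitudinal") {
    if (is.null(timepoints) || timepoints < 2)
      stop_invalid("longitudinal mode requires timepoints >= 2")
  } else timepoints <- 1L
  if (sex_ratio < 0 || sex_ratio > 1) stop_invalid("sex_ratio must lie in [0, 1]")
  structure(list(mode = mode, n_subjects = as.integer(n_subjects),
                 age_range = as.numeric(age_range),
                 timepoints = as.integer(timepoints), sex_ratio = sex_ratio,
                 species = species, scanner_gain_sd = scanner_gain_sd,
                 scanner_offset_sd = scanner_offset_sd,
                 drop_one_visit = isTRUE(drop_one_visit), seed = as.integer(seed)),
            class = "study_design")
}

# canonical group reference values used for the synthetic scanner model:
# a ventricle-like low reference and a white-matter-like high reference
GROUP_REF_LOW <- 0.5
GROUP_REF_HIGH <- 2.0

#' Generate a synthetic measurement table
#'
#' Draws a full long-format table: one row per (subject, visit, parcel,
#' depth bin) with `value = truth + beta_sex * I(male) + b_subject + eps`,
#' `eps ~ N(0, sigma^2)` and `b_subject ~ N(0, sigma_subject^2)` drawn once
#' per subject. The documented draw order under the single seed is: sexes,
#' ages, subject intercepts, scanner gains/offsets, then measurement noise
#' in row order (subjects x visits outer, parcels x depth bins inner), so
#' regeneration under the same seed is byte-identical. When the design has
#' nonzero scanner gain/offset sds, the table also carries `raw_value` and
#' per-subject reference columns (`ref_low`, `ref_high`) from which
#' [calibrate_ratio()] recovers `value` exactly.
#'
#' @param design a [study_design()].
#' @param truth a [trajectory_truth()].
#' @param seed RNG seed (defaults to the design's seed).
#' @return A `measurement_table` data.frame with columns `subject_id`,
#'   `species`, `visit`, `age`, `sex`, `parcel_id`, `depth_bin`, `value`
#'   (plus raw/reference columns when scanner effects are on).
#' @export
generate_dataset <- function(design, truth, seed = design$seed) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "trajectory_truth"))
  ns <- design$n_subjects
  cells <- truth$params[order(truth$params$parcel_id, truth$params$depth_bin), ]
  with_seed(seed, {
    sex <- ifelse(runif(ns) < design$sex_ratio, "F", "M")
    if (design$mode == "cross_sectional") {
      ages <- lapply(runif(ns, design$age_range[1], design$age_range[2]), identity)
    } else {
      tp <- design$timepoints
      grid <- seq(design$age_range[1], design$age_range[2], length.out = tp)
      jit <- 0.05 * diff(grid[1:2])
      ages <- lapply(seq_len(ns), function(i) {
        a <- grid + runif(tp, -jit, jit)
        pmin(pmax(a, design$age_range[1]), design$age_range[2])
      })
      if (design$drop_one_visit && ns >= 1)
        ages[[ns]] <- ages[[ns]][-tp]
    }
    b_subj <- rnorm(ns, 0, truth$sigma_subject)
    gains <- if (design$scanner_gain_sd > 0 || design$scanner_offset_sd > 0) {
      g <- pmax(0.2, 1 + rnorm(ns, 0, design$scanner_gain_sd))
      o <- rnorm(ns, 0, design$scanner_offset_sd)
      list(g = g, o = o)
    } else NULL

    n_visits <- lengths(ages)
    subj_idx <- rep(seq_len(ns), n_visits)
    visit_idx <- unlist(lapply(n_visits, seq_len))
    age_vec <- unlist(ages)
    nc <- nrow(cells)
    nr <- length(age_vec) * nc
    rows <- data.frame(
      subject_id = sprintf("S%04d", rep(subj_idx, each = nc)),
      species = design$species,
      visit = rep(visit_idx, each = nc),
      age = rep(age_vec, each = nc),
      sex = rep(sex[subj_idx], each = nc),
      parcel_id = rep(cells$parcel_id, times = length(age_vec)),
      depth_bin = rep(cells$depth_bin, times = length(age_vec)),
      stringsAsFactors = FALSE)
    mu <- ifelse(rows$age >= rep(cells$onset, length(age_vec)),
                 rep(cells$baseline, length(age_vec)) +
                   rep(cells$amplitude, length(age_vec)) *
                   (1 - exp(-rep(cells$rate, length(age_vec)) *
                            (rows$age - rep(cells$onset, length(age_vec))))),
                 rep(cells$baseline, length(age_vec)))
    eps <- rnorm(nr, 0, truth$sigma)
    rows$value <- mu + truth$beta_sex * (rows$sex == "M") +
      b_subj[rep(subj_idx, each = nc)] + eps
    if (!is.null(gains)) {
      g <- gains$g[rep(subj_idx, each = nc)]
      o <- gains$o[rep(subj_idx, each = nc)]
      rows$raw_value <- g * rows$value + o
      rows$ref_low <- g * GROUP_REF_LOW + o
      rows$ref_high <- g * GROUP_REF_HIGH + o
    }
    class(rows) <- c("measurement_table", "data.frame")
    rows
  })
}

#' Structured ground truth with hierarchy and depth gradients
#'
#' Builds a [trajectory_truth()] encoding the qualitative maturational
#' structure the pipeline is designed to detect: growth rate and amplitude
#' decrease from sensorimotor to association cortex (along `hierarchy`,
#' 0 = sensorimotor, 1 = association) and from deep to superficial bins
#' ("inside-out"), onsets shift later along the hierarchy, and the depth
#' modulation itself weakens toward association cortex. The default rate
#' scales are chosen so a rank-3 age smooth can represent the curves over
#' the observation window (see the package vignette): the `"human"`
#' timescale spans slow saturating growth over years; `"macaque"`
#' compresses maturation into the first years of life.
#'
#' @param parcel_ids vector of parcel identifiers.
#' @param hierarchy numeric in \[0, 1\], one value per parcel
#'   (0 = sensorimotor end, 1 = association end).
#' @param n_depth_bins number of depth bins (bin 1 = deepest).
#' @param timescale `"human"` or `"macaque"`.
#' @param sigma,sigma_subject,beta_sex,delta passed to [trajectory_truth()].
#' @return A `trajectory_truth`.
#' @export
structured_truth <- function(parcel_ids, hierarchy, n_depth_bins = 5L,
                             timescale = c("human", "macaque"),
                             sigma = 0.05, sigma_subject = 0,
                             beta_sex = 0.02, delta = sigma / 5) {
  timescale <- match.arg(timescale)
  if (length(hierarchy) != length(parcel_ids))
    stop_invalid("hierarchy must give one value per parcel")
  if (any(hierarchy < 0 | hierarchy > 1)) stop_invalid("hierarchy must lie in [0, 1]")
  d <- if (n_depth_bins > 1) (seq_len(n_depth_bins) - 1) / (n_depth_bins - 1) else 0
  grid <- expand.grid(i = seq_along(parcel_ids), bin = seq_len(n_depth_bins))
  h <- hierarchy[grid$i]
  dn <- d[grid$bin]
  mod <- (1 - 2 * dn) * (1 - 0.6 * h)  # inside-out contrast, weakening along the axis
  # Rate scales are set so that (i) association growth is still detectable at
  # the oldest observed human age while sensorimotor growth has saturated,
  # (ii) macaque association saturates within its window, and (iii) a rank-3
  # age smooth can represent the curves over each window (see vignette).
  if (timescale == "human") {
    r0 <- 0.14 - 0.115 * h
    a0 <- 4 + 1.0 * h
  } else {
    r0 <- 2.0 - 1.2 * h
    a0 <- 0.04 + 0.03 * h
  }
  A0 <- 0.65 - 0.15 * h
  params <- data.frame(
    parcel_id = parcel_ids[grid$i],
    depth_bin = grid$bin,
    baseline = 1.55 - 0.25 * dn - 0.15 * h,
    amplitude = A0 * (1 + 0.20 * mod),
    rate = r0 * (1 + 0.25 * mod),
    onset = a0)
  trajectory_truth(params, sigma = sigma, sigma_subject = sigma_subject,
                   beta_sex = beta_sex, delta = delta)
}

#' Write a truth object to JSON
#' @param truth a [trajectory_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(params = truth$params, sigma = truth$sigma,
                            sigma_subject = truth$sigma_subject,
                            beta_sex = truth$beta_sex, delta = truth$delta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
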