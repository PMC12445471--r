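#' Elementwise T1w/T2w ratio with masking
#'
#' Divides matched T1w by T2w intensities. Samples with zero T2w or
#' non-finite input are masked (`NA`); the mask count is attached as
#' attribute `n_masked` and reported via [message()].
#'
#' @param t1w,t2w numeric vectors of matched intensities.
#' @return ratio vector with `NA` at masked positions.
#' @export
compute_ratio <- function(t1w, t2w) {
  if (length(t1w) != length(t2w)) stop_invalid("t1w and t2w lengths differ")
  bad <- !is.finite(t1w) | !is.finite(t2w) | t2w == 0
  out <- ifelse(bad, NA_real_, t1w / t2w)
  if (any(bad)) message(sprintf("compute_ratio: masked %d of %d samples",
                                sum(bad), length(bad)))
  attr(out, "n_masked") <- sum(bad)
  out
}

#' Two-point reference calibration of ratio values
#'
#' T1w/T2w units are arbitrary, so values are calibrated against reference
#' structures: a white-matter-like high reference (corpus callosum or pons)
#' and a ventricle low reference. The affine map sending the individual's
#' reference pair onto the group-averaged pair is applied to all values:
#' `v' = L_g + (v - L_i) * (H_g - L_g) / (H_i - L_i)`.
#'
#' @param values numeric vector of uncalibrated values.
#' @param ref_high_individual,ref_low_individual the individual's high/low
#'   reference values (high > low); scalars or per-value vectors.
#' @param ref_high_group,ref_low_group group-averaged reference values.
#' @return calibrated values.
#' @export
calibrate_ratio <- function(values, ref_high_individual, ref_low_individual,
                            ref_high_group, ref_low_group) {
  if (any(ref_high_individual <= ref_low_individual))
    stop_invalid("individual references degenerate: high must exceed low")
  ref_low_group + (values - ref_low_individual) *
    (ref_high_group - ref_low_group) / (ref_high_individual - ref_low_individual)
}

#' Aggregate calibrated samples to a parcel x depth measurement table
#'
#' Averages member samples (arithmetic mean) within each
#' (subject, visit, parcel, depth bin) cell and retains member counts for
#' QC. Cells whose samples are all missing are omitted with a message.
#'
#' @param samples data.frame with columns `subject_id`, `species`, `age`,
#'   `sex`, `parcel_id`, `depth_bin`, `value` and optionally `visit`.
#' @return A `measurement_table` data.frame with a mean `value` and an
#'   `n_samples` count per cell.
#' @export
aggregate_to_table <- function(samples) {
  need <- c("subject_id", "species", "age", "sex", "parcel_id", "depth_bin", "value")
  if (!all(need %in% names(samples)))
    stop_invalid("samples must have columns %s", paste(need, collapse = ", "))
  if (!"visit" %in% names(samples)) samples$visit <- 1L
  keys <- c("subject_id", "species", "visit", "age", "sex", "parcel_id", "depth_bin")
  ok <- !is.na(samples$value)
  n_dropped_cells <- 0L
  agg <- aggregate(samples$value[ok], by = samples[ok, keys, drop = FALSE], FUN = mean)
  names(agg)[ncol(agg)] <- "value"
  cnt <- aggregate(samples$value[ok], by = samples[ok, keys, drop = FALSE], FUN = length)
  agg$n_samples <- cnt$x
  all_cells <- unique(samples[keys])
  n_dropped_cells <- nrow(all_cells) - nrow(agg)
  if (n_dropped_cells > 0)
    message(sprintf("aggregate_to_table: omitted %d empty cells", n_dropped_cells))
  agg <- agg[order(agg$subject_id, agg$visit, agg$parcel_id, agg$depth_bin), ]
  rownames(agg) <- NULL
  class(agg) <- c("measurement_table", "data.frame")
  agg
}

#' Age-balanced subject subsampling
#'
#' Robustness subsampler: bins subjects by age (left-closed right-open
#' bins of `bin_width` years anchored at the minimum age) and keeps at
#' most `per_bin` subjects per bin, drawn uniformly without replacement
#' (all kept when a bin is under-full). All rows of the selected subjects
#' are retained. For longitudinal tables a subject's bin is set by the
#' age at first visit.
#'
#' @param table a measurement table (data.frame).
#' @param bin_width age bin width in years (> 0).
#' @param per_bin subjects to keep per bin (>= 1).
#' @param seed RNG seed; fixed seed gives identical subject sets.
#' @return the subsampled table.
#' @export
balanced_subsample <- function(table, bin_width, per_bin, seed = 1L) {
  if (bin_width <= 0) stop_invalid("bin_width must be > 0")
  if (per_bin < 1) stop_invalid("per_bin must be >= 1")
  first_age <- tapply(table$age, table$subject_id, min)
  a0 <- min(first_age)
  bins <- floor((first_age - a0) / bin_width)
  keep <- with_seed(seed, {
    unlist(lapply(split(names(first_age), bins), function(subj) {
      if (length(subj) <= per_bin) subj
      else sort(sample(subj, per_bin))
    }), use.names = FALSE)
  })
  out <- table[table$subject_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write measurement tables as CSV
#' @param table a measurement table.
#' @param path CSV path.
#' @return `read_measurement_table` returns a `measurement_table`;
#'   `write_measurement_table` returns `path` invisibly.
#' @export
write_measurement_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_table
#' @export
read_measurement_table <- function(path) {
  t <- read.csv(path, stringsAsFactors = FALSE)
  class(t) <- c("measurement_table", "data.frame")
  t
}
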