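#' Geodesic distances from seed vertices along the mesh edge graph
#'
#' Shortest-path distance from every vertex to its nearest seed, with edge
#' weights equal to Euclidean edge lengths (Dijkstra on the vertex-edge
#' graph). This approximates the true surface geodesic; on reasonably
#' regular meshes the edge-graph path overestimates the continuous geodesic
#' by a bounded, subdivision-stable factor.
#'
#' @param mesh a [surface_mesh()].
#' @param seeds non-empty vector of seed vertex indices.
#' @return numeric vector of distances (mm), 0 exactly on seeds.
#' @export
geodesic_distances <- function(mesh, seeds) {
  stopifnot(inherits(mesh, "surface_mesh"))
  seeds <- unique(as.integer(seeds))
  if (length(seeds) == 0) stop_invalid("seed set must be non-empty")
  if (any(seeds < 1L | seeds > mesh$n_vertices))
    stop_invalid("seed indices must lie in [1, %d]", mesh$n_vertices)
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = seeds, weights = igraph::E(g)$length)
  out <- apply(d, 2, min)
  out <- out[order(as.integer(colnames(d)))]
  names(out) <- NULL
  if (any(!is.finite(out)))
    warning("mesh has vertices unreachable from all seeds; reporting Inf")
  out
}

#' Select seed vertices by k-means clustering of a region
#'
#' Clusters the 3D coordinates of the vertices in `region_mask` into
#' `n_clusters` k-means clusters, keeps a uniformly random
#' `ceiling(fraction * n_clusters)` subset of clusters, and returns, for
#' each kept cluster, the member vertex nearest the cluster centroid.
#' Deterministic under a fixed `seed`.
#'
#' @param mesh a [surface_mesh()].
#' @param region_mask non-empty vector of vertex indices defining the
#'   region (e.g., default-mode-network vertices).
#' @param n_clusters number of k-means clusters (<= region size).
#' @param fraction proportion of clusters kept as seeds, in (0, 1\].
#' @param seed RNG seed.
#' @return integer vector of seed vertex indices.
#' @export
select_seed_vertices <- function(mesh, region_mask, n_clusters, fraction = 0.1,
                                 seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  region_mask <- unique(as.integer(region_mask))
  if (length(region_mask) == 0) stop_invalid("region_mask must be non-empty")
  if (any(region_mask < 1L | region_mask > mesh$n_vertices))
    stop_invalid("region_mask indices out of range")
  if (fraction <= 0 || fraction > 1) stop_invalid("fraction must lie in (0, 1]")
  if (n_clusters < 1 || n_clusters > length(region_mask))
    stop_invalid("n_clusters must lie in [1, region size]")
  coords <- mesh$vertices[region_mask, , drop = FALSE]
  with_seed(seed, {
    km <- if (n_clusters == length(region_mask)) {
      list(cluster = seq_along(region_mask), centers = coords)
    } else {
      kmeans(coords, centers = n_clusters, nstart = 5, iter.max = 200)
    }
    keep <- sort(sample.int(n_clusters, ceiling(fraction * n_clusters)))
    vapply(keep, function(cl) {
      members <- which(km$cluster == cl)
      ctr <- km$centers[cl, ]
      d2 <- rowSums((coords[members, , drop = FALSE] -
                     matrix(ctr, length(members), 3, byrow = TRUE))^2)
      region_mask[members[which.min(d2)]]
    }, integer(1))
  })
}

#' Parcel-level hierarchy scores from per-vertex geodesic distances
#'
#' Averages per-vertex minimum geodesic distances within each parcel to a
#' per-parcel hierarchy score. With association-area seeds, larger scores
#' are farther from association cortex, i.e., more sensorimotor-like.
#'
#' @param mesh a [surface_mesh()].
#' @param parcellation integer vector of per-vertex parcel labels.
#' @param distances per-vertex distances from [geodesic_distances()].
#' @return A `hierarchy_axis` data.frame with columns `parcel_id`, `score`,
#'   `group` (NA until [tripartition()]), `source = "geodesic"`.
#' @export
parcel_hierarchy <- function(mesh, parcellation, distances) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(parcellation) != mesh$n_vertices)
    stop_invalid("parcellation must label every vertex (%d != %d)",
                 length(parcellation), mesh$n_vertices)
  if (length(distances) != mesh$n_vertices)
    stop_invalid("distances must cover every vertex")
  ids <- sort(unique(parcellation))
  score <- vapply(ids, function(p) {
    v <- distances[parcellation == p]
    if (length(v) == 0) stop_lookup("parcel %s has no vertices", p)
    mean(v)
  }, numeric(1))
  ax <- data.frame(parcel_id = ids, score = score,
                   group = NA_character_, source = "geodesic",
                   stringsAsFactors = FALSE)
  class(ax) <- c("hierarchy_axis", "data.frame")
  ax
}

#' Construct a hierarchy axis from externally supplied parcel scores
#'
#' @param parcel_id parcel identifiers.
#' @param score per-parcel axis position (e.g., an external
#'   sensorimotor-association rank).
#' @return A `hierarchy_axis` data.frame with `source = "external"`.
#' @export
external_axis <- function(parcel_id, score) {
  if (length(parcel_id) != length(score))
    stop_invalid("parcel_id and score lengths differ")
  ax <- data.frame(parcel_id = parcel_id, score = score,
                   group = NA_character_, source = "external",
                   stringsAsFactors = FALSE)
  class(ax) <- c("hierarchy_axis", "data.frame")
  ax
}

#' Partition parcels into sensorimotor / middle / association thirds
#'
#' Sorts parcels by axis score and cuts the ordering into three
#' near-equal-size groups (sizes differ by at most one; remainder parcels
#' go to the earlier groups). `ordering` states which end of the score is
#' sensorimotor: `"ascending"` means the lowest scores are sensorimotor
#' (e.g., an S-A rank), `"descending"` means the highest are (e.g.,
#' geodesic distance from association seeds). Ties are broken by parcel id.
#'
#' @param axis a `hierarchy_axis`.
#' @param ordering `"ascending"` or `"descending"`.
#' @return the axis with its `group` column filled
#'   (`"sensorimotor"`/`"middle"`/`"association"`).
#' @export
tripartition <- function(axis, ordering = c("ascending", "descending")) {
  ordering <- match.arg(ordering)
  stopifnot(inherits(axis, "hierarchy_axis"))
  n <- nrow(axis)
  if (n < 3) stop_invalid("tripartition needs at least 3 parcels, got %d", n)
  s <- if (ordering == "ascending") axis$score else -axis$score
  ord <- order(s, axis$parcel_id)
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, FALSE)
  grp <- rep(c("sensorimotor", "middle", "association"), times = sizes)
  axis$group[ord] <- grp
  axis
}

#' Best-overlap mapping between two parcellations
#'
#' Maps each parcel of labeling A to the parcel of labeling B sharing the
#' most vertices. Parcels with zero overlap are left unassigned (`NA`);
#' ties are broken toward the smaller B id with a warning.
#'
#' @param labelsA,labelsB per-vertex parcel labels on the same vertex set.
#' @return data.frame with columns `parcel_a`, `parcel_b`, `n_shared`.
#' @export
best_overlap_mapping <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop_invalid("label vectors must cover the same vertex set (%d != %d)",
                 length(labelsA), length(labelsB))
  keep <- !is.na(labelsA) & !is.na(labelsB)
  tab <- table(labelsA[keep], labelsB[keep])
  ids_a <- sort(unique(labelsA[!is.na(labelsA)]))
  res <- lapply(ids_a, function(a) {
    if (!as.character(a) %in% rownames(tab))
      return(data.frame(parcel_a = a, parcel_b = NA, n_shared = 0L))
    counts <- tab[as.character(a), ]
    best <- max(counts)
    if (best == 0L)
      return(data.frame(parcel_a = a, parcel_b = NA, n_shared = 0L))
    winners <- colnames(tab)[counts == best]
    if (length(winners) > 1L)
      warning(sprintf("parcel %s overlaps %d B-parcels equally; taking smallest id",
                      a, length(winners)))
    b <- sort(winners)[1]
    b <- if (is.numeric(labelsB)) as.numeric(b) else b
    data.frame(parcel_a = a, parcel_b = b, n_shared = as.integer(best))
  })
  do.call(rbind, res)
}

#' Pearson correlation between two hierarchy axes
#'
#' Correlates scores over the shared parcels of two axes, with a two-sided
#' p-value from the t distribution.
#'
#' @param axisA,axisB `hierarchy_axis` objects or named numeric vectors
#'   (names = parcel ids). Plain unnamed vectors are matched by position.
#' @return list with `r`, `p`, `n`.
#' @export
axis_correlation <- function(axisA, axisB) {
  get_scores <- function(x) {
    if (inherits(x, "hierarchy_axis")) setNames(x$score, x$parcel_id)
    else if (!is.null(names(x))) x
    else setNames(as.numeric(x), seq_along(x))
  }
  a <- get_scores(axisA); b <- get_scores(axisB)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop_invalid("need at least 3 shared parcels")
  x <- a[shared]; y <- b[shared]
  if (var(x) == 0 || var(y) == 0) stop_invalid("axis scores have zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
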