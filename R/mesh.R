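#' Triangulated surface mesh
#'
#' Container for a triangulated surface (e.g., a cortical midthickness
#' surface): vertex coordinates in mm and triangle vertex-index triples.
#' Validates that all triangle indices are in range, that no triangle is
#' degenerate (three distinct vertices, nonzero area), and that the edge
#' graph is connected.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @return An object of class `surface_mesh` with fields `vertices`,
#'   `triangles`, `n_vertices`, `n_triangles`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3) stop_invalid("vertices must be an n x 3 matrix")
  nv <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > nv))
    stop_invalid("triangle indices must lie in [1, %d]", nv)
  if (any(triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3]))
    stop_invalid("degenerate triangle: repeated vertex index")
  if (any(triangle_areas(vertices, triangles) <= 0))
    stop_invalid("degenerate triangle: zero area")
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         n_vertices = nv, n_triangles = nrow(triangles)),
                    class = "surface_mesh")
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no > 1L)
    stop_invalid("mesh edge graph is not connected")
  mesh
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  u <- vertices[triangles[, 2], , drop = FALSE] - a
  v <- vertices[triangles[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Unique undirected edges of a mesh with Euclidean lengths
#' @param mesh a `surface_mesh`.
#' @return data.frame with columns `from`, `to`, `length`.
#' @export
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  data.frame(from = e[, 1], to = e[, 2], length = d)
}

# igraph edge graph with edge weights = Euclidean edge length
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = seq_len(mesh$n_vertices)))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              x$n_vertices, x$n_triangles))
  invisible(x)
}

#' Icosphere test mesh
#'
#' Builds a subdivided icosahedron projected onto a sphere, the standard
#' closed test surface standing in for a cortical hemisphere mesh. Vertex
#' count is `10 * 4^subdivisions + 2`.
#'
#' @param subdivisions non-negative integer, number of 4-to-1 triangle
#'   subdivisions.
#' @param radius sphere radius in mm (> 0).
#' @return A `surface_mesh`.
#' @examples
#' m <- make_test_mesh(1, 1)   # 42 vertices, 80 triangles
#' @export
make_test_mesh <- function(subdivisions = 0L, radius = 1) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop_invalid("radius must be a single positive number")
  if (!is.numeric(subdivisions) || subdivisions < 0 || subdivisions != round(subdivisions))
    stop_invalid("subdivisions must be a non-negative integer")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  f <- 1L + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  for (i in seq_len(subdivisions)) {
    res <- subdivide_once(v, f)
    v <- res$v; f <- res$f
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f)
}

subdivide_once <- function(v, f) {
  midpoint_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- v
  get_mid <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    idx <- midpoint_env[[key]]
    if (is.null(idx)) {
      verts <<- rbind(verts, (v[i, ] + v[j, ]) / 2)
      idx <- nrow(verts)
      midpoint_env[[key]] <- idx
    }
    idx
  }
  newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    newf[(4 * k - 3):(4 * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
  }
  list(v = verts, f = newf)
}

#' Read / write a mesh in OFF format
#'
#' Plain-text Object File Format: a header line `OFF`, counts, vertex
#' coordinates, then faces as `3 i j k` (0-based indices).
#'
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @return `read_mesh_off` returns a `surface_mesh`; `write_mesh_off`
#'   returns `path` invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", mesh$n_vertices, mesh$n_triangles), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1])) != "OFF") stop_invalid("not an OFF file: %s", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"), quiet = TRUE),
              ncol = 3, byrow = TRUE)
  f <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nf)], collapse = "\n"), quiet = TRUE),
              ncol = 4, byrow = TRUE)
  surface_mesh(v, f[, 2:4] + 1L)
}
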