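# Shared fixtures and independent oracles for the test suite.

# Numeric oracle for equi-volume placement: integrate the linear-taper
# local area and invert the cumulative volume by root finding.
equivolume_oracle <- function(alpha, A_in, A_out) {
  area <- function(rho) A_in + (A_out - A_in) * rho
  total <- stats::integrate(area, 0, 1)$value
  vapply(alpha, function(a) {
    if (a <= 0) return(0)
    if (a >= 1) return(1)
    stats::uniroot(function(r) stats::integrate(area, 0, r)$value - a * total,
                   c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}

# Brute-force all-pairs shortest paths (vectorized Floyd-Warshall),
# independent of the igraph-based implementation.
floyd_warshall <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- mesh$n_vertices
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[cbind(e$from, e$to)] <- e$length
  D[cbind(e$to, e$from)] <- e$length
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Random-geometry mesh: icosphere with radial jitter (topology fixed,
# random edge lengths).
jittered_mesh <- function(subdivisions, seed, jitter = 0.15) {
  m <- make_test_mesh(subdivisions, 1)
  set.seed(seed)
  r <- 1 + runif(m$n_vertices, -jitter, jitter)
  surface_mesh(m$vertices * r, m$triangles)
}

# Brute-force Benjamini-Hochberg: q_i = min over j with p_j >= p_i of
# p_(j) * m / rank(j), straight from the step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- numeric(m)
  r[o] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    j <- which(r >= r[i])
    min(1, min(p[j] * m / r[j]))
  }, numeric(1))
}

# Flat-truth regression data for GAM calibration tests.
flat_data <- function(n, sigma = 0.05, age_range = c(5.5, 36)) {
  df <- data.frame(age = runif(n, age_range[1], age_range[2]),
                   sex = sample(c("F", "M"), n, replace = TRUE))
  df$value <- 1.5 + 0.02 * (df$sex == "M") + rnorm(n, 0, sigma)
  df
}

# Saturating-exponential data on the human-like window.
sat_data <- function(n, r, A = 0.3, sigma = 0.03, a0 = 5,
                     age_range = c(5, 36), B = 1.2) {
  df <- data.frame(age = runif(n, age_range[1], age_range[2]),
                   sex = sample(c("F", "M"), n, replace = TRUE))
  df$value <- B + A * (1 - exp(-r * pmax(df$age - a0, 0))) +
    0.02 * (df$sex == "M") + rnorm(n, 0, sigma)
  df
}

# Hand-built derivative_band object for plateau-rule unit tests.
fake_band <- function(grid, estimate, half_width) {
  structure(list(grid = grid, estimate = estimate,
                 se = half_width, lower = estimate - half_width,
                 upper = estimate + half_width, crit = 1, level = 0.95,
                 n_sim = 0L, seed = 0L),
            class = "derivative_band")
}
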