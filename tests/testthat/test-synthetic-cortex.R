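test_that("icosphere meshes have the expected combinatorics and geometry", {
  cases <- list(list(s = 0, v = 12L, t = 20L), list(s = 1, v = 42L, t = 80L),
                list(s = 2, v = 162L, t = 320L))
  for (cs in cases) {
    m <- make_test_mesh(cs$s, 1)
    expect_identical(m$n_vertices, cs$v)
    expect_identical(m$n_triangles, cs$t)
  }
  m <- make_test_mesh(2, 2.5)
  expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 2.5)), 1e-9)
  expect_error(make_test_mesh(1, 0), class = "laminardev_invalid_parameter")
  expect_error(make_test_mesh(-1, 1), class = "laminardev_invalid_parameter")
})

test_that("surface_mesh validates triangles and connectivity", {
  v <- diag(3)
  expect_error(surface_mesh(v, matrix(c(1, 2, 4), 1)),
               class = "laminardev_invalid_parameter")
  expect_error(surface_mesh(v, matrix(c(1, 2, 2), 1)),
               class = "laminardev_invalid_parameter")
  # two disjoint triangles -> disconnected edge graph
  v6 <- rbind(diag(3), diag(3) + 10)
  expect_error(surface_mesh(v6, rbind(c(1, 2, 3), c(4, 5, 6))),
               class = "laminardev_invalid_parameter")
})

test_that("assign_parcels saturates, degenerates, and is deterministic", {
  m12 <- make_test_mesh(0, 1)
  expect_identical(assign_parcels(m12, 12, seed = 3), 1:12)
  expect_identical(assign_parcels(m12, 1, seed = 3), rep(1L, 12))
  m <- make_test_mesh(2, 1)
  p1 <- assign_parcels(m, 10, seed = 7)
  p2 <- assign_parcels(m, 10, seed = 7)
  expect_identical(p1, p2)
  expect_setequal(unique(p1), 1:10)
  expect_length(p1, m$n_vertices)
  expect_error(assign_parcels(m12, 13), class = "laminardev_invalid_parameter")
})

test_that("parcels are spatially contiguous on the mesh graph", {
  m <- make_test_mesh(2, 1)
  g <- igraph::graph_from_data_frame(mesh_edges(m), directed = FALSE,
                                     vertices = data.frame(name = 1:m$n_vertices))
  for (seed in c(1, 9)) {
    p <- assign_parcels(m, 12, seed = seed)
    for (lab in unique(p)) {
      sub <- igraph::induced_subgraph(g, which(p == lab))
      expect_equal(igraph::components(sub)$no, 1)
    }
  }
})

test_that("true_trajectory evaluates the saturating exponential", {
  par <- data.frame(parcel_id = 1, depth_bin = 1, baseline = 1,
                    amplitude = 0.5, rate = 0.3, onset = 0)
  tr <- trajectory_truth(par, sigma = 0)
  expect_equal(true_trajectory(tr, 1, 1, 0), 1.0)
  # closed form evaluated independently
  expect_equal(true_trajectory(tr, 1, 1, 10), 1 + 0.5 * (1 - exp(-3)),
               tolerance = 1e-12)
  flat <- trajectory_truth(data.frame(parcel_id = 1, depth_bin = 1,
                                      baseline = 1, amplitude = 0,
                                      rate = 0.3, onset = 0), sigma = 0)
  expect_equal(true_trajectory(flat, 1, 1, c(0, 5, 40)), rep(1, 3))
  # monotone non-decreasing
  ages <- seq(0, 40, by = 0.5)
  expect_true(all(diff(true_trajectory(tr, 1, 1, ages)) >= 0))
  expect_error(true_trajectory(tr, 2, 1, 5), class = "laminardev_lookup_error")
  expect_error(true_trajectory(tr, 1, 1, -1), class = "laminardev_invalid_parameter")
})

test_that("true_plateau matches a root-finding oracle", {
  par <- expand.grid(parcel_id = 1:3, depth_bin = 1)
  par$baseline <- 1; par$onset <- c(0, 2, 4)
  par$amplitude <- c(0.3, 0.5, 0.2); par$rate <- c(0.25, 0.1, 0.4)
  tr <- trajectory_truth(par, sigma = 0.05, delta = 0.004)
  tp <- true_plateau(tr)
  for (i in 1:3) {
    # oracle: solve A r exp(-r (a - a0)) = delta numerically
    f <- function(a) par$amplitude[i] * par$rate[i] *
      exp(-par$rate[i] * (a - par$onset[i])) - 0.004
    a_star <- uniroot(f, c(par$onset[i], 200), tol = 1e-12)$root
    expect_equal(tp$true_plateau[i], a_star, tolerance = 1e-8)
  }
  # A r below delta -> plateau at onset
  small <- trajectory_truth(data.frame(parcel_id = 1, depth_bin = 1,
                                       baseline = 1, amplitude = 0.01,
                                       rate = 0.1, onset = 3), delta = 0.01)
  expect_equal(true_plateau(small)$true_plateau, 3)
})

test_that("generate_dataset is exact in the noiseless limit", {
  par <- expand.grid(parcel_id = 1:3, depth_bin = 1:2)
  par$baseline <- 1.2; par$amplitude <- 0.4
  par$rate <- 0.2 + 0.05 * par$depth_bin; par$onset <- 2
  tr <- trajectory_truth(par, sigma = 0, sigma_subject = 0, beta_sex = 0)
  des <- study_design("cross_sectional", 20, c(5, 30), seed = 5)
  tab <- generate_dataset(des, tr)
  for (i in sample(nrow(tab), 25)) {
    expect_equal(tab$value[i],
                 true_trajectory(tr, tab$parcel_id[i], tab$depth_bin[i], tab$age[i]),
                 tolerance = 1e-12)
  }
})

test_that("longitudinal design yields 164 subject-visits (33 x 5, one with 4)", {
  par <- data.frame(parcel_id = 1, depth_bin = 1, baseline = 1.2,
                    amplitude = 0.4, rate = 1, onset = 0.05)
  tr <- trajectory_truth(par, sigma = 0.05, sigma_subject = 0.08)
  des <- study_design("longitudinal", 33, c(1 / 12, 3), timepoints = 5, seed = 2)
  tab <- generate_dataset(des, tr)
  expect_identical(nrow(tab), 164L)  # 32 * 5 + 4
  expect_identical(length(unique(tab$subject_id)), 33L)
  visits <- table(tab$subject_id)
  expect_identical(sort(unique(as.integer(visits))), c(4L, 5L))
  expect_identical(sum(visits == 4L), 1L)
  expect_true(all(tab$age >= 1 / 12 & tab$age <= 3))
})

test_that("cross-sectional design has one visit per subject per cell", {
  par <- expand.grid(parcel_id = 1:2, depth_bin = 1:2)
  par$baseline <- 1; par$amplitude <- 0.3; par$rate <- 0.1; par$onset <- 4
  tr <- trajectory_truth(par)
  des <- study_design("cross_sectional", 200, c(5.5, 36), seed = 8)
  tab <- generate_dataset(des, tr)
  expect_identical(length(unique(tab$subject_id)), 200L)
  counts <- table(tab$subject_id, paste(tab$parcel_id, tab$depth_bin))
  expect_true(all(counts == 1L))
})

test_that("generation is byte-identical under the same seed", {
  par <- expand.grid(parcel_id = 1:2, depth_bin = 1:2)
  par$baseline <- 1; par$amplitude <- 0.3; par$rate <- 0.1; par$onset <- 4
  tr <- trajectory_truth(par, sigma_subject = 0.05)
  des <- study_design("longitudinal", 10, c(0.1, 3), timepoints = 5,
                      scanner_gain_sd = 0.05, scanner_offset_sd = 0.02, seed = 3)
  t1 <- generate_dataset(des, tr)
  t2 <- generate_dataset(des, tr)
  expect_identical(t1, t2)
  t3 <- generate_dataset(des, tr, seed = 4)
  expect_false(identical(t1$value, t3$value))
})

test_that("scanner effects are exactly removed by reference calibration", {
  par <- data.frame(parcel_id = 1, depth_bin = 1, baseline = 1.2,
                    amplitude = 0.3, rate = 0.15, onset = 4)
  tr <- trajectory_truth(par, sigma = 0.02)
  des <- study_design("cross_sectional", 50, c(5.5, 36),
                      scanner_gain_sd = 0.08, scanner_offset_sd = 0.03, seed = 6)
  tab <- generate_dataset(des, tr)
  expect_true(all(c("raw_value", "ref_low", "ref_high") %in% names(tab)))
  cal <- calibrate_ratio(tab$raw_value, tab$ref_high, tab$ref_low,
                         laminardev:::GROUP_REF_HIGH, laminardev:::GROUP_REF_LOW)
  expect_equal(cal, tab$value, tolerance = 1e-10)
})

test_that("structured truth carries the designed gradients", {
  h <- seq(0, 1, length.out = 12)
  for (ts in c("human", "macaque")) {
    tr <- structured_truth(1:12, h, n_depth_bins = 5, timescale = ts,
                           sigma = 0.05, delta = 0.001)
    p <- tr$params
    # rate strictly decreasing along the hierarchy at fixed depth
    for (b in 1:5) {
      rb <- p$rate[p$depth_bin == b][order(p$parcel_id[p$depth_bin == b])]
      expect_true(all(diff(rb) < 0))
    }
    # rate strictly decreasing with superficiality within each parcel
    for (pc in c(1, 6, 12)) {
      rp <- p$rate[p$parcel_id == pc][order(p$depth_bin[p$parcel_id == pc])]
      expect_true(all(diff(rp) < 0))
    }
    # true plateau strictly increasing with superficiality (delta = 0.001)
    tp <- true_plateau(tr)
    for (pc in c(1, 6, 12)) {
      pl <- tp$true_plateau[tp$parcel_id == pc][order(tp$depth_bin[tp$parcel_id == pc])]
      expect_true(all(diff(pl) > 0))
    }
  }
})

test_that("study_design and trajectory_truth validate their invariants", {
  expect_error(study_design("longitudinal", 10, c(0, 3)),
               class = "laminardev_invalid_parameter")
  expect_error(study_design("cross_sectional", 0, c(0, 3)),
               class = "laminardev_invalid_parameter")
  expect_error(study_design("cross_sectional", 10, c(3, 3)),
               class = "laminardev_invalid_parameter")
  base <- data.frame(parcel_id = 1, depth_bin = 1, baseline = 1,
                     amplitude = 0.1, rate = 0.1, onset = 0)
  bad <- base; bad$rate <- 0
  expect_error(trajectory_truth(bad), class = "laminardev_invalid_parameter")
  bad <- base; bad$amplitude <- -1
  expect_error(trajectory_truth(bad), class = "laminardev_invalid_parameter")
  expect_error(trajectory_truth(rbind(base, base)),
               class = "laminardev_invalid_parameter")
})

test_that("mesh and truth round-trip through their text formats", {
  m <- make_test_mesh(1, 2)
  path <- withr::local_tempfile(fileext = ".off")
  write_mesh_off(m, path)
  m2 <- read_mesh_off(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(m2$triangles, m$triangles)
  tr <- structured_truth(1:4, c(0, 0.3, 0.6, 1), 3)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_truth_json(tr, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$params$rate, tr$params$rate, tolerance = 1e-12)
  expect_equal(back$sigma, tr$sigma)
})
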