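test_that("signed distance follows the half-voxel face convention", {
  d <- c(6, 6, 20)
  region <- array(FALSE, d); region[, , 1:10] <- TRUE  # half-space z <= 10
  phi <- signed_distance(region, spacing = c(1, 1, 1))
  expect_equal(phi$data[3, 3, 7], 3.5)    # 3 mm + half-voxel placement
  expect_equal(phi$data[3, 3, 13], -2.5)
  expect_equal(phi$data[3, 3, 10], 0.5)   # innermost region plane
  expect_equal(phi$data[3, 3, 11], -0.5)
  # digital ball radius 8: centre value within 8 +/- 0.5 voxel
  db <- c(21, 21, 21)
  ctr <- which(array(TRUE, db), arr.ind = TRUE)
  r <- sqrt(rowSums(sweep(ctr, 2, 11)^2))
  ball <- array(r <= 8, db)
  phib <- signed_distance(ball, spacing = c(1, 1, 1))
  expect_lte(abs(phib$data[11, 11, 11] - 8), 0.5 + 1e-9)
  # complement antisymmetry is exact
  phin <- signed_distance(!ball, spacing = c(1, 1, 1))
  expect_equal(phin$data, -phib$data)
  expect_error(signed_distance(array(FALSE, c(4, 4, 4))), "empty")
  expect_error(signed_distance(array(TRUE, c(4, 4, 4))), "whole grid")
})

test_that("signed distance matches brute force on random blobs (anisotropic too)", {
  for (seed in 1:5) {
    blob <- random_blob(14, seed = seed)
    sp <- if (seed %% 2 == 0) c(0.7, 1, 1.3) else c(1, 1, 1)
    fast <- signed_distance(blob, spacing = sp)$data
    slow <- brute_force_signed_distance(blob, sp)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("levelset gradient magnitude is ~1 away from the medial axis", {
  ph <- small_sphere_labels(r = c(11, 9, 7), n = 30)
  phi <- signed_distance(ph$truth$labels$data >= 1, spacing = c(1, 1, 1))
  a <- phi$data
  d <- dim(a)
  gx <- (a[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] -
           a[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)]) / 2
  gy <- (a[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] -
           a[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)]) / 2
  gz <- (a[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]] -
           a[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)]) / 2
  gm <- sqrt(gx^2 + gy^2 + gz^2)
  inner <- a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  sel <- abs(inner) > 1.5 & inner < 8  # off the zero band and medial axis
  expect_true(all(gm[sel] >= 0.8 & gm[sel] <= 1.2))
  # |phi| bounded by the grid diagonal
  expect_lt(max(abs(a)), sqrt(sum((dim(a))^2)))
  # zero crossing sits on the label boundary: boundary voxels have
  # |phi| <= half the voxel diagonal
  reg <- ph$truth$labels$data >= 1
  bnd <- reg & !mcthick:::binary_erode(reg, mcthick:::offsets_face6())
  expect_true(all(abs(a[bnd]) <= sqrt(3) / 2 + 1e-9))
})

test_that("concentric spheres yield the analytic shell thicknesses", {
  ph <- small_sphere_labels(r = c(10, 8, 6), n = 28)
  nl <- labels_from_array(ph$truth$labels$data)
  maps <- cortical_thickness(nl)
  p <- maps$pial
  truth <- c(T = 4, G = 2, M = 2)
  for (met in names(truth)) {
    vals <- maps[[met]]$data[p]
    expect_lt(abs(mean(vals) - truth[[met]]), 0.5)  # pial mean
    expect_lt(max(abs(vals - truth[[met]])), 1)     # two digitized boundaries
  }
  expect_lt(abs(mean(maps$P$data[p]) - 0.5), 0.1)
  # identity T = G + M exact at every defined voxel
  def <- !is.na(maps$T$data)
  expect_lt(max(abs(maps$T$data[def] - maps$G$data[def] - maps$M$data[def])),
            1e-9)
  expect_true(all(maps$T$data[p] >= 0) && all(maps$G$data[p] >= 0))
  expect_true(all(maps$P$data[def] >= 0 & maps$P$data[def] <= 1))
})

test_that("coincident GM/mGM and mGM/WM boundaries give M = 0, T = G", {
  lab <- array(0L, c(20, 20, 20))
  ctr <- which(array(TRUE, c(20, 20, 20)), arr.ind = TRUE)
  r <- array(sqrt(rowSums(sweep(ctr, 2, 10.5)^2)), c(20, 20, 20))
  lab[r <= 8] <- 1L
  lab[r <= 5] <- 3L  # WM directly inside GM: empty mGM shell
  maps <- cortical_thickness(labels_from_array(lab))
  p <- maps$pial
  expect_equal(maps$M$data[p], rep(0, sum(p)))
  expect_equal(maps$T$data[p], maps$G$data[p])
  expect_equal(maps$P$data[p], rep(0, sum(p)))
})

test_that("proportional thickness is direct arithmetic", {
  # T = 4, M = 2 -> P = 0.5 via a flat slab with exact layer geometry
  lab <- array(0L, c(10, 10, 24))
  lab[, , 3:12] <- 3L
  lab[, , 13:14] <- 2L
  lab[, , 15:16] <- 1L
  maps <- cortical_thickness(labels_from_array(lab))
  # central column, pial voxel at z = 16
  expect_equal(maps$T$data[5, 5, 16], 4)
  expect_equal(maps$M$data[5, 5, 16], 2)
  expect_equal(maps$P$data[5, 5, 16], 0.5)
})

test_that("integer translation shifts thickness maps without changing values", {
  ph <- small_sphere_labels(r = c(9, 7, 5), n = 30)
  lab <- ph$truth$labels$data
  sh <- array(0L, dim(lab))
  sh[4:30, 3:30, 2:30] <- lab[1:27, 1:28, 1:29]
  m1 <- cortical_thickness(labels_from_array(lab))
  m2 <- cortical_thickness(labels_from_array(sh))
  a1 <- m1$T$data[1:27, 1:28, 1:29]
  a2 <- m2$T$data[4:30, 3:30, 2:30]
  expect_equal(a2, a1)
})

test_that("halving the voxel size does not worsen the sphere recovery", {
  r <- c(10, 8, 6)
  err <- function(spacing, n) {
    spec <- phantom_spec(r_pial = r[1], r_gm_mgm = r[2], r_wm_inner = r[3],
                         noise_sd = 0, spacing = spacing, shape = n,
                         seed = 1)
    ph <- generate_phantom(spec)
    nl <- mcthick:::new_nested_labels(
      array(as.integer(ph$truth$labels$data), dim(ph$truth$labels$data)),
      rep(spacing, 3), diag(c(rep(spacing, 3), 1)))
    maps <- cortical_thickness(nl)
    abs(maps$qc$pial_mean[c("T", "G", "M")] - c(4, 2, 2))
  }
  e1 <- err(1, 28)
  e05 <- err(0.5, 56)
  # allow the sub-0.01 mm discretization noise floor (M is already there)
  expect_true(all(e05 <= e1 + 0.01))
})

test_that("one-voxel-thick cortex stays finite and non-negative", {
  lab <- array(0L, c(12, 12, 12))
  lab[4:9, 4:9, 4:9] <- 3L
  shell <- array(0L, dim(lab))
  shell[3:10, 3:10, 3:10] <- 1L
  lab[shell == 1L & lab == 0L] <- 1L
  maps <- cortical_thickness(labels_from_array(lab))
  p <- maps$pial
  expect_true(all(is.finite(maps$T$data[p])))
  expect_true(all(maps$T$data[p] >= 0))
})

test_that("surface sampling is a nearest-neighbour identity lookup", {
  ph <- small_sphere_labels(r = c(10, 8, 6), n = 28)
  maps <- cortical_thickness(labels_from_array(ph$truth$labels$data))
  # sampling at pial voxels returns their own values
  tab <- sample_metric_on_surface(maps, "T", maps$pial)
  expect_equal(nrow(tab), sum(maps$pial))
  expect_false(any(tab$outside_cortex))
  expect_lt(abs(mean(tab$value) - 4), 0.5)
  one <- which(maps$pial, arr.ind = TRUE)[1, , drop = FALSE]
  t1 <- sample_metric_on_surface(maps, "T", one)
  expect_equal(t1$value, maps$T$data[one])
  # voxels outside the cortex are flagged
  out <- sample_metric_on_surface(maps, "T", matrix(c(1L, 1L, 1L), 1))
  expect_true(out$outside_cortex)
  # empty surface set -> empty table
  empty <- sample_metric_on_surface(maps, "T", array(FALSE, dim(maps$pial)))
  expect_equal(nrow(empty), 0)
  expect_error(sample_metric_on_surface(maps, "T", matrix(c(99L, 1L, 1L), 1)),
               "outside the grid")
})
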