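test_that("noiseless three-class phantom is segmented exactly with beta = 0", {
  ph <- small_sphere_labels()
  mem <- fcm_segment(ph$ratio, ph$truth$mask, tol = 1e-12, max_iter = 300)
  expect_equal(mem$centroids, c(1, 2, 3), tolerance = 1e-6)
  # voxels at a centroid get a one-hot membership
  m <- mem$mask
  usum <- mem$u$gm$data[m] + mem$u$mgm$data[m] + mem$u$wm$data[m]
  expect_true(all(abs(usum - 1) < 1e-6))
  lab_true <- ph$truth$labels$data
  expect_true(all(mem$u$gm$data[lab_true == 1] > 1 - 1e-6))
  expect_true(all(mem$u$mgm$data[lab_true == 2] > 1 - 1e-6))
  expect_true(all(mem$u$wm$data[lab_true == 3] > 1 - 1e-6))
  # hard labels reproduce the generating classes exactly before morphology
  lab <- build_nested_labels(mem)
  expect_identical(lab$labels$data, lab_true)
  # objective trace is non-increasing
  expect_true(all(diff(mem$objective) <= 1e-9 * abs(mem$objective[-1]) + 1e-12))
})

test_that("FCM matches a brute-force minimizer on a tiny 1D instance", {
  y <- c(1, 1, 2, 2, 3, 3)
  v <- vol3d(array(y, c(6, 1, 1)))
  mem <- fcm_segment(v, as_mask(array(1, c(6, 1, 1))), tol = 1e-14,
                     max_iter = 500)
  oracle <- brute_force_fcm(y, restarts = 50, seed = 11)
  expect_equal(mem$centroids, oracle$centroids, tolerance = 1e-4)
  # implementation's final objective is as good as the oracle's
  expect_lte(tail(mem$objective, 1), oracle$objective + 1e-8)
  # at this optimum each value sits on a centroid: one-hot memberships
  expect_equal(mem$u$gm$data[1:2], c(1, 1), tolerance = 1e-6)
  expect_equal(mem$u$mgm$data[3:4], c(1, 1), tolerance = 1e-6)
  expect_equal(mem$u$wm$data[5:6], c(1, 1), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  v <- vol3d(array(1, c(5, 5, 5)))
  expect_error(fcm_segment(v, as_mask(array(1, c(5, 5, 5)))), "distinct")
  expect_error(fcm_segment(vol3d(array(1:125 / 125, c(5, 5, 5))),
                           fuzziness = 1), "fuzziness")
})

test_that("spatial regularization keeps the objective monotone and removes salt noise", {
  spec <- phantom_spec(r_pial = 11, r_gm_mgm = 8.5, r_wm_inner = 6.5,
                       noise_sd = 0, shape = 30, seed = 2)
  ph <- generate_phantom(spec)
  # salt noise: flip a fixed 2% of mask voxels far off their class value
  set.seed(99)
  m <- which(ph$truth$mask$data == 1)
  flip <- sample(m, round(0.02 * length(m)))
  ratio <- ph$ratio
  ratio$data[flip] <- ratio$data[flip] + 1  # push one class up
  # count isolated misclassified voxels: argmax-membership label differs
  # from the truth and from every 6-neighbour label (salt specks)
  isolated_errors <- function(beta) {
    mem <- fcm_segment(ratio, ph$truth$mask, beta = beta, tol = 1e-10,
                       max_iter = 300)
    expect_true(all(diff(mem$objective) <=
                      1e-8 * abs(mem$objective[-1]) + 1e-10))
    u <- array(0, c(dim(ph$ratio$data), 3))
    for (k in 1:3) u[, , , k] <- mem$u[[k]]$data
    hard <- array(max.col(matrix(u, ncol = 3)), dim(ph$ratio$data))
    hard[!mem$mask] <- 0L
    diff_all_nb <- array(TRUE, dim(hard))
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      nb <- mcthick:::shift_array_num(hard, off)
      diff_all_nb <- diff_all_nb & (nb != hard | nb == 0)
    }
    sum(mem$mask & hard != ph$truth$labels$data & diff_all_nb)
  }
  e0 <- isolated_errors(0)
  e1 <- isolated_errors(0.3)
  expect_lt(e1, e0)
})

test_that("class order of the initial centroids does not change the result", {
  y <- c(rep(1, 20), rep(2.2, 20), rep(3.1, 20)) + seq(-0.01, 0.01,
                                                       length.out = 60)
  fit_a <- mcthick:::fcm_run(y, rep(TRUE, 60), c(60, 1, 1),
                             centroids = c(1, 2.2, 3.1), q = 2, beta = 0,
                             tol = 1e-12, max_iter = 300)
  fit_b <- mcthick:::fcm_run(y, rep(TRUE, 60), c(60, 1, 1),
                             centroids = c(3.1, 1, 2.2), q = 2, beta = 0,
                             tol = 1e-12, max_iter = 300)
  expect_equal(sort(fit_a$centroids), sort(fit_b$centroids),
               tolerance = 1e-8)
})

test_that("threshold semantics: strict, sequential, innermost first", {
  # three single-voxel cases embedded in a 3-voxel volume
  u_wm <- array(c(0.15, 0.10, 0.00), c(3, 1, 1))
  u_mgm <- array(c(0.85, 0.55, 0.00), c(3, 1, 1))
  u_gm <- array(c(0.00, 0.35, 1.00), c(3, 1, 1))
  mem <- make_membership_set(u_gm, u_mgm, u_wm)
  lab <- build_nested_labels(mem)  # thresholds 0.1 / 0.5 / 0.5
  # 0.15 > 0.1 -> WM wins although mGM membership dominates
  # 0.10 is not > 0.1 -> falls through to mGM
  # pure GM voxel -> GM
  expect_equal(as.vector(lab$labels$data), c(3L, 2L, 1L))
  expect_error(build_nested_labels(mem, wm_threshold = 0), "strictly")
  expect_error(build_nested_labels(mem, gm_threshold = 1), "strictly")
  # voxels passing no threshold stay background
  lab0 <- build_nested_labels(make_membership_set(
    array(0.4, c(1, 1, 1)), array(0.35, c(1, 1, 1)),
    array(0.05, c(1, 1, 1))))
  expect_equal(as.vector(lab0$labels$data), 0L)
})

test_that("loosening the WM threshold grows WM without moving the GM/mGM boundary", {
  # membership profile along z mimicking a cortical column: GM, mGM, a
  # partial-volume band at the WM interface (high mGM, intermediate WM
  # membership), then WM
  d <- c(8, 8, 12)
  u_gm <- array(0, d); u_mgm <- array(0, d); u_wm <- array(0, d)
  u_gm[, , 1:3] <- 0.9; u_mgm[, , 1:3] <- 0.08; u_wm[, , 1:3] <- 0.02
  u_gm[, , 4:6] <- 0.08; u_mgm[, , 4:6] <- 0.9; u_wm[, , 4:6] <- 0.02
  u_gm[, , 7:8] <- 0.05; u_mgm[, , 7:8] <- 0.65; u_wm[, , 7:8] <- 0.3
  u_gm[, , 9:12] <- 0.02; u_mgm[, , 9:12] <- 0.08; u_wm[, , 9:12] <- 0.9
  mem <- make_membership_set(u_gm, u_mgm, u_wm)
  strict <- build_nested_labels(mem, wm_threshold = 0.5)
  loose <- build_nested_labels(mem, wm_threshold = 0.1)
  # the partial-volume band flips mGM -> WM
  expect_gt(sum(region_wm(loose)), sum(region_wm(strict)))
  expect_true(all(region_wm(strict) <= region_wm(loose)))
  # ... but the inner (GM/mGM) region, hence its boundary, is unchanged
  expect_identical(region_inner(loose), region_inner(strict))
})

test_that("largest-component cleanup demotes disconnected WM to mGM", {
  lab <- array(0L, c(20, 20, 20))
  lab[2:19, 2:19, 2:19] <- 1L
  lab[4:16, 4:16, 4:16] <- 2L
  lab[5:9, 5:9, 5:9] <- 3L        # 125-voxel WM blob
  lab[13:14, 13:14, 13:13] <- 3L  # disjoint 4-voxel WM blob
  nl <- labels_from_array(lab)
  out <- keep_largest_component(nl)
  expect_equal(sum(region_wm(out)), 125)
  expect_equal(out$labels$data[13, 13, 13], 2L)
  expect_nested(out)
  # agreement with an independent BFS labelling
  comp <- brute_force_components(lab == 3L)
  expect_equal(max(comp), 2)
  expect_equal(sum(comp == 1), 125)
  # already-connected WM is untouched
  lab2 <- lab; lab2[13:14, 13:14, 13:13] <- 2L
  nl2 <- labels_from_array(lab2)
  expect_identical(keep_largest_component(nl2)$labels$data,
                   nl2$labels$data)
})

test_that("equal-size components: the first in scan order is kept", {
  lab <- array(0L, c(12, 12, 12))
  lab[2:11, 2:11, 2:11] <- 2L
  lab[3, 3, 3] <- 3L
  lab[9, 9, 9] <- 3L
  out <- keep_largest_component(labels_from_array(lab))
  expect_equal(out$labels$data[3, 3, 3], 3L)
  expect_equal(out$labels$data[9, 9, 9], 2L)
})

test_that("morphological smoothing removes sub-kernel features only", {
  # solid ball: essentially unchanged (<= 1-voxel boundary shift)
  ph <- small_sphere_labels(r = c(12, 9, 7), n = 30)
  nl <- labels_from_array(ph$truth$labels$data)
  sm <- smooth_inner_boundary(nl, kernel_mm = 2)
  changed <- sum(sm$labels$data != nl$labels$data)
  inner <- region_inner(nl)
  boundary <- inner & !mcthick:::binary_erode(inner, mcthick:::offsets_face6())
  expect_lte(changed, sum(boundary))  # only boundary-shell voxels may move
  expect_nested(sm)
  # isolated single mGM voxel is opened away
  lab <- array(0L, c(14, 14, 14))
  lab[2:13, 2:13, 2:13] <- 1L
  lab[4:10, 4:10, 4:10] <- 2L
  lab[5:9, 5:9, 5:9] <- 3L
  lab[12, 12, 12] <- 2L  # isolated speck
  out <- smooth_inner_boundary(labels_from_array(lab), kernel_mm = 2)
  expect_equal(out$labels$data[12, 12, 12], 1L)
  expect_nested(out)
  # 2 mm kernel at 1 mm spacing -> ball radius 1 voxel (7 offsets)
  offs <- mcthick:::ball_offsets_mm(1, c(1, 1, 1))
  expect_equal(nrow(offs), 7)
  expect_true(all(rowSums(abs(offs)) <= 1))
})

test_that("pial-voxel stripping confines inner tissue to the eroded cortex", {
  # slab 10 voxels thick, inner tissue everywhere: after stripping, the
  # inner region is confined to the central 8 planes
  lab <- array(0L, c(12, 12, 14))
  lab[, , 3:12] <- 2L
  nl <- labels_from_array(lab)
  out <- strip_pial_voxels(nl)
  inner <- region_inner(out)
  expect_true(all(which(inner, arr.ind = TRUE)[, 3] %in% 4:11))
  expect_nested(out)
  # interior inner region: no-op
  lab2 <- array(0L, c(12, 12, 12))
  lab2[2:11, 2:11, 2:11] <- 1L
  lab2[4:9, 4:9, 4:9] <- 2L
  nl2 <- labels_from_array(lab2)
  expect_identical(strip_pial_voxels(nl2)$labels$data, nl2$labels$data)
  # an mGM voxel on the outer shell is demoted to GM
  lab3 <- lab2; lab3[2, 5, 5] <- 2L
  out3 <- strip_pial_voxels(labels_from_array(lab3))
  expect_equal(out3$labels$data[2, 5, 5], 1L)
})
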