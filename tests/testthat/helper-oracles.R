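# Independent brute-force oracles used to cross-check the fast
# implementations, plus small fixture builders. All fixtures are built in
# code at test time.

# signed distance by exhaustive search over voxel centres of the opposite
# class, with the same half-voxel boundary offset convention
brute_force_signed_distance <- function(region, spacing) {
  d <- dim(region)
  ctr <- which(array(TRUE, d), arr.ind = TRUE)
  ctr <- sweep(ctr, 2, spacing, `*`)
  fg <- ctr[which(region), , drop = FALSE]
  bg <- ctr[which(!region), , drop = FALSE]
  off <- 0.5 * min(spacing)
  mind <- function(p, sites) {
    min(sqrt((sites[, 1] - p[1])^2 + (sites[, 2] - p[2])^2 +
               (sites[, 3] - p[3])^2))
  }
  phi <- array(NA_real_, d)
  idx <- which(region)
  for (i in idx) phi[i] <- mind(ctr[i, ], bg) - off
  idx <- which(!region)
  for (i in idx) phi[i] <- -(mind(ctr[i, ], fg) - off)
  phi
}

# 26-connectivity components by plain BFS in R
brute_force_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(p, d)
      for (r in seq_len(nrow(nb))) {
        q <- ijk + nb[r, ]
        if (any(q < 1) || any(q > d)) next
        ql <- (q[3] - 1) * d[1] * d[2] + (q[2] - 1) * d[1] + q[1]
        if (mask[ql] && lab[ql] == 0L) {
          lab[ql] <- nxt
          queue <- c(queue, ql)
        }
      }
    }
  }
  lab
}

# random smooth 3D blob: thresholded sum of a few random Gaussian bumps
random_blob <- function(n = 20, seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  f <- 0
  for (b in 1:4) {
    c0 <- runif(3, n * 0.25, n * 0.75)
    s0 <- runif(1, n / 8, n / 4)
    f <- f + exp(-((g$x - c0[1])^2 + (g$y - c0[2])^2 +
                     (g$z - c0[3])^2) / (2 * s0^2))
  }
  blob <- array(f > quantile(f, 0.8), c(n, n, n))
  # guarantee both classes present
  if (!any(blob)) blob[n / 2, n / 2, n / 2] <- TRUE
  if (all(blob)) blob[1, 1, 1] <- FALSE
  blob
}

# reduced fuzzy c-means objective (q = 2, beta = 0) as a function of the
# centroids only, minimized by random-restart Nelder-Mead
brute_force_fcm <- function(y, k = 3, restarts = 50, seed = 1) {
  set.seed(seed)
  J <- function(cc) {
    s <- 0
    for (yi in y) {
      d <- (yi - cc)^2
      if (any(d == 0)) next
      s <- s + 1 / sum(1 / d)
    }
    s
  }
  best <- NULL
  rng <- range(y)
  for (r in seq_len(restarts)) {
    c0 <- sort(runif(k, rng[1], rng[2]))
    o <- optim(c0, J, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(centroids = sort(best$par), objective = best$value)
}

# membership_set built directly from given membership arrays (for testing
# the thresholding semantics in isolation)
make_membership_set <- function(u_gm, u_mgm, u_wm, spacing = c(1, 1, 1)) {
  mask <- !is.na(u_gm)
  mk <- function(a) mcthick::vol3d(a, spacing = spacing, unit = "probability")
  structure(list(u = list(gm = mk(u_gm), mgm = mk(u_mgm), wm = mk(u_wm)),
                 centroids = c(1, 2, 3),
                 objective = c(1, 0.5), converged = TRUE, iterations = 2,
                 mask = mask,
                 params = list(n_classes = 3, fuzziness = 2, beta = 0,
                               tol = 1e-8, max_iter = 100)),
            class = "membership_set")
}

# nested_labels from a plain integer array
labels_from_array <- function(lab, spacing = c(1, 1, 1)) {
  mcthick:::new_nested_labels(array(as.integer(lab), dim(lab)), spacing,
                              diag(c(spacing, 1)))
}

# small noiseless three-layer sphere used across tests
small_sphere_labels <- function(r = c(10, 8, 6), n = 28) {
  spec <- phantom_spec(r_pial = r[1], r_gm_mgm = r[2], r_wm_inner = r[3],
                       noise_sd = 0, shape = n, seed = 1)
  generate_phantom(spec)
}

# vectorized Monte-Carlo power of the pooled two-sample two-sided t-test
mc_power <- function(delta, sd, n, alpha, reps, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(reps * n, 0, sd), reps)
  y <- matrix(rnorm(reps * n, delta, sd), reps)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, var); vy <- apply(y, 1, var)
  sp <- sqrt((vx + vy) / 2)
  tstat <- (my - mx) / (sp * sqrt(2 / n))
  crit <- qt(1 - alpha / 2, df = 2 * n - 2)
  mean(abs(tstat) > crit)
}

expect_nested <- function(labels) {
  expect_true(all(region_wm(labels) <= region_inner(labels)))
  expect_true(all(region_inner(labels) <= region_cortex(labels)))
}
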