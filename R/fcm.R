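#' Spatially regularized fuzzy c-means tissue segmentation
#'
#' Clusters the cerebrum-masked ratio image into `n_classes` intensity
#' classes by minimizing
#' \deqn{J = \sum_i \sum_k u_{ik}^q (y_i - c_k)^2 +
#'       \frac{\beta}{2} \sum_i \sum_k u_{ik}^q
#'       \sum_{n \in N_i} \sum_{m \ne k} u_{mn}^q}
#' where \eqn{u_{ik}} are per-voxel class memberships (summing to 1),
#' \eqn{c_k} class centroid intensities, \eqn{q > 1} the fuzziness exponent
#' and \eqn{N_i} the 6-neighbourhood of voxel \eqn{i}. The neighbourhood
#' penalty discourages a voxel from committing to a class its neighbours
#' reject; with `beta = 0` the algorithm reduces to plain fuzzy c-means,
#' which is the verifiable limit used by the test suite.
#'
#' Centroids are initialized deterministically at the 25th/50th/75th
#' intensity percentiles of the masked image (evenly spread percentiles for
#' other class counts); `seed` only matters when `n_restarts > 0`, which
#' adds randomly jittered restarts and keeps the best objective. Classes in
#' the returned object are sorted by centroid, so for three classes GM is
#' the lowest intensity and WM the highest (T1-weighted signal increases
#' with myelin content).
#'
#' @param ratio Ratio image ([vol3d]); background 0 outside the mask.
#' @param mask Cerebrum mask; defaults to `ratio != 0`.
#' @param n_classes Number of tissue classes (default 3: GM, mGM, WM).
#' @param fuzziness Exponent `q > 1` (default 2).
#' @param beta Spatial regularization weight `>= 0` (default 0 = off).
#' @param tol Convergence tolerance on the relative objective change.
#' @param max_iter Iteration cap; non-convergence yields a warning and the
#'   best iterate.
#' @param n_restarts Extra randomly initialized restarts (default 0).
#' @param seed RNG seed used only for restarts.
#' @return An object of class `membership_set`: per-class membership
#'   volumes (`$u`, named `gm`/`mgm`/`wm` for 3 classes), sorted
#'   `$centroids`, the per-iteration `$objective` trace, `$converged`,
#'   `$mask` and the call parameters.
#' @export
fcm_segment <- function(ratio, mask = NULL, n_classes = 3, fuzziness = 2,
                        beta = 0, tol = 1e-8, max_iter = 200,
                        n_restarts = 0, seed = NULL) {
  if (!is_vol3d(ratio)) ratio <- vol3d(ratio)
  if (is.null(mask)) {
    m <- ratio$data != 0
  } else {
    if (!inherits(mask, "mask_vol3d"))
      mask <- as_mask(mask, spacing = ratio$spacing, affine = ratio$affine)
    stop_if_incompatible(ratio, mask, what = "ratio/mask")
    m <- mask_logical(mask)
  }
  if (sum(m) < n_classes) stop("mask has fewer voxels than classes")
  y <- ratio$data[m]
  if (length(unique(y)) < n_classes)
    stop("degenerate clustering input: fewer than ", n_classes,
         " distinct intensities inside the mask (constant image?)")
  if (fuzziness <= 1) stop("`fuzziness` must be > 1")
  if (beta < 0) stop("`beta` must be >= 0")

  probs <- seq(0.25, 0.75, length.out = n_classes)
  init0 <- unname(stats::quantile(y, probs))
  if (any(diff(init0) <= 1e-12 * diff(range(y)))) {
    # strongly unbalanced class volumes can collapse two percentile
    # centroids onto one value; spread the initial centroids evenly instead
    init0 <- seq(min(y), max(y),
                 length.out = n_classes + 2)[seq_len(n_classes) + 1]
  }
  inits <- list(init0)
  if (n_restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    rng <- diff(range(y))
    for (r in seq_len(n_restarts))
      inits[[r + 1L]] <- sort(inits[[1]] + stats::runif(n_classes, -0.2, 0.2) * rng)
  }

  best <- NULL
  for (init in inits) {
    fit <- fcm_run(y, m, dim(ratio$data), init, q = fuzziness, beta = beta,
                   tol = tol, max_iter = max_iter)
    if (is.null(best) || utils::tail(fit$objective, 1) < utils::tail(best$objective, 1))
      best <- fit
  }
  fit <- best
  if (!fit$converged)
    warning("FCM did not converge in ", max_iter,
            " iterations; returning best iterate")

  ord <- order(fit$centroids)
  cls_names <- if (n_classes == 3) c("gm", "mgm", "wm")
               else paste0("class", seq_len(n_classes))
  u <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    a <- array(NA_real_, dim(ratio$data))
    a[!m] <- NA
    a[m] <- fit$u[, ord[k]]
    u[[k]] <- vol3d(a, spacing = ratio$spacing, affine = ratio$affine,
                    unit = "probability")
  }
  names(u) <- cls_names
  structure(list(u = u, centroids = fit$centroids[ord],
                 objective = fit$objective, converged = fit$converged,
                 iterations = length(fit$objective),
                 mask = m,
                 params = list(n_classes = n_classes, fuzziness = fuzziness,
                               beta = beta, tol = tol, max_iter = max_iter)),
            class = "membership_set")
}

#' @export
print.membership_set <- function(x, ...) {
  cat(sprintf("<membership_set> %d classes, centroids: %s\n",
              x$params$n_classes,
              paste(signif(x$centroids, 6), collapse = ", ")))
  cat(sprintf("  %d iterations, converged: %s, final objective %.6g\n",
              x$iterations, x$converged, utils::tail(x$objective, 1)))
  invisible(x)
}

# core alternating optimization on the masked voxel vector.
# memberships are updated from the current centroids (and, for beta > 0,
# the previous iteration's neighbour memberships, Pham-style), then
# centroids from the memberships; the objective is evaluated after each
# full sweep.
fcm_run <- function(y, m, dims, centroids, q, beta, tol, max_iter) {
  k <- length(centroids)
  nmv <- length(y)
  expn <- -1 / (q - 1)
  u <- NULL
  pen <- matrix(0, nmv, k)  # neighbourhood penalty term per voxel/class
  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d_data <- outer(y, centroids, function(a, b) (a - b)^2)
    d <- d_data + beta * pen
    u <- membership_update(d, expn)
    uq <- u^q
    centroids <- colSums(uq * y) / colSums(uq)
    d_data <- outer(y, centroids, function(a, b) (a - b)^2)
    if (beta > 0) pen <- neighbour_penalty(uq, m, dims)
    J <- sum(uq * d_data) + (beta / 2) * sum(uq * pen)
    obj <- c(obj, J)
    if (it > 1) {
      prev <- obj[it - 1]
      if (abs(prev - J) <= tol * max(abs(prev), .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  list(u = u, centroids = centroids, objective = obj, converged = converged)
}

membership_update <- function(d, expn) {
  # voxels sitting exactly on a centroid get a one-hot membership
  zero <- d <= 0
  anyz <- rowSums(zero) > 0
  w <- d
  w[!zero] <- d[!zero]^expn
  u <- w / rowSums(w)
  if (any(anyz)) {
    zi <- which(anyz)
    u[zi, ] <- zero[zi, , drop = FALSE] / rowSums(zero[zi, , drop = FALSE])
  }
  u
}

# pen[i,k] = sum over 6-neighbours n of sum_{m != k} u_mn^q,
# computed by embedding u^q in the volume (0 outside the mask, so
# out-of-mask neighbours contribute nothing).
neighbour_penalty <- function(uq, m, dims) {
  k <- ncol(uq)
  vols <- vector("list", k)
  s_tot <- array(0, dims)
  for (j in seq_len(k)) {
    a <- array(0, dims)
    a[m] <- uq[, j]
    vols[[j]] <- neighbour_sum6(a)
    s_tot <- s_tot + vols[[j]]
  }
  pen <- matrix(0, sum(m), k)
  for (j in seq_len(k))
    pen[, j] <- (s_tot - vols[[j]])[m]
  pen
}

neighbour_sum6 <- function(a) {
  out <- array(0, dim(a))
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out + shift_array_num(a, off)
  out
}

# value at voxel p of the result is a[p - off]; zero fill at edges
shift_array_num <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]; n <- d[ax]
    if (abs(o) >= n) return(out)
    if (o >= 0) { dst[[ax]] <- seq(1 + o, n); src[[ax]] <- seq(1, n - o) }
    else        { dst[[ax]] <- seq(1, n + o); src[[ax]] <- seq(1 - o, n) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
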