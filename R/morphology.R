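# Binary morphology on 3D logical arrays via array shifting.
# Outside the grid counts as background for both erosion and dilation.

shift_array_lgl <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
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

# offsets (rows) of a Euclidean ball of radius_mm, in voxel steps.
# Always contains at least the centre + 6 face neighbours so a sub-voxel
# radius still yields a usable structuring element.
ball_offsets_mm <- function(radius_mm, spacing) {
  r <- max(radius_mm, min(spacing))
  nmax <- floor(r / spacing)
  g <- expand.grid(i = -nmax[1]:nmax[1], j = -nmax[2]:nmax[2],
                   k = -nmax[3]:nmax[3])
  keep <- sqrt((g$i * spacing[1])^2 + (g$j * spacing[2])^2 +
                 (g$k * spacing[3])^2) <= r + 1e-9
  offs <- as.matrix(g[keep, , drop = FALSE])
  face <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  offs <- unique(rbind(offs, face))
  dimnames(offs) <- NULL
  offs
}

offsets_face6 <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

binary_erode <- function(a, offs) {
  out <- array(TRUE, dim(a))
  for (r in seq_len(nrow(offs)))
    out <- out & shift_array_lgl(a, -offs[r, ])
  out
}

binary_dilate <- function(a, offs) {
  out <- array(FALSE, dim(a))
  for (r in seq_len(nrow(offs)))
    out <- out | shift_array_lgl(a, offs[r, ])
  out
}

binary_open <- function(a, offs) binary_dilate(binary_erode(a, offs), offs)
binary_close <- function(a, offs) binary_erode(binary_dilate(a, offs), offs)

# 26-connectivity component labelling (Rcpp flood fill)
label_components <- function(mask) {
  label_components_cpp(mask, dim(mask))
}
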