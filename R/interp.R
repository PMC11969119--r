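# Point location and interpolation on the structured block maps.
#
# Every mesh block is a mapped rectangle: columns at fixed x stations and a
# fixed cross-fraction grid between two boundary curves. A physical point is
# located by its column interval and its normalized cross coordinate
# eta = (y - y_lo(x)) / (y_hi(x) - y_lo(x)), and nodal fields are
# interpolated bilinearly in (x, eta).

# locate points: returns list(block, k, xi, eta) with NA block when outside
# the lumen. Points strictly inside a block are assigned directly; points
# slightly outside every block (within eta_tol of a wall, or anywhere in
# `nearest` mode) are assigned to the block with the smallest wall
# overshoot, with eta clamped into [0, 1].
.locate_points <- function(mesh, px, py, tol = 1e-9, eta_tol = 0.02,
                           nearest = FALSE) {
  np <- length(px)
  blk <- rep(NA_integer_, np)
  kk <- rep(NA_integer_, np); xi <- rep(NA_real_, np); eta <- rep(NA_real_, np)
  best_v <- rep(Inf, np)
  bb <- rep(NA_integer_, np); bk <- rep(NA_integer_, np)
  bxi <- rep(NA_real_, np); beta <- rep(NA_real_, np)
  for (bi in seq_along(mesh$blocks)) {
    b <- mesh$blocks[[bi]]
    cand <- which(is.na(blk) & px >= b$xcols[1] - tol &
                    px <= b$xcols[length(b$xcols)] + tol)
    if (!length(cand)) next
    x <- pmin(pmax(px[cand], b$xcols[1]), b$xcols[length(b$xcols)])
    k <- findInterval(x, b$xcols, all.inside = TRUE)
    x0 <- b$xcols[k]; x1 <- b$xcols[k + 1]
    t_ <- (x - x0) / (x1 - x0)
    nr <- ncol(b$idx)
    ylo <- (1 - t_) * mesh$nodes[b$idx[k, 1], 2] +
      t_ * mesh$nodes[b$idx[k + 1, 1], 2]
    yhi <- (1 - t_) * mesh$nodes[b$idx[k, nr], 2] +
      t_ * mesh$nodes[b$idx[k + 1, nr], 2]
    e <- (py[cand] - ylo) / (yhi - ylo)
    inside <- e >= -1e-9 & e <= 1 + 1e-9
    sel <- cand[inside]
    blk[sel] <- bi; kk[sel] <- k[inside]; xi[sel] <- t_[inside]
    eta[sel] <- pmin(pmax(e[inside], 0), 1)
    # remember the nearest block for the rest
    v <- pmax(-e, e - 1)
    out <- which(!inside & v < best_v[cand])
    selo <- cand[out]
    best_v[selo] <- v[out]
    bb[selo] <- bi; bk[selo] <- k[out]; bxi[selo] <- t_[out]
    beta[selo] <- pmin(pmax(e[out], 0), 1)
  }
  fix <- is.na(blk) & !is.na(bb) & (if (nearest) TRUE else best_v <= eta_tol)
  blk[fix] <- bb[fix]; kk[fix] <- bk[fix]
  xi[fix] <- bxi[fix]; eta[fix] <- beta[fix]
  list(block = blk, k = kk, xi = xi, eta = eta)
}

#' Interpolate nodal fields at arbitrary points
#'
#' Bilinear interpolation on the structured block maps of the mesh. Points
#' outside the lumen yield `NA`.
#'
#' @param mesh A `mesh2d`.
#' @param values Numeric vector (one value per mesh node) or a matrix with
#'   one column per field.
#' @param px,py Point coordinates (m).
#' @return A vector (or matrix) of interpolated values.
#' @export
interpolate_field <- function(mesh, values, px, py) {
  values <- as.matrix(values)
  loc <- .locate_points(mesh, px, py)
  out <- matrix(NA_real_, length(px), ncol(values))
  ok <- which(!is.na(loc$block))
  if (!length(ok)) return(drop(out))
  for (bi in unique(loc$block[ok])) {
    b <- mesh$blocks[[bi]]
    sel <- ok[loc$block[ok] == bi]
    k <- loc$k[sel]; xi <- loc$xi[sel]; eta <- loc$eta[sel]
    j <- findInterval(eta, b$f, all.inside = TRUE)
    z <- (eta - b$f[j]) / (b$f[j + 1] - b$f[j])
    n00 <- b$idx[cbind(k, j)];     n10 <- b$idx[cbind(k + 1, j)]
    n01 <- b$idx[cbind(k, j + 1)]; n11 <- b$idx[cbind(k + 1, j + 1)]
    w00 <- (1 - xi) * (1 - z); w10 <- xi * (1 - z)
    w01 <- (1 - xi) * z;       w11 <- xi * z
    out[sel, ] <- w00 * values[n00, , drop = FALSE] +
      w10 * values[n10, , drop = FALSE] +
      w01 * values[n01, , drop = FALSE] +
      w11 * values[n11, , drop = FALSE]
  }
  drop(out)
}
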