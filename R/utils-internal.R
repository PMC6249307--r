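# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_msipk <- function(msg, class) {
  rlang::abort(msg, class = c(class, "msipk_error"))
}

assert_that <- function(cond, msg, class = "msipk_invalid_argument") {
  if (!isTRUE(cond)) abort_msipk(msg, class)
  invisible(TRUE)
}

# Run code with a temporary RNG state seeded at `seed`; restores the caller's
# state so generators never perturb user RNG streams.
with_seed <- function(seed, code) {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Filled ellipse mask on an nrow x ncol grid. center/radii in (row, col) px.
ellipse_mask <- function(nrow, ncol, center, radii, angle = 0) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  dr <- rr - center[1]
  dc <- cc - center[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- dr * ca + dc * sa
  v <- -dr * sa + dc * ca
  (u / radii[1])^2 + (v / radii[2])^2 <= 1
}

# Binary erosion with a (2*depth+1)^2 square structuring element.
erode_square <- function(mask, depth) {
  out <- mask
  for (i in seq_len(depth)) {
    m <- out
    n <- nrow(m); p <- ncol(m)
    pad <- matrix(FALSE, n + 2, p + 2)
    pad[2:(n + 1), 2:(p + 1)] <- m
    out <- pad[2:(n + 1), 2:(p + 1)] &
      pad[1:n, 2:(p + 1)] & pad[3:(n + 2), 2:(p + 1)] &
      pad[2:(n + 1), 1:p] & pad[2:(n + 1), 3:(p + 2)] &
      pad[1:n, 1:p] & pad[1:n, 3:(p + 2)] &
      pad[3:(n + 2), 1:p] & pad[3:(n + 2), 3:(p + 2)]
  }
  out
}

dilate_square <- function(mask, depth) {
  !erode_square(!mask, depth)
}

# Separable box blur used for smooth phantom fields (not a user-facing filter).
box_blur <- function(m, radius) {
  if (radius < 1) return(m)
  k <- 2 * radius + 1
  n <- nrow(m); p <- ncol(m)
  padded <- m[pmin(pmax(seq(1 - radius, n + radius), 1), n),
              pmin(pmax(seq(1 - radius, p + radius), 1), p), drop = FALSE]
  cs <- apply(padded, 2, cumsum)
  vert <- (cs[(k):(n + k - 1), , drop = FALSE] -
             rbind(0, cs)[(k):(n + k - 1), , drop = FALSE]) / k
  cs2 <- t(apply(vert, 1, cumsum))
  (cs2[, (k):(p + k - 1), drop = FALSE] -
      cbind(0, cs2)[, (k):(p + k - 1), drop = FALSE]) / k
}

# NA-aware bilinear sampling of matrix `img` at fractional (row, col) points.
# Points outside the grid, or touching only NA neighbours, return `fill`.
bilinear_sample <- function(img, rows, cols, fill = NA_real_) {
  n <- nrow(img); p <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  out <- rep(fill, length(rows))
  ok <- r0 >= 1 & c0 >= 1 & (r0 + 1) <= n & (c0 + 1) <= p
  # allow points exactly on the last row/col
  edge <- rows >= 1 & cols >= 1 & rows <= n & cols <= p & !ok
  if (any(edge)) {
    ri <- pmin(pmax(round(rows[edge]), 1), n)
    ci <- pmin(pmax(round(cols[edge]), 1), p)
    out[edge] <- img[cbind(ri, ci)]
  }
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    v00 <- img[cbind(r0k, c0k)]
    v10 <- img[cbind(r0k + 1, c0k)]
    v01 <- img[cbind(r0k, c0k + 1)]
    v11 <- img[cbind(r0k + 1, c0k + 1)]
    out[ok] <- v00 * (1 - frk) * (1 - fck) + v10 * frk * (1 - fck) +
      v01 * (1 - frk) * fck + v11 * frk * fck
  }
  out
}

nearest_sample <- function(img, rows, cols, fill = NA) {
  n <- nrow(img); p <- ncol(img)
  ri <- round(rows); ci <- round(cols)
  ok <- ri >= 1 & ci >= 1 & ri <= n & ci <= p
  out <- rep(fill, length(rows))
  out[ok] <- img[cbind(ri[ok], ci[ok])]
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
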