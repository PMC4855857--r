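# Independent oracles and small fixture builders used across the suite.

# Brute-force even-odd ray-casting point-in-polygon test (horizontal ray to
# +x), independent of the package's rasterization path.  on_boundary
# decides whether a point lying on an edge counts as inside.
pip_oracle <- function(px, py, poly, on_boundary = TRUE) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  on_edge <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j]; y2 <- ys[j]
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-9 &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9)
        return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (on_edge(x, y)) return(on_boundary)
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- ys[i]; y2 <- ys[j]
      if ((y1 > y) != (y2 > y)) {
        xint <- xs[i] + (y - y1) / (y2 - y1) * (xs[j] - xs[i])
        if (xint > x) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# Grid-search oracle for the posterior-equality threshold: argmin over a
# fine grid of |pi_n N_n(t) - pi_i N_i(t)| restricted to (mu_n, mu_i).
threshold_grid_oracle <- function(pair, step = 1e-4) {
  ts <- seq(pair$mu_n, pair$mu_i, by = step)
  gap <- abs(pair$pi_n * dnorm(ts, pair$mu_n, pair$sd_n) -
             pair$pi_i * dnorm(ts, pair$mu_i, pair$sd_i))
  ts[which.min(gap)]
}

# Bare gaussian_pair builder for threshold tests.
make_pair <- function(mu_n, sd_n, mu_i, sd_i, pi_i) {
  structure(list(mu_n = mu_n, sd_n = sd_n, mu_i = mu_i, sd_i = sd_i,
                 pi_n = 1 - pi_i, pi_i = pi_i),
            class = "gaussian_pair")
}

# Random pair for which the posterior-equality threshold exists inside
# (mu_n, mu_i): the mixture must favor the normal class at mu_n and the
# infarct class at mu_i (both components "retain mass" there), which is
# what an EM fit of genuinely bimodal data produces.  Rejection-sampled.
draw_valid_pair <- function() {
  repeat {
    pair <- make_pair(mu_n = 0,
                      sd_n = stats::runif(1, 0.3, 2),
                      mu_i = stats::runif(1, 1.5, 8),
                      sd_i = stats::runif(1, 0.3, 3),
                      pi_i = stats::runif(1, 0.02, 0.6))
    f <- function(t) pair$pi_n * dnorm(t, pair$mu_n, pair$sd_n) -
                     pair$pi_i * dnorm(t, pair$mu_i, pair$sd_i)
    if (f(pair$mu_n) > 0 && f(pair$mu_i) < 0) return(pair)
  }
}

# Regular-polygon approximation of a circle in pixel coordinates.
circle_poly <- function(cx, cy, r, n = 96L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Minimal lv_segmentation-like object built directly from masks, for tests
# that need full control over geometry (sector assignment, MVO slices).
seg_from_masks <- function(myo, blood = NULL, centers = NULL) {
  d <- dim(myo)
  blood <- blood %||% array(FALSE, d)
  if (is.null(centers)) {
    centers <- matrix(NA_real_, d[3], 2L)
    for (s in seq_len(d[3])) {
      m <- myo[, , s]
      if (any(m)) centers[s, ] <- c(mean(col(m)[m]), mean(row(m)[m]))
    }
  }
  structure(list(contours = vector("list", d[3]), myocardium_mask = myo,
                 blood_mask = blood, lv_center = centers),
            class = "lv_segmentation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform annular mask on one slice (used by sector/remote tests).
annulus_mask <- function(n, r_in, r_out, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), times = n), n, n)
  rr <- sqrt((x - cx)^2 + (y - cy)^2)
  rr >= r_in & rr <= r_out
}
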