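# Internal array helpers shared across pipeline stages.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a matrix by (dr, dc), padding the exposed border with `fill`.
#' @noRd
shift2d <- function(m, dr, dc, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  if (abs(dr) >= nr || abs(dc) >= nc) return(out)
  sr <- max(1L, 1L - dr):min(nr, nr - dr)
  sc <- max(1L, 1L - dc):min(nc, nc - dc)
  out[sr + dr, sc + dc] <- m[sr, sc, drop = FALSE]
  out
}

# Shift a 3D logical/numeric array by (dr, dc, ds).
#' @noRd
shift3d <- function(a, dr, dc, ds, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  if (abs(dr) >= d[1] || abs(dc) >= d[2] || abs(ds) >= d[3]) return(out)
  sr <- max(1L, 1L - dr):min(d[1], d[1] - dr)
  sc <- max(1L, 1L - dc):min(d[2], d[2] - dc)
  ss <- max(1L, 1L - ds):min(d[3], d[3] - ds)
  out[sr + dr, sc + dc, ss + ds] <- a[sr, sc, ss, drop = FALSE]
  out
}

# Neighbour offsets for connected-component labelling.
# 2D: connectivity 4 or 8; 3D: connectivity 6 or 26.
#' @noRd
neighbour_offsets <- function(ndim, connectivity) {
  if (ndim == 2L) {
    if (connectivity == 4L)
      return(cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L)))
    if (connectivity == 8L) {
      g <- expand.grid(dr = -1:1, dc = -1:1)
      g <- g[!(g$dr == 0 & g$dc == 0), ]
      return(as.matrix(g))
    }
  } else if (ndim == 3L) {
    if (connectivity == 6L)
      return(cbind(c(-1L, 1L, 0L, 0L, 0L, 0L),
                   c(0L, 0L, -1L, 1L, 0L, 0L),
                   c(0L, 0L, 0L, 0L, -1L, 1L)))
    if (connectivity == 26L) {
      g <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
      g <- g[!(g$dr == 0 & g$dc == 0 & g$ds == 0), ]
      return(as.matrix(g))
    }
  }
  stop("unsupported connectivity ", connectivity, " for ", ndim, "D")
}

#' Label connected components of a binary mask
#'
#' Breadth-first labelling of the foreground of a 2D or 3D logical array.
#' Used for the 3D (26-connectivity) region bookkeeping of the small-region
#' filter, where slice-spanning infarct regions must count as one component.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4 or 8 (2D), 6 or 26 (3D).
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 3L) 26L else 4L) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("mask must be a 2D matrix or 3D array")
  is2d <- length(d) == 2L
  if (is2d) d <- c(d, 1L)
  arr <- array(as.logical(mask), d)
  offs <- neighbour_offsets(if (is2d) 2L else 3L, as.integer(connectivity))
  if (is2d) offs <- cbind(offs, 0L)
  labels <- array(0L, d)
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  queue <- integer(sum(arr))
  lab <- 0L
  fg <- which(arr)
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      idx <- queue[head]; head <- head + 1L
      s <- (idx - 1L) %/% (nr * nc)
      rem <- idx - 1L - s * nr * nc
      cc <- rem %/% nr
      rr <- rem - cc * nr
      r1 <- rr + 1L; c1 <- cc + 1L; s1 <- s + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- r1 + offs[k, 1L]; c2 <- c1 + offs[k, 2L]; s2 <- s1 + offs[k, 3L]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc || s2 < 1L || s2 > ns) next
        j <- r2 + (c2 - 1L) * nr + (s2 - 1L) * nr * nc
        if (arr[j] && labels[j] == 0L) {
          labels[j] <- lab
          tail <- tail + 1L
          queue[tail] <- j
        }
      }
    }
  }
  if (is2d) dim(labels) <- dim(mask)
  labels
}

# Clamp numeric values into [lo, hi].
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 3x3 cross-shaped structuring element used for the MVO morphological closing.
#' @noRd
cross_kernel <- function() matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3L, 3L)
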