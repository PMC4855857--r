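# Step 2: constrained two-Gaussian expectation-maximization classification
# of myocardial intensities into normal myocardium and infarct, and the
# optimal intensity threshold between the two fitted components.

#' Percentile constraints for the constrained EM fit
#'
#' Intensities below the `p_lo`th percentile are forced to the normal class
#' and intensities above the `p_hi`th percentile to the infarct class at
#' every E-step; the initial classification thresholds at the `p_init`th
#' percentile.  The constraints stabilize the EM fit and keep the two
#' Gaussians separated.  Percentiles are estimated by linear interpolation
#' between order statistics (`stats::quantile` type 7); the constraint
#' boundaries depend on this estimator.
#'
#' @param p_lo,p_hi,p_init percentiles in (0, 100).
#' @return object of class `em_constraints`.
#' @export
em_constraints <- function(p_lo = 5, p_hi = 95, p_init = 90) {
  if (!(0 < p_lo && p_lo < p_init && p_init < 100))
    stop("require 0 < p_lo < p_init < 100")
  if (!(p_lo < p_hi)) stop("require p_lo < p_hi")
  structure(list(p_lo = p_lo, p_hi = p_hi, p_init = p_init),
            class = "em_constraints")
}

#' Initial infarct/normal classification
#'
#' Labels as infarct exactly the intensities strictly above the 90th
#' percentile (linear-interpolation estimator), i.e. a deliberately small
#' initial infarct of ~10% of the myocardium; ties at the percentile break
#' toward normal.  When a mass of tied values at the maximum makes the
#' strict cut empty (quantized or noiseless data), the cut falls back to
#' `>=` so the maximal values seed the infarct class.
#'
#' @param intensities numeric vector (>= 20 samples, non-constant).
#' @param constraints [em_constraints]
#' @return logical vector, TRUE = initial infarct label.
#' @export
initialize_labels <- function(intensities, constraints = em_constraints()) {
  x <- as.numeric(intensities)
  if (length(x) < 20L) stop("need at least 20 intensity samples")
  if (max(x) - min(x) <= 0) stop("degenerate input: constant intensities")
  q <- stats::quantile(x, constraints$p_init / 100, names = FALSE, type = 7)
  lab <- x > q
  if (!any(lab)) lab <- x >= q
  lab
}

#' Constrained EM fit of a two-Gaussian mixture
#'
#' Alternates an E-step (posterior responsibilities under the current
#' parameters, then overwritten: infarct responsibility 0 below the 5th
#' percentile, 1 above the 95th) with a responsibility-weighted M-step for
#' the means, standard deviations and mixing weights.  Internally the
#' intensities are standardized (fit parameters are mapped back afterwards),
#' which makes the fit, and hence the optimal threshold, exactly equivariant
#' under affine intensity rescaling.  Iteration stops when the maximum
#' absolute parameter change on the standardized scale drops below `tol` or
#' after `max_iter` iterations.  The component with the larger mean is the
#' infarct component.
#'
#' @param intensities numeric vector of myocardial intensities (>= 20,
#'   non-constant).
#' @param constraints [em_constraints]
#' @param tol convergence tolerance on the standardized parameters.
#' @param max_iter iteration cap.
#' @return object of class `gaussian_pair`: `mu_n`, `sd_n`, `mu_i`, `sd_i`,
#'   `pi_n`, `pi_i`, `threshold` (the posterior-equality threshold, see
#'   [optimal_threshold]), `iterations`, `converged`, and `objective` (the
#'   per-iteration EM lower bound on the observed-data log-likelihood:
#'   expected complete-data log-likelihood plus responsibility entropy,
#'   non-decreasing across iterations).
#' @export
em_fit <- function(intensities, constraints = em_constraints(),
                   tol = 1e-6, max_iter = 500L) {
  x <- as.numeric(intensities)
  if (length(x) < 20L) stop("need at least 20 intensity samples")
  rng <- max(x) - min(x)
  if (rng <= 0) stop("degenerate input: constant intensities")
  ctr <- mean(x); scl <- stats::sd(x)
  z <- (x - ctr) / scl
  q <- stats::quantile(z, c(constraints$p_lo, constraints$p_init,
                            constraints$p_hi) / 100,
                       names = FALSE, type = 7)
  lo_set <- z < q[1]
  hi_set <- z > q[3]
  r <- as.numeric(z > q[2])  # initial infarct responsibility
  if (!any(r > 0)) r <- as.numeric(z >= q[2])  # tied mass at the maximum
  # variance floor keeps quantized/noiseless inputs fittable (a component
  # sitting on a single repeated value would otherwise degenerate)
  sd_floor <- 1e-6 * (max(z) - min(z))
  m_step <- function(r) {
    wi <- sum(r); wn <- sum(1 - r)
    if (wi < 1e-6 || wn < 1e-6)
      stop("EM component collapse: effective weight below 1e-6 ",
           sprintf("(normal %.3g, infarct %.3g)", wn, wi))
    mu_i <- sum(r * z) / wi
    mu_n <- sum((1 - r) * z) / wn
    sd_i <- max(sqrt(sum(r * (z - mu_i)^2) / wi), sd_floor)
    sd_n <- max(sqrt(sum((1 - r) * (z - mu_n)^2) / wn), sd_floor)
    c(mu_n = mu_n, sd_n = sd_n, mu_i = mu_i, sd_i = sd_i,
      pi_i = wi / length(z))
  }
  par <- m_step(r)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step with percentile clamping
    di <- par["pi_i"] * stats::dnorm(z, par["mu_i"], par["sd_i"])
    dn <- (1 - par["pi_i"]) * stats::dnorm(z, par["mu_n"], par["sd_n"])
    r <- di / (di + dn)
    r[!is.finite(r)] <- 0.5
    r[lo_set] <- 0
    r[hi_set] <- 1
    new_par <- m_step(r)
    # EM lower bound on the observed-data log-likelihood: expected
    # complete-data log-likelihood plus the responsibility entropy.  With
    # the clamp sets fixed, both the E-step and the M-step can only raise
    # it, so the trace is non-decreasing.
    pi_i <- new_par["pi_i"]
    q <- sum(r * (log(pi_i) + stats::dnorm(z, new_par["mu_i"],
                                           new_par["sd_i"], log = TRUE)) +
             (1 - r) * (log(1 - pi_i) + stats::dnorm(z, new_par["mu_n"],
                                                     new_par["sd_n"],
                                                     log = TRUE)))
    xlx <- function(v) ifelse(v > 0, v * log(v), 0)
    objective <- c(objective, q - sum(xlx(r) + xlx(1 - r)))
    if (max(abs(new_par - par)) < tol) {
      par <- new_par
      converged <- TRUE
      break
    }
    par <- new_par
  }
  if (par["mu_i"] < par["mu_n"]) {  # larger mean is the infarct component
    par <- c(mu_n = unname(par["mu_i"]), sd_n = unname(par["sd_i"]),
             mu_i = unname(par["mu_n"]), sd_i = unname(par["sd_n"]),
             pi_i = unname(1 - par["pi_i"]))
  }
  pair <- structure(
    list(mu_n = ctr + scl * unname(par["mu_n"]),
         sd_n = scl * unname(par["sd_n"]),
         mu_i = ctr + scl * unname(par["mu_i"]),
         sd_i = scl * unname(par["sd_i"]),
         pi_n = 1 - unname(par["pi_i"]),
         pi_i = unname(par["pi_i"]),
         iterations = iter,
         converged = converged,
         objective = objective),
    class = "gaussian_pair")
  pair$threshold <- optimal_threshold(pair)
  pair
}

#' @export
print.gaussian_pair <- function(x, ...) {
  cat(sprintf(paste0("<gaussian_pair> normal N(%.3g, %.3g) pi=%.3f | ",
                     "infarct N(%.3g, %.3g) pi=%.3f | t*=%.4g (%d iter%s)\n"),
              x$mu_n, x$sd_n, x$pi_n, x$mu_i, x$sd_i, x$pi_i, x$threshold,
              x$iterations, if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Optimal threshold between the two fitted Gaussians
#'
#' The intensity at which a voxel is equally likely to represent normal
#' myocardium or infarct.  With `weighted = TRUE` (default) this is the
#' posterior-equality point, solving
#' `pi_n N(t; mu_n, sd_n) = pi_i N(t; mu_i, sd_i)` (a quadratic in `t`);
#' with `weighted = FALSE` the class-conditional densities are equated
#' (mixing weights ignored).  Of the up to two real roots the one inside
#' `(mu_n, mu_i)` is returned; if neither lies inside, the root closest to
#' that interval.  The equal-variance case degenerates to a linear equation.
#'
#' @param pair [gaussian_pair]
#' @param weighted equate mixture-weighted (posterior) densities rather
#'   than class-conditional densities.
#' @return threshold t*.
#' @export
optimal_threshold <- function(pair, weighted = TRUE) {
  mu_n <- pair$mu_n; sd_n <- pair$sd_n
  mu_i <- pair$mu_i; sd_i <- pair$sd_i
  if (sd_n <= 0 || sd_i <= 0) stop("invalid gaussian_pair: non-positive sd")
  k <- if (weighted) log((pair$pi_i * sd_n) / (pair$pi_n * sd_i))
       else log(sd_n / sd_i)
  # (t - mu_i)^2 / (2 sd_i^2) - (t - mu_n)^2 / (2 sd_n^2) = k
  A <- 1 / (2 * sd_i^2) - 1 / (2 * sd_n^2)
  B <- mu_n / sd_n^2 - mu_i / sd_i^2
  C <- mu_i^2 / (2 * sd_i^2) - mu_n^2 / (2 * sd_n^2) - k
  if (abs(A) < 1e-12 * (1 / sd_i^2 + 1 / sd_n^2)) {
    if (abs(B) < .Machine$double.eps)
      stop("threshold error: coincident components")
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("threshold error: no real root")
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  inside <- roots > mu_n & roots < mu_i
  if (any(inside)) return(roots[inside][1])
  dist <- pmax(mu_n - roots, roots - mu_i, 0)
  roots[which.min(dist)]
}
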