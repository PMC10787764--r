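#' Circular statistics utilities
#'
#' Small toolbox for directional data on the circle: mean resultant length,
#' circular mean, von Mises density, random generation, concentration
#' estimation, kernel density with a von Mises kernel, and a finite von
#' Mises mixture fitted by EM. Angles are in radians, counterclockwise from
#' the positive x axis (east); outputs in tables are reported in degrees.
#'
#' @name circular-utils
NULL

#' Wrap angles to (-pi, pi]
#' @param theta angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Mean resultant length of a set of angles
#' @param theta angles in radians.
#' @return scalar in \[0, 1\].
#' @export
resultant_length <- function(theta) {
  stopifnot(length(theta) >= 1)
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' Circular mean
#' @param theta angles in radians.
#' @return mean direction in (-pi, pi].
#' @export
circ_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta)))
}

#' Smallest angular distance between two directions
#' @param a,b angles in radians.
#' @return distance in \[0, pi\].
#' @export
ang_dist <- function(a, b) abs(wrap_angle(a - b))

#' von Mises density
#' @param theta angles (radians).
#' @param mu mean direction.
#' @param kappa concentration (>= 0).
#' @return density values.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1) {
  # exponentially scaled Bessel keeps this finite for large kappa
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' von Mises random deviates (Best & Fisher rejection sampler)
#' @param n number of draws.
#' @param mu mean direction.
#' @param kappa concentration; 0 gives the circular uniform.
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

#' Maximum-likelihood concentration for a given mean resultant length
#'
#' Solves A1(kappa) = I1(kappa)/I0(kappa) = R by root finding.
#' @param R mean resultant length in \[0, 1).
#' @param kappa_max upper bound for the solution.
#' @return concentration estimate.
#' @export
kappa_from_R <- function(R, kappa_max = 500) {
  if (R <= 1e-8) return(0)
  A1 <- function(k) besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  if (A1(kappa_max) <= R) return(kappa_max)
  stats::uniroot(function(k) A1(k) - R, c(1e-8, kappa_max), tol = 1e-8)$root
}

#' Circular kernel density estimate with a von Mises kernel
#' @param theta angles (radians).
#' @param kappa_kernel kernel concentration (larger = narrower).
#' @param n_grid number of evaluation points on the circle.
#' @return list with `grid` (angles) and `density`.
#' @export
vm_kde <- function(theta, kappa_kernel = 25, n_grid = 360) {
  # midpoint grid: symmetric under reflection, so mode-separation
  # statistics are exactly mirror invariant
  grid <- (seq_len(n_grid) - 0.5) * 2 * pi / n_grid - pi
  cs <- outer(grid, theta, function(g, t) cos(g - t))
  dens <- rowMeans(exp(kappa_kernel * (cs - 1))) /
    (2 * pi * besselI(kappa_kernel, 0, expon.scaled = TRUE))
  list(grid = grid, density = dens)
}

#' Local maxima of a circular density
#' @param kde output of [vm_kde()].
#' @return data.frame with `angle` and `density` of each local maximum,
#'   ordered by decreasing density.
#' @export
circ_modes <- function(kde) {
  d <- kde$density
  n <- length(d)
  up <- d > d[c(n, seq_len(n - 1))]        # greater than left neighbour
  dn <- d >= d[c(seq_len(n - 1) + 1, 1)]   # at least right neighbour (plateau tie-break)
  is_max <- up & dn
  if (!any(is_max)) {                      # flat density
    return(data.frame(angle = kde$grid[1], density = d[1]))
  }
  out <- data.frame(angle = kde$grid[is_max], density = d[is_max])
  out[order(-out$density), , drop = FALSE]
}

#' Fit a finite von Mises mixture by EM
#'
#' Mixture of `k` von Mises components on the circle, fitted by
#' expectation-maximisation with multiple random restarts. Concentrations
#' are capped to keep degenerate single-point components finite.
#'
#' @param theta angles (radians), length >= k.
#' @param k number of components.
#' @param n_restarts random restarts; best log-likelihood kept.
#' @param max_iter EM iterations per restart.
#' @param kappa_max concentration cap.
#' @param tol log-likelihood convergence tolerance.
#' @return list with `weights`, `mu`, `kappa`, `logLik`, `bic`,
#'   `assignment` (hard labels), `k`.
#' @export
fit_vm_mixture <- function(theta, k, n_restarts = 20, max_iter = 200,
                           kappa_max = 100, tol = 1e-8) {
  n <- length(theta)
  stopifnot(k >= 1, n >= k)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- theta[sample.int(n, k)]
    kap <- rep(5, k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k),
                     function(j) w[j] * dvonmises(theta, mu[j], kap[j]),
                     numeric(n))
      dens <- matrix(dens, nrow = n)
      rowsum_d <- rowSums(dens)
      rowsum_d[rowsum_d < 1e-300] <- 1e-300
      resp <- dens / rowsum_d
      ll <- sum(log(rowsum_d))
      nj <- colSums(resp)
      if (any(nj < 1e-8)) break            # empty component; restart
      w <- nj / n
      for (j in seq_len(k)) {
        C <- sum(resp[, j] * cos(theta)); S <- sum(resp[, j] * sin(theta))
        mu[j] <- atan2(S, C)
        Rj <- min(sqrt(C^2 + S^2) / nj[j], 1 - 1e-10)
        kap[j] <- kappa_from_R(Rj, kappa_max)
      }
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.null(best) || (is.finite(ll) && ll > best$logLik)) {
      best <- list(weights = w, mu = mu, kappa = kap, logLik = ll)
    }
  }
  # hard assignment and BIC (k means + k kappas + k-1 weights)
  dens <- vapply(seq_len(k),
                 function(j) best$weights[j] * dvonmises(theta, best$mu[j], best$kappa[j]),
                 numeric(n))
  dens <- matrix(dens, nrow = n)
  best$assignment <- max.col(dens, ties.method = "first")
  best$bic <- -2 * best$logLik + (3 * k - 1) * log(n)
  best$k <- k
  best
}
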