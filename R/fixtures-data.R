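# Synthetic observable generators. Each inverts the corresponding estimator
# analytically, so generator + estimator form a round trip at known truth;
# all are deterministic under a fixed seed.

withSeed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Synthetic tilt-divergence samples
#'
#' Gaussian samples with variance \eqn{1/(\kappa A_l)}, the equilibrium
#' distribution implied by a harmonic tilt-divergence energy at bending
#' modulus kappa.
#'
#' @param kappa generator bending modulus, kT
#' @param Al area per lipid, nm^2
#' @param n sample count
#' @param seed RNG seed
#' @return numeric vector of divergence samples (1/nm)
#' @export
tiltFixture <- function(kappa, Al, n = 1e5, seed = 1) {
  stopifnot(kappa > 0, Al > 0)
  withSeed(seed, stats::rnorm(n, 0, sqrt(1 / (kappa * Al))))
}

#' Synthetic in-plane tilt components
#'
#' Isotropic 2D Gaussian components with per-component variance
#' \eqn{1/(\kappa_\theta A_l)}, matching the tilt-modulus estimator.
#'
#' @param ktheta generator tilt modulus, kT/nm^2
#' @param Al area per lipid, nm^2
#' @param n sample count
#' @param seed RNG seed
#' @return n x 2 matrix
#' @export
tiltVectorFixture <- function(ktheta, Al, n = 1e5, seed = 1) {
  stopifnot(ktheta > 0, Al > 0)
  withSeed(seed, matrix(stats::rnorm(2 * n, 0, sqrt(1 / (ktheta * Al))), n, 2))
}

#' Synthetic lateral stress profile with prescribed moments
#'
#' Builds a smooth symmetric profile from three mirrored Gaussian bump
#' pairs at \eqn{z_k = l/4, l/2, 3l/4} whose amplitudes solve the linear
#' moment conditions exactly: zero integral (tension-free apart from the
#' \code{pN} offset), first bending moment \eqn{\int_0^l \pi z\,dz =
#' \kappa J_s} and second moment \eqn{\int_{-l}^{l} \pi z^2\,dz =
#' \bar\kappa_b}. A narrow width keeps the boundary truncation of the
#' analytic moments far below the estimator tolerances.
#'
#' @param pN constant offset added to the profile (recovered by
#'   [normalizePN()])
#' @param kappaJs target first moment over \[0, l\], kT/nm
#' @param kbar target second moment over \[-l, l\], kT
#' @param l monolayer extent, nm
#' @param n grid points
#' @param sigma Gaussian width, nm (default l/16)
#' @return a [stressProfile()] on \[-l, l\] with attribute \code{targets}
#' @export
stressProfileFixture <- function(pN = 0, kappaJs = 0, kbar = 0, l = 2,
                                 n = 801, sigma = NULL) {
  if (is.null(sigma)) sigma <- l / 16
  z <- seq(-l, l, length.out = n)
  zk <- c(l / 4, l / 2, 3 * l / 4)
  g <- function(z, z0) exp(-(z - z0)^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
  # mirrored unit-mass bump pair at +-zk: zeroth moment 2, first moment over
  # [0, l] equals zk, second moment over [-l, l] equals 2 (zk^2 + sigma^2)
  A <- rbind(rep(2, 3), zk, 2 * (zk^2 + sigma^2))
  rhs <- c(0, kappaJs, kbar)
  a <- tryCatch(solve(A, rhs),
                error = function(e) stop("infeasible moment combination"))
  prof <- rep(pN, length(z))
  for (k in 1:3) prof <- prof + a[k] * (g(z, zk[k]) + g(z, -zk[k]))
  out <- stressProfile(z, prof)
  attr(out, "targets") <- list(pN = pN, kappaJs = kappaJs, kbar = kbar, l = l)
  out
}

#' Synthetic 2D radial distribution function
#'
#' Exclusion core plus a Gaussian peak:
#' \eqn{g(r) = [1 + A \exp(-(r - r_p)^2 / 2 w^2)] S(r)} with a smooth
#' sigmoidal core turn-on S. The exact Kirkwood--Buff integral is computed
#' numerically on a fine grid and attached for reference.
#'
#' @param rmax grid extent, nm
#' @param n grid points
#' @param core exclusion radius, nm
#' @param peak peak position, nm
#' @param amplitude peak amplitude above 1
#' @param width peak width, nm
#' @return list(r, g) with attribute \code{gammaPerRho} (excess per unit
#'   density)
#' @export
rdfFixture <- function(rmax = 6, n = 601, core = 1.2, peak = 2.0,
                       amplitude = 0.5, width = 0.35) {
  r <- seq(0, rmax, length.out = n)
  S <- 1 / (1 + exp(-(r - core) / 0.08))
  g <- (1 + amplitude * exp(-(r - peak)^2 / (2 * width^2))) * S
  fine <- seq(0, rmax, length.out = 20001)
  Sf <- 1 / (1 + exp(-(fine - core) / 0.08))
  gf <- (1 + amplitude * exp(-(fine - peak)^2 / (2 * width^2))) * Sf
  integ <- (gf - 1) * 2 * pi * fine
  gam <- sum(diff(fine) * (head(integ, -1) + tail(integ, -1)) / 2)
  structure(list(r = r, g = g), gammaPerRho = gam)
}

#' Synthetic correlated energy series (AR(1))
#'
#' First-order autoregressive series with coefficient \code{rho}; its
#' integrated autocorrelation gives a statistical inefficiency of
#' \eqn{(1+\rho)/(1-\rho)} in the long-series limit.
#'
#' @param n length
#' @param rho AR(1) coefficient in (-1, 1)
#' @param mean,sd stationary mean and standard deviation
#' @param seed RNG seed
#' @export
energySeriesFixture <- function(n = 1e5, rho = 0.9, mean = 0, sd = 1,
                                seed = 1) {
  stopifnot(abs(rho) < 1)
  withSeed(seed, {
    innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd)
    for (k in 2:n) x[k] <- rho * x[k - 1] + innov[k]
    mean + x
  })
}
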