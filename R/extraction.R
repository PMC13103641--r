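# Elastic-parameter extraction from molecular-dynamics style observables:
# real-space tilt-divergence fluctuations and lateral stress profile moments.
# Raw trajectory processing (surface interpolation, stress tensor contours)
# is out of scope; the functions consume sample sets and profiles as plain
# columnar data.

#' Bending modulus from tilt-divergence fluctuations
#'
#' The equilibrium distribution of the director-divergence field is Gaussian
#' with variance set by the bending modulus,
#' \eqn{P(\nabla\cdot t) \propto \exp[-\tfrac12 \kappa \beta (\nabla\cdot
#' t)^2 A_l]}, so \eqn{\kappa = 1 / (A_l\, \mathrm{Var}[\nabla\cdot t])} in
#' kT units. The standard error comes from a moving-block bootstrap with the
#' block length chosen from the series' statistical inefficiency.
#'
#' @param divt samples of the tilt divergence, 1/nm
#' @param Al area per lipid, nm^2
#' @param nBoot bootstrap resamples
#' @param seed RNG seed for the bootstrap
#' @return list(kappa, se) in kT
#' @export
kappaFromTilt <- function(divt, Al, nBoot = 200, seed = 1) {
  stopifnot(Al > 0)
  divt <- divt[is.finite(divt)]
  if (length(divt) < 100) stop("need at least 100 samples")
  v <- stats::var(divt)
  if (v <= 0) stop("zero variance: degenerate sample set")
  est <- function(x) 1 / (Al * stats::var(x))
  list(kappa = est(divt), se = blockBootstrapSE(divt, est, nBoot, seed))
}

#' Tilt modulus from tilt-vector fluctuations
#'
#' Gaussian-fluctuation estimator with per-lipid-area weighting, analogous
#' to the bending-modulus estimator: for in-plane tilt components
#' \eqn{t = (t_x, t_y)} with \eqn{\langle |t|^2 \rangle = 2/(\kappa_\theta
#' A_l)}, \eqn{\kappa_\theta = 2 / (A_l \langle |t|^2 \rangle)} (kT/nm^2).
#' The estimator is rotation-invariant in the membrane plane. The exact
#' normalization convention is validated on self-consistent synthetic data
#' (see the package vignette).
#'
#' @param tilt n x 2 matrix of in-plane tilt components, or a vector of
#'   tilt magnitudes
#' @param Al area per lipid, nm^2
#' @param nBoot,seed bootstrap controls
#' @return list(ktheta, se) in kT/nm^2
#' @export
tiltModulus <- function(tilt, Al, nBoot = 200, seed = 1) {
  stopifnot(Al > 0)
  t2 <- if (is.matrix(tilt)) rowSums(tilt^2) else as.numeric(tilt)^2
  t2 <- t2[is.finite(t2)]
  if (length(t2) < 100) stop("need at least 100 samples")
  if (mean(t2) <= 0) stop("zero tilt: degenerate sample set")
  est <- function(x) 2 / (Al * mean(x))
  list(ktheta = est(t2), se = blockBootstrapSE(t2, est, nBoot, seed))
}

blockBootstrapSE <- function(x, est, nBoot, seed) {
  n <- length(x)
  s <- tryCatch(statisticalInefficiency(x)$s, error = function(e) 1)
  bl <- max(1L, min(as.integer(ceiling(s)), n %/% 4))
  nb <- ceiling(n / bl)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  vals <- vapply(seq_len(nBoot), function(k) {
    starts <- sample.int(n - bl + 1L, nb, replace = TRUE)
    idx <- as.vector(outer(0:(bl - 1L), starts, "+"))[seq_len(n)]
    est(x[idx])
  }, numeric(1))
  stats::sd(vals)
}

#' Stress profile container
#'
#' @param z membrane-normal grid, nm (strictly increasing, midplane at 0)
#' @param pi lateral pressure profile \eqn{\pi(z) = \sigma_\parallel -
#'   \sigma_\perp}, kT/nm^3
#' @param units units of the supplied values: "kT/nm^3" or "bar"
#' @param temperature used for the bar conversion
#' @return list of class \code{stressProfile}
#' @export
stressProfile <- function(z, pi, units = "kT/nm^3", temperature = 300) {
  stopifnot(length(z) == length(pi), all(diff(z) > 0))
  if (units == "bar") pi <- pi / barPerKTnm3(temperature)
  else if (units != "kT/nm^3") stop("units must be 'kT/nm^3' or 'bar'")
  structure(list(z = as.numeric(z), pi = as.numeric(pi)),
            class = "stressProfile")
}

#' Lateral pressure from stress components
#'
#' Pointwise \eqn{\pi(z) = \sigma_\parallel(z) - \sigma_\perp(z)} on a
#' common grid.
#'
#' @param z common grid
#' @param sigmaPar,sigmaPerp lateral and normal stress profiles
#' @param ... passed to [stressProfile()]
#' @export
lateralPressure <- function(z, sigmaPar, sigmaPerp, ...) {
  if (length(sigmaPar) != length(z) || length(sigmaPerp) != length(z))
    stop("stress components must share the z grid")
  stressProfile(z, sigmaPar - sigmaPerp, ...)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Normal-pressure normalization of a stress profile
#'
#' For a tension-free membrane the integral of the lateral pressure
#' vanishes; the constant normal pressure \eqn{p_N} is therefore fixed by
#' \eqn{\int [\pi(z) - p_N] dz = 0} and subtracted.
#'
#' @param profile a [stressProfile()]
#' @return list(pN, profile) with the shifted (tension-free) profile
#' @export
normalizePN <- function(profile) {
  stopifnot(inherits(profile, "stressProfile"))
  z <- profile$z
  pN <- trapz(z, profile$pi) / (max(z) - min(z))
  list(pN = pN, profile = stressProfile(z, profile$pi - pN))
}

interpTo <- function(profile, znew) stats::approx(profile$z, profile$pi, xout = znew)$y

#' First bending moment of a stress profile
#'
#' \eqn{\kappa J_s = \int_0^l \pi(z)\, z\, dz} over one monolayer
#' (midplane origin); given a bending modulus the spontaneous curvature
#' follows as \eqn{J_s = \kappa J_s / \kappa}.
#'
#' @param profile a tension-free [stressProfile()]
#' @param l monolayer extent, nm (within the grid)
#' @param kappa optional monolayer bending modulus (kT) to report Js
#' @return list(kappaJs (kT/nm), Js (1/nm) when kappa given)
#' @export
firstBendingMoment <- function(profile, l, kappa = NULL) {
  stopifnot(inherits(profile, "stressProfile"))
  z <- profile$z
  if (l <= 0 || l > max(z) + 1e-12) stop("monolayer bound l outside the grid")
  zz <- sort(unique(c(0, z[z > 0 & z < l], l)))
  pp <- interpTo(profile, zz)
  kJs <- trapz(zz, pp * zz)
  list(kappaJs = kJs, Js = if (is.null(kappa)) NULL else kJs / kappa)
}

#' Second bending moment: bilayer Gaussian modulus
#'
#' \eqn{\bar\kappa_b = \int_{-l}^{l} \pi(z)\, z^2\, dz} over both leaflets.
#' A grid that does not cover \[-l, l\] symmetrically is symmetrized by
#' reflection with a warning.
#'
#' @param profile a tension-free [stressProfile()]
#' @param l monolayer extent, nm
#' @return kbar_b in kT
#' @export
secondBendingMoment <- function(profile, l) {
  stopifnot(inherits(profile, "stressProfile"))
  z <- profile$z
  if (min(z) > -l + 1e-9 || max(z) < l - 1e-9) {
    warning("grid does not span [-l, l]; symmetrizing by reflection")
    zz <- sort(unique(c(z[abs(z) <= l], -z[abs(z) <= l], -l, l)))
    pp <- interpTo(profile, abs(zz))
  } else {
    zz <- sort(unique(c(-l, z[z > -l & z < l], l)))
    pp <- interpTo(profile, zz)
  }
  trapz(zz, pp * zz^2)
}

#' Read / write columnar sample and profile files
#'
#' Tab-separated columns with a \code{# units:} header line, matching
#' typical molecular-dynamics post-processing output.
#'
#' @param path file path
#' @return for profiles, a [stressProfile()]; for samples, a numeric matrix
#' @export
readProfileTSV <- function(path) {
  ln <- readLines(path, n = 5)
  units <- "kT/nm^3"
  uh <- grep("^#\\s*units:", ln, value = TRUE)
  if (length(uh)) units <- trimws(sub("^#\\s*units:", "", uh[1]))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  stressProfile(tab[[1]], tab[[2]], units = units)
}

#' @rdname readProfileTSV
#' @param profile a stressProfile
#' @param units units to declare in the header
#' @export
writeProfileTSV <- function(profile, path, units = "kT/nm^3") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# units:", units), con)
  writeLines("z\tpi", con)
  pi <- profile$pi
  if (units == "bar") pi <- pi * barPerKTnm3()
  writeLines(paste(fmtNum(profile$z), fmtNum(pi), sep = "\t"), con)
  invisible(path)
}

#' @rdname readProfileTSV
#' @export
readSamplesTSV <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  as.matrix(tab)
}

#' @rdname readProfileTSV
#' @param samples numeric vector or matrix of samples
#' @export
writeSamplesTSV <- function(samples, path) {
  samples <- as.matrix(samples)
  if (is.null(colnames(samples)))
    colnames(samples) <- paste0("s", seq_len(ncol(samples)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(samples), collapse = "\t"), con)
  writeLines(apply(samples, 1, function(r) paste(fmtNum(r), collapse = "\t")), con)
  invisible(path)
}
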