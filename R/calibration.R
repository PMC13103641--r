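# Flat-patch demixing model: links molecular binding free energies to the
# effective peptide footprint area through the lipid demixing it causes.

#' Flat-patch system for the demixing model
#'
#' A flat membrane patch of \code{nLipids} lipids at global composition
#' \code{composition} with \code{nPeptides} adsorbed peptides. The peptides
#' jointly cover \code{Mcov} lipids: by default \code{nPeptides * Ap /
#' a0(composition)}, or \code{coverage * nLipids} when a coverage ratio is
#' imposed explicitly.
#'
#' @param composition named number fractions
#' @param nLipids total lipid count M
#' @param nPeptides peptide count
#' @param Ap footprint area, nm^2 (defaults to the adsorbate table value)
#' @param coverage optional imposed covered-lipid ratio (fraction of M)
#' @param adsorbate adsorbate name
#' @param tables a \linkS4class{MaterialTables}
#' @return a list of class \code{patchSystem}
#' @export
patchSystem <- function(composition = c(DOPE = 0.6, DOPS = 0.2, DOPC = 0.2),
                        nLipids = 2048, nPeptides = 64, Ap = NULL,
                        coverage = NULL, adsorbate = "R9",
                        tables = materialTables()) {
  phi <- checkFractions(composition, tables)
  ad <- tables@adsorbates[[adsorbate]]
  if (is.null(ad)) stop("unknown adsorbate: ", adsorbate)
  if (is.null(Ap)) Ap <- ad$Ap
  a0mix <- sum(phi * tables@lipids$a0)
  Mcov <- if (is.null(coverage)) nPeptides * Ap / a0mix else coverage * nLipids
  if (Mcov >= nLipids) stop("covered lipid count reaches the whole patch")
  structure(list(phi = phi, M = nLipids, np = nPeptides, Ap = Ap,
                 Mcov = Mcov, mu = stats::setNames(ad$table$mu, ad$table$name),
                 kT = kTkJmol(tables@temperature), a0 = tables@lipids$a0,
                 adsorbate = adsorbate),
            class = "patchSystem")
}

#' Equilibrium lipid demixing under adsorbed peptides
#'
#' Minimizes the two-region free energy
#' \deqn{F(x) = n_p \sum_i x_i \mu_{ads,i}
#'       + k_B T\,[M_{cov} \sum_i x_i \ln x_i + M_{unc} \sum_i y_i \ln y_i]}
#' over the covered composition x, with the uncovered composition y fixed by
#' lipid conservation \eqn{M_{cov} x_i + M_{unc} y_i = M \phi_i}. The
#' objective is convex; the interior stationarity condition
#' \eqn{x_i / y_i = C\, e^{-n_p \mu_i / (k_B T M_{cov})}} reduces the
#' problem to a one-dimensional monotone root find in C, which is solved to
#' machine precision (this is the exact solution of the convex program).
#' Species exhausted by the conservation constraint pin the solution to the
#' feasible boundary, reported with a warning.
#'
#' @param patch a [patchSystem()]
#' @return list of class \code{demixResult}: covered fractions \code{x},
#'   uncovered fractions \code{y}, per-peptide excess lipids \code{Gamma}
#'   (\eqn{\Gamma_i = M_{cov}(x_i - \phi_i)/n_p}), the minimized free energy
#'   \code{F} (kJ/mol), and the free energy \code{Funiform} of the uniform
#'   (undemixed) composition
#' @export
equilibriumDemix <- function(patch) {
  stopifnot(inherits(patch, "patchSystem"))
  phi <- patch$phi; mu <- patch$mu[names(phi)]
  M <- patch$M; np <- patch$np; Mc <- patch$Mcov
  Mu <- M - Mc
  kT <- patch$kT
  entU <- kT * M * sum(ifelse(phi > 0, phi * log(phi), 0))
  if (all(abs(mu - mu[1]) < 1e-12)) {
    # equal binding energies: no demixing force
    return(structure(list(x = phi, y = phi,
                          Gamma = stats::setNames(numeric(length(phi)), names(phi)),
                          F = np * sum(phi * mu) + entU, Funiform = entU,
                          patch = patch),
                     class = "demixResult"))
  }
  b <- -np * mu / (kT * Mc)
  eb <- exp(b - max(b))
  f <- Mc / M
  g <- function(lC) sum(exp(lC) * eb * phi / ((1 - f) + f * exp(lC) * eb)) - 1
  lo <- -60; hi <- 60
  if (g(lo) > 0 || g(hi) < 0) {
    warning("demixing pinned to the feasible boundary")
    hi <- 60
  }
  lC <- uniroot(g, c(lo, hi), tol = 1e-14)$root
  y <- phi / ((1 - f) + f * exp(lC) * eb)
  x <- exp(lC) * eb * y
  ent <- function(p) sum(ifelse(p > 0, p * log(p), 0))
  Fmin <- np * sum(x * mu) + kT * (Mc * ent(x) + Mu * ent(y))
  # reference state: no peptide bound, uniform composition
  structure(list(x = x, y = y, Gamma = Mc * (x - phi) / np,
                 F = Fmin, Funiform = entU, patch = patch),
            class = "demixResult")
}

#' @export
print.demixResult <- function(x, ...) {
  cat("Equilibrium demixing (", x$patch$np, "peptide(s),",
      format(x$patch$Mcov, digits = 5), "covered of", x$patch$M, "lipids)\n")
  df <- data.frame(lipid = names(x$x), covered = round(x$x, 4),
                   uncovered = round(x$y, 4), Gamma = round(x$Gamma, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predicted peptide binding free energy on a mixed patch
#'
#' \eqn{\Delta G = [F(\mathrm{bound, demixed}) - F(\mathrm{unbound,
#' uniform})] / n_p} in kJ/mol: the binding energy at the demixed
#' equilibrium composition including the mixing-entropy cost of the
#' demixing. With demixing suppressed (\code{demix = FALSE}) this reduces to
#' the ideal-mixing value \eqn{\sum_i \phi_i \mu_{ads,i}}.
#'
#' @param patch a [patchSystem()]
#' @param demix allow lipid demixing (default TRUE)
#' @return kJ/mol per peptide
#' @export
predictBindingEnergy <- function(patch, demix = TRUE) {
  if (!demix)
    return(sum(patch$phi * patch$mu[names(patch$phi)]))
  d <- equilibriumDemix(patch)
  (d$F - d$Funiform) / patch$np
}

#' Calibrate the peptide footprint area against measured excess lipids
#'
#' One-dimensional least-squares fit of the demixing model's per-peptide
#' excess lipids \eqn{\Gamma_i(A_p)} to measured targets (for instance
#' Kirkwood--Buff integrals from molecular dynamics), over a bracketing
#' interval of footprint areas. Equal weights by default.
#'
#' @param targets named vector of measured excess lipids per peptide
#' @param composition,nLipids,nPeptides,adsorbate,tables passed to
#'   [patchSystem()]
#' @param bounds search interval for Ap, nm^2
#' @param weights optional named weights of the squared deviations
#' @return list: Ap (nm^2), Gamma at the optimum, objective value, and the
#'   footprint radius sqrt(Ap/pi)
#' @export
optimizeFootprint <- function(targets,
                              composition = c(DOPE = 0.6, DOPS = 0.2,
                                              DOPC = 0.2),
                              nLipids = 2048, nPeptides = 64,
                              adsorbate = "R9", tables = materialTables(),
                              bounds = c(4, 40), weights = NULL) {
  if (length(targets) < 2) stop("need excess-lipid targets for at least 2 species")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(targets)),
                                                   names(targets))
  # keep the covered region strictly inside the patch
  phi <- checkFractions(composition, tables)
  apMax <- 0.95 * nLipids * sum(phi * tables@lipids$a0) / nPeptides
  bounds[2] <- min(bounds[2], apMax)
  obj <- function(Ap) {
    p <- patchSystem(composition, nLipids, nPeptides, Ap = Ap,
                     adsorbate = adsorbate, tables = tables)
    G <- equilibriumDemix(p)$Gamma[names(targets)]
    sum(weights[names(targets)] * (G - targets)^2)
  }
  op <- optimize(obj, bounds, tol = 1e-8)
  if (min(abs(op$minimum - bounds)) < 1e-3 * diff(bounds))
    stop("no interior footprint optimum in the given bounds")
  p <- patchSystem(composition, nLipids, nPeptides, Ap = op$minimum,
                   adsorbate = adsorbate, tables = tables)
  list(Ap = op$minimum, Gamma = equilibriumDemix(p)$Gamma,
       objective = op$objective, radius = sqrt(op$minimum / pi))
}

#' Two-dimensional Kirkwood--Buff integral
#'
#' Excess number of neighbors from a 2D radial distribution function:
#' \deqn{\Gamma = \rho \int_0^{r_{max}} (g(r) - 1)\, 2\pi r\, dr}
#' by the trapezoid rule on the provided grid.
#'
#' @param r radial grid, nm (strictly increasing, starting at or above 0)
#' @param g g(r) samples on the grid
#' @param rho 2D number density, 1/nm^2
#' @param rmax upper integration limit (must lie within the grid)
#' @return excess neighbor count
#' @export
kirkwoodBuff2D <- function(r, g, rho, rmax = max(r)) {
  stopifnot(length(r) == length(g), all(diff(r) > 0))
  if (rmax > max(r) + 1e-12) stop("rmax beyond the sampled grid")
  keep <- r <= rmax
  rr <- r[keep]; gg <- g[keep]
  if (rr[length(rr)] < rmax) {   # interpolate the endpoint
    gend <- stats::approx(r, g, xout = rmax)$y
    rr <- c(rr, rmax); gg <- c(gg, gend)
  }
  integrand <- (gg - 1) * 2 * pi * rr
  rho * sum(diff(rr) * (head(integrand, -1) + tail(integrand, -1)) / 2)
}
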