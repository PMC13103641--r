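#' @include membrane-system.R
NULL

#' Energy decomposition of a membrane system
#'
#' The total free energy is
#' \deqn{F = E_{HF} + E_{pV} + E_{stretch} + \sum_{face} F_b + F_{mix,b}}
#' with the Helfrich term \eqn{E_{HF} = \int dA\, [\kappa/2 (2H - J_s)^2 +
#' \bar\kappa_b K_G]}, osmotic work \eqn{E_{pV} = c_0 k_B T [(V - V_0) - V_0
#' \log(V/V_0)]}, area compression \eqn{E_{stretch} = (K_A/2)(1 - A/A_0)^2
#' A_0}, peptide binding \eqn{F_b} and ideal mixing entropy \eqn{F_{mix}}.
#' All values in kT.
#'
#' @slot EHF,EpV,Estretch,Fb,Fmix,total energies, kT
#' @slot area nm^2; @slot volume nm^3
#' @slot nu instantaneous reduced volume; @slot nu0 target reduced volume
#' @export
setClass("EnergyBreakdown",
  representation(EHF = "numeric", EpV = "numeric", Estretch = "numeric",
                 Fb = "numeric", Fmix = "numeric", total = "numeric",
                 area = "numeric", volume = "numeric", nu = "numeric",
                 nu0 = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  s <- object@EHF + object@EpV + object@Estretch + object@Fb + object@Fmix
  if (abs(s - object@total) > 1e-9 * max(1, abs(object@total)))
    return("terms do not sum to total")
  if (object@EpV < -1e-9 || object@Estretch < -1e-9)
    return("osmotic and stretch terms must be non-negative")
  TRUE
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf(paste0("EnergyBreakdown (kT): EHF %.4g | EpV %.4g | Estretch %.4g",
                     " | Fb %.4g | Fmix %.4g | total %.6g\n"),
              object@EHF, object@EpV, object@Estretch, object@Fb, object@Fmix,
              object@total))
  cat(sprintf("  A = %.6g nm^2, V = %.6g nm^3, nu = %.4f (target nu0 = %.4f)\n",
              object@area, object@volume, object@nu, object@nu0))
})

breakdownFromList <- function(b) {
  new("EnergyBreakdown", EHF = b$EHF, EpV = b$EpV, Estretch = b$Estretch,
      Fb = b$Fb, Fmix = b$Fmix, total = b$total, area = b$area,
      volume = b$volume, nu = b$nu, nu0 = b$nu0)
}

#' @describeIn totalEnergy full decomposition of a membrane system
#' @param x a \linkS4class{MembraneSystem}
#' @param order quadrature order
#' @export
setMethod("totalEnergy", "MembraneSystem", function(x, order = 4) {
  a <- systemArgs(x, order = order)
  res <- do.call(cppSystemEnergy, a)
  bd <- breakdownFromList(res$breakdown)
  attr(bd, "perFace") <- as.data.frame(res$perFace)
  bd
})

#' Helfrich curvature energy of a system
#' @param system a \linkS4class{MembraneSystem}
#' @param order quadrature order
#' @return kT
#' @export
helfrichEnergy <- function(system, order = 4) {
  totalEnergy(system, order = order)@EHF
}

#' Osmotic volume energy
#'
#' \eqn{E_{pV} = c_0 k_B T [(V - V_0) - V_0 \ln(V/V_0)]}, non-negative with
#' its minimum (zero) exactly at \eqn{V = V_0}. The concentration converts as
#' 1 mM = 6.022e-4 molecules/nm^3, so the returned value is in kT.
#'
#' @param V volume, nm^3
#' @param params an \linkS4class{EnsembleParams}
#' @return kT
#' @export
osmoticEnergy <- function(V, params) {
  if (any(V <= 0)) stop("volume must be positive")
  V0 <- params@V0
  Vf <- pmax(V, 1e-6 * V0)
  mMPerNm3(params@c0) * ((Vf - V0) - V0 * log(Vf / V0))
}

#' Area-compression energy
#'
#' \eqn{E_{stretch} = (K_A/2) (1 - A/A_0)^2 A_0}; the reference-area factor
#' makes the expression an energy for a per-area modulus KA (pN/nm converted
#' to kT/nm^2 at the ensemble temperature).
#'
#' @param A area, nm^2
#' @param params an \linkS4class{EnsembleParams}
#' @return kT
#' @export
stretchEnergy <- function(A, params) {
  ka <- params@KA * pNnmPerKT(params@temperature)
  0.5 * ka * (1 - A / params@A0)^2 * params@A0
}

#' Ideal mixing free energy of one (or many) leaflet populations
#'
#' \eqn{F_{mix} = k_B T\, M \sum_i \phi_i \ln \phi_i} with the convention
#' \eqn{0 \ln 0 = 0}; M is the lipid population behind the fractions.
#'
#' @param M lipid count (scalar or vector, recycled against rows)
#' @param fractions numeric vector (or matrix with one population per row)
#'   of lipid fractions
#' @return kT
#' @export
mixingFreeEnergy <- function(M, fractions) {
  if (is.matrix(fractions)) {
    ent <- apply(fractions, 1, function(p) sum(ifelse(p > 0, p * log(p), 0)))
    return(sum(M * ent))
  }
  if (any(fractions < 0)) stop("negative fraction")
  M * sum(ifelse(fractions > 0, fractions * log(fractions), 0))
}

#' Local energy change of a proposed move
#'
#' Computes the free-energy difference of a single proposed edit from the
#' star of the touched vertex or the two touched faces, with the global
#' osmotic and stretching terms updated through the incremental area and
#' volume. Agrees with a full re-evaluation to numerical precision and is
#' the quantity the Metropolis sampler uses.
#'
#' @param system a \linkS4class{MembraneSystem}
#' @param move a list: \code{list(type = "vertex", id =, position =)},
#'   \code{list(type = "normal", id =, normal =)},
#'   \code{list(type = "lipid", from =, to =, species = c(i, j), amount =,
#'   leaflet =)}, \code{list(type = "peptide", from =, to =)} or
#'   \code{list(type = "null")}
#' @param order quadrature order
#' @return kT
#' @export
energyDelta <- function(system, move, order = 4) {
  a <- systemArgs(system, order = order)
  do.call(cppEnergyDelta, c(a, list(move = move)))
}
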