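#' @include vesiform-package.R
NULL

#' Material parameter tables
#'
#' Per-lipid monolayer elastic parameters and per-(lipid, adsorbate) binding
#' and curvature-generation parameters. The bundled defaults describe the
#' DOPE/DOPS/DOPC + nonaarginine (R9) / nonalysine (K9) system, with
#' monolayer bending moduli and spontaneous curvatures estimated from
#' all-atom simulation (real-space tilt fluctuations and stress-profile
#' moments) and whole-peptide binding free energies from potentials of mean
#' force on single-component bilayers.
#'
#' @slot lipids data.frame with columns name, kappa (monolayer bending
#'   modulus, kT), c0 (monolayer spontaneous curvature, 1/nm), a0 (area per
#'   lipid, nm^2).
#' @slot adsorbates named list; each entry a list with Ap (footprint area,
#'   nm^2) and a data.frame (rows matching the lipids) with mu (binding free
#'   energy, kJ/mol), Js (spontaneous curvature of the covered lipid,
#'   1/nm) and kappa (bending modulus of the covered lipid, kT).
#' @slot temperature K
#' @slot thickness monolayer-scale thickness d entering the Gaussian-modulus
#'   expansion, nm
#' @slot gaussFactor monolayer Gaussian factor: kbar_mono = -gaussFactor *
#'   kappa_mono
#' @export
setClass("MaterialTables",
  representation(lipids = "data.frame", adsorbates = "list",
                 temperature = "numeric", thickness = "numeric",
                 gaussFactor = "numeric"))

setValidity("MaterialTables", function(object) {
  lp <- object@lipids
  if (!all(c("name", "kappa", "c0", "a0") %in% names(lp)))
    return("lipids needs columns name, kappa, c0, a0")
  if (any(lp$kappa <= 0)) return("bending moduli must be positive")
  if (any(lp$a0 <= 0)) return("areas per lipid must be positive")
  for (ad in object@adsorbates) {
    if (ad$Ap <= 0) return("adsorbate footprint Ap must be positive")
    if (nrow(ad$table) != nrow(lp))
      return("adsorbate table must have one row per lipid")
    if (any(ad$table$kappa <= 0)) return("covered bending moduli must be positive")
  }
  if (object@gaussFactor < 0) return("gaussFactor must be >= 0")
  TRUE
})

#' Default lipid table
#'
#' Monolayer bending modulus (kT), monolayer spontaneous curvature (1/nm) and
#' bilayer area per lipid (nm^2) for DOPE, DOPS and DOPC.
#' @export
defaultLipidTable <- function() {
  data.frame(name = c("DOPE", "DOPS", "DOPC"),
             kappa = c(15.83, 14.27, 11.56),
             c0 = c(-0.24, -0.06, 0.0),
             a0 = c(0.6164, 0.6338, 0.6802),
             stringsAsFactors = FALSE)
}

#' Default adsorbate tables (R9 and K9)
#'
#' Whole-peptide binding free energies mu (kJ/mol) to single-component
#' bilayers, spontaneous curvature Js and bending modulus kappa of the
#' peptide-covered lipid, per lipid of [defaultLipidTable()]. K9 does not
#' bind the uncharged lipids; its covered-lipid elastic parameters for those
#' default to the bare-lipid values and its mu to 0.
#' @export
defaultAdsorbateTables <- function() {
  list(
    R9 = list(Ap = 14.786,
              table = data.frame(name = c("DOPE", "DOPS", "DOPC"),
                                 mu = c(-23.2, -86.0, -19.6),
                                 Js = c(-0.30, -0.26, -0.03),
                                 kappa = c(16.20, 13.16, 10.88),
                                 stringsAsFactors = FALSE)),
    K9 = list(Ap = 14.786,
              table = data.frame(name = c("DOPE", "DOPS", "DOPC"),
                                 mu = c(-0.7, -51.4, 0.0),
                                 Js = c(-0.24, -0.17, 0.0),
                                 kappa = c(15.83, 16.26, 11.56),
                                 stringsAsFactors = FALSE)))
}

#' Construct material tables
#'
#' @param lipids lipid data.frame (see [defaultLipidTable()])
#' @param adsorbates adsorbate list (see [defaultAdsorbateTables()])
#' @param temperature K
#' @param thickness d of the Gaussian-modulus expansion, nm
#' @param gaussFactor monolayer Gaussian factor in \[0.8, 0.85\] by
#'   convention; results are robust against values down to 0
#' @export
materialTables <- function(lipids = defaultLipidTable(),
                           adsorbates = defaultAdsorbateTables(),
                           temperature = 300, thickness = 2.0,
                           gaussFactor = 0.8) {
  new("MaterialTables", lipids = lipids, adsorbates = adsorbates,
      temperature = temperature, thickness = thickness,
      gaussFactor = gaussFactor)
}

setMethod("show", "MaterialTables", function(object) {
  cat("MaterialTables:", nrow(object@lipids), "lipids,",
      length(object@adsorbates), "adsorbates;",
      sprintf("T = %g K, d = %g nm, gaussFactor = %g\n",
              object@temperature, object@thickness, object@gaussFactor))
  print(object@lipids, row.names = FALSE)
})

#' Read / write a lipid table as TSV
#' @param path file path
#' @export
readLipidTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "kappa", "c0", "a0")
  if (!all(need %in% names(tab))) stop("lipid table needs columns ",
                                       paste(need, collapse = ", "))
  tab
}

#' @rdname readLipidTable
#' @param table a lipid data.frame
#' @export
writeLipidTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

checkFractions <- function(fractions, tables) {
  if (is.null(names(fractions))) stop("fractions must be named by lipid")
  unknown <- setdiff(names(fractions), tables@lipids$name)
  if (length(unknown)) stop("unknown lipid name(s): ", paste(unknown, collapse = ", "))
  if (any(fractions < -1e-12)) stop("negative lipid fraction")
  if (abs(sum(fractions) - 1) > 1e-9) stop("lipid fractions must sum to 1")
  full <- stats::setNames(numeric(nrow(tables@lipids)), tables@lipids$name)
  full[names(fractions)] <- fractions
  full
}

#' Composition-mixed spontaneous curvature
#'
#' Linear blend of the per-lipid monolayer spontaneous curvatures with the
#' area fractions: \eqn{J_s = \sum_i \phi_i c_i^0}.
#'
#' @param fractions named lipid fractions summing to 1
#' @param tables a \linkS4class{MaterialTables}
#' @return monolayer Js in 1/nm
#' @export
mixSpontaneousCurvature <- function(fractions, tables = materialTables()) {
  phi <- checkFractions(fractions, tables)
  sum(phi * tables@lipids$c0)
}

#' Composition-mixed bending rigidity
#'
#' Harmonic average over the components:
#' \eqn{1/\kappa = \sum_i \phi_i / \kappa_i}; the result always lies between
#' the smallest and largest component modulus.
#'
#' @inheritParams mixSpontaneousCurvature
#' @return monolayer kappa in kT
#' @export
mixBendingRigidity <- function(fractions, tables = materialTables()) {
  phi <- checkFractions(fractions, tables)
  if (any(tables@lipids$kappa <= 0)) stop("bending moduli must be positive")
  1 / sum(phi / tables@lipids$kappa)
}

#' Adsorbate coverage fraction
#'
#' \eqn{\phi_p = n_p A_p / A_l}, clamped at 1 (full coverage) with a warning.
#'
#' @param np integer number of adsorbed peptides
#' @param Ap footprint area, nm^2
#' @param Al reference area of the lipid patch, nm^2
#' @export
adsorbateCoverage <- function(np, Ap, Al) {
  if (Al <= 0) stop("reference area must be positive")
  phip <- np * Ap / Al
  if (phip > 1 + 1e-12) {
    warning(sprintf("coverage %.3f exceeds 1; clamping", phip))
    phip <- 1
  }
  min(phip, 1)
}

#' Spontaneous curvature under adsorbate coverage
#'
#' \eqn{J_s = \phi_p \sum_i \phi_i J_{s,ip} + (1 - \phi_p) J_{s,n}} with
#' \eqn{J_{s,n}} the free-lipid blend of [mixSpontaneousCurvature()]. The sum
#' over covered-lipid curvatures is fraction-weighted, mirroring the
#' free-lipid rule.
#'
#' @inheritParams mixSpontaneousCurvature
#' @param coverage adsorbate coverage fraction in \[0, 1\]
#' @param adsorbate adsorbate name (entry of the tables)
#' @return monolayer Js in 1/nm
#' @export
adsorbateSpontaneousCurvature <- function(fractions, coverage,
                                          adsorbate = "R9",
                                          tables = materialTables()) {
  stopifnot(coverage >= 0, coverage <= 1)
  phi <- checkFractions(fractions, tables)
  ad <- tables@adsorbates[[adsorbate]]
  if (is.null(ad)) stop("unknown adsorbate: ", adsorbate)
  if (any(phi > 0 & is.na(ad$table$Js)))
    stop("missing covered-lipid Js for a present lipid")
  coverage * sum(phi * ad$table$Js) + (1 - coverage) * sum(phi * tables@lipids$c0)
}

#' Bending rigidity under adsorbate coverage
#'
#' Harmonic (area-fraction) blend of covered and free material:
#' \eqn{1/\kappa = \sum_i \phi_i [\phi_p/\kappa_{ip} + (1-\phi_p)/\kappa_i]}.
#'
#' @inheritParams adsorbateSpontaneousCurvature
#' @export
adsorbateBendingRigidity <- function(fractions, coverage, adsorbate = "R9",
                                     tables = materialTables()) {
  stopifnot(coverage >= 0, coverage <= 1)
  phi <- checkFractions(fractions, tables)
  ad <- tables@adsorbates[[adsorbate]]
  if (is.null(ad)) stop("unknown adsorbate: ", adsorbate)
  1 / sum(phi * (coverage / ad$table$kappa + (1 - coverage) / tables@lipids$kappa))
}

#' Peptide binding free energy of a face
#'
#' \eqn{F_b = n_p \sum_i \phi_i \mu_{ads,i}}, evaluated with the lipid
#' fractions of the face the peptides sit on. Tabulated in kJ/mol; converted
#' to kT at the table temperature when \code{units = "kT"}.
#'
#' @inheritParams adsorbateSpontaneousCurvature
#' @param np number of peptides
#' @param units "kJ/mol" (default) or "kT"
#' @export
bindingFreeEnergy <- function(np, fractions, adsorbate = "R9",
                              tables = materialTables(), units = "kJ/mol") {
  phi <- checkFractions(fractions, tables)
  ad <- tables@adsorbates[[adsorbate]]
  if (is.null(ad)) stop("unknown adsorbate: ", adsorbate)
  fb <- np * sum(phi * ad$table$mu)
  if (units == "kT") fb / kTkJmol(tables@temperature) else fb
}

#' Bilayer Gaussian bending modulus
#'
#' Linear-in-thickness expansion around the bilayer midplane:
#' \deqn{\bar\kappa_b = 2\bar\kappa - 4 J_s \kappa d, \qquad
#'       \bar\kappa = -f\,\kappa,}
#' with monolayer \eqn{\kappa} (kT), monolayer \eqn{J_s} (1/nm), thickness d
#' (nm) and the monolayer Gaussian factor f (0.8--0.85 by convention).
#'
#' @param kappa monolayer bending modulus, kT
#' @param Js monolayer spontaneous curvature, 1/nm
#' @param thickness d, nm
#' @param monolayerFactor f
#' @return bilayer Gaussian modulus, kT
#' @export
gaussianModulusBilayer <- function(kappa, Js, thickness = 2.0,
                                   monolayerFactor = 0.8) {
  stopifnot(thickness >= 0)
  kbar <- -monolayerFactor * kappa
  2 * kbar - 4 * Js * kappa * thickness
}

#' Per-face bilayer material parameters
#'
#' Combines the two leaflets of one face into bilayer parameters. The
#' peptides sit on the outer leaflet only; with the outward-normal sign
#' convention the inner leaflet's spontaneous curvature enters with opposite
#' sign, so symmetric bare leaflets give a vanishing bilayer Js:
#' \deqn{\kappa_b = \kappa_{out} + \kappa_{in}, \quad
#'       J_s = J_{s,out} - J_{s,in},}
#' and the Gaussian modulus generalizes the symmetric expansion per leaflet:
#' \deqn{\bar\kappa_b = -f(\kappa_{out} + \kappa_{in})
#'       - 2 d (J_{s,out}\kappa_{out} + J_{s,in}\kappa_{in}).}
#'
#' @param outer named outer-leaflet lipid fractions
#' @param inner named inner-leaflet lipid fractions
#' @param np peptides on the outer leaflet
#' @param Al outer-leaflet reference area of the face, nm^2
#' @param adsorbate adsorbate name
#' @param tables a \linkS4class{MaterialTables}
#' @return list with kappa (kT), Js (1/nm), kbar (kT), coverage, and the
#'   face binding energy Fb (kT)
#' @export
faceMaterial <- function(outer, inner, np = 0, Al = NULL, adsorbate = "R9",
                         tables = materialTables()) {
  if (is.null(Al)) Al <- tables@adsorbates[[adsorbate]]$Ap
  phip <- if (np > 0) adsorbateCoverage(np, tables@adsorbates[[adsorbate]]$Ap, Al) else 0
  JsOut <- adsorbateSpontaneousCurvature(outer, phip, adsorbate, tables)
  kOut <- adsorbateBendingRigidity(outer, phip, adsorbate, tables)
  JsIn <- mixSpontaneousCurvature(inner, tables)
  kIn <- mixBendingRigidity(inner, tables)
  kbar <- -tables@gaussFactor * (kOut + kIn) -
    2 * tables@thickness * (JsOut * kOut + JsIn * kIn)
  list(kappa = kOut + kIn, Js = JsOut - JsIn, kbar = kbar, coverage = phip,
       Fb = bindingFreeEnergy(np, outer, adsorbate, tables, units = "kT"))
}
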