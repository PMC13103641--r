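#' @include surface-mesh.R material.R
NULL

#' Ensemble parameters
#'
#' Fixed thermodynamic-ensemble inputs of the total energy: osmolarity,
#' target volume, stress-free reference area, area modulus and temperature.
#'
#' @slot c0 osmolyte concentration, mM
#' @slot V0 target (zero-osmotic-pressure) volume, nm^3
#' @slot A0 stress-free reference area, nm^2
#' @slot KA area compressibility modulus, pN/nm
#' @slot temperature K
#' @export
setClass("EnsembleParams",
  representation(c0 = "numeric", V0 = "numeric", A0 = "numeric",
                 KA = "numeric", temperature = "numeric"))

setValidity("EnsembleParams", function(object) {
  if (any(c(object@c0, object@V0, object@A0, object@KA, object@temperature) <= 0))
    return("all ensemble parameters must be positive")
  TRUE
})

#' @param c0 osmolyte concentration, mM (physiological buffers ~300)
#' @param V0 target volume, nm^3
#' @param A0 stress-free area, nm^2
#' @param KA area modulus, pN/nm
#' @param temperature K
#' @rdname EnsembleParams-class
#' @export
ensembleParams <- function(c0 = 300, V0, A0, KA = 200, temperature = 300) {
  new("EnsembleParams", c0 = c0, V0 = V0, A0 = A0, KA = KA,
      temperature = temperature)
}

# internal units for the compiled core
ensembleInternal <- function(params, tables) {
  list(c0nm = mMPerNm3(params@c0), V0 = params@V0, A0 = params@A0,
       KA = params@KA * pNnmPerKT(params@temperature),
       d = tables@thickness, gaussFactor = tables@gaussFactor)
}

#' Membrane system: mesh + per-face state + materials + ensemble
#'
#' The simulated object: a closed curved-element mesh whose faces carry
#' per-leaflet lipid amounts (in nm^2 of reference area, so lipid-swap moves
#' conserve reference area exactly), integer peptide occupancies on the outer
#' leaflet, the material tables and the ensemble parameters.
#'
#' @slot mesh a \linkS4class{SurfaceMesh}
#' @slot amountsOuter,amountsInner numeric matrices (lipids x faces) of
#'   reference-area amounts, nm^2
#' @slot peptides integer per-face peptide counts (outer leaflet)
#' @slot adsorbate active adsorbate name
#' @slot tables a \linkS4class{MaterialTables}
#' @slot ensemble an \linkS4class{EnsembleParams}
#' @export
setClass("MembraneSystem",
  representation(mesh = "SurfaceMesh", amountsOuter = "matrix",
                 amountsInner = "matrix", peptides = "integer",
                 adsorbate = "character", tables = "MaterialTables",
                 ensemble = "EnsembleParams"))

setValidity("MembraneSystem", function(object) {
  nf <- nFaces(object@mesh)
  nl <- nrow(object@tables@lipids)
  if (!all(dim(object@amountsOuter) == c(nl, nf))) return("amountsOuter has wrong shape")
  if (!all(dim(object@amountsInner) == c(nl, nf))) return("amountsInner has wrong shape")
  if (length(object@peptides) != nf) return("one peptide count per face required")
  if (any(object@peptides < 0)) return("negative peptide count")
  if (any(object@amountsOuter < -1e-9) || any(object@amountsInner < -1e-9))
    return("negative lipid amount")
  ad <- object@tables@adsorbates[[object@adsorbate]]
  if (is.null(ad)) return("adsorbate not found in tables")
  cover <- object@peptides * ad$Ap
  if (any(cover > colSums(object@amountsOuter) * (1 + 1e-6)))
    return("peptide coverage exceeds 1 on some face")
  TRUE
})

#' Construct a membrane system
#'
#' Lipid amounts are initialized uniformly: every face receives the same
#' per-leaflet reference area (total mesh area / number of faces) split
#' across species by the area fractions that correspond to the given number
#' composition. Peptides are laid down deterministically, cycling over the
#' faces until the requested coverage is reached; a Monte Carlo run
#' redistributes them thermally.
#'
#' @param mesh a closed \linkS4class{SurfaceMesh}
#' @param composition named number fractions of the lipids (both leaflets)
#' @param coverage target outer-leaflet adsorbate coverage fraction
#'   \eqn{\phi_p} in \[0, 1\]
#' @param adsorbate adsorbate name
#' @param tables material tables
#' @param ensemble ensemble parameters; if missing, built with A0 equal to
#'   the current mesh area and V0 from \code{nu0}
#' @param nu0 target reduced volume used to derive V0 when \code{ensemble}
#'   is missing
#' @param referenceArea total stress-free reference area of the lipids,
#'   nm^2; defaults to the current mesh area. Pass an explicit value when
#'   comparing systems built on differently deformed meshes, so they carry
#'   identical lipid budgets.
#' @return a \linkS4class{MembraneSystem}
#' @export
membraneSystem <- function(mesh, composition = c(DOPE = 0.6, DOPS = 0.2,
                                                 DOPC = 0.2),
                           coverage = 0, adsorbate = "R9",
                           tables = materialTables(), ensemble = NULL,
                           nu0 = 1.0, referenceArea = NULL) {
  if (!isClosedMesh(mesh)) stop("membraneSystem needs a closed mesh")
  lp <- tables@lipids
  phi <- checkFractions(composition, tables)
  areaFrac <- phi * lp$a0 / sum(phi * lp$a0)
  av <- totalAreaVolume(mesh)
  if (is.null(referenceArea)) referenceArea <- av[["area"]]
  nf <- nFaces(mesh)
  faceRef <- referenceArea / nf
  amt <- matrix(rep(areaFrac * faceRef, nf), nrow = nrow(lp))
  rownames(amt) <- lp$name
  if (is.null(ensemble))
    ensemble <- ensembleParams(V0 = nu0 * referenceArea^1.5 / (6 * sqrt(pi)),
                               A0 = referenceArea)
  ad <- tables@adsorbates[[adsorbate]]
  if (is.null(ad)) stop("unknown adsorbate: ", adsorbate)
  npTotal <- floor(coverage * referenceArea / ad$Ap)
  np <- integer(nf)
  capacity <- floor(faceRef / ad$Ap + 1e-9)
  if (npTotal > nf * capacity)
    stop("requested coverage exceeds face capacity")
  k <- 0L
  while (npTotal > 0) {
    f <- (k %% nf) + 1L
    if (np[f] < capacity) { np[f] <- np[f] + 1L; npTotal <- npTotal - 1 }
    k <- k + 1L
  }
  new("MembraneSystem", mesh = mesh, amountsOuter = amt, amountsInner = amt,
      peptides = np, adsorbate = adsorbate, tables = tables,
      ensemble = ensemble)
}

setMethod("show", "MembraneSystem", function(object) {
  cat("MembraneSystem:", nFaces(object@mesh), "faces,",
      sum(object@peptides), "peptides of", object@adsorbate, "\n")
  show(object@mesh)
  nu0 <- 6 * sqrt(pi) * object@ensemble@V0 / object@ensemble@A0^1.5
  cat(sprintf("  ensemble: c0 = %g mM, KA = %g pN/nm, target nu0 = %.3f\n",
              object@ensemble@c0, object@ensemble@KA, nu0))
})

#' @export
setMethod("peptideCounts", "MembraneSystem", function(x) x@peptides)

#' Per-face, per-leaflet lipid fractions
#' @param x a MembraneSystem
#' @param leaflet "outer" or "inner"
#' @export
setMethod("leafletFractions", "MembraneSystem", function(x, leaflet = "outer") {
  amt <- if (leaflet == "outer") x@amountsOuter else x@amountsInner
  sweep(amt, 2, colSums(amt), "/")
})

# lipid-table list for the compiled core (energies converted to kT)
lipidInternal <- function(system) {
  tab <- system@tables
  lp <- tab@lipids
  ad <- tab@adsorbates[[system@adsorbate]]
  list(c0 = lp$c0, kappa = lp$kappa, a0 = lp$a0,
       Jsip = ad$table$Js, kappap = ad$table$kappa,
       mu = ad$table$mu / kTkJmol(tab@temperature))
}

systemArgs <- function(system, order = 4, svdTol = 1e-8) {
  m <- system@mesh
  list(V = m@vertices, N = m@normals, Fm = m@faces, EVm = m@edges,
       EFm = m@edgeFaces, FEm = m@faceEdges,
       aOut = system@amountsOuter, aIn = system@amountsInner,
       npv = as.integer(system@peptides),
       lip = lipidInternal(system),
       Ap = system@tables@adsorbates[[system@adsorbate]]$Ap,
       ensL = ensembleInternal(system@ensemble, system@tables),
       order = as.integer(order), svdTol = svdTol)
}

systemFromResult <- function(system, res) {
  mesh <- new("SurfaceMesh", vertices = res$vertices, normals = res$normals,
              faces = res$faces, edges = res$EV, edgeFaces = res$EF,
              faceEdges = res$FE)
  amtO <- res$amountsOuter
  amtI <- res$amountsInner
  rownames(amtO) <- rownames(system@amountsOuter)
  rownames(amtI) <- rownames(system@amountsInner)
  new("MembraneSystem", mesh = mesh, amountsOuter = amtO, amountsInner = amtI,
      peptides = as.integer(res$np), adsorbate = system@adsorbate,
      tables = system@tables, ensemble = system@ensemble)
}

#' Flip one interior edge of a membrane system
#'
#' Replaces the shared edge of two adjacent triangles by the opposite
#' diagonal. The two faces' lipid amounts and peptides are pooled and
#' redistributed proportionally to the new face areas (peptides integer,
#' biased to the larger face on ties), so species totals, reference area and
#' Euler characteristic are conserved exactly. Illegal flips (boundary edge,
#' duplicate diagonal, valence below 3, quality guards) raise an error and
#' leave the system untouched.
#'
#' @param system a \linkS4class{MembraneSystem}
#' @param edge edge index
#' @return the updated system, with the local energy change in attribute
#'   \code{deltaF}
#' @export
flipEdge <- function(system, edge) {
  a <- systemArgs(system)
  res <- do.call(cppFlipEdge, c(a, list(edge = as.integer(edge))))
  out <- systemFromResult(system, res)
  attr(out, "deltaF") <- res$deltaF
  out
}
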