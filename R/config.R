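# Structured run configuration (YAML). A config fully determines a
# simulation: geometry, composition, adsorbate load, ensemble, MC protocol
# and seed. Unknown keys are rejected so typos fail loudly.

#' Default run configuration
#'
#' The reference production setup: a 50 nm vesicle meshed so the mean face
#' area tracks the peptide footprint, 60:20:20 DOPE:DOPS:DOPC in both
#' leaflets, R9 at 50% outer-leaflet coverage, 300 mM osmolyte, area
#' modulus 200 pN/nm.
#'
#' @return nested named list
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    steps = 100000L,
    mesh = list(kind = "sphere", radius = 50, targetFaceArea = 14.786,
                frequency = NULL, path = NULL),
    composition = list(DOPE = 0.6, DOPS = 0.2, DOPC = 0.2),
    adsorbate = list(name = "R9", coverage = 0.5),
    ensemble = list(c0 = 300, KA = 200, temperature = 300, nu0 = 1.0),
    material = list(thickness = 2.0, gaussFactor = 0.8,
                    lipidTable = NULL, adsorbateTable = NULL),
    mc = list(stepVertex = 1.0, stepNormal = 1.0, stepLipid = NULL,
              mixVertex = 0.4, mixNormal = 0.3, mixLipid = 0.2,
              mixPeptide = 0.1, tune = TRUE, tuneBatch = 500L,
              tuneCycles = 10L, flipEvery = 1200L, flipIters = 10L,
              recordEvery = 1000L, snapshotEvery = 0L))
}

mergeChecked <- function(def, usr, path = "") {
  for (nm in names(usr)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(def))
      stop("unknown configuration key: ", here)
    if (is.list(def[[nm]]) && !is.null(usr[[nm]]) && is.list(usr[[nm]]) &&
        !is.null(names(def[[nm]])))
      def[[nm]] <- mergeChecked(def[[nm]], usr[[nm]], here)
    else def[nm] <- usr[nm]
  }
  def
}

#' Read and validate a run configuration
#'
#' Reads YAML, validates every key against [defaultRunConfig()] (unknown
#' keys raise an error naming them), fills defaults, and checks that all
#' referenced lipids exist.
#'
#' @param path YAML file
#' @return fully-resolved config list
#' @export
readRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- mergeChecked(defaultRunConfig(), usr)
  lipids <- if (is.null(cfg$material$lipidTable)) defaultLipidTable()$name
            else vapply(cfg$material$lipidTable, function(r) r$name, "")
  unknown <- setdiff(names(cfg$composition), lipids)
  if (length(unknown))
    stop("composition references unknown lipid(s): ",
         paste(unknown, collapse = ", "))
  if (abs(sum(unlist(cfg$composition)) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  cfg
}

#' @rdname readRunConfig
#' @param config a config list
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Materialize a configured run
#'
#' Builds the mesh, tables and \linkS4class{MembraneSystem} described by a
#' resolved configuration.
#'
#' @param config list from [readRunConfig()] or [defaultRunConfig()]
#' @return list(system, config, mcConfig)
#' @export
buildRun <- function(config = defaultRunConfig()) {
  mc <- config$mesh
  mesh <- if (!is.null(mc$path)) readMesh(mc$path)
  else switch(mc$kind,
    sphere = icosphereMesh(mc$radius, frequency = mc$frequency,
                           targetFaceArea = mc$targetFaceArea),
    stop("unknown mesh kind: ", mc$kind))
  lip <- if (is.null(config$material$lipidTable)) defaultLipidTable()
         else do.call(rbind, lapply(config$material$lipidTable, as.data.frame))
  ads <- if (is.null(config$material$adsorbateTable)) defaultAdsorbateTables()
         else config$material$adsorbateTable
  tables <- materialTables(lip, ads,
                           temperature = config$ensemble$temperature,
                           thickness = config$material$thickness,
                           gaussFactor = config$material$gaussFactor)
  av <- totalAreaVolume(mesh)
  ens <- ensembleParams(c0 = config$ensemble$c0,
                        V0 = v0FromNu0(config$ensemble$nu0, av[["area"]]),
                        A0 = av[["area"]], KA = config$ensemble$KA,
                        temperature = config$ensemble$temperature)
  sys <- membraneSystem(mesh, unlist(config$composition),
                        coverage = config$adsorbate$coverage,
                        adsorbate = config$adsorbate$name,
                        tables = tables, ensemble = ens)
  m <- config$mc
  mcc <- mcConfig(stepVertex = m$stepVertex, stepNormal = m$stepNormal,
                  stepLipid = m$stepLipid,
                  mix = c(vertex = m$mixVertex, normal = m$mixNormal,
                          lipid = m$mixLipid, peptide = m$mixPeptide),
                  tune = m$tune, tuneBatch = m$tuneBatch,
                  tuneCycles = m$tuneCycles, flipEvery = m$flipEvery,
                  flipIters = m$flipIters, recordEvery = m$recordEvery,
                  snapshotEvery = m$snapshotEvery, seed = config$seed)
  list(system = sys, config = config, mcConfig = mcc)
}
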