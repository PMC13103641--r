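#' @include energy.R
NULL

#' Monte Carlo configuration
#'
#' Step sizes, move mix, autotuning and remeshing cadence of the Metropolis
#' sampler. Defaults follow the production protocol: vertex and normal step
#' sizes start at 1.0 (nm / dimensionless) and are autotuned over the first
#' 10 tuning cycles toward acceptance targets of about 0.3 (vertex), 0.7
#' (normal) and 0.8 (lipid); bond-flip remeshing runs every 1200 steps with
#' 10 iterations per cycle during production (a higher cadence is used while
#' constricting a neck); the move mix is 40/30/20/10 percent
#' vertex/normal/lipid/peptide.
#'
#' @param stepVertex initial vertex displacement scale, nm
#' @param stepNormal initial normal perturbation scale (dimensionless)
#' @param stepLipid lipid-swap amount scale, nm^2 of reference area; default
#'   is a quarter of the adsorbate footprint, set at run time when NULL
#' @param mix named move-mix weights (vertex, normal, lipid, peptide)
#' @param tune logical, autotune step sizes
#' @param tuneTargets named acceptance targets for vertex/normal/lipid moves
#' @param tuneBatch attempts per move class per tuning cycle
#' @param tuneCycles number of tuning cycles before step sizes freeze
#' @param flipEvery remeshing interval in MC steps (0 disables)
#' @param flipIters flip iterations per remeshing cycle
#' @param flipAttempts flip attempts per iteration; default one fifth of the
#'   edge count, set at run time when NULL
#' @param recordEvery energy-trace cadence, steps
#' @param snapshotEvery per-face snapshot cadence, steps (0 disables)
#' @param seed integer random seed
#' @param beta inverse temperature in 1/kT (the energies are already in kT,
#'   so 1 samples the physical ensemble)
#' @param maxH curvature hygiene cap: reject moves creating faces with
#'   |H| above this (1/nm); prevents near-conical degenerate elements
#' @param maxKGA companion cap on the per-face |KG|*area (an angle-deficit
#'   scale); spiky cone faces would otherwise let composition-dependent
#'   Gaussian moduli lower the energy without bound
#' @param lipidLeaflets also swap lipids on the inner leaflet (flip-flop
#'   between leaflets is never performed)
#' @return a validated config list
#' @export
mcConfig <- function(stepVertex = 1.0, stepNormal = 1.0, stepLipid = NULL,
                     mix = c(vertex = 0.4, normal = 0.3, lipid = 0.2,
                             peptide = 0.1),
                     tune = TRUE,
                     tuneTargets = c(vertex = 0.3, normal = 0.7, lipid = 0.8),
                     tuneBatch = 500, tuneCycles = 10,
                     flipEvery = 1200, flipIters = 10, flipAttempts = NULL,
                     recordEvery = 1000, snapshotEvery = 0, seed = 1,
                     beta = 1, maxH = 1.0, maxKGA = 2.0,
                     lipidLeaflets = TRUE) {
  stopifnot(stepVertex > 0, stepNormal > 0, all(mix >= 0), sum(mix) > 0,
            all(tuneTargets > 0), all(tuneTargets < 1))
  mix <- mix / sum(mix)
  list(stepVertex = stepVertex, stepNormal = stepNormal, stepLipid = stepLipid,
       mix = mix, tune = tune, tuneTargets = tuneTargets,
       tuneBatch = as.integer(tuneBatch), tuneCycles = as.integer(tuneCycles),
       flipEvery = as.integer(flipEvery), flipIters = as.integer(flipIters),
       flipAttempts = flipAttempts, recordEvery = as.integer(recordEvery),
       snapshotEvery = as.integer(snapshotEvery), seed = as.integer(seed),
       beta = beta, maxH = maxH, maxKGA = maxKGA,
       lipidLeaflets = isTRUE(lipidLeaflets))
}

cfgInternal <- function(config, system, steps, seed = NULL) {
  ad <- system@tables@adsorbates[[system@adsorbate]]
  stepL <- config$stepLipid
  if (is.null(stepL)) stepL <- 0.25 * ad$Ap
  fa <- config$flipAttempts
  if (is.null(fa)) fa <- max(10L, as.integer(nEdges(system@mesh) / 5))
  list(steps = as.numeric(steps), stepVertex = config$stepVertex,
       stepNormal = config$stepNormal, stepLipid = stepL,
       mixVertex = config$mix[["vertex"]], mixNormal = config$mix[["normal"]],
       mixLipid = config$mix[["lipid"]], beta = config$beta,
       tune = config$tune,
       tuneTargets = as.numeric(config$tuneTargets),
       tuneBatch = config$tuneBatch, tuneCycles = config$tuneCycles,
       flipEvery = as.numeric(config$flipEvery), flipIters = config$flipIters,
       flipAttempts = as.integer(fa),
       recordEvery = as.numeric(config$recordEvery),
       snapshotEvery = as.numeric(config$snapshotEvery),
       seed = as.numeric(if (is.null(seed)) config$seed else seed),
       maxH = config$maxH, maxKGA = config$maxKGA,
       lipidLeaflets = config$lipidLeaflets)
}

v0FromNu0 <- function(nu0, A0) nu0 * A0^1.5 / (6 * sqrt(pi))

#' Run Metropolis Monte Carlo on a membrane system
#'
#' Evolves vertices, vertex normals, per-face lipid amounts and peptide
#' occupancies with the Metropolis rule on the total free energy;
#' connectivity changes through bond-flip remeshing at the configured
#' cadence. A seeded run is reproducible bit-for-bit on the same build.
#'
#' @param system a \linkS4class{MembraneSystem}
#' @param steps number of MC steps
#' @param config an [mcConfig()] list
#' @param schedule optional data.frame(step, V0) piecewise-linear target
#'   volume schedule; the final scheduled V0 is kept in the returned system
#' @param seed overrides \code{config$seed} when given
#' @param order quadrature order
#' @return list with the updated \code{system}, the energy \code{trace}
#'   (data.frame), per-class \code{acceptance} rates, final tuned
#'   \code{stepSizes}, flip statistics, optional per-face \code{snapshots}
#'   and the final \code{breakdown}
#' @export
runMC <- function(system, steps, config = mcConfig(), schedule = NULL,
                  seed = NULL, order = 4) {
  a <- systemArgs(system, order = order)
  cfg <- cfgInternal(config, system, steps, seed)
  sched <- if (is.null(schedule)) list(step = numeric(0), V0 = numeric(0))
           else list(step = as.numeric(schedule$step), V0 = as.numeric(schedule$V0))
  res <- do.call(cppRunMC, c(a, list(cfg = cfg, sched = sched)))
  out <- systemFromResult(system, res)
  if (!is.null(schedule))
    out@ensemble@V0 <- tail(as.numeric(schedule$V0), 1)
  tr <- as.data.frame(res$trace)
  names(tr) <- c("step", "EHF", "EpV", "Estretch", "Fb", "Fmix", "total",
                 "area", "volume", "nu")
  snaps <- lapply(res$snapshots, function(sm) {
    colnames(sm) <- c("area", "H", "KG", "np", rownames(system@amountsOuter))
    sm
  })
  res$snapshots <- snaps
  list(system = out, trace = tr,
       acceptance = res$acceptance, stepSizes = res$stepSizes,
       flips = res$flips, guardRejections = res$guardRejections,
       snapshots = snaps, breakdown = breakdownFromList(res$breakdown))
}

#' Classify a configuration as stomatocyte (inward-budded)
#'
#' A stomatocyte exposes a face subpopulation with negative mean curvature
#' and positive Gaussian curvature (the interior of the bud); the
#' classification requires that region to cover at least \code{areaFraction}
#' of the total area.
#'
#' @param system a \linkS4class{MembraneSystem}
#' @param areaFraction threshold (default 0.05)
#' @param depth optional bud-depth requirement in units of the equivalent
#'   sphere curvature: faces count only when \eqn{H < -depth/R_{eq}}. The
#'   default 0 is the bare sign rule; thermally rough meshes benefit from a
#'   small positive depth (around 0.5) to exclude near-flat faces jittering
#'   across H = 0.
#' @export
isStomatocyte <- function(system, areaFraction = 0.05, depth = 0) {
  g <- faceGeometry(system@mesh)
  rEq <- sqrt(sum(g$area) / (4 * pi))
  frac <- sum(g$area[g$H < -depth / rEq & g$KG > 0]) / sum(g$area)
  structure(frac >= areaFraction, budArea = frac)
}

#' Shape-annealing protocol toward a stomatocyte
#'
#' Starting from a (near-)spherical state, the target volume is dropped to a
#' deep deflation target to drive invagination, then iterated back and forth
#' near the working reduced volume (a triangle wave of configurable
#' amplitude) under a high bond-flip cadence (every 500 steps, 10
#' iterations) to constrict a narrow neck while re-inflating. The deflation
#' default (0.60) lies below the two-fused-spheres value \eqn{1/\sqrt 2}:
#' at coarse resolutions the shallower target produces only dimples that
#' thermal shape fluctuations flatten again, while a transient deep
#' deflation followed by re-inflation retains the bud. Failure to invaginate
#' within the step budget is reported in the result, not raised.
#'
#' @param system a \linkS4class{MembraneSystem} (spherical initial mesh)
#' @param annealSteps steps of the deflation phase
#' @param constrictSteps steps of the neck-constriction phase
#' @param nu0Anneal deflation target (default 0.60)
#' @param nu0Constrict center of the constriction oscillation (default 0.75,
#'   the working reduced volume of the shape studies)
#' @param amplitude half-amplitude of the \eqn{\nu_0} triangle wave
#' @param period oscillation period, steps
#' @param config an [mcConfig()]; its flip cadence is overridden to every
#'   500 steps during both phases
#' @param seed master seed (phases use derived seeds)
#' @return list(system, stomatocyte flag, budArea, traces)
#' @export
annealToStomatocyte <- function(system, annealSteps = 2e5,
                                constrictSteps = 1e5,
                                nu0Anneal = 0.60,
                                nu0Constrict = 0.75, amplitude = 0.03,
                                period = 2e4, config = mcConfig(),
                                seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  A0 <- system@ensemble@A0
  cfgA <- config
  cfgA$flipEvery <- 500L
  # phase 1: deep deflation at a fixed target volume
  system@ensemble@V0 <- v0FromNu0(nu0Anneal, A0)
  r1 <- runMC(system, annealSteps, cfgA, seed = seed)
  # phase 2: constrict the neck, oscillating V0 near nu0Constrict
  knots <- seq(0, constrictSteps, by = period / 2)
  wave <- nu0Constrict + amplitude * rep_len(c(-1, 1), length(knots))
  sched <- data.frame(step = knots, V0 = v0FromNu0(wave, A0))
  cfgA$tune <- FALSE  # keep step sizes frozen after the first phase
  r2 <- runMC(r1$system, constrictSteps, cfgA, schedule = sched,
              seed = seed + 1L)
  st <- isStomatocyte(r2$system)
  list(system = r2$system, stomatocyte = as.logical(st),
       budArea = attr(st, "budArea"),
       traces = list(anneal = r1$trace, constrict = r2$trace))
}

#' Volume (hysteresis) scan along a shape branch
#'
#' For each target reduced volume the system is equilibrated in chunks until
#' the standard deviation of the instantaneous reduced volume over the
#' assessment window drops below \code{convergence} (flagged unconverged
#' past the chunk budget), then sampled; means are reported with
#' autocorrelation-corrected standard errors. The state is carried from one
#' grid point to the next, so scanning continues along the branch the
#' initial state sits on.
#'
#' @param system starting \linkS4class{MembraneSystem} (one branch)
#' @param nu0Grid vector of target reduced volumes
#' @param equilChunk steps per equilibration chunk
#' @param maxChunks chunk budget per grid point
#' @param sampleSteps production steps per grid point
#' @param convergence threshold on sd(nu)
#' @param config an [mcConfig()]
#' @param seed master seed
#' @param keepSystems return the end state of every grid point
#' @return list(results = data.frame, systems = list or NULL,
#'   system = final state)
#' @export
volumeScan <- function(system, nu0Grid, equilChunk = 5e4, maxChunks = 10,
                       sampleSteps = 1e5, convergence = 0.01,
                       config = mcConfig(), seed = NULL,
                       keepSystems = FALSE) {
  if (is.null(seed)) seed <- config$seed
  A0 <- system@ensemble@A0
  rows <- list()
  systems <- list()
  cfg <- config
  for (i in seq_along(nu0Grid)) {
    system@ensemble@V0 <- v0FromNu0(nu0Grid[i], A0)
    converged <- FALSE
    for (ch in seq_len(maxChunks)) {
      r <- runMC(system, equilChunk, cfg, seed = seed + 100L * i + ch)
      system <- r$system
      cfg$tune <- FALSE
      if (nrow(r$trace) > 3 && sd(r$trace$nu) < convergence) {
        converged <- TRUE
        break
      }
    }
    cfgS <- cfg
    # record densely enough for the autocorrelation analysis
    cfgS$recordEvery <- max(1L, as.integer(sampleSteps / 500))
    rs <- runMC(system, sampleSteps, cfgS, seed = seed + 100L * i + 99L)
    system <- rs$system
    tr <- rs$trace
    est <- statisticalInefficiency(tr$total)
    rows[[i]] <- data.frame(nu0 = nu0Grid[i],
                            EHF = mean(tr$EHF), EpV = mean(tr$EpV),
                            Estretch = mean(tr$Estretch), Fb = mean(tr$Fb),
                            Fmix = mean(tr$Fmix), total = mean(tr$total),
                            se = est$se, s = est$s, nu = mean(tr$nu),
                            sdnu = sd(tr$nu), converged = converged)
    if (keepSystems) systems[[i]] <- system
  }
  list(results = do.call(rbind, rows),
       systems = if (keepSystems) systems else NULL, system = system)
}
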