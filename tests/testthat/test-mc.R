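# Sampling correctness of the Metropolis engine: Boltzmann statistics on
# constructed two-level systems, conservation laws, autotuning, determinism.

# tables in which peptides change only the binding energy (no curvature or
# rigidity effect), so two-level tests isolate Fb
inertTables <- function(muA, muB) {
  materialTables(
    lipids = data.frame(name = c("A", "B"), kappa = c(14, 14), c0 = c(0, 0),
                        a0 = c(0.65, 0.65)),
    adsorbates = list(P = list(Ap = 14.786,
                               table = data.frame(name = c("A", "B"),
                                                  mu = c(muA, muB),
                                                  Js = c(0, 0),
                                                  kappa = c(14, 14)))),
    gaussFactor = 0)
}

peptideOnlyConfig <- function(seed, snapshotEvery = 50) {
  mcConfig(mix = c(vertex = 0, normal = 0, lipid = 0, peptide = 1),
           tune = FALSE, flipEvery = 0, recordEvery = 0,
           snapshotEvery = snapshotEvery, seed = seed)
}

test_that("one peptide over faces with a 2 kT binding contrast samples Boltzmann", {
  # face 1 is pure lipid A with mu_A = -2 kT; all other faces pure B, mu_B = 0
  dE <- 2 * kTkJmol(300)   # 2 kT in kJ/mol
  tab <- inertTables(-dE, 0)
  mesh <- octahedron(10)
  sys <- membraneSystem(mesh, c(A = 0.5, B = 0.5), coverage = 0,
                        adsorbate = "P", tables = tab)
  faceRef <- sum(sys@amountsOuter[, 1])
  sys@amountsOuter[] <- 0
  sys@amountsOuter[1, 1] <- faceRef          # face 1: pure A
  sys@amountsOuter[2, 2:8] <- faceRef        # others: pure B
  sys@amountsInner <- sys@amountsOuter
  sys@peptides <- c(1L, rep(0L, 7))
  r <- runMC(sys, 2e5, peptideOnlyConfig(seed = 5))
  occ1 <- vapply(r$snapshots, function(sm) sm[1, "np"], numeric(1))
  pExp <- exp(2) / (exp(2) + 7)   # Boltzmann occupancy of the favored face
  est <- statisticalInefficiency(occ1)
  expect_gt(est$se, 0)
  expect_lt(abs(mean(occ1) - pExp), 3 * est$se + 1e-12)
  # and the estimate is actually informative
  expect_lt(est$se, 0.05)
  # conservation of the total peptide count
  expect_identical(sum(r$system@peptides), 1L)
})

test_that("equal binding energies give uniform peptide occupancy", {
  tab <- inertTables(0, 0)
  mesh <- octahedron(10)
  sys <- membraneSystem(mesh, c(A = 0.5, B = 0.5), coverage = 0,
                        adsorbate = "P", tables = tab)
  sys@peptides <- c(1L, rep(0L, 7))
  r <- runMC(sys, 2e5, peptideOnlyConfig(seed = 9))
  occ1 <- vapply(r$snapshots, function(sm) sm[1, "np"], numeric(1))
  est <- statisticalInefficiency(occ1)
  expect_lt(abs(mean(occ1) - 1 / 8), 3 * est$se + 1e-12)
})

test_that("lipid swaps with equal energies stay symmetric about the mean", {
  tab <- inertTables(0, 0)
  mesh <- octahedron(10)
  sys <- membraneSystem(mesh, c(A = 0.5, B = 0.5), coverage = 0,
                        adsorbate = "P", tables = tab)
  cfg <- mcConfig(mix = c(vertex = 0, normal = 0, lipid = 1, peptide = 0),
                  tune = FALSE, flipEvery = 0, recordEvery = 0,
                  snapshotEvery = 100, seed = 13, lipidLeaflets = FALSE)
  r <- runMC(sys, 2e5, cfg)
  phiA <- vapply(r$snapshots, function(sm) sm[1, 5], numeric(1))
  est <- statisticalInefficiency(phiA)
  expect_lt(abs(mean(phiA) - 0.5), 3 * est$se + 1e-12)
  expect_gt(stats::sd(phiA), 0.01)  # the composition really fluctuates
})

test_that("conservation laws hold over a mixed-move run with remeshing", {
  sys <- membraneSystem(sphere320, coverage = 0.4)
  totOut <- rowSums(sys@amountsOuter)
  totIn <- rowSums(sys@amountsInner)
  npT <- sum(sys@peptides)
  r <- runMC(sys, 2e4, mcConfig(seed = 17, flipEvery = 500))
  s2 <- r$system
  expect_lt(max(abs(rowSums(s2@amountsOuter) - totOut)), 1e-9 * sum(totOut))
  expect_lt(max(abs(rowSums(s2@amountsInner) - totIn)), 1e-9 * sum(totIn))
  expect_identical(sum(s2@peptides), npT)
  expect_equal(eulerCharacteristic(s2@mesh), 2)
  expect_true(validObject(s2))
  expect_gt(r$flips[["accepted"]], 0)
})

test_that("autotuning drives the vertex acceptance to its target", {
  sys <- membraneSystem(sphere320, coverage = 0)
  # deliberately bad starting step
  r1 <- runMC(sys, 2e4, mcConfig(stepVertex = 5, seed = 23))
  tuned <- r1$stepSizes[["vertex"]]
  expect_lt(tuned, 5)   # too-large step must shrink
  r2 <- runMC(r1$system, 2e4, mcConfig(stepVertex = tuned, tune = FALSE,
                                       seed = 29))
  expect_lt(abs(r2$acceptance[["vertex"]] - 0.3), 0.1)
})

test_that("seeded runs are bit-reproducible; different seeds decorrelate", {
  sys <- membraneSystem(sphere320, coverage = 0.3)
  a <- runMC(sys, 5000, mcConfig(seed = 31))
  b <- runMC(sys, 5000, mcConfig(seed = 31))
  expect_identical(a$trace, b$trace)
  expect_identical(a$system@mesh@vertices, b$system@mesh@vertices)
  c <- runMC(sys, 5000, mcConfig(seed = 32))
  expect_false(identical(a$trace$total, c$trace$total))
})

test_that("trace bookkeeping: decomposition sums to total at every record", {
  sys <- membraneSystem(sphere320, coverage = 0.3)
  r <- runMC(sys, 5000, mcConfig(seed = 37, recordEvery = 500))
  with(r$trace, expect_lt(max(abs(EHF + EpV + Estretch + Fb + Fmix - total)),
                          1e-6))
  expect_equal(nrow(r$trace), 11)  # step 0 plus 10 records
})

test_that("the shape-annealing protocol invaginates; without driving it stays round", {
  sys <- membraneSystem(icosphereMesh(50, frequency = 5), coverage = 0.5,
                        adsorbate = "R9", referenceArea = 4 * pi * 2500)
  an <- annealToStomatocyte(sys, annealSteps = 2e5, constrictSteps = 1e5,
                            seed = 77)
  expect_true(an$stomatocyte)
  expect_gt(an$budArea, 0.05)
  # a deflation target of 1 provides no driving force: no deep bud appears
  flat <- runMC(sys, 1e5, mcConfig(seed = 78))
  expect_false(isStomatocyte(flat$system, depth = 0.5))
})

test_that("volume scan steps along a branch and reports corrected errors", {
  sys <- membraneSystem(sphere320, coverage = 0, nu0 = 0.95)
  sc <- volumeScan(sys, nu0Grid = c(0.92, 0.88), equilChunk = 2e4,
                   maxChunks = 3, sampleSteps = 3e4,
                   config = mcConfig(seed = 53), keepSystems = TRUE)
  res <- sc$results
  expect_equal(nrow(res), 2)
  expect_equal(res$nu0, c(0.92, 0.88))
  # the instantaneous reduced volume follows the targets downward
  expect_true(all(diff(res$nu) < 0))
  expect_true(all(res$se > 0))
  expect_true(all(res$s >= 1))
  expect_true(all(is.logical(res$converged)))
  # hysteresis continuation: the branch state is carried between points
  expect_length(sc$systems, 2)
  expect_equal(6 * sqrt(pi) * sc$system@ensemble@V0 / sys@ensemble@A0^1.5,
               0.88, tolerance = 1e-12)
})
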