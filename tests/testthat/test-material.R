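tab <- materialTables()

test_that("spontaneous-curvature mixing: pure lipids and hand-mixed blends", {
  expect_equal(mixSpontaneousCurvature(c(DOPE = 1), tab), -0.24)
  expect_equal(mixSpontaneousCurvature(c(DOPC = 1), tab), 0.0)
  expect_equal(mixSpontaneousCurvature(defaultComposition, tab),
               0.6 * -0.24 + 0.2 * -0.06 + 0.2 * 0, tolerance = 1e-12)
  expect_error(mixSpontaneousCurvature(c(DLPC = 1), tab), "unknown lipid")
})

test_that("bending-rigidity mixing is harmonic and bounded by the components", {
  expect_equal(mixBendingRigidity(c(DOPS = 1), tab), 14.27)
  # equal-kappa mixture keeps the common kappa
  t2 <- materialTables(data.frame(name = c("A", "B"), kappa = c(10, 10),
                                  c0 = c(0, 0), a0 = c(0.6, 0.6)),
                       adsorbates = list())
  expect_equal(mixBendingRigidity(c(A = 0.5, B = 0.5), t2), 10)
  k <- mixBendingRigidity(defaultComposition, tab)
  expect_equal(k, 1 / (0.6 / 15.83 + 0.2 / 14.27 + 0.2 / 11.56),
               tolerance = 1e-12)
  expect_gt(k, min(tab@lipids$kappa))
  expect_lt(k, max(tab@lipids$kappa))
})

test_that("mixing is invariant under permutation of the lipid labels", {
  comp <- c(DOPE = 0.5, DOPS = 0.3, DOPC = 0.2)
  perm <- comp[c("DOPC", "DOPE", "DOPS")]
  expect_equal(mixSpontaneousCurvature(comp, tab),
               mixSpontaneousCurvature(perm, tab))
  expect_equal(mixBendingRigidity(comp, tab), mixBendingRigidity(perm, tab))
})

test_that("adsorbate curvature interpolates between free and covered values", {
  expect_equal(adsorbateSpontaneousCurvature(defaultComposition, 0, "R9", tab),
               mixSpontaneousCurvature(defaultComposition, tab))
  expect_equal(adsorbateSpontaneousCurvature(c(DOPS = 1), 1, "R9", tab), -0.26)
  expect_equal(adsorbateSpontaneousCurvature(c(DOPS = 1), 0.5, "R9", tab),
               0.5 * -0.26 + 0.5 * -0.06, tolerance = 1e-12)
})

test_that("coverage is np*Ap/Al, clamped at full coverage with a warning", {
  expect_equal(adsorbateCoverage(0, 14.786, 14.786), 0)
  expect_equal(adsorbateCoverage(1, 14.786, 14.786), 1)
  expect_warning(phi <- adsorbateCoverage(2, 14.786, 14.786), "clamp")
  expect_equal(phi, 1)
  expect_error(adsorbateCoverage(1, 14.786, 0), "positive")
})

test_that("binding free energy blends pure-bilayer values with the fractions", {
  expect_equal(bindingFreeEnergy(0, defaultComposition, "R9", tab), 0)
  expect_equal(bindingFreeEnergy(1, defaultComposition, "R9", tab),
               0.6 * -23.2 + 0.2 * -86.0 + 0.2 * -19.6, tolerance = 1e-12)
  expect_equal(bindingFreeEnergy(1, c(DOPS = 1), "K9", tab), -51.4)
  # kJ/mol -> kT at the table temperature
  expect_equal(bindingFreeEnergy(1, c(DOPS = 1), "K9", tab, units = "kT"),
               -51.4 / kTkJmol(300), tolerance = 1e-12)
})

test_that("bilayer Gaussian modulus follows the thickness expansion", {
  expect_equal(gaussianModulusBilayer(10, 0, monolayerFactor = 0.8), -16)
  expect_equal(gaussianModulusBilayer(15.83, -0.24, thickness = 2,
                                      monolayerFactor = 0.8),
               2 * (-0.8 * 15.83) - 4 * (-0.24) * 15.83 * 2, tolerance = 1e-12)
  expect_equal(gaussianModulusBilayer(12, -0.1, thickness = 0,
                                      monolayerFactor = 0), 0)
})

test_that("face material combines leaflets with the sign convention", {
  # symmetric bare leaflets: bilayer Js cancels
  fm <- faceMaterial(defaultComposition, defaultComposition, np = 0,
                     tables = tab)
  expect_equal(fm$Js, 0, tolerance = 1e-12)
  expect_equal(fm$kappa, 2 * mixBendingRigidity(defaultComposition, tab),
               tolerance = 1e-12)
  # kappa additivity across leaflets
  fm2 <- faceMaterial(c(DOPS = 1), c(DOPS = 1), np = 0, tables = tab)
  expect_equal(fm2$kappa, 2 * 14.27, tolerance = 1e-12)
  # fully covered outer DOPS over bare DOPS
  fm3 <- faceMaterial(c(DOPS = 1), c(DOPS = 1), np = 1, Al = 14.786,
                      adsorbate = "R9", tables = tab)
  expect_equal(fm3$Js, -0.26 - (-0.06), tolerance = 1e-12)
  expect_equal(fm3$coverage, 1)
})

test_that("face material is deterministic and unit-consistent", {
  fm1 <- faceMaterial(defaultComposition, defaultComposition, np = 1,
                      Al = 30, tables = tab)
  fm2 <- faceMaterial(defaultComposition, defaultComposition, np = 1,
                      Al = 30, tables = tab)
  expect_identical(fm1, fm2)
  # energy-unit audit: Fb in kT equals the kJ/mol value over kT(T)
  fb_kj <- bindingFreeEnergy(1, defaultComposition, "R9", tab)
  expect_equal(fm1$Fb, fb_kj / kTkJmol(tab@temperature), tolerance = 1e-12)
})
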