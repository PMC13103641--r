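toyTables <- function(muA = -10, muB = 0) {
  materialTables(
    lipids = data.frame(name = c("A", "B"), kappa = c(14, 14), c0 = c(0, 0),
                        a0 = c(0.65, 0.65)),
    adsorbates = list(P = list(Ap = 6.5,
                               table = data.frame(name = c("A", "B"),
                                                  mu = c(muA, muB),
                                                  Js = c(0, 0),
                                                  kappa = c(14, 14)))))
}

test_that("equal binding energies produce no demixing", {
  p <- patchSystem(c(A = 0.5, B = 0.5), nLipids = 20, nPeptides = 1,
                   coverage = 0.5, adsorbate = "P", tables = toyTables(-5, -5))
  d <- equilibriumDemix(p)
  expect_equal(unname(d$Gamma), c(0, 0))
  # binding offsets the unbound reference by exactly the ideal-mixing value
  expect_equal(d$F - d$Funiform, 0.5 * -5 + 0.5 * -5)
})

test_that("vanishing binding energies give the ideal-mixing zero", {
  p <- patchSystem(c(A = 0.5, B = 0.5), nLipids = 20, nPeptides = 1,
                   coverage = 0.5, adsorbate = "P", tables = toyTables(0, 0))
  expect_equal(predictBindingEnergy(p), 0)
})

test_that("two-lipid demixing matches an exhaustive grid minimization", {
  kT <- kTkJmol(300)
  phi <- c(A = 0.5, B = 0.5); M <- 20; Mc <- 10; Mu <- 10; mu <- c(-10, 0)
  Fof <- function(xA) {
    x <- c(xA, 1 - xA)
    y <- (M * phi - Mc * x) / Mu
    if (any(y <= 0)) return(Inf)
    sum(x * mu) + kT * (Mc * sum(x * log(x)) + Mu * sum(y * log(y)))
  }
  grid <- seq(1e-3, 1 - 1e-3, by = 1e-3)
  fvals <- vapply(grid, Fof, numeric(1))
  xStar <- grid[which.min(fvals)]
  p <- patchSystem(phi, nLipids = M, nPeptides = 1, coverage = 0.5,
                   adsorbate = "P", tables = toyTables(-10, 0))
  d <- equilibriumDemix(p)
  expect_equal(unname(d$x["A"]), xStar, tolerance = 2e-3)
  expect_lte(d$F, min(fvals) + 1e-9)   # at least as good as the best grid point
  expect_lt(d$F, d$Funiform)           # demixing lowers F for unequal mu
})

test_that("demixing conserves every species to high precision", {
  p <- patchSystem(nLipids = 2048, nPeptides = 64)
  d <- equilibriumDemix(p)
  M <- p$M; Mc <- p$Mcov; Mu <- M - Mc
  recon <- Mc * d$x + Mu * d$y
  expect_lt(max(abs(recon - M * p$phi)), 1e-9 * M)
  expect_equal(sum(d$x), 1, tolerance = 1e-12)
  expect_equal(sum(d$Gamma), 0, tolerance = 1e-9)  # covered count is fixed
})

test_that("excess lipids respond monotonically to the binding energies", {
  gammaA <- vapply(c(-2, -6, -10, -14), function(mu) {
    p <- patchSystem(c(A = 0.5, B = 0.5), nLipids = 40, nPeptides = 1,
                     coverage = 0.4, adsorbate = "P",
                     tables = toyTables(mu, 0))
    equilibriumDemix(p)$Gamma[["A"]]
  }, numeric(1))
  expect_true(all(diff(gammaA) > 0))   # more negative mu_A -> larger excess
})

test_that("ideal-mixing binding energy reproduces the fraction-weighted blend", {
  p <- patchSystem(nLipids = 64, nPeptides = 1, coverage = 0.328)
  expect_equal(predictBindingEnergy(p, demix = FALSE),
               0.6 * -23.2 + 0.2 * -86.0 + 0.2 * -19.6, tolerance = 1e-12)
  # demixing can only strengthen binding
  expect_lt(predictBindingEnergy(p), predictBindingEnergy(p, demix = FALSE))
})

test_that("footprint optimization recovers a self-generated footprint", {
  ApTrue <- 12.5
  p <- patchSystem(nLipids = 2048, nPeptides = 64, Ap = ApTrue)
  targets <- equilibriumDemix(p)$Gamma
  fit <- optimizeFootprint(targets, nLipids = 2048, nPeptides = 64)
  expect_equal(fit$Ap, ApTrue, tolerance = 1e-3)
  expect_equal(fit$radius, sqrt(ApTrue / pi), tolerance = 1e-3)
  expect_lt(fit$objective, 1e-10)
})

test_that("optimization without an interior optimum errors", {
  expect_error(optimizeFootprint(c(DOPE = 50, DOPS = 80, DOPC = -90),
                                 bounds = c(4, 10)),
               "optimum")
})

test_that("Kirkwood-Buff integrals: flat, hard-disk and Gaussian oracles", {
  r <- seq(0, 5, length.out = 2001)
  expect_equal(kirkwoodBuff2D(r, rep(1, length(r)), rho = 0.7), 0)
  r0 <- 1.5
  gHard <- as.numeric(r >= r0)
  expect_equal(kirkwoodBuff2D(r, gHard, rho = 0.7), -0.7 * pi * r0^2,
               tolerance = 5e-3)   # trapezoid on a discontinuous integrand
  rdf <- rdfFixture()
  expect_equal(kirkwoodBuff2D(rdf$r, rdf$g, rho = 1),
               attr(rdf, "gammaPerRho"), tolerance = 0.005)
  expect_error(kirkwoodBuff2D(r, gHard, rho = 1, rmax = 10), "beyond")
})
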