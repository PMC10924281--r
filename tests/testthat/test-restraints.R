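test_that("stereochemistry score vanishes when constraints are satisfied", {
  # two bonded beads touching at radius sum
  m <- handModel("A", 3, rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(scoreStereochemistry(m), 0)
  # within slack: still zero
  m2 <- handModel("A", 3, rbind(c(0, 0, 0), c(7.5, 0, 0)))
  expect_equal(scoreStereochemistry(m2, slack = 2), 0)
  # beyond slack: harmonic in the gap
  m3 <- handModel("A", 3, rbind(c(0, 0, 0), c(11, 0, 0)))
  expect_equal(scoreStereochemistry(m3, kBond = 1, slack = 2), -(11 - 8)^2)
})

test_that("excluded volume penalizes overlapping non-bonded beads", {
  # two coincident single-bead chains, r = 2: overlap 4, kEV = 1 -> -16
  expect_equal(scoreStereochemistry(twoChainModel(0, radius = 2), kEV = 1), -16)
  expect_equal(scoreStereochemistry(twoChainModel(4, radius = 2)), 0)
  expect_equal(scoreStereochemistry(twoChainModel(3, radius = 2), kEV = 2), -2)
})

test_that("scores are invariant under rigid transformation", {
  p <- preset("globular")
  m <- randomizeModel(coarseGrain(p$topology, 10), seed = 7)
  mT <- m
  beadCoords(mT) <- rigidTransform(beadCoords(m), seed = 3)
  expect_equal(scoreStereochemistry(mT), scoreStereochemistry(m), tolerance = 1e-9)
  expect_equal(scoreCrosslinks(mT, p$crosslinks), scoreCrosslinks(m, p$crosslinks),
               tolerance = 1e-9)
  # density restraint: invariant when the density is transformed identically
  dT <- p$density
  dT@means <- rigidTransform(dT@means, seed = 3)
  R <- withr::with_seed(3, nsrep:::rotationMatrix(stats::rnorm(3),
                                                  stats::runif(1, 0, 2 * pi)))
  dT@covariances <- lapply(dT@covariances, function(C) R %*% C %*% t(R))
  expect_equal(scoreEM(mT, dT), scoreEM(m, p$density), tolerance = 1e-6)
})

test_that("crosslink forward model follows the erf-sigmoid in surface distance", {
  r <- 2; d0 <- 21; psi <- 0.05; sigma <- 10
  term <- function(gap) {
    m <- twoChainModel(gap + 2 * r, radius = r)
    scoreCrosslinks(m, oneLink(d0 = d0, psi = psi, sigma = sigma))
  }
  # at the linker length the sigmoid is exactly half: log(psi + (1-2psi)/2)
  expect_equal(term(d0), log(0.5))
  # satisfied link approaches log(1 - psi)
  expect_equal(term(0), log(psi + (1 - 2 * psi) * pnorm(d0 / sigma)))
  expect_lt(abs(term(0) - log(1 - psi)), 0.02)
  # violated link approaches log(psi)
  expect_equal(term(500), log(psi), tolerance = 1e-6)
  # every term is bounded and monotone non-increasing in distance
  d <- seq(0, 120, by = 2.5)
  v <- vapply(d, term, numeric(1))
  expect_true(all(v <= log(1 - psi) + 1e-12 & v >= log(psi) - 1e-12))
  expect_true(all(diff(v) <= 1e-12))
})

test_that("crosslinks referencing unknown residues fail loudly", {
  m <- twoChainModel(10)
  expect_error(scoreCrosslinks(m, oneLink(res2 = 7)), "unknown residue B:7")
  expect_error(scoreCrosslinks(m, oneLink(chain2 = "C")), "unknown residue")
  expect_equal(scoreCrosslinks(m, emptyLinks()), 0)
})

test_that("density score is a normalized Gaussian overlap", {
  # model mixture identical to the data mixture: cc = 1, score 0
  m <- handModel("A", 3, rbind(c(1, 2, 3)))
  g <- GMMDensity(1, rbind(c(1, 2, 3)), list(diag(3) * 9))
  expect_equal(scoreEM(m, g), 0, tolerance = 1e-9)
  # two isotropic unit-variance components at distance 2: cc = exp(-1)
  m1 <- handModel("A", 1, rbind(c(0, 0, 0)))
  g1 <- GMMDensity(1, rbind(c(2, 0, 0)), list(diag(3)))
  expect_equal(scoreEM(m1, g1), -1, tolerance = 1e-9)
  # far displaced: cc clamps at eps
  gFar <- GMMDensity(1, rbind(c(1e4, 0, 0)), list(diag(3)))
  expect_equal(scoreEM(m1, gFar), log(1e-12))
  expect_equal(scoreEM(m1, gFar, emWeight = 2.5), 2.5 * log(1e-12))
})

test_that("density score matches grid-quadrature cross-correlation", {
  model <- handModel("A", c(2, 3), rbind(c(0, 0, 0), c(5, 1, -2)), nres = c(4L, 9L))
  w <- c(4, 9) / 13
  C1 <- matrix(c(9, 2, 0, 2, 6, 1, 0, 1, 8), 3, 3)
  C2 <- diag(3) * 12
  C3 <- matrix(c(7, -1, 0, -1, 9, 2, 0, 2, 11), 3, 3)
  g <- GMMDensity(c(0.5, 0.3, 0.2), rbind(c(1, 0, 0), c(6, 2, -1), c(-3, 2, 2)),
                  list(C1, C2, C3))
  oracle <- gridCC(w, beadCoords(model), list(diag(3) * 4, diag(3) * 9),
                   g@weights, g@means, g@covariances, spacing = 0.45)
  expect_equal(scoreEM(model, g), log(oracle), tolerance = 1e-3)
})

test_that("degenerate densities are rejected", {
  expect_error(GMMDensity(1, rbind(c(0, 0, 0)), list(matrix(0, 3, 3))),
               "positive definite")
  expect_error(GMMDensity(1, rbind(c(0, 0, 0)),
                          list(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3, 3))),
               "symmetric")
})

test_that("restraint partitioning is exact, disjoint and seed-stable", {
  p <- preset("globular")
  links10 <- CrosslinkDataset(linkTable(p$crosslinks)[1:10, ])
  pa <- partitionRestraints(links10, 0.3, seed = 11)
  expect_equal(nLinks(priorLinks(pa)), 3L)
  expect_equal(nLinks(likelihoodLinks(pa)), 7L)
  both <- rbind(linkTable(priorLinks(pa)), linkTable(likelihoodLinks(pa)))
  expect_equal(nrow(unique(both)), 10L)
  pb <- partitionRestraints(links10, 0.3, seed = 11)
  expect_identical(pa@priorIdx, pb@priorIdx)
  p0 <- partitionRestraints(links10, 0, seed = 1)
  expect_equal(nLinks(priorLinks(p0)), 0L)
  expect_error(partitionRestraints(links10, 1), "fraction")
  expect_error(partitionRestraints(links10, -0.1), "fraction")
})

test_that("prior times likelihood is invariant to the partition", {
  p <- preset("globular")
  model <- coarseGrain(p$topology, 10)
  for (s in 1:20) {
    m <- randomizeModel(model, seed = s)
    tot <- vapply(1:3, function(ps) {
      pa <- partitionRestraints(p$crosslinks, 0.3, seed = ps,
                                density = p$density)
      modifiedLogPrior(m, pa) + logLikelihood(m, pa)
    }, numeric(1))
    expect_lt(max(abs(tot - tot[1])), 1e-9)
  }
})

test_that("partition boundaries behave as documented", {
  p <- preset("globular")
  m <- randomizeModel(coarseGrain(p$topology, 20), seed = 2)
  p0 <- partitionRestraints(p$crosslinks, 0, seed = 1)
  expect_equal(modifiedLogPrior(m, p0), scoreStereochemistry(m))
  # no links, no density: likelihood is identically zero
  pe <- partitionRestraints(emptyLinks(), 0.3, seed = 1)
  expect_equal(logLikelihood(m, pe), 0)
})
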