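rg <- function(X) sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))

test_that("generated chains are valid polymers and seed-deterministic", {
  a <- generateAssembly(c(40, 30), compactness = c(0, 0.8), seed = 5)
  expect_s4_class(a, "SyntheticAssembly")
  for (X in a@coords) {
    bonds <- sqrt(rowSums((X[-1, ] - X[-nrow(X), ])^2))
    expect_true(all(abs(bonds - 3.8) < 1e-6))
  }
  # no two residues closer than the steric minimum
  all <- do.call(rbind, a@coords)
  expect_gte(min(dist(all)), 2.0)
  b <- generateAssembly(c(40, 30), compactness = c(0, 0.8), seed = 5)
  expect_identical(a@coords, b@coords)
  c2 <- generateAssembly(c(40, 30), compactness = c(0, 0.8), seed = 6)
  expect_false(identical(a@coords, c2@coords))
  expect_error(generateAssembly(5), "lengths")
})

test_that("compactness controls the radius of gyration", {
  for (s in 1:10) {
    ext <- generateAssembly(80, compactness = 0, seed = 1000 + s)
    glb <- generateAssembly(80, compactness = 1, seed = 1000 + s)
    expect_gt(rg(ext@coords$A), rg(glb@coords$A))
  }
})

test_that("simulated crosslinks respect the distance cutoff and counts", {
  a <- generateAssembly(60, compactness = 0.5, seed = 9)
  X <- a@coords$A
  refDist <- function(links) {
    tab <- linkTable(links)
    sqrt(rowSums((X[tab$residue1, , drop = FALSE] -
                  X[tab$residue2, , drop = FALSE])^2))
  }
  tp <- simulateCrosslinks(a, 20, dMax = 25, fpRate = 0, seed = 2)
  expect_equal(nLinks(tp), 20L)
  expect_true(all(refDist(tp) <= 25))
  fp <- simulateCrosslinks(a, 10, dMax = 25, fpRate = 1, seed = 3)
  expect_equal(nLinks(fp), 10L)
  expect_true(all(refDist(fp) > 25))
  mix <- simulateCrosslinks(a, 20, dMax = 25, fpRate = 0.1, seed = 4)
  expect_equal(sum(refDist(mix) > 25), 2L)
  expect_equal(anyDuplicated(linkTable(mix)), 0L)
  # near-sequence pairs are excluded
  tab <- linkTable(mix)
  intra <- tab$chain1 == tab$chain2
  expect_true(all(abs(tab$residue1 - tab$residue2)[intra] >= 5))
  expect_error(simulateCrosslinks(a, 1e5, dMax = 25, fpRate = 0.5, seed = 1),
               "insufficient candidate pairs")
})

test_that("simulated densities are normalized mixtures over the structure", {
  a <- generateAssembly(60, compactness = 0.5, seed = 9)
  g1 <- simulateDensity(a, 1, blurSigma = 5, seed = 1)
  expect_equal(length(g1@weights), 1L)
  expect_equal(g1@means[1, ], colMeans(a@coords$A))
  g <- simulateDensity(a, 5, blurSigma = 5, seed = 1)
  expect_equal(sum(g@weights), 1)
  for (C in g@covariances)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(simulateDensity(a, 1000, seed = 1), "nComponents")
})

test_that("the density prefers the true structure over shuffled coordinates", {
  a <- generateAssembly(60, compactness = 0.5, seed = 9)
  g <- simulateDensity(a, 5, blurSigma = 5, seed = 1)
  m <- coarseGrain(a@topology, 10)
  b <- beadTable(m)
  Xtrue <- t(vapply(seq_len(nrow(b)), function(i)
    colMeans(a@coords$A[b$first[i]:b$last[i], , drop = FALSE]), numeric(3)))
  mTrue <- m; beadCoords(mTrue) <- Xtrue
  for (s in 1:10) {
    mShuf <- m
    beadCoords(mShuf) <- withr::with_seed(s, Xtrue[sample(nrow(Xtrue)), ] +
                                            matrix(stats::rnorm(length(Xtrue), 0, 10),
                                                   ncol = 3))
    expect_gte(scoreEM(mTrue, g), scoreEM(mShuf, g))
  }
})

test_that("presets are reproducible bundles", {
  p1 <- syntheticPreset("mixed")
  p2 <- syntheticPreset("mixed")
  expect_identical(p1$assembly@coords, p2$assembly@coords)
  expect_identical(linkTable(p1$crosslinks), linkTable(p2$crosslinks))
  expect_identical(p1$density@means, p2$density@means)
  expect_equal(length(p1$assembly@coords), 2L)
  # the mixed preset has one compact and one extended chain
  expect_gt(rg(p1$assembly@coords$B) / nrow(p1$assembly@coords$B),
            rg(p1$assembly@coords$A) / nrow(p1$assembly@coords$A))
  # and a structured rigid core on the compact chain
  seg <- segments(p1$topology)
  expect_true(any(seg$kind == "structured" & seg$chain_id == "A"))
})
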