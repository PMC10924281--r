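test_that("proposals are local, symmetric in structure, and rigid-body safe", {
  m <- randomizeModel(coarseGrain(preset("globular")$topology, 10), seed = 1)
  b <- beadTable(m)
  # zero step sizes: null proposal
  m0 <- proposeMove(m, MoveSet(flexStep = 0, rigidTranslateStep = 0,
                               rigidRotateStep = 0), seed = 2)
  expect_equal(beadCoords(m0), beadCoords(m), tolerance = 1e-12)
  idx <- which(!is.na(b$rigid_body))
  for (s in 1:25) {
    mp <- proposeMove(m, MoveSet(), seed = s)
    moved <- which(rowSums(abs(beadCoords(mp) - beadCoords(m))) > 1e-12)
    # exactly one flexible bead or exactly one rigid body moved
    expect_true(identical(length(moved), 1L) || setequal(moved, idx))
    if (setequal(moved, idx)) {
      expect_equal(as.vector(dist(beadCoords(mp)[idx, ])),
                   as.vector(dist(beadCoords(m)[idx, ])), tolerance = 1e-9)
    }
  }
})

test_that("a model with no movable degrees of freedom is rejected", {
  ctx <- list(flex = integer(0), bodies = list())
  expect_error(nsrep:::.proposeCoords(matrix(0, 1, 3), ctx, MoveSet()),
               "no movable")
})

test_that("MCMC trajectories are seed-deterministic with positive step time", {
  p <- preset("globular")
  pa <- partitionRestraints(p$crosslinks, 0.3, seed = 1, density = p$density)
  start <- randomizeModel(coarseGrain(p$topology, 20), seed = 5)
  b1 <- mcmcFromModifiedPrior(start, pa, MoveSet(), nSteps = 40, seed = 9)
  b2 <- mcmcFromModifiedPrior(start, pa, MoveSet(), nSteps = 40, seed = 9)
  expect_identical(b1@models, b2@models)
  expect_identical(b1@logPriors, b2@logPriors)
  expect_gt(b1@perStepTime, 0)
  expect_equal(length(b1@models), 4L)  # thin interval 10 over 40 steps
  # snapshots carry consistent scores
  for (k in seq_along(b1@models)) {
    mk <- start; beadCoords(mk) <- b1@models[[k]]
    expect_equal(modifiedLogPrior(mk, pa), b1@logPriors[k], tolerance = 1e-9)
    expect_equal(logLikelihood(mk, pa), b1@logLikelihoods[k], tolerance = 1e-9)
  }
})

test_that("on a flat landscape nearly every move is accepted", {
  # no links, no density, two distant single-bead chains: flat modified prior
  m <- twoChainModel(150, radius = 2)
  pa <- partitionRestraints(emptyLinks(), 0, seed = 1)
  batch <- mcmcFromModifiedPrior(m, pa, MoveSet(nReplicas = 1, thinInterval = 1),
                                 nSteps = 400, seed = 3, boxHalfSide = 1e4)
  X <- t(vapply(batch@models, function(x) x[1, ], numeric(3)))
  # cold replica position changes at (almost) every snapshot
  moves <- rowSums(abs(diff(X))) > 1e-12
  expect_gt(mean(moves), 0.45)  # bead 1 is picked about half the time
  expect_true(all(batch@logPriors == 0))
})

test_that("sampled modified-prior statistics match an independent quadrature", {
  # two bonded flexible beads with one prior-side crosslink in a small box:
  # the long-run mean modified prior from MCMC must match a plain Monte
  # Carlo quadrature over the uniform box (a Boltzmann / detailed-balance
  # check against an independent oracle)
  m <- handModel(c("A", "A"), 2, rbind(c(0, 0, 0), c(6, 0, 0)))
  link <- oneLink(chain1 = "A", chain2 = "A", res1 = 1, res2 = 2,
                  d0 = 12, sigma = 4, psi = 0.05)
  pa <- partitionRestraints(link, fraction = 0.9, seed = 1)
  expect_equal(nLinks(priorLinks(pa)), 1L)
  box <- 40
  lp_of_d <- function(d) -pmax(0, d - 6)^2 +
    log(0.05 + 0.9 * stats::pnorm((12 - pmax(0, d - 4)) / 4))
  batch <- mcmcFromModifiedPrior(m, pa, MoveSet(nReplicas = 2, thinInterval = 5,
                                                flexStep = 8),
                                 nSteps = 6000, seed = 17, boxHalfSide = box)
  drop <- 100  # burn-in snapshots
  samp <- batch@logPriors[-seq_len(drop)]
  oracle <- withr::with_seed(99, {
    p1 <- matrix(stats::runif(3 * 2e5, -box, box), ncol = 3)
    p2 <- matrix(stats::runif(3 * 2e5, -box, box), ncol = 3)
    lp <- lp_of_d(sqrt(rowSums((p1 - p2)^2)))
    w <- exp(lp)
    sum(lp * w) / sum(w)
  })
  se <- stats::sd(samp) / sqrt(length(samp) / 20)  # autocorrelation allowance
  expect_lt(abs(mean(samp) - oracle), 4 * se + 0.05)
})

test_that("constrained sampling honours thresholds and failure budgets", {
  p <- preset("globular")
  pa <- partitionRestraints(p$crosslinks, 0.3, seed = 1, density = p$density)
  live <- lapply(1:4, function(s) randomizeModel(coarseGrain(p$topology, 20),
                                                 seed = s))
  res <- sampleConstrained(-Inf, live, pa, MoveSet(), batchSize = 30, seed = 5)
  expect_true(res$success)
  expect_equal(res$failures, 0L)
  expect_true(is.finite(res$logLikelihood))
  expect_equal(logLikelihood(res$model, pa), res$logLikelihood, tolerance = 1e-9)
  # moderate threshold: returned model satisfies it
  thr <- res$logLikelihood
  res2 <- sampleConstrained(thr, live, pa, MoveSet(), batchSize = 30, seed = 6)
  if (res2$success) expect_gte(res2$logLikelihood, thr)
  # impossible threshold (log-probabilities cannot exceed 0)
  res3 <- sampleConstrained(1, live, pa, MoveSet(), batchSize = 20,
                            maxFailures = 3, seed = 7)
  expect_false(res3$success)
  expect_equal(res3$failures, 3L)
})
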