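# Replica-exchange MCMC sampling from the modified prior.

# one symmetric move on a coordinate matrix: either translate one flexible
# bead inside a uniform ball, or translate + rotate one rigid body
.proposeCoords <- function(X, ctx, moveset) {
  nUnits <- length(ctx$flex) + length(ctx$bodies)
  if (nUnits == 0L) stop("model has no movable degrees of freedom")
  u <- sample.int(nUnits, 1L)
  if (u <= length(ctx$flex)) {
    i <- ctx$flex[u]
    X[i, ] <- X[i, ] + runifBall(moveset@flexStep)
  } else {
    idx <- ctx$bodies[[u - length(ctx$flex)]]
    ctr <- colMeans(X[idx, , drop = FALSE])
    R <- rotationMatrix(stats::rnorm(3),
                        stats::runif(1, -moveset@rigidRotateStep, moveset@rigidRotateStep))
    shift <- ctr + runifBall(moveset@rigidTranslateStep)
    X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2, ctr) %*% t(R), 2, shift, "+")
  }
  X
}

#' Propose one Monte Carlo move
#'
#' Applies one randomly chosen symmetric mover to the model: a uniform-ball
#' translation of a single flexible bead, or a rigid-body translation plus
#' a small random rotation about the body centroid.  All other coordinates
#' are unchanged; intra-body pairwise distances are preserved exactly.
#'
#' @param model a \linkS4class{BeadModel}.
#' @param moveset a \linkS4class{MoveSet}.
#' @param seed optional integer seed for a deterministic proposal.
#' @return a \linkS4class{BeadModel} with proposed coordinates.
#' @export
proposeMove <- function(model, moveset = MoveSet(), seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, proposeMove(model, moveset)))
  rb <- model@beads$rigid_body
  ctx <- list(flex = which(is.na(rb)),
              bodies = lapply(unique(stats::na.omit(rb)),
                              function(id) which(!is.na(rb) & rb == id)))
  model@coords <- .proposeCoords(model@coords, ctx, moveset)
  model
}

# Replica-exchange Metropolis sampling of the modified prior.
# Returns cold-replica snapshots (coordinates + scores) and the mean
# wall-clock time per MCMC step across replicas.
.remcmc <- function(ctx, start, moveset, nSteps, burnin = 0L,
                    collectLik = TRUE) {
  nr <- moveset@nReplicas
  beta <- 1 / moveset@ladder
  Xs <- rep(list(start), nr)
  lp <- rep(.ctxPrior(ctx, start), nr)
  if (!is.finite(lp[1L]))
    stop("non-finite modified prior at MCMC start")
  snaps <- list(); sp <- numeric(0); sl <- numeric(0)
  t0 <- proc.time()[["elapsed"]]
  for (step in seq_len(nSteps)) {
    for (k in seq_len(nr)) {
      Xp <- .proposeCoords(Xs[[k]], ctx, moveset)
      lpp <- .ctxPrior(ctx, Xp)
      if (is.finite(lpp) &&
          (lpp >= lp[k] || stats::runif(1) < exp(beta[k] * (lpp - lp[k])))) {
        Xs[[k]] <- Xp; lp[k] <- lpp
      }
    }
    if (nr > 1L && step %% moveset@swapInterval == 0L) {
      for (k in seq_len(nr - 1L)) {
        dlogr <- (beta[k] - beta[k + 1L]) * (lp[k + 1L] - lp[k])
        if (dlogr >= 0 || stats::runif(1) < exp(dlogr)) {
          tmp <- Xs[[k]]; Xs[[k]] <- Xs[[k + 1L]]; Xs[[k + 1L]] <- tmp
          tmp <- lp[k]; lp[k] <- lp[k + 1L]; lp[k + 1L] <- tmp
        }
      }
    }
    if (step > burnin && step %% moveset@thinInterval == 0L) {
      snaps[[length(snaps) + 1L]] <- Xs[[1L]]
      sp <- c(sp, lp[1L])
      sl <- c(sl, if (collectLik) .ctxLik(ctx, Xs[[1L]]) else NA_real_)
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  list(snaps = snaps, logPriors = sp, logLiks = sl,
       perStepTime = max(elapsed, 1e-9) / (nSteps * nr),
       final = Xs[[1L]], finalLogPrior = lp[1L])
}

#' Sample bead models from the modified prior
#'
#' Runs replica-exchange Metropolis MCMC on the modified prior
#' (stereochemistry plus prior-side crosslinks), with a geometric
#' temperature ladder and periodic swap attempts between adjacent
#' replicas.  The prior is truncated to a cubic bounding box so that its
#' mass is proper.  Snapshots are taken from the cold replica every
#' \code{thinInterval} steps.
#'
#' @param start a \linkS4class{BeadModel} providing the starting
#'   coordinates.
#' @param partition a \linkS4class{RestraintPartition}.
#' @param moveset a \linkS4class{MoveSet}.
#' @param nSteps number of MCMC steps per replica.
#' @param seed optional integer seed; a fixed seed gives a bitwise
#'   identical trajectory.
#' @param kBond,kEV,slack stereochemistry parameters, see
#'   [scoreStereochemistry()].
#' @param boxHalfSide half-side of the bounding box (angstroms).
#' @return a \linkS4class{SampleBatch}.
#' @export
mcmcFromModifiedPrior <- function(start, partition, moveset = MoveSet(),
                                  nSteps = 50, seed = NULL,
                                  kBond = 1, kEV = 1, slack = 2,
                                  boxHalfSide = 300) {
  if (!is.null(seed))
    return(withr::with_seed(seed, mcmcFromModifiedPrior(
      start, partition, moveset, nSteps, seed = NULL,
      kBond = kBond, kEV = kEV, slack = slack, boxHalfSide = boxHalfSide)))
  stopifnot(nSteps >= 1)
  ctx <- .scoreContext(start, partition, kBond, kEV, slack, boxHalfSide)
  res <- .remcmc(ctx, start@coords, moveset, as.integer(nSteps))
  new("SampleBatch", models = res$snaps, logPriors = res$logPriors,
      logLikelihoods = res$logLiks, perStepTime = res$perStepTime)
}

# Draw one model from the likelihood-constrained modified prior: fresh
# RE-MCMC segments started from a random live point (burn-in of half the
# segment before snapshots), first snapshot with logL >= threshold wins.
# Fails after maxFailures consecutive empty batches.
.sampleConstrained <- function(ctx, liveCoords, threshold, moveset, nSteps,
                               maxFailures) {
  failures <- 0L
  times <- numeric(0)
  while (failures < maxFailures) {
    start <- liveCoords[[sample.int(length(liveCoords), 1L)]]
    res <- .remcmc(ctx, start, moveset, nSteps, burnin = nSteps %/% 2L)
    times <- c(times, res$perStepTime)
    ok <- which(res$logLiks >= threshold)
    if (length(ok)) {
      k <- ok[1L]
      return(list(success = TRUE, coords = res$snaps[[k]],
                  logLik = res$logLiks[k], logPrior = res$logPriors[k],
                  failures = failures, perStepTime = mean(times)))
    }
    failures <- failures + 1L
  }
  list(success = FALSE, failures = failures, perStepTime = mean(times))
}

#' Sample from the likelihood-constrained modified prior
#'
#' Draws replica-exchange MCMC batches from the modified prior, each
#' started from a random model of \code{live}, and returns the first
#' snapshot whose log-likelihood reaches the threshold.  The constraint is
#' non-strict (\code{>=}) so that likelihood plateaus can still be
#' traversed and detected by the plateau convergence rule.  Returns a
#' failure after \code{maxFailures} consecutive batches without a valid
#' snapshot; the failure count feeds the nested-sampling convergence
#' logic.
#'
#' @param threshold log-likelihood threshold (finite or \code{-Inf}).
#' @param live a \linkS4class{BeadModel} or list of bead models used as
#'   batch starting points.
#' @param partition a \linkS4class{RestraintPartition}.
#' @param moveset a \linkS4class{MoveSet}.
#' @param batchSize MCMC steps per batch.
#' @param maxFailures consecutive empty batches tolerated.
#' @param seed optional integer seed.
#' @inheritParams mcmcFromModifiedPrior
#' @return a list with elements \code{success}, \code{model} (on success),
#'   \code{logLikelihood}, \code{failures} and \code{perStepTime}.
#' @export
sampleConstrained <- function(threshold, live, partition, moveset = MoveSet(),
                              batchSize = 50, maxFailures = 4, seed = NULL,
                              kBond = 1, kEV = 1, slack = 2, boxHalfSide = 300) {
  if (!is.null(seed))
    return(withr::with_seed(seed, sampleConstrained(
      threshold, live, partition, moveset, batchSize, maxFailures, seed = NULL,
      kBond = kBond, kEV = kEV, slack = slack, boxHalfSide = boxHalfSide)))
  if (is(live, "BeadModel")) live <- list(live)
  template <- live[[1L]]
  ctx <- .scoreContext(template, partition, kBond, kEV, slack, boxHalfSide)
  res <- .sampleConstrained(ctx, lapply(live, beadCoords), threshold, moveset,
                            as.integer(batchSize), as.integer(maxFailures))
  if (res$success) {
    out <- template
    out@coords <- res$coords
    list(success = TRUE, model = out, logLikelihood = res$logLik,
         failures = res$failures, perStepTime = res$perStepTime)
  } else {
    list(success = FALSE, model = NULL, logLikelihood = NA_real_,
         failures = res$failures, perStepTime = res$perStepTime)
  }
}
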