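# Core nested-sampling loop: live points, constrained replacement,
# evidence accumulation on the L-vs-X curve, convergence detection.

#' Expected prior mass at iteration i
#'
#' The standard expectation of the remaining prior mass after \code{i}
#' shrinkage steps with \code{N} live points: \eqn{X_i = e^{-i/N}}.
#'
#' @param i iteration (>= 0).
#' @param N number of live points (>= 1).
#' @return prior-mass proportion in (0, 1].
#' @examples
#' priorMass(0, 50)    # 1
#' priorMass(50, 50)   # exp(-1)
#' @export
priorMass <- function(i, N) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(i < 0)) stop("i must be >= 0")
  exp(-i / N)
}

#' Likelihood-plateau test
#'
#' One of the convergence triggers: the run is on a likelihood plateau at
#' iteration \code{i} when the likelihood grows more slowly than the prior
#' mass shrinks, i.e. \eqn{L_{i+1}/L_i < X_i/X_{i+1}}, equivalently
#' \eqn{\log L_{i+1} - \log L_i < 1/N}.  The inequality is strict, so an
#' increment of exactly \code{1/N} is not a plateau.
#'
#' @param logLNext log-likelihood of the next dead point.
#' @param logLCurr log-likelihood of the current dead point.
#' @param N number of live points.
#' @return logical.
#' @export
checkPlateau <- function(logLNext, logLCurr, N) {
  (logLNext - logLCurr) < 1 / N
}

.nsFailure <- function(msg) {
  stop(errorCondition(msg, class = c("nsRunFailure", "error")))
}

# The loop shared by the structural and the pluggable-likelihood runners.
# `draw(threshold, states)` must return list(success, state, logl) and may
# carry perStepTime.  States are opaque.
.nsLoop <- function(states, logl, draw, nLive, maxPlateau, maxIterations,
                    integration = c("trapezoid", "rectangle")) {
  integration <- match.arg(integration)
  i <- 0L
  logZ <- -Inf
  plateauStreak <- 0L
  prevDead <- NA_real_
  termination <- NULL
  tr_logL <- tr_logX <- tr_logZ <- numeric(0)
  stepTimes <- numeric(0)
  repeat {
    worst <- which.min(logl)
    Lw <- logl[worst]
    res <- draw(Lw, states)
    if (!is.null(res$perStepTime)) stepTimes <- c(stepTimes, res$perStepTime)
    if (!isTRUE(res$success)) {
      termination <- "failure_limit"
      break
    }
    i <- i + 1L
    if (i > 1L) {
      plateauStreak <- if (checkPlateau(Lw, prevDead, nLive))
        plateauStreak + 1L else 0L
    }
    dX <- priorMass(i - 1L, nLive) - priorMass(i, nLive)
    lbar <- switch(integration,
      rectangle = Lw,
      trapezoid = logMeanExp(c(if (i == 1L) Lw else prevDead, Lw)))
    logZ <- logSumExp(c(logZ, lbar + log(dX)))
    tr_logL <- c(tr_logL, Lw)
    tr_logX <- c(tr_logX, -i / nLive)
    tr_logZ <- c(tr_logZ, logZ)
    states[[worst]] <- res$state
    logl[worst] <- res$logl
    prevDead <- Lw
    if (plateauStreak >= maxPlateau) { termination <- "plateau_limit"; break }
    if (i >= maxIterations) { termination <- "max_iterations"; break }
  }
  remainder <- logSumExp(logl) - log(nLive) + log(priorMass(i, nLive))
  logZ <- logSumExp(c(logZ, remainder))
  list(logZ = logZ, termination = termination, iterations = i,
       trace = data.frame(iteration = seq_len(i), logL = tr_logL,
                          logX = tr_logX, logZ = tr_logZ),
       states = states, logl = logl, stepTimes = stepTimes)
}

#' Run nested sampling for one representation
#'
#' Estimates the log model evidence of a coarse-grained representation.
#' \code{nLive} models are first equilibrated into the modified prior by
#' replica-exchange MCMC; at every iteration the worst live point is
#' removed, the evidence is incremented with its likelihood and the
#' trapezoidal prior-mass width, and the point is replaced by a sample
#' from the likelihood-constrained modified prior.  The run terminates
#' when constrained sampling fails \code{maxFailures} consecutive batches,
#' when \code{maxPlateau} consecutive likelihood-plateau iterations occur,
#' or at \code{maxIterations}.  On termination the live-point remainder
#' \eqn{X_{final}\,\overline{L}_{live}} is added, so that in particular a
#' constant likelihood \eqn{L_0} yields \eqn{Z = L_0} exactly.
#'
#' @param topology a \linkS4class{ChainTopology}.
#' @param scheme a \linkS4class{RepresentationScheme} or number.
#' @param partition a \linkS4class{RestraintPartition}.
#' @param moveset a \linkS4class{MoveSet}.
#' @param nLive number of live points; a warning is emitted when this is
#'   below the free-parameter bound \code{3n + 6m}.
#' @param nSteps MCMC steps per sampling batch.
#' @param maxFailures consecutive failed batches before termination.
#' @param maxPlateau consecutive plateau iterations before termination.
#' @param maxIterations iteration cap (set high; convergence is expected
#'   through the other two conditions).
#' @param seed integer seed; all randomness in the run flows from it.
#' @param integration \code{"trapezoid"} (default) or \code{"rectangle"}
#'   quadrature on the L-vs-X curve.
#' @inheritParams mcmcFromModifiedPrior
#' @return an \linkS4class{NSRunResult}.
#' @export
runNestedSampling <- function(topology, scheme, partition, moveset = MoveSet(),
                              nLive = 50, nSteps = 50, maxFailures = 4,
                              maxPlateau = 20, maxIterations = 10000,
                              seed = NULL, integration = "trapezoid",
                              kBond = 1, kEV = 1, slack = 2, boxHalfSide = 300) {
  if (!is.null(seed))
    return(withr::with_seed(seed, runNestedSampling(
      topology, scheme, partition, moveset, nLive, nSteps, maxFailures,
      maxPlateau, maxIterations, seed = NULL, integration = integration,
      kBond = kBond, kEV = kEV, slack = slack, boxHalfSide = boxHalfSide)))
  t0 <- proc.time()[["elapsed"]]
  if (!is(scheme, "RepresentationScheme")) scheme <- RepresentationScheme(scheme)
  model <- coarseGrain(topology, scheme)
  nLive <- as.integer(nLive)
  if (nLive < 1L) stop("nLive must be >= 1")
  nfp <- countFreeParameters(model)
  if (nLive < nfp)
    warning(sprintf("nLive (%d) is below the free-parameter bound 3n+6m = %d for scheme '%s'",
                    nLive, nfp, scheme@label))
  ctx <- .scoreContext(model, partition, kBond, kEV, slack, boxHalfSide)
  stepTimes <- numeric(0)

  # initial live set: equilibrate randomized models into the modified prior
  states <- vector("list", nLive)
  logl <- numeric(nLive)
  for (k in seq_len(nLive)) {
    ok <- FALSE
    for (try in 1:5) {
      X0 <- beadCoords(randomizeModel(model, boxHalfSide))
      if (!is.finite(.ctxPrior(ctx, X0))) next
      res <- .remcmc(ctx, X0, moveset, as.integer(nSteps))
      stepTimes <- c(stepTimes, res$perStepTime)
      ll <- .ctxLik(ctx, res$final)
      if (is.finite(ll)) {
        states[[k]] <- res$final; logl[k] <- ll; ok <- TRUE; break
      }
    }
    if (!ok)
      .nsFailure(sprintf("no finite-likelihood starting model found for scheme '%s'",
                         scheme@label))
  }

  draw <- function(threshold, live) {
    r <- .sampleConstrained(ctx, live, threshold, moveset, as.integer(nSteps),
                            as.integer(maxFailures))
    list(success = r$success, state = r$coords, logl = r$logLik,
         perStepTime = r$perStepTime)
  }
  out <- .nsLoop(states, logl, draw, nLive, maxPlateau, maxIterations,
                 integration)
  stepTimes <- c(stepTimes, out$stepTimes)
  new("NSRunResult", logZ = out$logZ, termination = out$termination,
      iterations = as.integer(out$iterations),
      perStepTime = mean(stepTimes), processTime = proc.time()[["elapsed"]] - t0,
      trace = out$trace, nLive = nLive, scheme = scheme@label,
      seed = as.integer(seed %||% NA_integer_))
}

#' Nested sampling with a pluggable likelihood
#'
#' Runs the same nested-sampling loop on an abstract problem given by a
#' prior sampler and a log-likelihood, bypassing the structural scoring
#' core.  Constrained replacement uses a short Metropolis walk on the
#' prior, started from a random live point and restricted to
#' \code{logLik >= threshold}.  This is the analytic test surface: toys
#' with closed-form evidence validate the estimator.
#'
#' @param rprior function() returning one draw from the prior (numeric
#'   vector).
#' @param logLik function(x) returning the log-likelihood.
#' @param logPrior function(x) returning the (possibly unnormalized) prior
#'   log-density; \code{-Inf} outside the support.
#' @param nLive number of live points.
#' @param mcmcSteps Metropolis steps per replacement.
#' @param proposalSd proposal standard deviation per dimension; default is
#'   the spread of the initial live points.
#' @param maxPlateau,maxIterations,seed,integration see
#'   [runNestedSampling()].
#' @return an \linkS4class{NSRunResult} (with an empty scheme label).
#' @examples
#' # uniform prior on [-5, 5], standard normal likelihood; Z ~= 0.1
#' r <- runNestedSamplingFn(
#'   rprior = function() runif(1, -5, 5),
#'   logLik = function(x) dnorm(x, log = TRUE),
#'   logPrior = function(x) if (abs(x) <= 5) 0 else -Inf,
#'   nLive = 50, seed = 1)
#' logZ(r)
#' @export
runNestedSamplingFn <- function(rprior, logLik, logPrior, nLive = 100,
                                mcmcSteps = 30, proposalSd = NULL,
                                maxPlateau = 20, maxIterations = 5000,
                                seed = NULL, integration = "trapezoid") {
  if (!is.null(seed))
    return(withr::with_seed(seed, runNestedSamplingFn(
      rprior, logLik, logPrior, nLive, mcmcSteps, proposalSd,
      maxPlateau, maxIterations, seed = NULL, integration = integration)))
  t0 <- proc.time()[["elapsed"]]
  nLive <- as.integer(nLive)
  states <- lapply(seq_len(nLive), function(k) rprior())
  logl <- vapply(states, logLik, numeric(1))
  if (!any(is.finite(logl)))
    .nsFailure("no finite-likelihood starting point found")
  if (any(!is.finite(logl))) {
    for (k in which(!is.finite(logl))) {
      for (try in 1:20) {
        x <- rprior(); ll <- logLik(x)
        if (is.finite(ll)) { states[[k]] <- x; logl[k] <- ll; break }
      }
      if (!is.finite(logl[k]))
        .nsFailure("no finite-likelihood starting point found")
    }
  }
  d <- length(states[[1L]])
  if (is.null(proposalSd)) {
    sds <- apply(do.call(rbind, states), 2, stats::sd)
    proposalSd <- ifelse(is.finite(sds) & sds > 0, sds, 1)
  }
  proposalSd <- rep_len(proposalSd, d)

  draw <- function(threshold, live) {
    t1 <- proc.time()[["elapsed"]]
    x <- live[[sample.int(length(live), 1L)]]
    lp <- logPrior(x); ll <- logLik(x)
    for (s in seq_len(mcmcSteps)) {
      xp <- x + stats::rnorm(d, 0, proposalSd)
      lpp <- logPrior(xp)
      if (!is.finite(lpp)) next
      llp <- logLik(xp)
      if (llp < threshold) next
      if (lpp >= lp || stats::runif(1) < exp(lpp - lp)) {
        x <- xp; lp <- lpp; ll <- llp
      }
    }
    list(success = is.finite(ll) && ll >= threshold, state = x, logl = ll,
         perStepTime = max(proc.time()[["elapsed"]] - t1, 1e-9) / mcmcSteps)
  }
  out <- .nsLoop(states, logl, draw, nLive, maxPlateau, maxIterations,
                 integration)
  new("NSRunResult", logZ = out$logZ, termination = out$termination,
      iterations = as.integer(out$iterations),
      perStepTime = mean(out$stepTimes), processTime = proc.time()[["elapsed"]] - t0,
      trace = out$trace, nLive = nLive, scheme = "",
      seed = as.integer(seed %||% NA_integer_))
}
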