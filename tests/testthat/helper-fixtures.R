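# Shared fixtures, built in code and cached per session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

preset <- function(name) cached(paste0("preset_", name), syntheticPreset(name))

# single unstructured chain
chainTop <- function(len, id = "A") {
  ChainTopology(data.frame(chain_id = id, start = 1L, end = as.integer(len),
                           kind = "unstructured"))
}

# hand-built bead model: one bead per row of `beads`, explicit radii/coords
handModel <- function(chain, radius, coords, rigid = NA_integer_, nres = 1L) {
  n <- nrow(coords)
  beads <- data.frame(chain_id = rep_len(chain, n),
                      rigid_body = rep_len(as.integer(rigid), n),
                      radius = rep_len(radius, n), stringsAsFactors = FALSE)
  beads$nres <- rep_len(as.integer(nres), n)
  first <- unlist(lapply(split(beads$nres, beads$chain_id)[unique(beads$chain_id)],
                         function(x) cumsum(c(1L, x[-length(x)]))))
  beads$first <- as.integer(first)
  beads$last <- beads$first + beads$nres - 1L
  new("BeadModel", beads = beads[, c("chain_id", "first", "last", "nres",
                                     "radius", "rigid_body")],
      coords = as.matrix(coords), scheme = "hand")
}

# two single-bead chains separated by `d` along x; non-bonded pair
twoChainModel <- function(d, radius = 2) {
  handModel(c("A", "B"), radius, rbind(c(0, 0, 0), c(d, 0, 0)))
}

oneLink <- function(res1 = 1L, res2 = 1L, chain1 = "A", chain2 = "B", ...) {
  CrosslinkDataset(data.frame(chain1 = chain1, residue1 = res1,
                              chain2 = chain2, residue2 = res2), ...)
}

emptyLinks <- function(...) {
  CrosslinkDataset(data.frame(chain1 = character(0), residue1 = integer(0),
                              chain2 = character(0), residue2 = integer(0)), ...)
}

gaussianToy <- function(nLive, seed, ...) {
  runNestedSamplingFn(
    rprior = function() stats::runif(1, -5, 5),
    logLik = function(x) stats::dnorm(x, log = TRUE),
    logPrior = function(x) if (abs(x) <= 5) 0 else -Inf,
    nLive = nLive, seed = seed, ...)
}

gaussianToyTruth <- function() log((stats::pnorm(5) - stats::pnorm(-5)) / 10)

# brute-force Gaussian-overlap cross-correlation by grid quadrature
gridCC <- function(weights1, means1, covs1, weights2, means2, covs2,
                   spacing = 0.5, pad = 14) {
  dens <- function(w, m, C, pts) {
    out <- numeric(nrow(pts))
    for (j in seq_along(w)) {
      d <- sweep(pts, 2, m[j, ])
      P <- solve(C[[j]])
      q <- rowSums((d %*% P) * d)
      out <- out + w[j] * exp(-1.5 * log(2 * pi) -
        0.5 * determinant(C[[j]])$modulus[1] - 0.5 * q)
    }
    out
  }
  all <- rbind(means1, means2)
  lo <- apply(all, 2, min) - pad; hi <- apply(all, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  f <- dens(weights1, means1, covs1, pts)
  g <- dens(weights2, means2, covs2, pts)
  sum(f * g) / sqrt(sum(f * f) * sum(g * g))
}

# independent brute-force implementation of the selection rule
bruteSelect <- function(df, fold = 3, semMult = 1) {
  best <- which.max(df$meanLogZ)
  overlaps <- function(a, b) {
    (df$meanLogZ[a] + semMult * df$semLogZ[a] >=
       df$meanLogZ[b] - semMult * df$semLogZ[b]) &&
      (df$meanLogZ[b] + semMult * df$semLogZ[b] >=
         df$meanLogZ[a] - semMult * df$semLogZ[a])
  }
  top <- vapply(seq_len(nrow(df)), function(i) overlaps(i, best), logical(1))
  tmin <- min(df$meanPerStepTime[top])
  opt <- top & df$meanPerStepTime <= fold * tmin
  df$scheme[opt]
}

# random rigid transform applied to a coordinate matrix
rigidTransform <- function(X, seed = 1) {
  withr::with_seed(seed, {
    R <- nsrep:::rotationMatrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
    t <- stats::runif(3, -20, 20)
    sweep(X %*% t(R), 2, t, "+")
  })
}
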