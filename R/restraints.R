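# Scoring: stereochemistry prior, Bayesian crosslink likelihood, GMM
# density cross-correlation, and posterior repartitioning.

# bead pair lists; pairs inside one rigid body are skipped (their relative
# geometry is fixed, so they contribute a constant)
.pairIndices <- function(beads) {
  n <- nrow(beads)
  ch <- beads$chain_id
  rb <- beads$rigid_body
  bonded_i <- integer(0); bonded_j <- integer(0)
  if (n > 1L) {
    i <- seq_len(n - 1L)
    keep <- ch[i] == ch[i + 1L] &
      !(!is.na(rb[i]) & !is.na(rb[i + 1L]) & rb[i] == rb[i + 1L])
    bonded_i <- i[keep]; bonded_j <- i[keep] + 1L
  }
  if (n > 1L) {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- ut[, 1L]; j <- ut[, 2L]
    same_rb <- !is.na(rb[i]) & !is.na(rb[j]) & rb[i] == rb[j]
    # exclude sequence-local pairs (1-2 and 1-3 bead neighbours) from the
    # excluded-volume sum: consecutive bead spheres overlap by construction
    near <- (ch[i] == ch[j]) & (j - i <= 2L)
    keep <- !same_rb & !near
    nb_i <- i[keep]; nb_j <- j[keep]
  } else {
    nb_i <- integer(0); nb_j <- integer(0)
  }
  list(bonded_i = bonded_i, bonded_j = bonded_j, nb_i = nb_i, nb_j = nb_j)
}

.stereoScore <- function(X, r, pairs, kBond, kEV, slack) {
  s <- 0
  if (length(pairs$bonded_i)) {
    d <- sqrt(rowSums((X[pairs$bonded_i, , drop = FALSE] -
                       X[pairs$bonded_j, , drop = FALSE])^2))
    gap <- d - (r[pairs$bonded_i] + r[pairs$bonded_j] + slack)
    s <- s + kBond * sum(pmax(gap, 0)^2)
  }
  if (length(pairs$nb_i)) {
    d <- sqrt(rowSums((X[pairs$nb_i, , drop = FALSE] -
                       X[pairs$nb_j, , drop = FALSE])^2))
    ov <- (r[pairs$nb_i] + r[pairs$nb_j]) - d
    s <- s + kEV * sum(pmax(ov, 0)^2)
  }
  -s
}

# residue -> bead index lookup, per chain
.residueBeadMap <- function(model) {
  b <- model@beads
  maps <- list()
  for (ch in unique(b$chain_id)) {
    s <- b[b$chain_id == ch, , drop = FALSE]
    m <- integer(max(s$last))
    m[] <- NA_integer_
    m[unlist(Map(seq.int, s$first, s$last))] <- rep(which(b$chain_id == ch), s$nres)
    maps[[ch]] <- m
  }
  maps
}

.linkBeadIdx <- function(model, links) {
  tab <- linkTable(links)
  if (nrow(tab) == 0L) return(cbind(i = integer(0), j = integer(0)))
  maps <- .residueBeadMap(model)
  lookup <- function(ch, res, k) {
    if (!ch %in% names(maps) || res < 1L || res > length(maps[[ch]]) ||
        is.na(maps[[ch]][res]))
      stop(sprintf("crosslink %d references unknown residue %s:%d", k, ch, res))
    maps[[ch]][res]
  }
  i <- j <- integer(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    i[k] <- lookup(tab$chain1[k], tab$residue1[k], k)
    j[k] <- lookup(tab$chain2[k], tab$residue2[k], k)
  }
  cbind(i = i, j = j)
}

.xlScore <- function(X, r, idx, d0, psi, sigma) {
  if (nrow(idx) == 0L) return(0)
  d <- sqrt(rowSums((X[idx[, 1L], , drop = FALSE] - X[idx[, 2L], , drop = FALSE])^2))
  ds <- pmax(0, d - r[idx[, 1L]] - r[idx[, 2L]])
  S <- stats::pnorm((d0 - ds) / sigma)
  sum(log(psi + (1 - 2 * psi) * S))
}

#' Stereochemistry score of a bead model
#'
#' Harmonic sequence-connectivity and excluded-volume restraints:
#' \deqn{-\sum_{bonded} k_c \max(0, d - r_i - r_j - s)^2
#'       -\sum_{nonbonded} k_{ev} \max(0, r_i + r_j - d)^2}
#' where \eqn{d} is the center distance.  Zero when all bonded neighbours
#' are within slack of touching and no non-bonded pair overlaps.  Pairs
#' inside one rigid body are excluded (constant contribution), as are
#' intra-chain pairs at bead separation <= 2 (the 1-2/1-3 exclusions of
#' molecular force fields: sequence-neighbouring bead spheres overlap by
#' construction at fine resolutions).
#'
#' @param model a \linkS4class{BeadModel}.
#' @param kBond connectivity force constant (1/angstrom^2).
#' @param kEV excluded-volume force constant (1/angstrom^2).
#' @param slack allowed bonded-gap slack (angstroms).
#' @return log-probability (<= 0).
#' @export
scoreStereochemistry <- function(model, kBond = 1, kEV = 1, slack = 2) {
  pairs <- .pairIndices(model@beads)
  .stereoScore(model@coords, model@beads$radius, pairs, kBond, kEV, slack)
}

#' Bayesian crosslink log-likelihood
#'
#' Each link contributes \eqn{\log[\psi + (1-2\psi) S(d)]} with the
#' erf-sigmoid forward model
#' \eqn{S(d) = \frac12(1 - \mathrm{erf}((d - d_0)/(\sigma\sqrt2)))} and
#' \eqn{d} the bead-surface distance (center distance minus both radii,
#' floored at zero).  Using the surface distance ensures coarser beads are
#' not spuriously penalized; the structural uncertainty \eqn{\sigma}
#' absorbs the positional blur of coarse-graining.  Every per-link term
#' lies in \eqn{[\log\psi, \log(1-\psi)]}.
#'
#' @param model a \linkS4class{BeadModel}.
#' @param links a \linkS4class{CrosslinkDataset}.
#' @return log-likelihood.
#' @export
scoreCrosslinks <- function(model, links) {
  idx <- .linkBeadIdx(model, links)
  .xlScore(model@coords, model@beads$radius, idx, links@d0, links@psi, links@sigma)
}

# --- GMM density restraint ------------------------------------------------

# precompute bead-class x component inverse covariances and log constants
.emContext <- function(model, density) {
  b <- model@beads
  r <- b$radius
  w <- b$nres / sum(b$nres)
  v <- density@weights
  m <- density@means
  K <- length(v)
  n <- length(r)
  cls <- match(r, unique(r))
  ur <- unique(r)
  E <- array(0, dim = c(length(ur), K, 6))
  LC <- matrix(0, length(ur), K)
  for (u in seq_along(ur)) {
    for (j in seq_len(K)) {
      M <- diag(3) * ur[u]^2 + density@covariances[[j]]
      Minv <- solve(M)
      E[u, j, ] <- c(Minv[1, 1], Minv[2, 2], Minv[3, 3],
                     Minv[1, 2], Minv[1, 3], Minv[2, 3])
      LC[u, j] <- -1.5 * log(2 * pi) - 0.5 * determinant(M)$modulus[1]
    }
  }
  # ||g||^2 is coordinate-independent
  gg <- 0
  for (j in seq_len(K)) for (l in seq_len(K)) {
    M <- density@covariances[[j]] + density@covariances[[l]]
    dm <- m[j, ] - m[l, ]
    gg <- gg + v[j] * v[l] * exp(-1.5 * log(2 * pi) -
      0.5 * determinant(M)$modulus[1] - 0.5 * sum(dm * solve(M, dm)))
  }
  S2 <- outer(r^2, r^2, "+")
  list(r = r, w = w, v = v, m = m, K = K, cls = cls, E = E, LC = LC,
       gg = gg, S2 = S2, lcf = -1.5 * log(2 * pi * S2))
}

.emCC <- function(em, X) {
  # <f,g>
  fg <- 0
  for (j in seq_len(em$K)) {
    dx <- X[, 1L] - em$m[j, 1L]; dy <- X[, 2L] - em$m[j, 2L]; dz <- X[, 3L] - em$m[j, 3L]
    e <- em$E[em$cls, j, , drop = FALSE]
    q <- e[, 1L, 1L] * dx^2 + e[, 1L, 2L] * dy^2 + e[, 1L, 3L] * dz^2 +
      2 * (e[, 1L, 4L] * dx * dy + e[, 1L, 5L] * dx * dz + e[, 1L, 6L] * dy * dz)
    fg <- fg + em$v[j] * sum(em$w * exp(em$LC[em$cls, j] - 0.5 * q))
  }
  # ||f||^2
  rs <- rowSums(X^2)
  D2 <- pmax(outer(rs, rs, "+") - 2 * tcrossprod(X), 0)
  ff <- sum(tcrossprod(em$w) * exp(em$lcf - D2 / (2 * em$S2)))
  fg / sqrt(ff * em$gg)
}

#' GMM density log-likelihood (normalized cross-correlation)
#'
#' The model is converted into a Gaussian mixture with one isotropic
#' component per bead (mean = bead center, variance = radius^2, weight
#' proportional to residue count) and compared to the data density by the
#' normalized Gaussian overlap
#' \eqn{cc = \langle f,g\rangle / (\|f\| \|g\|)}, evaluated with the
#' closed-form Gaussian product integral.  Returns
#' \code{emWeight * log(cc)} with \code{cc} clamped to \code{[eps, 1]};
#' zero when the model mixture equals the data mixture.
#'
#' @param model a \linkS4class{BeadModel}.
#' @param density a \linkS4class{GMMDensity}.
#' @param emWeight weight of the density score (default 1).
#' @param eps lower clamp on the cross-correlation (default 1e-12).
#' @return log-likelihood (<= 0).
#' @export
scoreEM <- function(model, density, emWeight = 1, eps = 1e-12) {
  validObject(density)
  em <- .emContext(model, density)
  cc <- min(max(.emCC(em, model@coords), eps), 1)
  emWeight * log(cc)
}

# --- posterior repartitioning --------------------------------------------

#' Split crosslinks into prior and likelihood subsets
#'
#' Posterior repartitioning: a uniformly random subset of
#' \code{round(fraction * nLinks)} crosslinks is moved into the nested
#' sampling prior (alongside the stereochemistry restraints), improving the
#' overlap between prior and posterior; the remaining links and the
#' optional density restraint form the likelihood.  The prior-likelihood
#' product is unchanged by the split.
#'
#' @param links a \linkS4class{CrosslinkDataset}.
#' @param fraction fraction of links assigned to the prior, in [0, 1)
#'   (default 0.3).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param density optional \linkS4class{GMMDensity} scored in the
#'   likelihood.
#' @param useEM whether the density contributes to the likelihood.
#' @param emWeight weight of the density score.
#' @return a \linkS4class{RestraintPartition}.
#' @export
partitionRestraints <- function(links, fraction = 0.3, seed = 1,
                                density = NULL, useEM = !is.null(density),
                                emWeight = 1) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  n <- nLinks(links)
  k <- round(fraction * n)
  idx <- if (k > 0L) withr::with_seed(seed, sort(sample.int(n, k))) else integer(0)
  new("RestraintPartition", links = links, priorIdx = as.integer(idx),
      useEM = useEM, density = density, emWeight = emWeight,
      fraction = fraction, seed = as.integer(seed))
}

#' Modified prior log-probability
#'
#' Stereochemistry restraints plus the prior-side crosslink subset of the
#' partition; this is the distribution the replica-exchange sampler draws
#' from during nested sampling.
#'
#' @param model a \linkS4class{BeadModel}.
#' @param partition a \linkS4class{RestraintPartition}.
#' @inheritParams scoreStereochemistry
#' @return log-probability (unnormalized).
#' @export
modifiedLogPrior <- function(model, partition, kBond = 1, kEV = 1, slack = 2) {
  scoreStereochemistry(model, kBond = kBond, kEV = kEV, slack = slack) +
    scoreCrosslinks(model, priorLinks(partition))
}

#' Likelihood log-probability
#'
#' The likelihood-side crosslink subset plus, when enabled, the GMM density
#' restraint.  For any model, \code{modifiedLogPrior + logLikelihood} is
#' invariant to how the links were partitioned.
#'
#' @param model a \linkS4class{BeadModel}.
#' @param partition a \linkS4class{RestraintPartition}.
#' @return log-likelihood.
#' @export
logLikelihood <- function(model, partition) {
  s <- scoreCrosslinks(model, likelihoodLinks(partition))
  if (partition@useEM)
    s <- s + scoreEM(model, partition@density, emWeight = partition@emWeight)
  s
}

# --- internal scoring context for the sampler ----------------------------

# Precomputes pair lists, link bead indices and EM tables once, so the
# MCMC inner loop only does vectorized arithmetic on a coordinate matrix.
.scoreContext <- function(model, partition, kBond = 1, kEV = 1, slack = 2,
                          boxHalfSide = 300) {
  pairs <- .pairIndices(model@beads)
  priorIdx <- .linkBeadIdx(model, priorLinks(partition))
  likIdx <- .linkBeadIdx(model, likelihoodLinks(partition))
  d <- partition@links
  em <- if (partition@useEM) .emContext(model, partition@density) else NULL
  rb <- model@beads$rigid_body
  bodies <- lapply(unique(stats::na.omit(rb)),
                   function(id) which(!is.na(rb) & rb == id))
  list(model = model, r = model@beads$radius, pairs = pairs,
       priorIdx = priorIdx, likIdx = likIdx,
       d0 = d@d0, psi = d@psi, sigma = d@sigma,
       em = em, emWeight = partition@emWeight,
       kBond = kBond, kEV = kEV, slack = slack, box = boxHalfSide,
       flex = which(is.na(rb)), bodies = bodies)
}

.ctxPrior <- function(ctx, X) {
  if (max(abs(X)) > ctx$box) return(-Inf)
  .stereoScore(X, ctx$r, ctx$pairs, ctx$kBond, ctx$kEV, ctx$slack) +
    .xlScore(X, ctx$r, ctx$priorIdx, ctx$d0, ctx$psi, ctx$sigma)
}

.ctxLik <- function(ctx, X) {
  s <- .xlScore(X, ctx$r, ctx$likIdx, ctx$d0, ctx$psi, ctx$sigma)
  if (!is.null(ctx$em))
    s <- s + ctx$emWeight * log(min(max(.emCC(ctx$em, X), 1e-12), 1))
  s
}
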