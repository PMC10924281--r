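# Synthetic fixtures: toy assemblies, simulated crosslinks and simulated
# densities with known ground truth.

# self-avoiding random walk for one chain; bond length fixed, steps biased
# toward the running centroid by `compactness`
.growChain <- function(length, compactness, origin, others, bond = 3.8,
                       minDist = 3.0, maxTriesPerStep = 60L, maxRestarts = 40L) {
  for (restart in seq_len(maxRestarts)) {
    X <- matrix(NA_real_, length, 3)
    X[1, ] <- origin
    ok <- TRUE
    for (i in 2:length) {
      placed <- FALSE
      ctr <- colMeans(X[seq_len(i - 1L), , drop = FALSE])
      toCtr <- ctr - X[i - 1L, ]
      nrmC <- sqrt(sum(toCtr^2))
      for (try in seq_len(maxTriesPerStep)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        # bias decays over retries so a blocked compact step can escape
        eff <- compactness * (1 - (try - 1) / maxTriesPerStep)
        if (nrmC > 1e-9 && eff > 0) {
          dir <- u + 0.5 * eff * toCtr / nrmC
          dir <- dir / sqrt(sum(dir^2))
        } else dir <- u
        cand <- X[i - 1L, ] + bond * dir
        prev <- X[seq_len(max(i - 2L, 1L)), , drop = FALSE]
        d2own <- min(rowSums(sweep(prev, 2, cand)^2))
        d2oth <- if (nrow(others)) min(rowSums(sweep(others, 2, cand)^2)) else Inf
        if (d2own >= minDist^2 && d2oth >= minDist^2) {
          X[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(X)
  }
  stop("could not grow a self-avoiding chain within the retry budget; ",
       "reduce compactness or chain length")
}

#' Generate a synthetic toy assembly
#'
#' Builds per-chain C-alpha traces as self-avoiding random walks with a
#' fixed 3.8-angstrom bond length.  \code{compactness} biases each step
#' toward the running chain centroid: 0 gives an extended coil, 1 a
#' collapsed globule.  Chains are placed so no two residues come closer
#' than 3 angstroms.  The result carries an all-unstructured topology with
#' reference coordinates attached; use [markStructured()] to declare rigid
#' segments.
#'
#' @param lengths integer vector of chain lengths (>= 10 residues each).
#' @param compactness numeric in [0, 1], recycled per chain.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param chainIds chain identifiers (default \code{"A"}, \code{"B"}, ...).
#' @return a \linkS4class{SyntheticAssembly}.
#' @examples
#' a <- generateAssembly(30, compactness = 0, seed = 1)
#' @export
generateAssembly <- function(lengths, compactness = 0.5, seed = 1,
                             chainIds = LETTERS[seq_along(lengths)]) {
  stopifnot(all(lengths >= 10))
  compactness <- rep_len(compactness, length(lengths))
  stopifnot(all(compactness >= 0 & compactness <= 1))
  withr::with_seed(seed, {
    coords <- list()
    placed <- matrix(numeric(0), 0, 3)
    for (c in seq_along(lengths)) {
      origin <- if (c == 1L) c(0, 0, 0) else {
        repeat {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- u * stats::runif(1, 10, 15) * c
          if (!nrow(placed) ||
              min(rowSums(sweep(placed, 2, cand)^2)) >= 4) break
        }
        cand
      }
      X <- .growChain(lengths[c], compactness[c], origin, placed)
      coords[[chainIds[c]]] <- X
      placed <- rbind(placed, X)
    }
    seg <- data.frame(chain_id = chainIds, start = 1L,
                      end = as.integer(lengths), kind = "unstructured",
                      stringsAsFactors = FALSE)
    top <- ChainTopology(seg, reference = coords)
    new("SyntheticAssembly", topology = top, coords = coords,
        compactness = compactness)
  })
}

#' Declare structured segments of an assembly topology
#'
#' Marks residue ranges as structured rigid bodies, splitting the
#' enclosing unstructured segments; the reference coordinates already
#' attached to the topology provide the rigid geometry.
#'
#' @param assembly a \linkS4class{SyntheticAssembly}.
#' @param structured data.frame with columns \code{chain_id}, \code{start},
#'   \code{end}, \code{rigid_body}.
#' @return the assembly with an updated topology.
#' @export
markStructured <- function(assembly, structured) {
  seg <- assembly@topology@segments
  for (k in seq_len(nrow(structured))) {
    ch <- structured$chain_id[k]
    a <- as.integer(structured$start[k]); b <- as.integer(structured$end[k])
    hit <- which(seg$chain_id == ch & seg$start <= a & seg$end >= b &
                 seg$kind == "unstructured")
    if (length(hit) != 1L)
      stop(sprintf("structured range %s:%d-%d does not fall inside one unstructured segment",
                   ch, a, b))
    s <- seg[hit, ]
    parts <- list()
    if (s$start < a) parts <- c(parts, list(data.frame(
      chain_id = ch, start = s$start, end = a - 1L, kind = "unstructured",
      rigid_body = NA_integer_, pdb_chain = s$pdb_chain)))
    parts <- c(parts, list(data.frame(
      chain_id = ch, start = a, end = b, kind = "structured",
      rigid_body = as.integer(structured$rigid_body[k]), pdb_chain = s$pdb_chain)))
    if (s$end > b) parts <- c(parts, list(data.frame(
      chain_id = ch, start = b + 1L, end = s$end, kind = "unstructured",
      rigid_body = NA_integer_, pdb_chain = s$pdb_chain)))
    seg <- rbind(seg[-hit, ], do.call(rbind, parts))
  }
  assembly@topology <- ChainTopology(seg, reference = assembly@topology@reference)
  assembly
}

.allResiduePairs <- function(assembly, minSeqSep = 5L) {
  chains <- names(assembly@coords)
  res <- do.call(rbind, lapply(chains, function(ch) data.frame(
    chain = ch, residue = seq_len(nrow(assembly@coords[[ch]])),
    stringsAsFactors = FALSE)))
  X <- do.call(rbind, assembly@coords)
  n <- nrow(res)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  keep <- res$chain[i] != res$chain[j] |
    abs(res$residue[i] - res$residue[j]) >= minSeqSep
  i <- i[keep]; j <- j[keep]
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  data.frame(chain1 = res$chain[i], residue1 = res$residue[i],
             chain2 = res$chain[j], residue2 = res$residue[j], dist = d,
             stringsAsFactors = FALSE)
}

#' Simulate a crosslink dataset from a reference assembly
#'
#' True-positive links are drawn uniformly from residue pairs whose
#' reference C-alpha distance is at most \code{dMax}; decoys
#' (false positives) are drawn from pairs farther apart.  Near-sequence
#' pairs (separation < \code{minSeqSep} within a chain) are excluded as
#' chemically uninformative.  Distances use the representation-independent
#' reference coordinates, so the ground truth does not depend on any
#' coarse-graining.
#'
#' @param assembly a \linkS4class{SyntheticAssembly}.
#' @param nLinks total number of links to emit.
#' @param dMax true-positive distance cutoff (angstroms, default 25).
#' @param fpRate fraction of links drawn as decoys (default 0.1).
#' @param seed integer seed.
#' @param minSeqSep minimum intra-chain sequence separation (default 5).
#' @param d0,psi,sigma forward-model parameters stored on the dataset, see
#'   \linkS4class{CrosslinkDataset}.
#' @return a \linkS4class{CrosslinkDataset}.
#' @export
simulateCrosslinks <- function(assembly, nLinks, dMax = 25, fpRate = 0.1,
                               seed = 1, minSeqSep = 5L, d0 = 21, psi = 0.05,
                               sigma = 10) {
  stopifnot(fpRate >= 0, fpRate <= 1)
  pairs <- .allResiduePairs(assembly, minSeqSep)
  nFP <- round(fpRate * nLinks)
  nTP <- nLinks - nFP
  tpPool <- which(pairs$dist <= dMax)
  fpPool <- which(pairs$dist > dMax)
  if (length(tpPool) < nTP || length(fpPool) < nFP)
    stop(sprintf("insufficient candidate pairs: %d/%d within %g A (need %d), %d beyond (need %d)",
                 length(tpPool), nrow(pairs), dMax, nTP, length(fpPool), nFP))
  withr::with_seed(seed, {
    sel <- c(sample(tpPool, nTP), sample(fpPool, nFP))
    CrosslinkDataset(pairs[sel, c("chain1", "residue1", "chain2", "residue2")],
                     d0 = d0, psi = psi, sigma = sigma)
  })
}

#' Simulate a Gaussian-mixture density from a reference assembly
#'
#' Emulates a low-resolution density map: the reference C-alpha positions
#' are partitioned into \code{nComponents} groups by k-means; each group
#' becomes one Gaussian with mean at the group centroid, covariance equal
#' to the group scatter plus \code{blurSigma^2 I} (the resolution blur),
#' and weight proportional to group size.
#'
#' @param assembly a \linkS4class{SyntheticAssembly}.
#' @param nComponents number of mixture components (>= 1, at most the
#'   residue count).
#' @param blurSigma isotropic blur added to every covariance (angstroms,
#'   default 5).
#' @param seed integer seed (k-means initialization).
#' @return a \linkS4class{GMMDensity}.
#' @export
simulateDensity <- function(assembly, nComponents, blurSigma = 5, seed = 1) {
  X <- do.call(rbind, assembly@coords)
  if (nComponents < 1L || nComponents > nrow(X))
    stop("nComponents must lie in [1, number of residues]")
  withr::with_seed(seed, {
    grp <- if (nComponents == 1L) rep(1L, nrow(X))
           else stats::kmeans(X, centers = nComponents, nstart = 5,
                              iter.max = 50)$cluster
    ids <- sort(unique(grp))
    w <- as.numeric(table(factor(grp, levels = ids)))
    means <- t(vapply(ids, function(g) colMeans(X[grp == g, , drop = FALSE]),
                      numeric(3)))
    covs <- lapply(ids, function(g) {
      pts <- X[grp == g, , drop = FALSE]
      S <- if (nrow(pts) > 1L) stats::cov(pts) else matrix(0, 3, 3)
      S + diag(3) * blurSigma^2
    })
    GMMDensity(w, means, covs)
  })
}

#' Named synthetic presets
#'
#' Fixed-seed fixture suites emulating the qualitative regimes of
#' interest: \code{"extended"} (one disordered extended chain, the regime
#' where fine representations are expected to score well),
#' \code{"globular"} (one compact chain with a structured rigid core), and
#' \code{"mixed"} (one compact chain with a rigid core plus one extended
#' chain).  Each preset bundles the assembly, a simulated crosslink set
#' and a simulated density.
#'
#' @param name one of \code{"extended"}, \code{"globular"}, \code{"mixed"}.
#' @return list with elements \code{assembly}, \code{topology},
#'   \code{crosslinks}, \code{density} and \code{schemes} (the candidate
#'   ladder typically explored).
#' @export
syntheticPreset <- function(name = c("extended", "globular", "mixed")) {
  name <- match.arg(name)
  switch(name,
    extended = {
      a <- generateAssembly(100, compactness = 0, seed = 101)
      list(assembly = a, topology = a@topology,
           crosslinks = simulateCrosslinks(a, 30, dMax = 25, fpRate = 0.1, seed = 102),
           density = simulateDensity(a, 10, blurSigma = 5, seed = 103),
           schemes = c(1, 5, 10, 20, 30, 50))
    },
    globular = {
      a <- generateAssembly(100, compactness = 0.9, seed = 201)
      a <- markStructured(a, data.frame(chain_id = "A", start = 21, end = 70,
                                        rigid_body = 1))
      list(assembly = a, topology = a@topology,
           crosslinks = simulateCrosslinks(a, 24, dMax = 25, fpRate = 0.1, seed = 202),
           density = simulateDensity(a, 4, blurSigma = 5, seed = 203),
           schemes = c(5, 20, 50))
    },
    mixed = {
      a <- generateAssembly(c(120, 100), compactness = c(0.9, 0), seed = 301)
      a <- markStructured(a, data.frame(chain_id = "A", start = 21, end = 100,
                                        rigid_body = 1))
      list(assembly = a, topology = a@topology,
           crosslinks = simulateCrosslinks(a, 60, dMax = 25, fpRate = 0.1, seed = 302),
           density = simulateDensity(a, 10, blurSigma = 5, seed = 303),
           schemes = c(1, 5, 10, 20, 50))
    })
}

#' Write a complete ready-to-run workspace for a preset
#'
#' Emits every input format the tool reads: topology TSV, CA-only
#' reference PDB, crosslink CSV, GMM text and a YAML config referencing
#' them.  All files are synthetic.
#'
#' @param dir output directory (created if needed).
#' @param preset preset name passed to [syntheticPreset()].
#' @param ... config overrides written into the YAML (e.g. \code{nRuns},
#'   \code{nLive}, \code{schemes}).
#' @return invisibly, the list of written paths.
#' @export
writeWorkspace <- function(dir, preset = "mixed", ...) {
  p <- syntheticPreset(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    topology = file.path(dir, "topology.tsv"),
    pdb = file.path(dir, "reference_synthetic.pdb"),
    crosslinks = file.path(dir, "crosslinks.csv"),
    density = file.path(dir, "density.gmm"),
    config = file.path(dir, "config.yaml"))
  writeTopology(p$topology, paths$topology)
  writePdbCa(p$assembly@coords, paths$pdb)
  writeCrosslinksCsv(p$crosslinks, paths$crosslinks)
  writeGmmText(p$density, paths$density)
  cfg <- c(list(topology = paths$topology, pdb = paths$pdb,
                crosslinks = paths$crosslinks, density = paths$density,
                schemes = p$schemes, outputDir = file.path(dir, "results")),
           list(...))
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
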