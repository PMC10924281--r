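#' @import methods
NULL

#' Chain topology of a multi-chain assembly
#'
#' A \code{ChainTopology} describes each chain of an assembly as an ordered
#' set of residue segments.  Every segment is either \code{structured}
#' (known reference coordinates, part of a rigid body) or
#' \code{unstructured} (modeled as flexible beads).  Residue numbering is
#' 1-based and segment ranges are inclusive on both ends; within a chain the
#' segments must tile \code{1..length} without gaps or overlaps.
#'
#' @slot segments \code{data.frame} with columns \code{chain_id},
#'   \code{start}, \code{end}, \code{kind} (\code{"structured"} or
#'   \code{"unstructured"}), \code{rigid_body} (integer id, \code{NA} for
#'   flexible segments) and \code{pdb_chain} (chain id in a reference PDB,
#'   \code{NA} if unused).
#' @slot reference named list (by chain id) of per-residue C-alpha
#'   coordinate matrices (length x 3, angstroms); may be empty when no
#'   reference structure is attached.
#'
#' @seealso [readTopology()], [attachReference()], [coarseGrain()]
#' @export
setClass("ChainTopology",
  representation(segments = "data.frame", reference = "list"))

setValidity("ChainTopology", function(object) {
  seg <- object@segments
  need <- c("chain_id", "start", "end", "kind", "rigid_body")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns", paste(need, collapse = ", ")))
  if (nrow(seg) == 0L) return("topology has no segments")
  if (any(seg$start > seg$end)) return("segment start > end")
  if (!all(seg$kind %in% c("structured", "unstructured")))
    return("segment kind must be 'structured' or 'unstructured'")
  if (any(seg$kind == "unstructured" & !is.na(seg$rigid_body)))
    return("unstructured segments cannot carry a rigid_body id")
  if (any(seg$kind == "structured" & is.na(seg$rigid_body)))
    return("structured segments must carry a rigid_body id")
  for (ch in unique(seg$chain_id)) {
    s <- seg[seg$chain_id == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (s$start[1] != 1L)
      return(sprintf("chain %s: segments must start at residue 1", ch))
    if (nrow(s) > 1L && any(s$start[-1] != s$end[-nrow(s)] + 1L))
      return(sprintf("chain %s: segments must tile the chain without gaps or overlaps", ch))
  }
  ref <- object@reference
  if (length(ref) && is.null(names(ref))) return("reference list must be named by chain id")
  TRUE
})

#' Construct a chain topology
#'
#' @param segments data.frame of segments; see \linkS4class{ChainTopology}.
#'   Columns \code{rigid_body} and \code{pdb_chain} are optional and default
#'   to \code{NA}.
#' @param reference optional named list of per-residue C-alpha coordinate
#'   matrices, one per chain.
#' @return A \linkS4class{ChainTopology}.
#' @examples
#' top <- ChainTopology(data.frame(
#'   chain_id = "A", start = 1, end = 30, kind = "unstructured"))
#' chainLengths(top)
#' @export
ChainTopology <- function(segments, reference = list()) {
  segments <- as.data.frame(segments)
  if (is.null(segments$rigid_body))
    segments$rigid_body <- rep(NA_integer_, nrow(segments))
  if (is.null(segments$pdb_chain))
    segments$pdb_chain <- rep(NA_character_, nrow(segments))
  segments$chain_id <- as.character(segments$chain_id)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$rigid_body <- as.integer(segments$rigid_body)
  ord <- order(match(segments$chain_id, unique(segments$chain_id)), segments$start)
  segments <- segments[ord, , drop = FALSE]
  rownames(segments) <- NULL
  new("ChainTopology", segments = segments, reference = reference)
}

#' Candidate coarse-grained representation scheme
#'
#' The object being selected over: how many contiguous residues each
#' spherical bead represents.  A uniform scheme assigns one value to every
#' segment (e.g. the classic 1-, 5-, 10-, 20-, 30-, 50-residues-per-bead
#' ladder); a mixed scheme assigns one value per topology segment.
#'
#' @slot label character scheme label (e.g. \code{"10"} or \code{"mixed"}).
#' @slot residuesPerBead integer vector, either length 1 (uniform) or one
#'   value per topology segment; all values >= 1.
#' @export
setClass("RepresentationScheme",
  representation(label = "character", residuesPerBead = "integer"))

setValidity("RepresentationScheme", function(object) {
  r <- object@residuesPerBead
  if (length(r) < 1L) return("residuesPerBead must be non-empty")
  if (any(is.na(r)) || any(r < 1L)) return("residuesPerBead must be >= 1")
  TRUE
})

#' @rdname RepresentationScheme-class
#' @param residuesPerBead integer: residues per bead, scalar for a uniform
#'   scheme or one value per segment for a mixed scheme.
#' @param label scheme label; defaults to the value for uniform schemes,
#'   \code{"mixed"} otherwise.
#' @examples
#' RepresentationScheme(10)
#' RepresentationScheme(c(5, 50), label = "mixed-5/50")
#' @export
RepresentationScheme <- function(residuesPerBead, label = NULL) {
  residuesPerBead <- as.integer(residuesPerBead)
  if (is.null(label))
    label <- if (length(residuesPerBead) == 1L) as.character(residuesPerBead) else "mixed"
  new("RepresentationScheme", label = label, residuesPerBead = residuesPerBead)
}

#' Coarse-grained bead model
#'
#' A structural model in a given representation: spherical beads with
#' centers (the sampled parameter space), radii and residue ranges.  Beads
#' from structured segments belong to rigid bodies whose internal geometry
#' is fixed; the remaining (flexible) beads move individually.
#'
#' @slot beads \code{data.frame} with columns \code{chain_id}, \code{first},
#'   \code{last}, \code{nres}, \code{radius}, \code{rigid_body}
#'   (\code{NA} for flexible beads).
#' @slot coords numeric matrix (nBeads x 3) of bead centers in angstroms.
#' @slot scheme character label of the representation scheme used.
#' @export
setClass("BeadModel",
  representation(beads = "data.frame", coords = "matrix", scheme = "character"))

setValidity("BeadModel", function(object) {
  b <- object@beads
  need <- c("chain_id", "first", "last", "nres", "radius", "rigid_body")
  if (!all(need %in% names(b)))
    return(paste("beads must have columns", paste(need, collapse = ", ")))
  if (nrow(b) == 0L) return("model has no beads")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != nrow(b))
    return("coords must be an nBeads x 3 numeric matrix")
  if (any(b$radius <= 0)) return("bead radii must be positive")
  for (ch in unique(b$chain_id)) {
    s <- b[b$chain_id == ch, , drop = FALSE]
    if (any(diff(s$first) <= 0) || any(s$first[-1] != s$last[-nrow(s)] + 1L))
      return(sprintf("chain %s: beads must cover contiguous non-overlapping ranges in order", ch))
    if (any(s$nres != s$last - s$first + 1L))
      return(sprintf("chain %s: nres inconsistent with residue range", ch))
  }
  TRUE
})

#' Chemical crosslink dataset
#'
#' Residue pairs observed to be chemically crosslinked, with the forward
#' model parameters of the Bayesian crosslink restraint: linker length
#' \code{d0}, false-positive weight \code{psi} and structural uncertainty
#' \code{sigma}.  Links are unordered pairs and are stored canonically
#' (smaller (chain, residue) first).
#'
#' @slot links \code{data.frame} with columns \code{chain1}, \code{residue1},
#'   \code{chain2}, \code{residue2}.
#' @slot d0 numeric linker length (angstroms, > 0).
#' @slot psi numeric false-positive weight in [0, 0.5).
#' @slot sigma numeric structural uncertainty (angstroms, > 0); absorbs,
#'   among other things, the positional uncertainty introduced by
#'   coarse-graining.
#' @export
setClass("CrosslinkDataset",
  representation(links = "data.frame", d0 = "numeric", psi = "numeric",
                 sigma = "numeric"))

setValidity("CrosslinkDataset", function(object) {
  l <- object@links
  need <- c("chain1", "residue1", "chain2", "residue2")
  if (!all(need %in% names(l)))
    return(paste("links must have columns", paste(need, collapse = ", ")))
  if (object@d0 <= 0) return("d0 must be > 0")
  if (object@psi < 0 || object@psi >= 0.5) return("psi must lie in [0, 0.5)")
  if (object@sigma <= 0) return("sigma must be > 0")
  TRUE
})

#' @rdname CrosslinkDataset-class
#' @param links data.frame with columns \code{chain1}, \code{residue1},
#'   \code{chain2}, \code{residue2}.
#' @param d0 linker length in angstroms (default 21, DSS/BS3).
#' @param psi false-positive weight (default 0.05).
#' @param sigma structural uncertainty in angstroms (default 10).
#' @export
CrosslinkDataset <- function(links, d0 = 21, psi = 0.05, sigma = 10) {
  links <- as.data.frame(links)
  links$chain1 <- as.character(links$chain1); links$chain2 <- as.character(links$chain2)
  links$residue1 <- as.integer(links$residue1); links$residue2 <- as.integer(links$residue2)
  if (nrow(links)) {
    flip <- links$chain1 > links$chain2 |
      (links$chain1 == links$chain2 & links$residue1 > links$residue2)
    if (any(flip)) {
      tmp <- links[flip, c("chain2", "residue2")]
      links[flip, c("chain2", "residue2")] <- links[flip, c("chain1", "residue1")]
      links[flip, c("chain1", "residue1")] <- tmp
    }
    rownames(links) <- NULL
  }
  new("CrosslinkDataset", links = links, d0 = d0, psi = psi, sigma = sigma)
}

#' Gaussian mixture density
#'
#' An experimental density map approximated as a 3-D Gaussian mixture, as
#' used for low-resolution EM restraints.  Weights are normalized to sum to
#' one; covariances must be symmetric positive definite.
#'
#' @slot weights numeric component weights (sum to 1).
#' @slot means numeric matrix (K x 3) of component means (angstroms).
#' @slot covariances list of K symmetric positive-definite 3x3 covariance
#'   matrices (angstrom^2).
#' @export
setClass("GMMDensity",
  representation(weights = "numeric", means = "matrix", covariances = "list"))

setValidity("GMMDensity", function(object) {
  k <- length(object@weights)
  if (k < 1L) return("density needs at least one component")
  if (nrow(object@means) != k || ncol(object@means) != 3L)
    return("means must be K x 3")
  if (length(object@covariances) != k) return("one covariance per component")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  for (C in object@covariances) {
    if (!is.matrix(C) || any(dim(C) != 3L)) return("covariances must be 3x3")
    if (max(abs(C - t(C))) > 1e-8) return("covariances must be symmetric")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return("covariances must be positive definite")
  }
  TRUE
})

#' @rdname GMMDensity-class
#' @param weights non-negative component weights (normalized internally).
#' @param means K x 3 matrix of component means.
#' @param covariances list of 3x3 covariance matrices.
#' @export
GMMDensity <- function(weights, means, covariances) {
  means <- as.matrix(means)
  if (is.null(dim(means))) means <- matrix(means, ncol = 3)
  w <- as.numeric(weights)
  if (sum(w) > 0) w <- w / sum(w)
  new("GMMDensity", weights = w, means = means, covariances = covariances)
}

#' Posterior repartitioning of the restraint set
#'
#' Nested sampling is inaccurate when the prior is dissimilar to the
#' posterior.  The restraint set is therefore repartitioned: the modified
#' prior comprises the stereochemistry restraints plus a random subset of
#' the crosslinks (e.g. 30 percent), while the remaining crosslinks and the
#' optional density restraint form the likelihood.  The product
#' prior x likelihood, and hence the posterior and the evidence, is
#' unchanged by the split.
#'
#' @slot links the full \linkS4class{CrosslinkDataset}.
#' @slot priorIdx integer indices of links assigned to the prior subset.
#' @slot useEM logical; when \code{TRUE} the density restraint contributes
#'   to the likelihood.
#' @slot density optional \linkS4class{GMMDensity}.
#' @slot emWeight numeric weight of the density log-score.
#' @slot fraction numeric fraction of links assigned to the prior.
#' @slot seed integer seed used for the random split.
#' @seealso [partitionRestraints()], [modifiedLogPrior()], [logLikelihood()]
#' @export
setClass("RestraintPartition",
  representation(links = "CrosslinkDataset", priorIdx = "integer",
                 useEM = "logical", density = "ANY",
                 emWeight = "numeric", fraction = "numeric", seed = "integer"))

setValidity("RestraintPartition", function(object) {
  n <- nrow(object@links@links)
  idx <- object@priorIdx
  if (anyDuplicated(idx)) return("priorIdx must be unique")
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    return("priorIdx out of range")
  if (!is.null(object@density) && !is(object@density, "GMMDensity"))
    return("density must be a GMMDensity or NULL")
  if (object@useEM && is.null(object@density))
    return("useEM = TRUE requires a density")
  TRUE
})

#' Replica-exchange move set
#'
#' Monte Carlo movers and replica-exchange settings used to sample bead
#' models from the modified prior.
#'
#' @slot flexStep maximum displacement of a flexible bead (angstroms).
#' @slot rigidTranslateStep maximum rigid-body translation (angstroms).
#' @slot rigidRotateStep maximum rigid-body rotation (radians).
#' @slot nReplicas number of replicas.
#' @slot ladder temperature ladder (ascending, starts at 1).
#' @slot swapInterval steps between replica-swap attempts.
#' @slot thinInterval steps between cold-replica snapshots.
#' @export
setClass("MoveSet",
  representation(flexStep = "numeric", rigidTranslateStep = "numeric",
                 rigidRotateStep = "numeric", nReplicas = "integer",
                 ladder = "numeric", swapInterval = "integer",
                 thinInterval = "integer"))

setValidity("MoveSet", function(object) {
  if (object@flexStep < 0 || object@rigidTranslateStep < 0 ||
      object@rigidRotateStep < 0) return("step sizes must be non-negative")
  lad <- object@ladder
  if (length(lad) != object@nReplicas) return("ladder length must equal nReplicas")
  if (abs(lad[1] - 1) > 1e-12 || is.unsorted(lad))
    return("ladder must be ascending and start at 1.0")
  if (object@swapInterval < 1L || object@thinInterval < 1L)
    return("intervals must be >= 1")
  TRUE
})

#' @rdname MoveSet-class
#' @param flexStep maximum flexible-bead displacement in angstroms.
#' @param rigidTranslateStep maximum rigid-body translation in angstroms.
#' @param rigidRotateStep maximum rigid-body rotation in radians.
#' @param nReplicas number of replicas.
#' @param maxTemperature hottest replica temperature; the ladder is
#'   geometric from 1 to this value.
#' @param swapInterval steps between swap attempts.
#' @param thinInterval steps between snapshots.
#' @export
MoveSet <- function(flexStep = 4, rigidTranslateStep = 2, rigidRotateStep = 0.2,
                    nReplicas = 4, maxTemperature = 2.5, swapInterval = 10,
                    thinInterval = 10) {
  nReplicas <- as.integer(nReplicas)
  ladder <- if (nReplicas == 1L) 1
            else maxTemperature^((seq_len(nReplicas) - 1) / (nReplicas - 1))
  new("MoveSet", flexStep = flexStep, rigidTranslateStep = rigidTranslateStep,
      rigidRotateStep = rigidRotateStep, nReplicas = nReplicas, ladder = ladder,
      swapInterval = as.integer(swapInterval), thinInterval = as.integer(thinInterval))
}

#' One batch of replica-exchange MCMC samples
#'
#' @slot models list of bead-coordinate snapshots (nBeads x 3 matrices) from
#'   the cold replica.
#' @slot logPriors modified-prior log-probabilities of the snapshots.
#' @slot logLikelihoods log-likelihoods of the snapshots.
#' @slot perStepTime mean wall-clock seconds per MCMC step (over all
#'   replicas).
#' @export
setClass("SampleBatch",
  representation(models = "list", logPriors = "numeric",
                 logLikelihoods = "numeric", perStepTime = "numeric"))

setValidity("SampleBatch", function(object) {
  n <- length(object@models)
  if (length(object@logPriors) != n || length(object@logLikelihoods) != n)
    return("models, logPriors and logLikelihoods must have equal length")
  if (object@perStepTime <= 0) return("perStepTime must be positive")
  TRUE
})

#' Result of one nested-sampling run
#'
#' @slot logZ estimated log model evidence.
#' @slot termination one of \code{"failure_limit"}, \code{"plateau_limit"},
#'   \code{"max_iterations"}.
#' @slot iterations number of dead points accumulated.
#' @slot perStepTime mean wall-clock seconds per MCMC step.
#' @slot processTime total wall-clock seconds for the run.
#' @slot trace \code{data.frame} with one row per dead point: columns
#'   \code{iteration}, \code{logL}, \code{logX}, \code{logZ} (running).
#' @slot nLive number of live points.
#' @slot scheme representation scheme label (empty for analytic problems).
#' @slot seed seed the run was launched with.
#' @export
setClass("NSRunResult",
  representation(logZ = "numeric", termination = "character",
                 iterations = "integer", perStepTime = "numeric",
                 processTime = "numeric", trace = "data.frame",
                 nLive = "integer", scheme = "character", seed = "integer"))

setValidity("NSRunResult", function(object) {
  if (!object@termination %in% c("failure_limit", "plateau_limit", "max_iterations"))
    return("unknown termination reason")
  if (!is.finite(object@logZ)) return("logZ must be finite")
  if (is.unsorted(object@trace$logL)) return("dead-point logL trace must be non-decreasing")
  TRUE
})

#' Collated evidence estimate for one representation
#'
#' @slot scheme representation scheme label.
#' @slot meanLogZ mean log evidence across runs.
#' @slot semLogZ standard error of the mean log evidence.
#' @slot nRuns number of runs collated.
#' @slot meanPerStepTime mean per-step MCMC sampling time (seconds).
#' @slot logZs per-run log evidences.
#' @export
setClass("EvidenceEstimate",
  representation(scheme = "character", meanLogZ = "numeric", semLogZ = "numeric",
                 nRuns = "integer", meanPerStepTime = "numeric", logZs = "numeric"))

setValidity("EvidenceEstimate", function(object) {
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  if (object@semLogZ < 0) return("semLogZ must be >= 0")
  TRUE
})

#' Synthetic assembly with known ground truth
#'
#' @slot topology the \linkS4class{ChainTopology} of the assembly (with
#'   reference coordinates attached).
#' @slot coords named list of per-chain C-alpha coordinate matrices
#'   (length x 3, angstroms).
#' @slot compactness per-chain compactness in [0, 1] used for generation
#'   (0 = extended coil, 1 = collapsed globule).
#' @export
setClass("SyntheticAssembly",
  representation(topology = "ChainTopology", coords = "list",
                 compactness = "numeric"))

setValidity("SyntheticAssembly", function(object) {
  if (length(object@coords) != length(object@compactness))
    return("one compactness value per chain")
  for (x in object@coords) {
    d <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2))
    if (any(d < 2.0 - 1e-9 | d > 4.5 + 1e-9))
      return("consecutive C-alpha distances must lie in [2.0, 4.5] angstroms")
  }
  TRUE
})
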