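# Accessor generics and show methods for the core classes.

#' @describeIn ChainTopology-class named integer vector of chain lengths.
#' @param topology a \linkS4class{ChainTopology}.
#' @export
chainLengths <- function(topology) {
  seg <- topology@segments
  vapply(split(seg$end, seg$chain_id)[unique(seg$chain_id)], max, integer(1))
}

#' @describeIn ChainTopology-class the segment table.
#' @export
segments <- function(topology) topology@segments

#' Number of beads in a model
#' @param model a \linkS4class{BeadModel}.
#' @export
nBeads <- function(model) nrow(model@beads)

#' Bead metadata table
#' @param model a \linkS4class{BeadModel}.
#' @return \code{data.frame} of bead residue ranges, radii and rigid-body ids.
#' @export
beadTable <- function(model) model@beads

#' Bead center coordinates
#' @param model a \linkS4class{BeadModel}.
#' @return numeric matrix (nBeads x 3), angstroms.
#' @export
beadCoords <- function(model) model@coords

#' Replace bead center coordinates
#' @param model a \linkS4class{BeadModel}.
#' @param value numeric matrix (nBeads x 3).
#' @export
`beadCoords<-` <- function(model, value) {
  model@coords <- value
  validObject(model)
  model
}

#' Number of flexible beads (not in any rigid body)
#' @param model a \linkS4class{BeadModel}.
#' @export
nFlexible <- function(model) sum(is.na(model@beads$rigid_body))

#' Number of rigid bodies
#' @param model a \linkS4class{BeadModel}.
#' @export
nRigidBodies <- function(model) length(unique(stats::na.omit(model@beads$rigid_body)))

#' Number of crosslinks in a dataset
#' @param links a \linkS4class{CrosslinkDataset}.
#' @export
nLinks <- function(links) nrow(links@links)

#' Crosslink table
#' @param links a \linkS4class{CrosslinkDataset}.
#' @export
linkTable <- function(links) links@links

#' Prior-side crosslink subset of a partition
#' @param partition a \linkS4class{RestraintPartition}.
#' @return a \linkS4class{CrosslinkDataset}.
#' @export
priorLinks <- function(partition) {
  d <- partition@links
  CrosslinkDataset(d@links[partition@priorIdx, , drop = FALSE],
                   d0 = d@d0, psi = d@psi, sigma = d@sigma)
}

#' Likelihood-side crosslink subset of a partition
#' @param partition a \linkS4class{RestraintPartition}.
#' @return a \linkS4class{CrosslinkDataset}.
#' @export
likelihoodLinks <- function(partition) {
  d <- partition@links
  keep <- setdiff(seq_len(nrow(d@links)), partition@priorIdx)
  CrosslinkDataset(d@links[keep, , drop = FALSE],
                   d0 = d@d0, psi = d@psi, sigma = d@sigma)
}

#' Log evidence of a run
#' @param x an \linkS4class{NSRunResult}.
#' @export
logZ <- function(x) x@logZ

#' Dead-point trace of a run
#' @param x an \linkS4class{NSRunResult}.
#' @return \code{data.frame} with columns \code{iteration}, \code{logL},
#'   \code{logX}, \code{logZ}.
#' @export
nsTrace <- function(x) x@trace

setMethod("show", "ChainTopology", function(object) {
  seg <- object@segments
  cat(sprintf("ChainTopology: %d chain(s), %d segment(s), %d residues\n",
              length(unique(seg$chain_id)), nrow(seg),
              sum(chainLengths(object))))
  cat(sprintf("  structured segments: %d (rigid bodies: %d); reference: %s\n",
              sum(seg$kind == "structured"),
              length(unique(stats::na.omit(seg$rigid_body))),
              if (length(object@reference)) "attached" else "none"))
})

setMethod("show", "RepresentationScheme", function(object) {
  cat(sprintf("RepresentationScheme '%s': %s residues per bead\n", object@label,
              paste(object@residuesPerBead, collapse = "/")))
})

setMethod("show", "BeadModel", function(object) {
  cat(sprintf("BeadModel (scheme '%s'): %d beads (%d flexible, %d rigid bodies)\n",
              object@scheme, nBeads(object), nFlexible(object), nRigidBodies(object)))
  cat(sprintf("  free-parameter bound 3n+6m = %d\n", countFreeParameters(object)))
})

setMethod("show", "CrosslinkDataset", function(object) {
  cat(sprintf("CrosslinkDataset: %d links (d0 = %g A, psi = %g, sigma = %g A)\n",
              nrow(object@links), object@d0, object@psi, object@sigma))
})

setMethod("show", "GMMDensity", function(object) {
  cat(sprintf("GMMDensity: %d components\n", length(object@weights)))
})

setMethod("show", "RestraintPartition", function(object) {
  n <- nrow(object@links@links)
  cat(sprintf("RestraintPartition: %d/%d links in prior, %d in likelihood; EM in likelihood: %s\n",
              length(object@priorIdx), n, n - length(object@priorIdx),
              if (object@useEM) "yes" else "no"))
})

setMethod("show", "NSRunResult", function(object) {
  cat(sprintf("NSRunResult: logZ = %.3f after %d iterations (%s)\n",
              object@logZ, object@iterations, object@termination))
  cat(sprintf("  per-step time %.2e s, total %.2f s, %d live points\n",
              object@perStepTime, object@processTime, object@nLive))
})

setMethod("show", "EvidenceEstimate", function(object) {
  cat(sprintf("EvidenceEstimate '%s': logZ = %.3f +/- %.3f (n = %d), %.2e s/step\n",
              object@scheme, object@meanLogZ, object@semLogZ, object@nRuns,
              object@meanPerStepTime))
})

setMethod("show", "SyntheticAssembly", function(object) {
  cat(sprintf("SyntheticAssembly: %d chain(s), %d residues\n",
              length(object@coords), sum(vapply(object@coords, nrow, integer(1)))))
})
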