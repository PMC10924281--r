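# Coarse-graining: topology + scheme -> bead model.

#' Bead radius from residue count
#'
#' Radius of a spherical bead representing \code{nResidues} contiguous
#' residues, from the volume of a sphere holding \code{nResidues} times the
#' mean per-residue volume: \eqn{r = (3 n V_{res} / 4\pi)^{1/3}}.
#'
#' @param nResidues number of residues in the bead (>= 1).
#' @param residueVolume mean per-residue volume in cubic angstroms
#'   (default 130).
#' @return radius in angstroms; strictly increasing in \code{nResidues}.
#' @examples
#' beadRadius(1)   # ~3.14 A
#' beadRadius(8) / beadRadius(1)  # exactly 2
#' @export
beadRadius <- function(nResidues, residueVolume = 130) {
  if (any(nResidues < 1)) stop("nResidues must be >= 1")
  (3 * nResidues * residueVolume / (4 * pi))^(1 / 3)
}

#' Coarse-grain a topology into a bead model
#'
#' Each topology segment is partitioned into consecutive beads of exactly
#' \code{residuesPerBead} residues; leftover residues at the segment end
#' form a smaller final bead.  Beads from structured segments inherit the
#' segment's rigid-body id and are centered at the centroid of their
#' residues' reference C-alpha coordinates when a reference is attached;
#' beads without reference coordinates are given provisional random
#' placements (see [randomizeModel()] for sampling-ready initialization).
#'
#' @param topology a \linkS4class{ChainTopology}.
#' @param scheme a \linkS4class{RepresentationScheme}, or a number
#'   (interpreted as a uniform scheme).
#' @return a \linkS4class{BeadModel}.
#' @examples
#' top <- ChainTopology(data.frame(
#'   chain_id = "A", start = 1, end = 101, kind = "unstructured"))
#' nBeads(coarseGrain(top, 50))  # 3 beads: 1-50, 51-100, 101-101
#' @export
coarseGrain <- function(topology, scheme) {
  stopifnot(is(topology, "ChainTopology"))
  if (!is(scheme, "RepresentationScheme")) scheme <- RepresentationScheme(scheme)
  validObject(topology); validObject(scheme)
  seg <- topology@segments
  rpb <- scheme@residuesPerBead
  if (length(rpb) == 1L) rpb <- rep(rpb, nrow(seg))
  if (length(rpb) != nrow(seg))
    stop("mixed scheme must provide one residuesPerBead value per topology segment (",
         nrow(seg), " segments, got ", length(rpb), ")")

  rows <- vector("list", nrow(seg))
  for (s in seq_len(nrow(seg))) {
    first <- seq.int(seg$start[s], seg$end[s], by = rpb[s])
    last <- pmin(first + rpb[s] - 1L, seg$end[s])
    rows[[s]] <- data.frame(
      chain_id = seg$chain_id[s], first = as.integer(first),
      last = as.integer(last), nres = as.integer(last - first + 1L),
      radius = beadRadius(last - first + 1L),
      rigid_body = seg$rigid_body[s], stringsAsFactors = FALSE)
  }
  beads <- do.call(rbind, rows)
  ord <- order(match(beads$chain_id, unique(seg$chain_id)), beads$first)
  beads <- beads[ord, , drop = FALSE]
  rownames(beads) <- NULL

  coords <- matrix(NA_real_, nrow(beads), 3)
  ref <- topology@reference
  for (i in seq_len(nrow(beads))) {
    ch <- beads$chain_id[i]
    if (!is.na(beads$rigid_body[i]) && ch %in% names(ref)) {
      coords[i, ] <- colMeans(ref[[ch]][beads$first[i]:beads$last[i], , drop = FALSE])
    }
  }
  # provisional placement for beads without reference coordinates:
  # continue from the previous bead of the chain at touching distance
  for (i in seq_len(nrow(beads))) {
    if (!anyNA(coords[i, ])) next
    prev <- if (i > 1L && beads$chain_id[i - 1L] == beads$chain_id[i]) coords[i - 1L, ] else NULL
    if (is.null(prev) || anyNA(prev)) {
      coords[i, ] <- runifBall(10)
    } else {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      coords[i, ] <- prev + u * (beads$radius[i] +
        if (i > 1L) beads$radius[i - 1L] else 0)
    }
  }
  # second pass for chains whose first beads were placed before a later
  # reference bead existed is unnecessary: placement only looks backwards
  new("BeadModel", beads = beads, coords = coords, scheme = scheme@label)
}

#' Upper bound on the number of free parameters
#'
#' Returns \eqn{3n + 6m} where \eqn{n} is the number of flexible beads
#' (three translational degrees of freedom each) and \eqn{m} the number of
#' rigid bodies (six degrees of freedom each).  The number of live points
#' used for nested sampling should ideally be at least this bound.
#'
#' @param model a \linkS4class{BeadModel}.
#' @return integer parameter count.
#' @export
countFreeParameters <- function(model) {
  3L * nFlexible(model) + 6L * nRigidBodies(model)
}

#' Randomize bead model coordinates
#'
#' Draws a fresh configuration: each rigid body is randomly rotated about
#' its centroid and its centroid placed uniformly in the central half of
#' the bounding box; flexible beads are re-grown as a random walk from the
#' previous bead of their chain at touching distance.
#'
#' @param model a \linkS4class{BeadModel}.
#' @param boxHalfSide half-side of the bounding box (angstroms).
#' @param seed optional integer seed; when given the result is
#'   deterministic.
#' @return a \linkS4class{BeadModel} with new coordinates.
#' @export
randomizeModel <- function(model, boxHalfSide = 300, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, randomizeModel(model, boxHalfSide)))
  b <- model@beads
  X <- model@coords
  half <- boxHalfSide / 2
  for (rb in unique(stats::na.omit(b$rigid_body))) {
    idx <- which(!is.na(b$rigid_body) & b$rigid_body == rb)
    ctr <- colMeans(X[idx, , drop = FALSE])
    R <- rotationMatrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
    target <- stats::runif(3, -half, half)
    X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2, ctr) %*% t(R), 2, target, "+")
  }
  # grow each contiguous flexible run from an already-placed neighbour
  # (forward from the previous bead, else backward from the next one)
  flex <- is.na(b$rigid_body)
  done <- !flex
  grow <- function(i, from) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    pmin(pmax(X[from, ] + u * (b$radius[i] + b$radius[from]),
              -boxHalfSide), boxHalfSide)
  }
  for (i in seq_len(nrow(b))) {
    if (done[i]) next
    prv <- i > 1L && b$chain_id[i - 1L] == b$chain_id[i] && done[i - 1L]
    if (prv) { X[i, ] <- grow(i, i - 1L); done[i] <- TRUE; next }
    # leading flexible run: find the next placed bead of this chain and
    # grow the run backwards from it, else start from a random point
    j <- i
    while (j < nrow(b) && b$chain_id[j + 1L] == b$chain_id[i] && !done[j + 1L])
      j <- j + 1L
    anchor <- j < nrow(b) && b$chain_id[min(j + 1L, nrow(b))] == b$chain_id[i] && done[min(j + 1L, nrow(b))]
    if (anchor) {
      for (k in seq.int(j, i)) {
        X[k, ] <- grow(k, k + 1L); done[k] <- TRUE
      }
    } else {
      X[i, ] <- stats::runif(3, -half, half); done[i] <- TRUE
    }
  }
  model@coords <- X
  model
}
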