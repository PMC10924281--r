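# Readers and writers for the plain-text input and output formats.

.parseStop <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' Read a topology file
#'
#' Tab-separated with header; columns \code{chain_id}, \code{start},
#' \code{end}, \code{kind} (\code{structured}|\code{unstructured}),
#' \code{rigid_body} (integer or \code{"-"}) and optionally
#' \code{pdb_chain}.
#'
#' @param path file path.
#' @return a \linkS4class{ChainTopology} (without reference coordinates;
#'   see [attachReference()]).
#' @export
readTopology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chain_id", "start", "end", "kind", "rigid_body")
  if (!all(need %in% names(raw)))
    .parseStop(path, 1L, paste("header must contain", paste(need, collapse = ", ")))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      .parseStop(path, bad[1L] + 1L, sprintf("column '%s' must be an integer", col))
    raw[[col]] <- v
  }
  bad <- which(!raw$kind %in% c("structured", "unstructured"))
  if (length(bad))
    .parseStop(path, bad[1L] + 1L, "kind must be 'structured' or 'unstructured'")
  rb <- ifelse(raw$rigid_body == "-", NA_character_, raw$rigid_body)
  rbi <- suppressWarnings(as.integer(rb))
  bad <- which(!is.na(rb) & is.na(rbi))
  if (length(bad))
    .parseStop(path, bad[1L] + 1L, "rigid_body must be an integer or '-'")
  raw$rigid_body <- rbi
  if (is.null(raw$pdb_chain)) raw$pdb_chain <- NA_character_
  raw$pdb_chain[raw$pdb_chain == "-"] <- NA_character_
  ChainTopology(raw)
}

#' @describeIn readTopology write a topology file.
#' @param topology a \linkS4class{ChainTopology}.
#' @export
writeTopology <- function(topology, path) {
  seg <- topology@segments
  out <- seg[, c("chain_id", "start", "end", "kind", "rigid_body", "pdb_chain")]
  out$rigid_body <- ifelse(is.na(out$rigid_body), "-", as.character(out$rigid_body))
  out$pdb_chain <- ifelse(is.na(out$pdb_chain), "-", out$pdb_chain)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Reads only the CA atoms of the requested chains.
#'
#' @param path PDB file path.
#' @param chains chain identifiers to read; default all.
#' @return named list (by chain) of coordinate matrices indexed by residue
#'   number (rows without a CA atom are \code{NA}).
#' @export
readPdbCa <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (is.null(chains)) chains <- unique(ca$chain)
  out <- list()
  for (ch in chains) {
    s <- ca[ca$chain == ch, , drop = FALSE]
    if (nrow(s) == 0L) stop("no CA atoms for chain ", ch, " in ", path)
    m <- matrix(NA_real_, max(s$resno), 3)
    m[s$resno, ] <- as.matrix(s[, c("x", "y", "z")])
    out[[ch]] <- m
  }
  out
}

#' @describeIn readPdbCa write per-chain C-alpha coordinates as a PDB file.
#' @param coords named list of per-chain coordinate matrices.
#' @export
writePdbCa <- function(coords, path) {
  n <- sum(vapply(coords, nrow, integer(1)))
  xyz <- unlist(lapply(coords, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = unlist(lapply(coords, function(m) seq_len(nrow(m)))),
                   chain = rep(names(coords), vapply(coords, nrow, integer(1))),
                   resid = rep("ALA", n), elety = rep("CA", n),
                   eleno = seq_len(n))
  invisible(path)
}

#' Attach reference coordinates to a topology
#'
#' Validates that every structured residue has a reference C-alpha
#' coordinate; missing residues are a hard error listing the offenders.
#' Topology chains are matched to coordinate chains through the
#' \code{pdb_chain} column when set, otherwise by chain id.
#'
#' @param topology a \linkS4class{ChainTopology}.
#' @param coords named list of per-residue coordinate matrices, e.g. from
#'   [readPdbCa()].
#' @return the topology with reference coordinates attached.
#' @export
attachReference <- function(topology, coords) {
  seg <- topology@segments
  ref <- list()
  for (ch in unique(seg$chain_id)) {
    s <- seg[seg$chain_id == ch, , drop = FALSE]
    src <- s$pdb_chain[!is.na(s$pdb_chain)][1]
    if (is.na(src) || is.null(src)) src <- ch
    str <- s[s$kind == "structured", , drop = FALSE]
    if (nrow(str) == 0L) next
    if (!src %in% names(coords))
      stop("no reference coordinates for chain ", ch, " (PDB chain ", src, ")")
    m <- coords[[src]]
    want <- unlist(Map(seq.int, str$start, str$end))
    bad <- vapply(want, function(rr) rr > nrow(m) || anyNA(m[rr, ]), logical(1))
    missing <- want[bad]
    if (length(missing))
      stop(sprintf("chain %s: missing reference CA coordinates for structured residues %s",
                   ch, paste(missing, collapse = ", ")))
    ref[[ch]] <- m
  }
  topology@reference <- ref
  topology
}

#' Read a crosslink CSV file
#'
#' Comma-separated with header \code{chain1,residue1,chain2,residue2}
#' and an optional \code{linker} column mapped to a linker length through
#' \code{linkerTable}.
#'
#' @param path file path.
#' @param linkerTable named vector of linker lengths in angstroms.
#' @param d0 default linker length when no linker column is present.
#' @param psi,sigma forward-model parameters stored on the dataset.
#' @return a \linkS4class{CrosslinkDataset}.
#' @export
readCrosslinksCsv <- function(path, linkerTable = c(DSS = 21, BS3 = 21),
                              d0 = 21, psi = 0.05, sigma = 10) {
  if (!file.exists(path)) stop("crosslink file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain1", "residue1", "chain2", "residue2")
  if (!all(need %in% names(raw)))
    .parseStop(path, 1L, paste("header must contain", paste(need, collapse = ",")))
  for (col in c("residue1", "residue2")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      .parseStop(path, bad[1L] + 1L, sprintf("column '%s' must be an integer", col))
    raw[[col]] <- v
  }
  if (!is.null(raw$linker) && nrow(raw)) {
    known <- raw$linker %in% names(linkerTable)
    if (any(!known))
      .parseStop(path, which(!known)[1L] + 1L,
                 paste("unknown linker; known:", paste(names(linkerTable), collapse = ", ")))
    d0s <- unique(linkerTable[raw$linker])
    if (length(d0s) > 1L)
      warning("multiple linker lengths in one dataset; using the largest")
    d0 <- max(d0s)
  }
  CrosslinkDataset(raw[, need], d0 = d0, psi = psi, sigma = sigma)
}

#' @describeIn readCrosslinksCsv write a crosslink CSV file.
#' @param links a \linkS4class{CrosslinkDataset}.
#' @export
writeCrosslinksCsv <- function(links, path) {
  utils::write.csv(linkTable(links), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Gaussian-mixture text file
#'
#' One component per line in the pipe-separated dialect
#' \code{index|weight|mx my mz|c11 c12 c13 c22 c23 c33} (covariance as six
#' upper-triangle values); lines starting with \code{#} are comments.
#'
#' @param path file path.
#' @return a \linkS4class{GMMDensity}.
#' @export
readGmmText <- function(path) {
  if (!file.exists(path)) stop("GMM file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop(path, ": no components found")
  w <- numeric(0); means <- NULL; covs <- list()
  for (ln in keep) {
    parts <- strsplit(lines[ln], "|", fixed = TRUE)[[1]]
    if (length(parts) != 4L)
      .parseStop(path, ln, "expected 'index|weight|mean(3)|covariance(6)'")
    wt <- suppressWarnings(as.numeric(parts[2]))
    mu <- suppressWarnings(as.numeric(strsplit(trimws(parts[3]), "\\s+")[[1]]))
    cv <- suppressWarnings(as.numeric(strsplit(trimws(parts[4]), "\\s+")[[1]]))
    if (is.na(wt) || length(mu) != 3L || anyNA(mu) || length(cv) != 6L || anyNA(cv))
      .parseStop(path, ln, "expected 'index|weight|mean(3)|covariance(6 upper-triangle)'")
    C <- matrix(c(cv[1], cv[2], cv[3],
                  cv[2], cv[4], cv[5],
                  cv[3], cv[5], cv[6]), 3, 3)
    w <- c(w, wt); means <- rbind(means, mu); covs <- c(covs, list(C))
  }
  GMMDensity(w, means, covs)
}

#' @describeIn readGmmText write a Gaussian-mixture text file.
#' @param density a \linkS4class{GMMDensity}.
#' @export
writeGmmText <- function(density, path) {
  lines <- vapply(seq_along(density@weights), function(j) {
    C <- density@covariances[[j]]
    sprintf("%d|%.10g|%s|%s", j - 1L, density@weights[j],
            paste(sprintf("%.10g", density@means[j, ]), collapse = " "),
            paste(sprintf("%.10g", c(C[1, 1], C[1, 2], C[1, 3],
                                     C[2, 2], C[2, 3], C[3, 3])), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-scheme results as JSON
#'
#' @param selection selection table from [selectOptimal()].
#' @param path output path.
#' @export
writeResultsJson <- function(selection, path) {
  recs <- lapply(seq_len(nrow(selection)), function(i) list(
    mean_logZ = selection$meanLogZ[i], sem_logZ = selection$semLogZ[i],
    n_runs = selection$nRuns[i], mean_per_step_time = selection$meanPerStepTime[i],
    top_evidence = selection$topEvidence[i], optimal = selection$optimal[i]))
  names(recs) <- selection$scheme
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the dead-point trace of a run as TSV
#'
#' Columns \code{iteration}, \code{logL}, \code{logX}, \code{logZ}; the
#' L-vs-X curve of the run.
#'
#' @param result an \linkS4class{NSRunResult}.
#' @param path output path.
#' @export
writeTraceTsv <- function(result, path) {
  utils::write.table(nsTrace(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a YAML workflow configuration
#'
#' @param path YAML file path.
#' @return named list of configuration values (see [runWorkflow()]).
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
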