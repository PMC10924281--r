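# Orchestration: parallel per-representation runs, relaunch of failed
# runs, collation, selection and reporting.

.configDefaults <- function() list(
  topology = NULL, pdb = NULL, crosslinks = NULL, density = NULL,
  schemes = c(1, 5, 10, 20, 30, 50), mixedSchemes = NULL,
  nRuns = 5, nLive = 50, nSteps = 50,
  maxFailures = 4, maxPlateau = 20, maxIterations = 10000,
  fraction = 0.3, partitionSeed = 1, psi = 0.05, sigma = 10, d0 = 21,
  emWeight = 1, useEM = NULL,
  flexStep = 4, rigidTranslateStep = 2, rigidRotateStep = 0.2,
  nReplicas = 4, maxTemperature = 2.5, swapInterval = 10, thinInterval = 10,
  kBond = 1, kEV = 1, slack = 2, boxHalfSide = 300,
  integration = "trapezoid", fold = 3, semMultiplier = 1,
  seed = 1, threads = 1, retries = 2, outputDir = NULL, plot = TRUE)

.mergeConfig <- function(config, dots) {
  cfg <- .configDefaults()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  unknown <- setdiff(c(names(config), names(dots)), names(.configDefaults()))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

.loadInputs <- function(cfg) {
  for (key in c("topology", "crosslinks", "pdb", "density")) {
    v <- cfg[[key]]
    if (is.character(v) && !file.exists(v))
      stop(sprintf("config: %s file does not exist: %s", key, v))
  }
  if (is.null(cfg$topology)) stop("config: topology is required")
  if (is.null(cfg$crosslinks)) stop("config: crosslinks are required")
  topology <- if (is.character(cfg$topology)) readTopology(cfg$topology) else cfg$topology
  if (!is.null(cfg$pdb)) {
    src <- if (is.character(cfg$pdb)) readPdbCa(cfg$pdb) else cfg$pdb
    topology <- attachReference(topology, src)
  } else if (any(topology@segments$kind == "structured") &&
             !length(topology@reference)) {
    stop("topology has structured segments but no reference coordinates; provide a PDB")
  }
  links <- if (is.character(cfg$crosslinks))
    readCrosslinksCsv(cfg$crosslinks, d0 = cfg$d0, psi = cfg$psi, sigma = cfg$sigma)
  else cfg$crosslinks
  density <- if (is.character(cfg$density)) readGmmText(cfg$density) else cfg$density
  # fail fast on links that reference nothing in the topology
  lens <- chainLengths(topology)
  tab <- linkTable(links)
  for (k in seq_len(nrow(tab))) {
    for (side in 1:2) {
      ch <- tab[[paste0("chain", side)]][k]
      res <- tab[[paste0("residue", side)]][k]
      if (!ch %in% names(lens))
        stop(sprintf("crosslink %d references chain '%s' absent from the topology", k, ch))
      if (res < 1L || res > lens[[ch]])
        stop(sprintf("crosslink %d references residue %s:%d outside the chain (length %d)",
                     k, ch, res, lens[[ch]]))
    }
  }
  if (nrow(tab) == 0L)
    warning("empty crosslink set: the modified prior is stereochemistry only")
  list(topology = topology, links = links, density = density)
}

.configSchemes <- function(cfg, topology) {
  schemes <- lapply(cfg$schemes, function(s)
    if (is(s, "RepresentationScheme")) s else RepresentationScheme(s))
  if (!is.null(cfg$mixedSchemes))
    schemes <- c(schemes, lapply(cfg$mixedSchemes, function(m)
      RepresentationScheme(m$residuesPerBead, label = m$label %||% "mixed")))
  schemes
}

#' Run the full representation-selection workflow
#'
#' For every candidate scheme, launches \code{nRuns} independent
#' nested-sampling runs (in parallel over at most \code{threads} workers),
#' relaunches failed runs with fresh seeds up to \code{retries} times,
#' collates evidence estimates, applies the selection rule, and optionally
#' writes a results bundle (JSON, per-run traces, markdown report, plot)
#' to \code{outputDir}.  Per-run seeds are derived deterministically from
#' the master seed, the scheme label and the run index, so results are
#' identical for any thread count.
#'
#' @param config named list of configuration values (e.g. from
#'   [readConfig()]); see Details.
#' @param ... individual configuration overrides (e.g. \code{nRuns = 3}).
#' @details Configuration keys and defaults:
#'   inputs \code{topology}, \code{crosslinks}, \code{pdb}, \code{density}
#'   (file paths or in-memory objects); \code{schemes} (default
#'   \code{c(1, 5, 10, 20, 30, 50)}) plus optional \code{mixedSchemes};
#'   run settings \code{nRuns} (5), \code{nLive} (50), \code{nSteps} (50),
#'   \code{maxFailures} (4), \code{maxPlateau} (20), \code{maxIterations}
#'   (10000); restraint settings \code{fraction} (0.3),
#'   \code{partitionSeed}, \code{psi} (0.05), \code{sigma} (10 A),
#'   \code{d0} (21 A), \code{emWeight} (1), \code{useEM}; mover settings as
#'   in [MoveSet()]; \code{boxHalfSide} (300 A); selection settings
#'   \code{fold} (3), \code{semMultiplier} (1); \code{seed}, \code{threads},
#'   \code{retries} (2), \code{outputDir}.
#' @return list with elements \code{runs} (per-scheme lists of
#'   \linkS4class{NSRunResult}), \code{estimates}, \code{selection} (the
#'   flagged table) and \code{config}.
#' @export
runWorkflow <- function(config = list(), ...) {
  cfg <- .mergeConfig(config, list(...))
  inp <- .loadInputs(cfg)
  schemes <- .configSchemes(cfg, inp$topology)
  if (!length(schemes)) stop("config: no candidate schemes")
  useEM <- cfg$useEM %||% !is.null(inp$density)
  partition <- partitionRestraints(inp$links, fraction = cfg$fraction,
                                   seed = cfg$partitionSeed,
                                   density = inp$density, useEM = useEM,
                                   emWeight = cfg$emWeight)
  moveset <- MoveSet(cfg$flexStep, cfg$rigidTranslateStep, cfg$rigidRotateStep,
                     cfg$nReplicas, cfg$maxTemperature, cfg$swapInterval,
                     cfg$thinInterval)

  jobs <- expand.grid(run = seq_len(cfg$nRuns), si = seq_along(schemes))
  runOne <- function(si, run, attempt) {
    scheme <- schemes[[si]]
    seed <- runSeed(cfg$seed, scheme@label, run + 1000L * attempt)
    tryCatch(
      runNestedSampling(inp$topology, scheme, partition, moveset,
                        nLive = cfg$nLive, nSteps = cfg$nSteps,
                        maxFailures = cfg$maxFailures,
                        maxPlateau = cfg$maxPlateau,
                        maxIterations = cfg$maxIterations, seed = seed,
                        integration = cfg$integration, kBond = cfg$kBond,
                        kEV = cfg$kEV, slack = cfg$slack,
                        boxHalfSide = cfg$boxHalfSide),
      nsRunFailure = function(e) NULL)
  }
  worker <- function(j) {
    for (attempt in 0:cfg$retries) {
      res <- runOne(jobs$si[j], jobs$run[j], attempt)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  results <- if (cfg$threads > 1L) {
    parallel::mclapply(seq_len(nrow(jobs)), worker,
                       mc.cores = cfg$threads, mc.preschedule = FALSE)
  } else lapply(seq_len(nrow(jobs)), worker)

  runsByScheme <- lapply(seq_along(schemes), function(si) {
    rs <- results[jobs$si == si]
    Filter(Negate(is.null), rs)
  })
  labels <- vapply(schemes, function(s) s@label, character(1))
  dead <- labels[vapply(runsByScheme, length, integer(1)) == 0L]
  if (length(dead))
    stop("no successful runs after relaunches for scheme(s): ",
         paste(dead, collapse = ", "), " (partial results discarded)")
  estimates <- Map(collateRuns, runsByScheme, labels)
  selection <- selectOptimal(estimates, fold = cfg$fold,
                             semMultiplier = cfg$semMultiplier)
  bundle <- list(runs = stats::setNames(runsByScheme, labels),
                 estimates = stats::setNames(estimates, labels),
                 selection = selection, config = cfg)
  if (!is.null(cfg$outputDir)) .writeBundle(bundle, cfg$outputDir)
  bundle
}

.writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeResultsJson(bundle$selection, file.path(dir, "results.json"))
  for (lab in names(bundle$runs)) {
    rs <- bundle$runs[[lab]]
    for (k in seq_along(rs))
      writeTraceTsv(rs[[k]], file.path(dir, sprintf("trace_%s_run%d.tsv", lab, k)))
  }
  sel <- bundle$selection
  md <- c("# Representation selection", "",
          sprintf("| scheme | mean logZ | sem | runs | s/step | top evidence | optimal |"),
          "|---|---|---|---|---|---|---|",
          sprintf("| %s | %.3f | %.3f | %d | %.2e | %s | %s |",
                  sel$scheme, sel$meanLogZ, sel$semLogZ, sel$nRuns,
                  sel$meanPerStepTime,
                  ifelse(sel$topEvidence, "yes", "no"),
                  ifelse(sel$optimal, "**yes**", "no")))
  writeLines(md, file.path(dir, "report.md"))
  if (isTRUE(bundle$config$plot) && requireNamespace("ggplot2", quietly = TRUE)) {
    tryCatch({
      p <- plotEvidence(sel)
      ggplot2::ggsave(file.path(dir, "evidence.png"), p,
                      width = 7, height = 4, dpi = 120)
    }, error = function(e) invisible(NULL))
  }
  invisible(dir)
}

#' Plot evidence and per-step sampling time per scheme
#'
#' Evidence (with one-standard-error bars) and per-step sampling time for
#' each candidate representation, side by side.
#'
#' @param selection selection table from [selectOptimal()], or a list of
#'   \linkS4class{EvidenceEstimate} objects.
#' @return a ggplot object.
#' @export
plotEvidence <- function(selection) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotEvidence requires the ggplot2 package")
  if (!is.data.frame(selection)) selection <- selectOptimal(selection)
  df <- selection
  df$scheme <- factor(df$scheme, levels = df$scheme)
  long <- rbind(
    data.frame(scheme = df$scheme, value = df$meanLogZ,
               lo = df$meanLogZ - df$semLogZ, hi = df$meanLogZ + df$semLogZ,
               metric = "mean log evidence", optimal = df$optimal),
    data.frame(scheme = df$scheme, value = df$meanPerStepTime,
               lo = NA_real_, hi = NA_real_,
               metric = "per-step time (s)", optimal = df$optimal))
  ggplot2::ggplot(long, ggplot2::aes(x = scheme, y = value, fill = optimal)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi), width = 0.2,
                           na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#E69F00", `FALSE` = "grey60")) +
    ggplot2::labs(x = "residues per bead", y = NULL, fill = "optimal") +
    ggplot2::theme_minimal()
}
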