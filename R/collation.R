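# Collation of independent runs, Bayes factors, and the
# evidence-plus-efficiency selection rule.

#' Collate independent nested-sampling runs
#'
#' Aggregates runs of one representation into a mean log evidence, its
#' standard error (sample SD over sqrt(n)), and the mean per-step MCMC
#' sampling time.
#'
#' @param results list of \linkS4class{NSRunResult} (>= 1 successful run).
#' @param scheme optional scheme label; defaults to the label carried by
#'   the runs.
#' @return an \linkS4class{EvidenceEstimate}.
#' @export
collateRuns <- function(results, scheme = NULL) {
  if (length(results) == 0L)
    stop("no successful runs to collate; relaunch the failed runs")
  stopifnot(all(vapply(results, is, logical(1), "NSRunResult")))
  lz <- vapply(results, logZ, numeric(1))
  ts <- vapply(results, function(r) r@perStepTime, numeric(1))
  labs <- unique(vapply(results, function(r) r@scheme, character(1)))
  if (is.null(scheme)) scheme <- labs[1L]
  if (length(labs) > 1L)
    warning("collating runs with differing scheme labels: ",
            paste(labs, collapse = ", "))
  n <- length(lz)
  sem <- if (n > 1L) stats::sd(lz) / sqrt(n) else {
    warning("single run: standard error of the evidence is reported as 0")
    0
  }
  new("EvidenceEstimate", scheme = scheme, meanLogZ = mean(lz),
      semLogZ = sem, nRuns = as.integer(n), meanPerStepTime = mean(ts),
      logZs = lz)
}

#' Log Bayes factor between two representations
#'
#' Under equal prior probability of the two representations, the Bayes
#' factor is the evidence ratio \eqn{K = Z_1 / Z_2}; its log is the
#' difference of mean log evidences, with error propagated as
#' \eqn{\sqrt{sem_1^2 + sem_2^2}}.
#'
#' @param est1,est2 \linkS4class{EvidenceEstimate} objects.
#' @return named numeric vector with elements \code{logBF} and \code{se}.
#' @export
bayesFactor <- function(est1, est2) {
  c(logBF = est1@meanLogZ - est2@meanLogZ,
    se = sqrt(est1@semLogZ^2 + est2@semLogZ^2))
}

.estimateTable <- function(estimates) {
  if (is.data.frame(estimates)) {
    need <- c("scheme", "meanLogZ", "semLogZ", "meanPerStepTime")
    stopifnot(all(need %in% names(estimates)))
    df <- estimates
    if (is.null(df$nRuns)) df$nRuns <- NA_integer_
    df[, c("scheme", "meanLogZ", "semLogZ", "nRuns", "meanPerStepTime")]
  } else {
    do.call(rbind, lapply(estimates, function(e) data.frame(
      scheme = e@scheme, meanLogZ = e@meanLogZ, semLogZ = e@semLogZ,
      nRuns = e@nRuns, meanPerStepTime = e@meanPerStepTime,
      stringsAsFactors = FALSE)))
  }
}

#' Select optimal representations
#'
#' Applies the two-criterion selection rule.  First the top-evidence group
#' is formed: every scheme whose evidence interval
#' \code{mean +/- semMultiplier * sem} overlaps the interval of the scheme
#' with the best mean log evidence.  Within that group, a scheme is
#' optimal when its mean per-step sampling time is within \code{fold}
#' times the fastest member of the group.  More than one optimal
#' representation can exist; the full flagged table is returned, ordered
#' by decreasing evidence, then increasing time.
#'
#' @param estimates list of \linkS4class{EvidenceEstimate} objects, or a
#'   data.frame with columns \code{scheme}, \code{meanLogZ},
#'   \code{semLogZ}, \code{meanPerStepTime}.
#' @param fold efficiency band factor (default 3).
#' @param semMultiplier multiplier on the standard error when testing
#'   interval overlap (default 1).
#' @return \code{data.frame} with the estimate columns plus logical flags
#'   \code{topEvidence} and \code{optimal}.
#' @export
selectOptimal <- function(estimates, fold = 3, semMultiplier = 1) {
  df <- .estimateTable(estimates)
  if (nrow(df) < 1L) stop("need at least one estimate")
  lo <- df$meanLogZ - semMultiplier * df$semLogZ
  hi <- df$meanLogZ + semMultiplier * df$semLogZ
  best <- which.max(df$meanLogZ)
  df$topEvidence <- hi >= lo[best] & lo <= hi[best]
  tmin <- min(df$meanPerStepTime[df$topEvidence])
  df$optimal <- df$topEvidence & df$meanPerStepTime <= fold * tmin
  df <- df[order(-df$meanLogZ, df$meanPerStepTime), , drop = FALSE]
  rownames(df) <- NULL
  df
}
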