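# Internal numerical helpers.

# log(sum(exp(x))) without overflow; -Inf for empty/all -Inf input
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logMeanExp <- function(x) logSumExp(x) - log(length(x))

# Deterministic per-run seed derived from (master seed, scheme label, run index).
# Plain LCG-style mixing kept below 2^31 (doubles are exact here).
runSeed <- function(master, label, run) {
  lab <- sum(utf8ToInt(as.character(label)) * seq_len(nchar(as.character(label))))
  h <- (as.double(master) %% 2147483647) * 1103515
  h <- (h + lab * 7919 + as.double(run) * 104729) %% 2147483647
  as.integer(h + 1)
}

# Rodrigues rotation matrix: angle (rad) about unit axis
rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform point in a ball of given radius
runifBall <- function(radius) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  u * radius * stats::runif(1)^(1 / 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
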