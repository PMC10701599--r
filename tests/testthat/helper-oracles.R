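## Independent oracles and small fixture builders shared across tests.

## Exhaustive-path forward log-likelihood: sums over all K^T state paths.
## Model spec mirrored independently: Gaussian emissions centred at the
## two-component mixture log2 ratio, sticky transitions with uniform
## off-diagonal mass, start mass 0.7 on the neutral state.
oracleStartProbs <- function(states, phi) {
  k <- length(states)
  p <- rep(1 / k, k)
  neutral <- which(states == phi)
  if (length(neutral) == 1 && k > 1) {
    p[] <- 0.3 / (k - 1)
    p[neutral] <- 0.7
  }
  p
}

oracleMeans <- function(n, states, phi, floor = -8) {
  num <- n * 2 + (1 - n) * states
  den <- n * 2 + (1 - n) * phi
  ifelse(num > 0, log2(num / den), floor)
}

oraclePaths <- function(k, tt) {
  as.matrix(expand.grid(rep(list(seq_len(k)), tt)))
}

oracleForward <- function(x, n, phi, states, s, sd) {
  k <- length(states)
  tt <- length(x)
  means <- oracleMeans(n, states, phi)
  start <- log(oracleStartProbs(states, phi))
  off <- if (k > 1) (1 - s) / (k - 1) else 0
  logP <- matrix(log(off), k, k)
  diag(logP) <- log(s)
  emis <- vapply(seq_len(k), function(j) dnorm(x, means[j], sd, log = TRUE),
                 numeric(tt))
  emis <- matrix(emis, ncol = k)
  paths <- oraclePaths(k, tt)
  ll <- start[paths[, 1]] + emis[cbind(1L, paths[, 1])]
  if (tt > 1) for (t in 2:tt) {
    ll <- ll + logP[cbind(paths[, t - 1], paths[, t])] +
      emis[cbind(t, paths[, t])]
  }
  m <- max(ll)
  m + log(sum(exp(ll - m)))
}

oracleViterbi <- function(x, n, phi, states, s, sd) {
  k <- length(states)
  tt <- length(x)
  means <- oracleMeans(n, states, phi)
  start <- log(oracleStartProbs(states, phi))
  off <- if (k > 1) (1 - s) / (k - 1) else 0
  logP <- matrix(log(off), k, k)
  diag(logP) <- log(s)
  emis <- vapply(seq_len(k), function(j) dnorm(x, means[j], sd, log = TRUE),
                 numeric(tt))
  emis <- matrix(emis, ncol = k)
  paths <- oraclePaths(k, tt)
  ll <- start[paths[, 1]] + emis[cbind(1L, paths[, 1])]
  if (tt > 1) for (t in 2:tt) {
    ll <- ll + logP[cbind(paths[, t - 1], paths[, t])] +
      emis[cbind(t, paths[, t])]
  }
  paths[which.max(ll), ]
}

## O(K^2) pairwise mean-absolute-difference Gini.
oracleGini <- function(p) {
  k <- length(p)
  sum(abs(outer(p, p, "-"))) / (2 * k * sum(p))
}

## A SAM file with one record failing each post-alignment filter plus one
## passing record.
writeSixRecordSAM <- function(path) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    "r_unmapped\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r_secondary\t256\tchr1\t100\t60\t100M\t*\t0\t0\t*\t*",
    "r_suppl\t2048\tchr1\t200\t60\t100M\t*\t0\t0\t*\t*",
    "r_dup\t1024\tchr1\t300\t60\t100M\t*\t0\t0\t*\t*",
    "r_lowq\t0\tchr1\t400\t4\t100M\t*\t0\t0\t*\t*",
    "r_pass\t0\tchr1\t500\t60\t100M\t*\t0\t0\t*\t*"), path)
  path
}

## Small shared reference, built once per test run.
.fixtures <- new.env(parent = emptyenv())
tinyRef <- function() {
  if (is.null(.fixtures$tinyRef))
    .fixtures$tinyRef <- makeToyReference(1, 2e5, 0.35, 0.55, seed = 4)
  .fixtures$tinyRef
}

## Manual FragmentSet builder on an explicit contig.
manualFragments <- function(contig, start1, end1, strand = "+", mapq = 60,
                            name = sprintf("r%04d", seq_along(start1)),
                            label = NA_character_, seqlen = NULL) {
  seqlens <- if (!is.null(seqlen)) setNames(seqlen, contig[1]) else NULL
  cfdnaflow:::newFragmentSet(contig, start1, end1, strand, mapq, name,
                             flag = ifelse(strand == "-", 16L, 0L),
                             label = label, seqlens = seqlens)
}
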