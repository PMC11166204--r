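# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from its definition with plain
# loops, sharing no code with the package.

# WD score from the definition, element by element over an avg-spec matrix
# (baits x preys) and a matching matrix of replicate detection counts.
wdOracle <- function(X, ndet) {
  K <- nrow(X)
  W <- X * 0
  for (p in seq_len(ncol(X))) {
    det <- X[, p] > 0
    f <- sum(det)
    if (f == 0) next
    vals <- X[det, p]
    omega <- if (f == 1) 1 else max(1, stats::sd(vals) / mean(vals))
    for (b in seq_len(nrow(X))) {
      if (X[b, p] > 0)
        W[b, p] <- sqrt(X[b, p] * ((K / f) * omega)^ndet[b, p])
    }
  }
  W
}

# Youden-optimal ROC threshold by exhaustive search over every observed
# score, smallest threshold on ties.
rocOracle <- function(scores, labels) {
  thr <- sort(unique(scores))
  best_j <- -Inf
  best_t <- NA
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  best_t
}

# mean silhouette width from the direct formula (singletons contribute 0)
silhouetteOracle <- function(labels, d) {
  D <- as.matrix(d)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) next
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# adjusted Rand index from the contingency-table formula
ariOracle <- function(x, y) {
  tab <- table(x, y)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expct <- sum_a * sum_b / n2
  (sum_ij - expct) / ((sum_a + sum_b) / 2 - expct)
}

# build a minimal screen from an avg-spec matrix (rows baits incl. controls)
screenFromMatrix <- function(X, cell_line = "HEK293",
                             controlBaits = character(),
                             avg_p = 0.99) {
  idx <- which(X > 0, arr.ind = TRUE)
  rec <- data.frame(bait = rownames(X)[idx[, 1]],
                    prey = colnames(X)[idx[, 2]],
                    cell_line = cell_line,
                    avg_spec = X[idx], avg_p = avg_p)
  BioidScreen(rec, controlBaits = controlBaits)
}

# two-replicate QC fixture: per-prey abundance spread wide, Poisson noise
makeReplicatePair <- function(nPreys = 300, shuffleSecond = FALSE) {
  mu <- exp(stats::rnorm(nPreys, log(20), 1.5))
  m <- cbind(r1 = stats::rpois(nPreys, mu), r2 = stats::rpois(nPreys, mu))
  if (shuffleSecond) m[, 2] <- sample(m[, 2])
  rownames(m) <- sprintf("P%03d", seq_len(nPreys))
  m
}
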