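# Independent brute-force oracles used to cross-check the vectorized
# implementations. Deliberately written as naive loops.

oracle_scatter <- function(Y) {
  S <- matrix(0, ncol(Y), ncol(Y))
  for (i in seq_len(nrow(Y))) S <- S + tcrossprod(Y[i, ])
  S
}

oracle_partial_cor <- function(theta) {
  p <- nrow(theta)
  rho <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    rho[i, j] <- if (i == j) 1 else
      -theta[i, j] / sqrt(theta[i, i] * theta[j, j])
  }
  rho
}

oracle_losses <- function(dh, dt) {
  p <- nrow(dh)
  D <- dh - dt
  l1 <- 0
  for (j in seq_len(p)) {
    cs <- 0
    for (i in seq_len(p)) cs <- cs + abs(D[i, j])
    l1 <- max(l1, cs)
  }
  l2 <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) l2 <- l2 + D[i, j]^2
  gh <- sort(eigen((dh + t(dh)) / 2)$values)
  gt <- sort(eigen((dt + t(dt)) / 2)$values)
  el1 <- 0; el2 <- 0
  for (i in seq_len(p)) {
    el1 <- el1 + abs(gh[i] - gt[i])
    el2 <- el2 + (gh[i] - gt[i])^2
  }
  c(l1 = l1, l2 = sqrt(l2), el1 = el1 / p, el2 = el2 / p,
    maxel1 = abs(gh[p] - gt[p]), minel1 = abs(gh[1] - gt[1]))
}

oracle_confusion <- function(tp, tn, fp, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(sp = div(tn, tn + fp), se = div(tp, tp + fn),
       fnr = div(fp, fp + tn), f1 = div(tp, tp + (fp + fn) / 2),
       mcc = if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den),
       precision = div(tp, tp + fp))
}

# Random symmetric binary adjacency with zero diagonal.
random_adjacency <- function(p, prob = 0.5) {
  A <- matrix(0L, p, p)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, prob)
  A + t(A)
}

all_structures <- c("ar1", "ar2", "sparse80", "sparse40", "scalefree",
                    "band", "cluster", "star", "circle")
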