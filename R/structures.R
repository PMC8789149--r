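#' Benchmark precision-matrix structures
#'
#' Generates one component of the nine benchmark precision-matrix pairs
#' used in the synthetic differential-network study. Closed-form
#' structures (`ar1`, `ar2`, `band`, `cluster`, `star`, `circle`) are
#' deterministic; `sparse80`, `sparse40` and `scalefree` are random and
#' require a `seed`. Every matrix is passed through
#' [ensure_positive_definite()] before it is returned, so a structure
#' whose printed parameterization is indefinite (the star second
#' component, whose diagonal the repair inflates) is still usable as a
#' Gaussian precision matrix.
#'
#' The structures are, per component:
#' \describe{
#'   \item{ar1}{\eqn{\theta_{ij} = 0.7^{|i-j|}} (component 1) or
#'     \eqn{0.75^{|i-j|}} (component 2).}
#'   \item{ar2}{tridiagonal-plus-one band: diagonal 0.1, first
#'     off-diagonal 0.05, second 0.025 (component 1); ten times that
#'     (1, 0.5, 0.25) for component 2.}
#'   \item{sparse80, sparse40}{symmetric random support with approximately
#'     up to 80\% (40\%) of off-diagonal entries zero; Erdos-Renyi upper
#'     triangle with edge probability 0.2 (0.6), nonzero magnitudes
#'     uniform on \eqn{\pm[0.2, 0.6]}. Component 2 shares the support of
#'     component 1 with re-drawn magnitudes.}
#'   \item{scalefree}{preferential-attachment tree (one edge per new
#'     node), edge weight 0.3, unit diagonal; component 2 is
#'     `scalefree_multiplier` times component 1 exactly.}
#'   \item{band}{two disjoint dense diagonal blocks of size `p/2`, unit
#'     diagonal; off-diagonal 0.2 and 0.5 (component 1), 0.7 and 0.9
#'     (component 2).}
#'   \item{cluster}{two disjoint dense blocks, unit diagonal; off-diagonal
#'     0.5 in both blocks (component 1), 0.9 (component 2).}
#'   \item{star}{node 1 connected to all others: unit diagonal,
#'     \eqn{\theta_{1j} = 0.1} (component 1) or 2.1 (component 2).}
#'   \item{circle}{diagonal 2, first off-diagonal 1, corner entry
#'     \eqn{\theta_{1p} = 0.45} (component 1); 4 / 2 / 0.95
#'     (component 2).}
#' }
#'
#' @param structure one of `"ar1"`, `"ar2"`, `"sparse80"`, `"sparse40"`,
#'   `"scalefree"`, `"band"`, `"cluster"`, `"star"`, `"circle"`.
#' @param p dimension (at least 2; even for `band`/`cluster`; at least 3
#'   for `circle`).
#' @param component 1 or 2.
#' @param seed RNG seed for the random structures; ignored by the
#'   closed-form ones.
#' @param scalefree_multiplier scalar applied to component 1 to obtain
#'   component 2 of the scale-free structure.
#' @param pd_margin minimum eigenvalue enforced by the positive-definite
#'   repair.
#' @return a symmetric positive-definite `p x p` matrix.
#' @seealso [structure_pair()], [true_diffnet()], [rggm()]
#' @examples
#' prec_structure("ar1", p = 3)
#' prec_structure("sparse80", p = 10, component = 2, seed = 1)
#' @export
prec_structure <- function(structure, p, component = 1,
                           seed = NULL,
                           scalefree_multiplier = 2,
                           pd_margin = 0.05) {
  structure <- match.arg(structure, c("ar1", "ar2", "sparse80", "sparse40",
                                      "scalefree", "band", "cluster",
                                      "star", "circle"))
  if (!is.numeric(p) || length(p) != 1L || p < 2 || p != round(p))
    stop("'p' must be an integer >= 2")
  if (!component %in% 1:2) stop("'component' must be 1 or 2")
  if (structure %in% c("band", "cluster") && p %% 2 != 0)
    stop("'p' must be even for the ", structure, " structure")
  if (structure == "circle" && p < 3)
    stop("'p' must be at least 3 for the circle structure")
  random <- structure %in% c("sparse80", "sparse40", "scalefree")
  if (random && is.null(seed))
    stop("a 'seed' is required for the random structure '", structure, "'")

  M <- switch(structure,
    ar1 = {
      rho <- if (component == 1) 0.7 else 0.75
      rho ^ abs(outer(seq_len(p), seq_len(p), "-"))
    },
    ar2 = {
      v <- if (component == 1) c(0.1, 0.05, 0.025) else c(1, 0.5, 0.25)
      d <- abs(outer(seq_len(p), seq_len(p), "-"))
      M <- matrix(0, p, p)
      M[d == 0] <- v[1]; M[d == 1] <- v[2]; M[d == 2] <- v[3]
      M
    },
    sparse80 = sparse_random(p, edge_prob = 0.2, component, seed),
    sparse40 = sparse_random(p, edge_prob = 0.6, component, seed),
    scalefree = {
      M <- scalefree_base(p, seed, pd_margin)
      if (component == 2) scalefree_multiplier * M else M
    },
    band = two_block(p, if (component == 1) c(0.2, 0.5) else c(0.7, 0.9)),
    cluster = two_block(p, if (component == 1) c(0.5, 0.5) else c(0.9, 0.9)),
    star = {
      a <- if (component == 1) 0.1 else 2.1
      M <- diag(p)
      M[1, -1] <- a; M[-1, 1] <- a
      M
    },
    circle = {
      v <- if (component == 1) c(2, 1, 0.45) else c(4, 2, 0.95)
      M <- diag(v[1], p)
      idx <- cbind(seq_len(p - 1), seq_len(p - 1) + 1)
      M[idx] <- v[2]; M[idx[, 2:1]] <- v[2]
      M[1, p] <- v[3]; M[p, 1] <- v[3]
      M
    })
  # scalefree is repaired before scaling so that component 2 is an exact
  # multiple of component 1; the other random structures get margin-based
  # conditioning; closed-form structures are kept exactly as printed
  # unless genuinely indefinite (the star second component)
  if (structure == "scalefree") M
  else if (random) ensure_positive_definite(M, pd_margin)
  else repair_if_indefinite(M, pd_margin)
}

# Printed benchmark matrices are used verbatim whenever they are already
# positive definite; only an indefinite parameterization is shifted.
repair_if_indefinite <- function(M, margin) {
  gmin <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (gmin > 0) M else ensure_positive_definite(M, margin)
}

# Erdos-Renyi support on the upper triangle; component 2 re-draws the
# nonzero magnitudes on the same support.
sparse_random <- function(p, edge_prob, component, seed) {
  local_rng(seed)
  ut <- which(upper.tri(matrix(0, p, p)))
  on <- runif(length(ut)) < edge_prob
  mag1 <- runif(length(ut), 0.2, 0.6) * sample(c(-1, 1), length(ut), TRUE)
  mag2 <- runif(length(ut), 0.2, 0.6) * sample(c(-1, 1), length(ut), TRUE)
  mag <- if (component == 1) mag1 else mag2
  M <- matrix(0, p, p)
  M[ut[on]] <- mag[on]
  M <- M + t(M)
  diag(M) <- 1
  M
}

scalefree_base <- function(p, seed, pd_margin) {
  local_rng(seed)
  g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  M <- 0.3 * A
  diag(M) <- 1
  ensure_positive_definite(M, pd_margin)
}

two_block <- function(p, off) {
  M <- diag(p)
  h <- p / 2
  M[1:h, 1:h] <- off[1]
  M[(h + 1):p, (h + 1):p] <- off[2]
  diag(M) <- 1
  M
}

#' Repair a symmetric matrix to positive definiteness
#'
#' If the smallest eigenvalue \eqn{\gamma_{\min}} of `M` is at least
#' `margin` the matrix is returned unchanged; otherwise
#' \eqn{(|\gamma_{\min}| + \mathrm{margin}) I} is added to the diagonal.
#' Deterministic; used by [prec_structure()] so that every generated
#' structure admits a Cholesky factorization.
#'
#' @param M symmetric matrix.
#' @param margin small positive eigenvalue floor.
#' @return a symmetric positive-definite matrix.
#' @examples
#' ensure_positive_definite(diag(2))        # unchanged
#' ensure_positive_definite(matrix(0, 2, 2)) # 0.05 * I
#' @export
ensure_positive_definite <- function(M, margin = 0.05) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (!isSymmetric(M, tol = 1e-8)) stop("'M' must be symmetric")
  gmin <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (gmin >= margin) M else M + diag(abs(gmin) + margin, nrow(M))
}

#' True differential network of a precision-matrix pair
#'
#' \eqn{\Delta = \Theta_2 - \Theta_1}, with the binary adjacency of its
#' off-diagonal support (entries exceeding `tol` in magnitude).
#'
#' @param theta1,theta2 precision matrices of the two conditions.
#' @param tol magnitude below which an off-diagonal difference is treated
#'   as zero.
#' @return a list with `delta` (the difference matrix) and `adjacency`
#'   (binary, symmetric, zero diagonal).
#' @examples
#' th <- prec_structure("ar1", 4)
#' true_diffnet(th, prec_structure("ar1", 4, component = 2))
#' @export
true_diffnet <- function(theta1, theta2, tol = 1e-8) {
  if (!identical(dim(theta1), dim(theta2)))
    stop("'theta1' and 'theta2' must have the same dimension")
  delta <- theta2 - theta1
  adjacency <- (abs(delta) > tol) * 1L
  diag(adjacency) <- 0L
  list(delta = delta, adjacency = adjacency)
}

#' Generate a benchmark structure pair and its true differential network
#'
#' Convenience wrapper building both components of a structure plus the
#' true differential network in one call.
#'
#' @inheritParams prec_structure
#' @param tol passed to [true_diffnet()].
#' @return list with `theta1`, `theta2`, `delta`, `adjacency`.
#' @export
structure_pair <- function(structure, p, seed = NULL,
                           scalefree_multiplier = 2, pd_margin = 0.05,
                           tol = 1e-8) {
  th1 <- prec_structure(structure, p, 1, seed, scalefree_multiplier, pd_margin)
  th2 <- prec_structure(structure, p, 2, seed, scalefree_multiplier, pd_margin)
  dn <- true_diffnet(th1, th2, tol)
  list(theta1 = th1, theta2 = th2, delta = dn$delta, adjacency = dn$adjacency)
}

#' Sample from a zero-mean Gaussian graphical model
#'
#' Draws `n` i.i.d. observations from \eqn{N_p(0, \Theta^{-1})} by
#' back-substitution against the Cholesky factor of the precision matrix.
#'
#' @param n sample size.
#' @param theta symmetric positive-definite precision matrix.
#' @param seed optional RNG seed.
#' @return an `n x p` data matrix.
#' @examples
#' Y <- rggm(50, prec_structure("ar1", 5), seed = 1)
#' @export
rggm <- function(n, theta, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  R <- chol(theta)                       # theta = R'R, cov = R^-1 R^-T
  p <- nrow(theta)
  Z <- matrix(rnorm(n * p), p, n)
  t(backsolve(R, Z))
}

# Seed the global RNG only when asked; used by generators that accept an
# explicit seed.
local_rng <- function(seed) if (!is.null(seed)) set.seed(seed)
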