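#' Bayesian differential network estimate from two samples
#'
#' Runs the Bayesian adaptive graphical lasso sampler ([baglasso()])
#' separately on each condition, determines each component's graph by
#' the chosen partial-correlation thresholding criterion, and assembles
#' the differential network \eqn{\hat\Delta = \hat\Theta_2 -
#' \hat\Theta_1} (difference of posterior means). The differential
#' adjacency is the elementwise OR of the two component adjacencies: an
#' entry of \eqn{\Delta} can only be nonzero where at least one
#' component has an edge. `delta_sparse` zeroes `delta_hat` outside that
#' support (its diagonal included, since adjacencies carry no
#' self-loops). Optionally, `delta_tol` additionally removes edges whose
#' estimated \eqn{|\hat\Delta_{ij}|} falls below a magnitude floor.
#'
#' Both component samplers (and both Wishart references) are run from
#' the same master-seed-derived sub-seed, so identical inputs give
#' `delta_hat` exactly zero and swapping the two samples exactly negates
#' it.
#'
#' @param Y1,Y2 data matrices for conditions 1 and 2 (same number of
#'   columns; sample sizes may differ).
#' @param eta sparsity threshold.
#' @param criterion `"partial"` ([edges_partial()], default) or
#'   `"ratio"` ([edges_ratio()]).
#' @param n_iter,n_burnin,r,s,lambda_diag,keep_draws passed to
#'   [baglasso()].
#' @param ridge prior ridge of the magnitude-criterion Wishart reference.
#' @param wishart_draws Monte-Carlo size for [wishart_partials()].
#' @param delta_tol optional magnitude floor on \eqn{|\hat\Delta_{ij}|};
#'   `NULL` (default) disables it.
#' @param seed optional master seed for the whole pipeline.
#' @return an object of class `"bnet"`: list with `delta_hat`,
#'   `delta_sparse`, `adjacency`, per-component `fits` (two
#'   `"baglasso"` objects), `component_adjacency` (list of two binary
#'   matrices), `eta`, `criterion`, `seed`.
#' @examples
#' pair <- structure_pair("cluster", p = 6)
#' Y1 <- rggm(60, pair$theta1, seed = 1)
#' Y2 <- rggm(60, pair$theta2, seed = 2)
#' fit <- bnet(Y1, Y2, eta = 0.3, n_iter = 300, n_burnin = 100, seed = 9)
#' fit$adjacency
#' @export
bnet <- function(Y1, Y2, eta = 0.3, criterion = c("partial", "ratio"),
                 n_iter = 10000, n_burnin = 5000,
                 r = 1e-2, s = 1e-6, lambda_diag = 1,
                 ridge = 0.001, wishart_draws = 2000,
                 delta_tol = NULL, keep_draws = FALSE, seed = NULL) {
  criterion <- match.arg(criterion)
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  if (ncol(Y1) != ncol(Y2))
    stop("'Y1' and 'Y2' must have the same number of variables")
  if (nrow(Y1) < 2 || nrow(Y2) < 2)
    stop("each condition needs at least 2 observations")
  check_eta(eta)
  if (!is.null(seed)) set.seed(seed)
  # one sub-seed per pipeline stage, shared across components (see
  # Details)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)

  fit_component <- function(Y) {
    fit <- baglasso(Y, n_iter = n_iter, n_burnin = n_burnin, r = r, s = s,
                    lambda_diag = lambda_diag, keep_draws = keep_draws,
                    seed = sub[1L])
    S <- scatter_matrix(Y)
    adj <- if (criterion == "partial") {
      E_h <- wishart_partials(S, nrow(Y), ridge = ridge,
                              n_draws = wishart_draws, seed = sub[2L])
      edges_partial(E_h, eta)
    } else {
      E_g <- wishart_partials(S, nrow(Y), ridge = 1,
                              n_draws = wishart_draws, seed = sub[2L])
      edges_ratio(fit$rho_tilde, E_g, eta)
    }
    list(fit = fit, adj = adj)
  }

  c1 <- fit_component(Y1)
  c2 <- fit_component(Y2)
  delta_hat <- c2$fit$theta_hat - c1$fit$theta_hat
  adjacency <- dn_adjacency(c1$adj, c2$adj)
  if (!is.null(delta_tol))
    adjacency <- adjacency * ((abs(delta_hat) > delta_tol) * 1L)
  delta_sparse <- delta_hat * adjacency

  structure(list(delta_hat = delta_hat, delta_sparse = delta_sparse,
                 adjacency = adjacency,
                 fits = list(c1$fit, c2$fit),
                 component_adjacency = list(c1$adj, c2$adj),
                 eta = eta, criterion = criterion,
                 delta_tol = delta_tol, seed = seed),
            class = "bnet")
}

#' @export
print.bnet <- function(x, ...) {
  p <- nrow(x$delta_hat)
  n_edges <- sum(x$adjacency[upper.tri(x$adjacency)])
  cat(sprintf(paste0("Bayesian differential network: p = %d, %d edge%s ",
                     "(criterion %s, eta = %.2f)\n"),
              p, n_edges, if (n_edges == 1) "" else "s",
              x$criterion, x$eta))
  cat(sprintf("||delta_hat||_F = %.3f\n", sqrt(sum(x$delta_hat^2))))
  invisible(x)
}

#' Combine two component adjacencies into the differential adjacency
#'
#' Elementwise OR: the differential network keeps a pair wherever either
#' component's graph has an edge.
#'
#' @param A1,A2 binary symmetric adjacency matrices of equal dimension.
#' @return binary symmetric adjacency matrix.
#' @export
dn_adjacency <- function(A1, A2) {
  if (!identical(dim(A1), dim(A2))) stop("adjacency dimensions differ")
  check_adjacency(A1); check_adjacency(A2)
  adj <- ((A1 + A2) > 0) * 1L
  diag(adj) <- 0L
  adj
}

check_adjacency <- function(A) {
  if (!all(A %in% c(0, 1))) stop("adjacency matrices must be binary")
  if (!isSymmetric(unname(A))) stop("adjacency matrices must be symmetric")
}
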