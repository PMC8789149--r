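#' Loss functions for differential-network estimates
#'
#' Six losses comparing an estimated matrix to the truth:
#' \describe{
#'   \item{l1}{matrix \eqn{L_1} norm: maximum absolute column sum of
#'     \eqn{\hat\Delta - \Delta}.}
#'   \item{l2}{Frobenius norm of \eqn{\hat\Delta - \Delta}.}
#'   \item{el1}{mean absolute difference of the sorted eigenvalue
#'     spectra, \eqn{\sum_i |\hat\gamma_i - \gamma_i| / p}.}
#'   \item{el2}{mean squared difference of the sorted spectra (no square
#'     root), \eqn{\sum_i (\hat\gamma_i - \gamma_i)^2 / p}.}
#'   \item{maxel1}{\eqn{|\hat\gamma_{\max} - \gamma_{\max}|}.}
#'   \item{minel1}{\eqn{|\hat\gamma_{\min} - \gamma_{\min}|}.}
#' }
#' Both spectra are sorted ascending before pairing.
#'
#' @param delta_hat,delta_true square matrices of equal dimension.
#' @return named numeric vector with components `l1`, `l2`, `el1`,
#'   `el2`, `maxel1`, `minel1`.
#' @examples
#' dn_losses(diag(3), diag(3))  # all zero
#' @export
dn_losses <- function(delta_hat, delta_true) {
  if (!identical(dim(delta_hat), dim(delta_true)))
    stop("'delta_hat' and 'delta_true' must have the same dimension")
  D <- delta_hat - delta_true
  g_hat <- sort(eigen(sym_part(delta_hat), symmetric = TRUE,
                      only.values = TRUE)$values)
  g_true <- sort(eigen(sym_part(delta_true), symmetric = TRUE,
                       only.values = TRUE)$values)
  p <- nrow(D)
  c(l1 = max(colSums(abs(D))),
    l2 = sqrt(sum(D^2)),
    el1 = sum(abs(g_hat - g_true)) / p,
    el2 = sum((g_hat - g_true)^2) / p,
    maxel1 = abs(max(g_hat) - max(g_true)),
    minel1 = abs(min(g_hat) - min(g_true)))
}

sym_part <- function(M) (M + t(M)) / 2

#' Edge-classification metrics for an estimated adjacency
#'
#' Confusion counts and derived scores over the strict upper triangle
#' (the diagonal is never scored). Metrics with a zero denominator —
#' including any Matthews-correlation factor — are reported as `NA`,
#' as happens when truth or estimate is single-class.
#'
#' The false negative rate is computed, by default, with the printed
#' benchmark formula `FP / (FP + TN)` (which is the textbook false
#' positive rate); `fnr_formula = "standard"` switches to
#' `FN / (FN + TP)`.
#'
#' @param adj_est,adj_true binary symmetric adjacency matrices.
#' @param fnr_formula `"printed"` (default) or `"standard"`.
#' @return list with counts `tp`, `tn`, `fp`, `fn` and scores `sp`
#'   (specificity), `se` (sensitivity), `fnr`, `f1`, `mcc`, `precision`.
#' @examples
#' a <- matrix(c(0, 1, 1, 0), 2, 2)
#' edge_confusion(a, a)
#' @export
edge_confusion <- function(adj_est, adj_true,
                           fnr_formula = c("printed", "standard")) {
  fnr_formula <- match.arg(fnr_formula)
  if (!identical(dim(adj_est), dim(adj_true)))
    stop("adjacency dimensions differ")
  if (!all(adj_est %in% c(0, 1)) || !all(adj_true %in% c(0, 1)))
    stop("adjacency matrices must be binary")
  ut <- upper.tri(adj_est)
  est <- adj_est[ut]; tru <- adj_true[ut]
  tp <- sum(est == 1 & tru == 1)
  tn <- sum(est == 0 & tru == 0)
  fp <- sum(est == 1 & tru == 0)
  fn <- sum(est == 0 & tru == 1)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sp = safe_div(tn, tn + fp),
       se = safe_div(tp, tp + fn),
       fnr = if (fnr_formula == "printed") safe_div(fp, fp + tn)
             else safe_div(fn, fn + tp),
       f1 = safe_div(tp, tp + (fp + fn) / 2),
       mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
       precision = safe_div(tp, tp + fp))
}

#' Replication study of differential-network estimation
#'
#' For each requested structure: fix the true precision-matrix pair,
#' then for each replication draw fresh Gaussian samples, fit the
#' Bayesian differential network ([bnet()]), and score the estimate —
#' losses of `delta_hat` against the true \eqn{\Delta} ([dn_losses()])
#' and edge classification of the thresholded adjacency against the
#' true differential adjacency ([edge_confusion()]). Medians and
#' standard errors (standard deviation divided by the square root of
#' the number of replications) are aggregated per metric.
#'
#' The threshold can be supplied per structure (scalar or named vector)
#' or, with `eta = NULL`, selected per structure by a fresh
#' [select_threshold()] grid scan.
#'
#' @param structures character vector of structure names (see
#'   [prec_structure()]).
#' @param p dimension.
#' @param n per-condition sample size (used for both conditions).
#' @param n_reps replications per structure.
#' @param eta scalar threshold, named vector (one entry per structure),
#'   or `NULL` for grid selection.
#' @param criterion thresholding criterion, see [bnet()].
#' @param n_iter,n_burnin,r,s,lambda_diag,wishart_draws,ridge sampler
#'   and reference settings.
#' @param grid,scan_reps threshold-scan settings when `eta = NULL`.
#' @param seed master seed; every replication derives its own sub-seed.
#' @return an object of class `"dn_study"`: list with `table` (long
#'   data frame: structure, metric, median, se), `raw` (per-structure
#'   list of replication x metric matrices), `eta` (per-structure
#'   thresholds used), `failures` (per-structure count of failed
#'   replications), and the study configuration.
#' @examples
#' st <- run_study("cluster", p = 6, n = 50, n_reps = 2, eta = 0.3,
#'                 n_iter = 200, n_burnin = 100, seed = 1)
#' subset(st$table, metric == "mcc")
#' @export
run_study <- function(structures, p = 10, n = 100, n_reps = 40,
                      eta = NULL, criterion = c("partial", "ratio"),
                      n_iter = 10000, n_burnin = 5000,
                      r = 1e-2, s = 1e-6, lambda_diag = 1,
                      wishart_draws = 2000, ridge = 0.001,
                      grid = seq(0.2, 0.6, by = 0.02), scan_reps = 10,
                      seed = NULL) {
  criterion <- match.arg(criterion)
  if (n_reps < 1) stop("'n_reps' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  metrics <- c("l1", "l2", "el1", "el2", "maxel1", "minel1",
               "sp", "se", "fnr", "f1", "mcc", "precision")
  raw <- list(); eta_used <- numeric(0); failures <- integer(0)
  rows <- list()

  for (st in structures) {
    st_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
    scan_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    truth <- structure_pair(st, p, seed = st_seed)
    eta_st <- resolve_eta(eta, st, p, n, criterion, grid, scan_reps,
                          n_iter, n_burnin, r, s, lambda_diag,
                          wishart_draws, ridge, scan_seed)
    vals <- matrix(NA_real_, n_reps, length(metrics),
                   dimnames = list(NULL, metrics))
    n_fail <- 0L
    for (rep in seq_len(n_reps)) {
      res <- tryCatch({
        set.seed(rep_seeds[rep])
        Y1 <- rggm(n, truth$theta1)
        Y2 <- rggm(n, truth$theta2)
        fit <- bnet(Y1, Y2, eta = eta_st, criterion = criterion,
                    n_iter = n_iter, n_burnin = n_burnin, r = r, s = s,
                    lambda_diag = lambda_diag, ridge = ridge,
                    wishart_draws = wishart_draws,
                    seed = rep_seeds[rep])
        conf <- edge_confusion(fit$adjacency, truth$adjacency)
        c(dn_losses(fit$delta_hat, truth$delta),
          unlist(conf[c("sp", "se", "fnr", "f1", "mcc", "precision")]))
      }, error = function(e) {
        warning(sprintf("structure %s, replication %d failed: %s",
                        st, rep, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(res)) n_fail <- n_fail + 1L else vals[rep, ] <- res
    }
    ok <- stats::complete.cases(vals[, c("l1", "l2"), drop = FALSE])
    vals_ok <- vals[ok, , drop = FALSE]
    med <- apply(vals_ok, 2, median, na.rm = TRUE)
    se_ <- apply(vals_ok, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
    })
    rows[[st]] <- data.frame(structure = st, metric = metrics,
                             median = unname(med), se = unname(se_),
                             row.names = NULL)
    raw[[st]] <- vals
    eta_used[st] <- eta_st
    failures[st] <- n_fail
  }

  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 raw = raw, eta = eta_used, failures = failures,
                 p = p, n = n, n_reps = n_reps, criterion = criterion,
                 n_iter = n_iter, n_burnin = n_burnin, seed = seed),
            class = "dn_study")
}

resolve_eta <- function(eta, st, p, n, criterion, grid, scan_reps,
                        n_iter, n_burnin, r, s, lambda_diag,
                        wishart_draws, ridge, scan_seed) {
  if (is.null(eta)) {
    scan <- select_threshold(st, p, n1 = n, grid = grid,
                             n_reps = scan_reps, criterion = criterion,
                             n_iter = n_iter, n_burnin = n_burnin, r = r,
                             s = s, lambda_diag = lambda_diag,
                             wishart_draws = wishart_draws, ridge = ridge,
                             seed = scan_seed)
    return(scan$eta_star)
  }
  if (!is.null(names(eta))) {
    if (!st %in% names(eta)) stop("no 'eta' supplied for structure ", st)
    return(unname(eta[st]))
  }
  eta
}

#' @export
print.dn_study <- function(x, ...) {
  cat(sprintf(paste0("Differential-network study: p = %d, n = %d, ",
                     "%d replications, %s criterion\n"),
              x$p, x$n, x$n_reps, x$criterion))
  wide <- stats::reshape(x$table[, c("structure", "metric", "median")],
                         direction = "wide", idvar = "metric",
                         timevar = "structure")
  names(wide) <- sub("^median\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  if (any(x$failures > 0))
    cat("Failed replications:",
        paste(sprintf("%s=%d", names(x$failures), x$failures),
              collapse = ", "), "\n")
  invisible(x)
}
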