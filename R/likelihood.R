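# log-likelihood for a matrix of theta rows (vectorized over parameters);
# returns -Inf where a split class with positive count has probability zero.
loglik_matrix <- function(theta_mat, sbar, n) {
  q <- cbind(theta_mat[, 1] * theta_mat[, 2],
             theta_mat[, 1] * theta_mat[, 3],
             theta_mat[, 2] * theta_mat[, 3])
  tmat <- 1 + q %*% t(cfn_split_signs())   # rows: theta; cols: split classes
  pos <- sbar > 0L
  ll <- rep(-n * log(8), nrow(theta_mat))
  for (a in which(pos)) {
    ta <- tmat[, a]
    term <- ifelse(ta > 0, sbar[a] * log(pmax(ta, 0)), -Inf)
    ll <- ll + term
  }
  ll
}

#' Log-likelihood of a three-leaf CFN tree
#'
#' Evaluates the log-likelihood
#' \deqn{\ell(\theta \mid s) = \sum_\alpha \bar s_\alpha \log \bar p_\alpha(\theta)
#'   - N \log 2}
#' of Hadamard parameters \eqn{\theta \in [0,1]^3} given observed pattern
#' counts.  Natural logarithms throughout.  The value is finite whenever every
#' split class with a positive count has positive probability, and exactly
#' \eqn{-\infty} otherwise (e.g. two zero-length branches combined with any
#' observed mismatch between the corresponding leaves); \eqn{-\infty} is a
#' value, not an error, and the function is upper semicontinuous on the cube.
#'
#' @param theta Numeric vector of three Hadamard parameters in \eqn{[0, 1]}.
#' @param counts Anything accepted by [cfn_counts()].
#' @return A single numeric value (possibly `-Inf`).
#' @examples
#' cfn_loglik(c(0, 0, 0), c(17, 5, 27, 5, 16, 5, 19, 6))  # -100 log 8
#' @export
cfn_loglik <- function(theta, counts) {
  theta <- assert_theta(theta)
  s <- cfn_counts(counts)
  sbar <- sbar_vector(s)
  unname(loglik_matrix(matrix(theta, nrow = 1L), sbar, sum(s)))
}

#' Numerical maximization oracle for the CFN likelihood
#'
#' An independent check on the closed-form solver: maximizes the
#' log-likelihood over the closed cube \eqn{[0,1]^3} by a dense grid scan
#' (grid points include the boundary faces, where maxima frequently lie)
#' followed by bounded quasi-Newton (`L-BFGS-B`) refinement from the best
#' grid points and from random interior restarts.  Deterministic for a fixed
#' `seed`.
#'
#' @inheritParams cfn_loglik
#' @param grid_n Number of grid points per axis (at least 11).
#' @param restarts Number of random interior restarts (at least 5).
#' @param seed Optional integer seed controlling the restart draws.
#' @return A list of class `"cfn_oracle"` with elements `best_theta`,
#'   `best_loglik`, `trace` (a tibble of refinement starts, end points and
#'   values), and `grid_n`.
#' @examples
#' cfn_numeric_oracle(c(21, 12, 9, 8, 7, 11, 17, 15), seed = 1)$best_theta
#' @export
cfn_numeric_oracle <- function(counts, grid_n = 11L, restarts = 8L, seed = NULL) {
  s <- cfn_counts(counts)
  sbar <- sbar_vector(s)
  n <- sum(s)
  if (n == 0L) stop("Empty data.", call. = FALSE)
  if (grid_n < 11L) stop("`grid_n` must be at least 11.", call. = FALSE)
  if (restarts < 5L) stop("`restarts` must be at least 5.", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)

  ax <- seq(0, 1, length.out = grid_n)
  grid <- as.matrix(expand.grid(theta1 = ax, theta2 = ax, theta3 = ax))
  gvals <- loglik_matrix(grid, sbar, n)
  best_grid <- order(gvals, decreasing = TRUE)[seq_len(8L)]

  signs <- cfn_split_signs()
  neg_ll <- function(th) {
    v <- loglik_matrix(matrix(th, nrow = 1L), sbar, n)
    if (!is.finite(v)) 1e12 else -v
  }
  # analytic gradient of -loglik; keeps the bounded quasi-Newton refinement
  # honest at the faces of the cube, where finite differencing would step
  # outside the box
  neg_gr <- function(th) {
    q <- c(th[1] * th[2], th[1] * th[3], th[2] * th[3])
    tvec <- as.numeric(1 + signs %*% q)
    if (any(tvec <= 0 & sbar > 0)) return(c(0, 0, 0))
    w <- ifelse(sbar > 0, sbar / tvec, 0)
    g1 <- sum(w * (signs[, 1] * th[2] + signs[, 2] * th[3]))
    g2 <- sum(w * (signs[, 1] * th[1] + signs[, 3] * th[3]))
    g3 <- sum(w * (signs[, 2] * th[1] + signs[, 3] * th[2]))
    -c(g1, g2, g3)
  }
  refine3d <- function(st) {
    fit <- tryCatch(
      stats::optim(st, neg_ll, gr = neg_gr, method = "L-BFGS-B",
                   lower = 0, upper = 1,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) list(par = st, value = neg_ll(st)))
    list(start = st, par = pmin(pmax(fit$par, 0), 1), value = -fit$value)
  }
  # 2-D refinement with one coordinate clamped to a face of the cube; maxima
  # of the likelihood frequently sit on faces, where full 3-D ascent can
  # stall on the flat independence saddle
  refine_face <- function(st, k, v) {
    free <- setdiff(1:3, k)
    embed <- function(x) { th <- numeric(3); th[k] <- v; th[free] <- x; th }
    fit <- tryCatch(
      stats::optim(st[free], function(x) neg_ll(embed(x)),
                   gr = function(x) neg_gr(embed(x))[free],
                   method = "L-BFGS-B", lower = 0, upper = 1,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) list(par = st[free], value = neg_ll(st)))
    list(start = st, par = pmin(pmax(embed(fit$par), 0), 1), value = -fit$value)
  }
  starts <- rbind(grid[best_grid, , drop = FALSE],
                  matrix(stats::runif(3L * restarts, 0.02, 0.98),
                         ncol = 3L, dimnames = list(NULL, colnames(grid))))
  runs <- apply(starts, 1L, refine3d)
  for (k in 1:3) {
    for (v in c(0, 1)) {
      # best grid point on the face and the face center seed the 2-D runs
      on_face <- which(grid[, k] == v)
      st <- grid[on_face[which.max(gvals[on_face])], ]
      mid <- numeric(3); mid[setdiff(1:3, k)] <- 0.5; mid[k] <- v
      runs <- c(runs, list(refine_face(st, k, v), refine_face(mid, k, v)))
    }
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.max(vals)]]
  best_loglik <- max(c(vals, gvals))
  best_theta <- if (max(vals) >= max(gvals)) best$par else grid[which.max(gvals), ]
  trace <- tibble::tibble(
    start = lapply(runs, function(r) unname(r$start)),
    converged = lapply(runs, function(r) unname(r$par)),
    value = vals)
  structure(list(best_theta = unname(best_theta), best_loglik = best_loglik,
                 trace = trace, grid_n = grid_n),
            class = "cfn_oracle")
}

#' @export
print.cfn_oracle <- function(x, ...) {
  cat("CFN numerical likelihood oracle\n")
  cat("  best theta:", paste(signif(x$best_theta, 6), collapse = ", "), "\n")
  cat("  best log-likelihood:", format(x$best_loglik, digits = 10), "\n")
  cat("  refinement runs:", nrow(x$trace), " grid:", x$grid_n, "^3\n")
  invisible(x)
}
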