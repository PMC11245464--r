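#' Convert branch lengths to Hadamard edge parameters
#'
#' The CFN model is most conveniently parameterized by the Hadamard (or
#' "path-set") parameters \eqn{\theta_e = \exp(-2 d_e)}, where \eqn{d_e} is
#' the branch length of edge \eqn{e} in expected substitutions per site.
#' \eqn{\theta_e} equals the correlation of the states at the two endpoints of
#' the edge: \eqn{\theta_e = 1} is a zero-length branch (perfect correlation)
#' and \eqn{\theta_e = 0} an infinitely long branch (independence).
#'
#' @param d Numeric vector of three nonnegative branch lengths; `Inf` is a
#'   first-class value and maps to \eqn{\theta = 0} exactly.
#' @return Numeric vector of three Hadamard parameters in \eqn{[0, 1]}.
#' @seealso [lengths_from_theta()] for the inverse map.
#' @examples
#' theta_from_lengths(c(0.5, 0.5, 0.5))
#' theta_from_lengths(c(0, 1, Inf))
#' @export
theta_from_lengths <- function(d) {
  if (!is.numeric(d) || length(d) != 3L || anyNA(d)) {
    stop("`d` must be a numeric vector of three nonnegative branch lengths.",
         call. = FALSE)
  }
  if (any(d < 0)) {
    stop("Branch lengths must be nonnegative (infinite values are allowed).",
         call. = FALSE)
  }
  exp(-2 * as.numeric(d))
}

#' Convert Hadamard edge parameters to branch lengths
#'
#' Inverts [theta_from_lengths()]: \eqn{d_e = -\tfrac{1}{2}\log\theta_e}, the
#' expected number of substitutions per site on edge \eqn{e}.  \eqn{\theta = 0}
#' maps to an infinite branch and \eqn{\theta = 1} to a zero-length branch.
#'
#' @param theta Numeric vector of three values in \eqn{[0, 1]}.
#' @return Numeric vector of three branch lengths in \eqn{[0, \infty]}.
#' @examples
#' lengths_from_theta(c(0.3, 0.12, 0.9))
#' @export
lengths_from_theta <- function(theta) {
  theta <- assert_theta(theta)
  -0.5 * log(theta)
}

# Full 8-entry pattern probability vector, Hadamard-parameter form:
# p_sigma = (1 + s1 s2 t1 t2 + s1 s3 t1 t3 + s2 s3 t2 t3) / 8.
p8_from_theta <- function(theta) {
  s <- cfn_sigma_matrix()
  as.numeric(
    1 + s[, 1] * s[, 2] * theta[1] * theta[2] +
        s[, 1] * s[, 3] * theta[1] * theta[3] +
        s[, 2] * s[, 3] * theta[2] * theta[3]) / 8
}

# 4-entry split-class probability vector (the expected site pattern spectrum).
pbar_from_theta <- function(theta) {
  q <- c(theta[1] * theta[2], theta[1] * theta[3], theta[2] * theta[3])
  as.numeric(1 + cfn_split_signs() %*% q) / 4
}

#' Site-pattern probabilities under the CFN model
#'
#' Computes the distribution of the leaf-state vector \eqn{X \in \{-1,+1\}^3}
#' on the three-leaf star tree with Hadamard parameters `theta`:
#' \deqn{P[X = \sigma] = \tfrac{1}{8}\left(1 + \sigma_1\sigma_2\theta_1\theta_2
#'   + \sigma_1\sigma_3\theta_1\theta_3 + \sigma_2\sigma_3\theta_2\theta_3\right).}
#' The distribution is symmetric under a global sign flip
#' (\eqn{p_\sigma = p_{-\sigma}}), so it is fully described by the four split
#' classes returned in the `split` column.
#'
#' @param theta Numeric vector of three Hadamard parameters in \eqn{[0, 1]}.
#' @return A tibble with one row per pattern, in binary order
#'   `"---"` to `"+++"`, and columns `pattern`, `split`, `probability`.
#' @examples
#' cfn_pattern_probs(c(0.5, 0.5, 0.5))
#' @export
cfn_pattern_probs <- function(theta) {
  theta <- assert_theta(theta)
  tibble::tibble(
    pattern = cfn_pattern_labels(),
    split = cfn_split_labels()[cfn_split_index()],
    probability = p8_from_theta(theta))
}

#' Split-class probabilities under the CFN model
#'
#' The expected site-pattern spectrum: the probability that the leaf states
#' realize each of the four split classes
#' \eqn{\emptyset, \{1\}, \{2\}, \{1,2\}} (a pattern and its global sign flip
#' are pooled).
#'
#' @inheritParams cfn_pattern_probs
#' @return A tibble with columns `split` and `probability` (four rows, summing
#'   to one).
#' @export
cfn_split_probs <- function(theta) {
  theta <- assert_theta(theta)
  tibble::tibble(split = cfn_split_labels(), probability = pbar_from_theta(theta))
}

#' Sylvester-type Hadamard matrix
#'
#' The \eqn{2^k \times 2^k} Hadamard matrix built by the Sylvester recursion
#' \eqn{H_{k+1} = [H_k, H_k; H_k, -H_k]} with \eqn{H_0 = [1]}.  Under the
#' lexicographic subset ordering its entries are
#' \eqn{h_{\alpha\beta} = (-1)^{|\alpha \cap \beta|}}, and
#' \eqn{H_k H_k = 2^k I}.  This is the character table of
#' \eqn{\mathbb{Z}_2^k}, i.e. the discrete Fourier transform used throughout
#' the analysis of group-based substitution models.
#'
#' @param k Nonnegative integer order; capped at 12 to bound memory.
#' @return An integer matrix with entries \eqn{\pm 1}.
#' @examples
#' hadamard_matrix(2)
#' @export
hadamard_matrix <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k != round(k)) {
    stop("`k` must be a single nonnegative integer.", call. = FALSE)
  }
  if (k > 12) {
    stop("`k` is capped at 12 (a 4096 x 4096 matrix).", call. = FALSE)
  }
  h <- matrix(1L, 1L, 1L)
  if (k >= 1) {
    for (i in seq_len(k)) {
      h <- rbind(cbind(h, h), cbind(h, -h))
    }
  }
  h
}

#' Hadamard conjugation
#'
#' Maps an edge spectrum \eqn{\gamma} to the expected site-pattern spectrum
#' via \eqn{\bar p = H^{-1} \exp(H \gamma)}, where \eqn{H} is the Sylvester
#' Hadamard matrix of matching size and `exp` acts componentwise.  For the
#' three-leaf tree the edge spectrum is
#' \eqn{\gamma = (-(d_1+d_2+d_3), d_1, d_2, d_3)} and the result coincides
#' with the split-class probabilities of [cfn_split_probs()].
#'
#' @param gamma Numeric vector of length \eqn{2^k} for some \eqn{k \ge 0}.
#' @return Numeric vector of length `length(gamma)`, the conjugated spectrum.
#' @examples
#' d <- c(0.5, 0.5, 0.5)
#' hadamard_conjugation(c(-sum(d), d))
#' @export
hadamard_conjugation <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) < 1L || anyNA(gamma)) {
    stop("`gamma` must be a numeric vector of length 2^k.", call. = FALSE)
  }
  k <- round(log2(length(gamma)))
  if (2^k != length(gamma)) {
    stop("`gamma` must have length a power of two.", call. = FALSE)
  }
  h <- hadamard_matrix(k)
  as.numeric(h %*% exp(h %*% as.numeric(gamma))) / 2^k
}

#' Fourier coordinates of a CFN distribution
#'
#' The discrete Fourier transform of the split-class probabilities,
#' \eqn{q = H_2 \bar p}.  For the three-leaf tree the coordinates factor into
#' monomials in the Hadamard parameters:
#' \eqn{q_{111} = 1}, \eqn{q_{101} = \theta_1\theta_3},
#' \eqn{q_{011} = \theta_2\theta_3}, \eqn{q_{110} = \theta_1\theta_2}.
#' Each nontrivial coordinate is the covariance of the states observed at the
#' corresponding leaf pair.
#'
#' @inheritParams cfn_pattern_probs
#' @return Named numeric vector `c(q111, q101, q011, q110)`.
#' @examples
#' fourier_from_theta(c(0.3, 0.5, 0.7))
#' @export
fourier_from_theta <- function(theta) {
  theta <- assert_theta(theta)
  c(q111 = 1,
    q101 = theta[1] * theta[3],
    q011 = theta[2] * theta[3],
    q110 = theta[1] * theta[2])
}

#' Semi-algebraic constraints of the three-leaf CFN model
#'
#' A point of the probability simplex arises from a tree with strictly
#' positive, finite branch lengths if and only if its Fourier coordinates
#' satisfy the positivity constraints \eqn{q_{101}, q_{011}, q_{110} > 0} and
#' the three triangle-type product constraints
#' \eqn{q_{110} q_{101} < q_{011}}, \eqn{q_{110} q_{011} < q_{101}},
#' \eqn{q_{101} q_{011} < q_{110}} — the triangle inequality on pairwise
#' evolutionary distances in disguise.  On the closed model (branch lengths
#' zero or infinite allowed) the constraints hold non-strictly.
#'
#' @param q Either a length-4 named Fourier vector as returned by
#'   [fourier_from_theta()] (with `q111 = 1`) or a length-3 vector of the
#'   nontrivial coordinates `(q101, q011, q110)`.
#' @param strict If `TRUE` (default) test the strict inequalities, otherwise
#'   the non-strict ones.
#' @return A tibble with columns `constraint`, `type` (`"positivity"` or
#'   `"product"`), and `holds`.
#' @examples
#' check_fourier_constraints(fourier_from_theta(c(0.5, 0.5, 0.5)))
#' @export
check_fourier_constraints <- function(q, strict = TRUE) {
  if (length(q) == 4L) {
    if (abs(q[[1]] - 1) > 1e-12) {
      stop("The trivial Fourier coordinate q111 must equal 1.", call. = FALSE)
    }
    q <- q[2:4]
  }
  if (!is.numeric(q) || length(q) != 3L || anyNA(q)) {
    stop("`q` must supply the three nontrivial Fourier coordinates.", call. = FALSE)
  }
  q101 <- q[[1]]; q011 <- q[[2]]; q110 <- q[[3]]
  lt <- if (strict) `<` else `<=`
  gt <- if (strict) `>` else `>=`
  tibble::tibble(
    constraint = c("q101 > 0", "q011 > 0", "q110 > 0",
                   "q110*q101 < q011", "q110*q011 < q101", "q101*q011 < q110"),
    type = rep(c("positivity", "product"), each = 3L),
    holds = c(gt(q101, 0), gt(q011, 0), gt(q110, 0),
              lt(q110 * q101, q011), lt(q110 * q011, q101),
              lt(q101 * q011, q110)))
}
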