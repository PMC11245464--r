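#' Simulate site patterns under the three-leaf CFN model
#'
#' Draws `n_sites` independent columns from the CFN process on the three-leaf
#' star tree: the internal-vertex state is uniform on \eqn{\{-1,+1\}}, and
#' each leaf copies it with probability \eqn{(1+\theta_i)/2}, flipping
#' otherwise.  Random draws are made in a fixed, documented order (root
#' states for all sites, then the flip draws for leaves 1, 2, 3), so a given
#' seed always reproduces the same counts.
#'
#' @param theta Numeric vector of three Hadamard parameters in \eqn{[0, 1]};
#'   alternatively supply `d` (branch lengths) instead.
#' @param n_sites Number of alignment columns to draw.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param d Optional branch lengths, converted via [theta_from_lengths()];
#'   supply either `theta` or `d`.
#' @param alignment If `TRUE`, attach the simulated leaf-state matrix
#'   (3 x `n_sites`, entries \eqn{\pm 1}) as attribute `"alignment"`.
#' @return A [cfn_counts] object.
#' @examples
#' simulate_cfn(c(0.6, 0.7, 0.8), n_sites = 1000, seed = 1)
#' @export
simulate_cfn <- function(theta = NULL, n_sites, seed = NULL, d = NULL,
                         alignment = FALSE) {
  if (is.null(theta) == is.null(d)) {
    stop("Supply exactly one of `theta` or `d`.", call. = FALSE)
  }
  if (!is.null(d)) theta <- theta_from_lengths(d)
  theta <- assert_theta(theta)
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1 ||
      n_sites != round(n_sites)) {
    stop("`n_sites` must be a positive integer.", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  if (!is.null(seed)) withr::local_seed(seed)
  root <- sample(c(-1L, 1L), n_sites, replace = TRUE)
  leaves <- matrix(0L, nrow = 3L, ncol = n_sites)
  for (i in 1:3) {
    flip <- stats::runif(n_sites) >= (1 + theta[i]) / 2
    leaves[i, ] <- ifelse(flip, -root, root)
  }
  # pattern index via binary encoding in the fixed order (-1 before +1)
  idx <- 1L + 4L * (leaves[1, ] > 0) + 2L * (leaves[2, ] > 0) + (leaves[3, ] > 0)
  out <- cfn_counts(tabulate(idx, nbins = 8L))
  if (alignment) attr(out, "alignment") <- leaves
  out
}

#' Write a simulated three-leaf alignment to FASTA
#'
#' Serializes a \eqn{\pm 1} leaf-state matrix (as attached by
#' `simulate_cfn(..., alignment = TRUE)`) to a three-record FASTA file using
#' the purine/pyrimidine ambiguity codes `R` (\eqn{-1}) and `Y` (\eqn{+1}),
#' which [read_alignment()] maps back losslessly.
#'
#' @param alignment Integer matrix with three rows and entries \eqn{\pm 1}.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cfn_fasta <- function(alignment, path) {
  if (!is.matrix(alignment) || nrow(alignment) != 3L ||
      !all(alignment %in% c(-1L, 1L))) {
    stop("`alignment` must be a 3-row matrix with entries -1/+1.", call. = FALSE)
  }
  lines <- character(0)
  for (i in 1:3) {
    lines <- c(lines, sprintf(">taxon%d", i),
               paste(ifelse(alignment[i, ] > 0, "Y", "R"), collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct count fixtures that land in a prescribed MLE regime
#'
#' Builds a site-frequency vector whose exact pair correlations fall in the
#' requested regime of the closed-form solver, by inverting the identity
#' \eqn{\bar s_\alpha = \tfrac{N}{4}(1 \pm B_{12} \pm B_{13} \pm B_{23})}
#' for an integer-compatible target triple \eqn{B}.  The construction is
#' exact (no sampling noise), so the fixtures sit precisely where intended;
#' the result is verified post hoc against [b_statistics()] and
#' [in_region_d()].
#'
#' @param regime One of `"interior"`, `"face_theta_one"`,
#'   `"curve_theta_zero"`, `"independence_union"`.
#' @param n_sites Total number of sites; must make the implied split-class
#'   counts integral (the defaults work with multiples of 100).
#' @param b Optional target triple \eqn{(B_{12}, B_{13}, B_{23})} overriding
#'   the regime default.
#' @return A [cfn_counts] object with `n_sites` total counts.
#' @examples
#' boundary_scenario_counts("curve_theta_zero")
#' @export
boundary_scenario_counts <- function(regime = c("interior", "face_theta_one",
                                                "curve_theta_zero",
                                                "independence_union"),
                                     n_sites = 100L, b = NULL) {
  regime <- match.arg(regime)
  if (is.null(b)) {
    b <- switch(regime,
      interior = c(0.1, 0.3, 0.2),
      face_theta_one = c(0.3, 0.12, 0.02),
      curve_theta_zero = c(-0.06, 0.1, -0.12),
      independence_union = c(-0.2, -0.08, -0.12))
  }
  sbar_exact <- n_sites / 4 * (1 + as.numeric(cfn_split_signs() %*% b))
  if (any(abs(sbar_exact - round(sbar_exact)) > 1e-9) || any(sbar_exact < 0)) {
    stop(sprintf(
      "Requested regime is infeasible at N = %d: implied split counts (%s) are not nonnegative integers.",
      n_sites, paste(signif(sbar_exact, 6), collapse = ", ")), call. = FALSE)
  }
  sbar <- as.integer(round(sbar_exact))
  # split each class count across its two patterns
  s <- integer(8)
  for (a in 1:4) {
    members <- which(cfn_split_index() == a)
    s[members[1]] <- sbar[a] %/% 2L + sbar[a] %% 2L
    s[members[2]] <- sbar[a] %/% 2L
  }
  out <- cfn_counts(s)
  achieved <- cfn_mle_regime(out)
  if (!identical(achieved, regime)) {
    stop(sprintf("Constructed counts fall in regime '%s', not '%s'.",
                 achieved, regime), call. = FALSE)
  }
  out
}

# regime classification only (no solving); shares the exact branching rules
cfn_mle_regime <- function(counts) {
  stats <- nb_statistics(cfn_counts(counts))
  nb <- stats$nb
  if (in_region_d(stats$b)$in_d) return("interior")
  nb_sorted <- sort(nb)
  if (nb_sorted[2] > 0) "face_theta_one"
  else if (nb_sorted[3] > 0) "curve_theta_zero"
  else "independence_union"
}
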