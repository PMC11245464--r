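#' Membership in the interior region D
#'
#' The closed-form MLE is an interior point (all branch lengths positive and
#' finite) precisely when the pair-correlation triple
#' \eqn{B = (B_{12}, B_{13}, B_{23})} lies in
#' \deqn{\mathcal{D} = \{x \in (0,1)^3 : x_i x_j < x_k
#'   \text{ for all distinct } i, j, k\},}
#' the empirical counterpart of the model's semi-algebraic constraints.
#' When `b` carries integer agreement counts (a [b_statistics()] tibble or
#' raw counts), every inequality is decided in exact integer arithmetic on
#' \eqn{N B_{ij}} (products \eqn{N B_i \cdot N B_j} vs \eqn{N \cdot N B_k}),
#' so membership never depends on floating-point rounding.
#'
#' @param b A [b_statistics()] tibble, anything accepted by [cfn_counts()],
#'   or a bare numeric triple \eqn{(B_{12}, B_{13}, B_{23})}.
#' @return A list of class `"cfn_region"` with elements `in_d` (logical),
#'   `failed` (labels of violated inequalities), and `checks` (a tibble of
#'   all six inequalities with verdicts).
#' @examples
#' in_region_d(c(0.1, 0.3, 0.2))$in_d
#' in_region_d(c(0.3, 0.12, 0.02))$failed
#' @export
in_region_d <- function(b) {
  v <- as_b_triple(b)
  nb <- v$nb; n <- v$n
  pos_labels <- paste0("positivity(", c("12", "13", "23"), ")")
  pos_ok <- nb > 0 & nb < n
  prods <- list(c("12", "13", "23"), c("12", "23", "13"), c("13", "23", "12"))
  prod_labels <- vapply(prods, function(p)
    sprintf("product(B%s*B%s < B%s)", p[1], p[2], p[3]), character(1))
  prod_ok <- vapply(prods, function(p)
    nb[[p[1]]] * nb[[p[2]]] < n * nb[[p[3]]], logical(1))
  checks <- tibble::tibble(
    inequality = c(pos_labels, prod_labels),
    type = rep(c("positivity", "product"), each = 3L),
    holds = c(unname(pos_ok), prod_ok))
  structure(list(in_d = all(checks$holds),
                 failed = checks$inequality[!checks$holds],
                 checks = checks),
            class = "cfn_region")
}

# Normalize the various B inputs to integer-like (nb, n).  Bare numeric
# triples are scaled by a power of ten so comparisons stay exact for
# terminating decimals.
as_b_triple <- function(b) {
  if (is.data.frame(b) && all(c("m_plus", "m_minus") %in% names(b))) {
    nb <- stats::setNames(as.numeric(b$m_plus - b$m_minus), b$pair)
    return(list(nb = nb, n = as.numeric(b$m_plus[1] + b$m_minus[1]),
                b = stats::setNames(b$b, b$pair)))
  }
  if (is.numeric(b) && length(b) == 3L) {
    scale <- 1e6
    nb <- stats::setNames(round(as.numeric(b) * scale), c("12", "13", "23"))
    return(list(nb = nb, n = scale, b = stats::setNames(as.numeric(b), c("12", "13", "23"))))
  }
  stats <- nb_statistics(cfn_counts(b))
  list(nb = as.numeric(stats$nb), n = as.numeric(stats$n),
       b = stats::setNames(stats$b$b, stats$b$pair))
}

#' @export
print.cfn_region <- function(x, ...) {
  cat("B ", if (x$in_d) "lies in" else "is outside", " the interior region D\n", sep = "")
  if (length(x$failed)) cat("  violated:", paste(x$failed, collapse = "; "), "\n")
  invisible(x)
}

#' Interior maximum likelihood estimate
#'
#' When \eqn{B \in \mathcal{D}} the likelihood has a unique maximizer strictly
#' inside the cube, given in closed form by
#' \deqn{\theta^* = \left(\sqrt{B_{12}B_{13}/B_{23}},\,
#'   \sqrt{B_{12}B_{23}/B_{13}},\, \sqrt{B_{13}B_{23}/B_{12}}\right),}
#' the inverse of the monomial map
#' \eqn{\theta \mapsto (\theta_1\theta_2, \theta_1\theta_3, \theta_2\theta_3)}
#' evaluated at the data: the fitted pairwise covariances reproduce the
#' observed ones exactly.
#'
#' @inheritParams in_region_d
#' @return Numeric vector of three Hadamard parameters in \eqn{(0,1)^3}.
#' @examples
#' interior_mle(c(0.1, 0.3, 0.2))
#' @export
interior_mle <- function(b) {
  v <- as_b_triple(b)
  region <- in_region_d(b)
  if (!region$in_d) {
    stop(sprintf(
      "B is outside the interior region D (violated: %s); use cfn_mle() for the boundary solution.",
      paste(region$failed, collapse = "; ")), call. = FALSE)
  }
  bb <- v$b
  c(sqrt(bb[["12"]] * bb[["13"]] / bb[["23"]]),
    sqrt(bb[["12"]] * bb[["23"]] / bb[["13"]]),
    sqrt(bb[["13"]] * bb[["23"]] / bb[["12"]]))
}

# Closed-form maximal log-likelihood of each regime.  Both printed forms of
# the boundary values are computed and asserted equal before returning.
boundary_loglik <- function(regime, b_tbl, n, sbar = NULL,
                            face_pairs = NULL, curve_pair = NULL) {
  bmap <- stats::setNames(seq_len(3L), b_tbl$pair)
  row <- function(pair) b_tbl[bmap[[pair]], ]
  switch(regime,
    interior = {
      if (any(sbar <= 0L)) stop("Interior value needs all split classes observed.",
                                call. = FALSE)
      sum(sbar * log(sbar / n)) - n * log(2)
    },
    face_theta_one = {
      vals <- vapply(face_pairs, function(p) {
        r <- row(p)
        if (r$m_plus == 0L || r$m_minus == 0L) {
          stop("Degenerate agreement counts (A.1 violated).", call. = FALSE)
        }
        c(direct = r$m_plus * log(1 + r$b) + r$m_minus * log(1 - r$b),
          compact = r$m_plus * log(r$m_plus / (sqrt(2) * n)) +
                    r$m_minus * log(r$m_minus / (sqrt(2) * n)))
      }, numeric(2))
      value <- sum(vals["compact", ])
      alt <- -n * log(8) + sum(vals["direct", ])  # the two printed forms agree
      stopifnot(abs(value - alt) < 1e-9 * max(1, abs(value)))
      value
    },
    curve_theta_zero = {
      r <- row(curve_pair)
      if (r$m_plus == 0L || r$m_minus == 0L) {
        stop("Degenerate agreement counts (A.1 violated).", call. = FALSE)
      }
      value <- r$m_plus * log(r$m_plus / (4 * n)) +
               r$m_minus * log(r$m_minus / (4 * n))
      alt <- r$m_plus * log(1 + r$b) + r$m_minus * log(1 - r$b) - n * log(8)
      stopifnot(abs(value - alt) < 1e-9 * max(1, abs(value)))
      value
    },
    independence_union = -n * log(8),
    stop("Unknown regime: ", regime, call. = FALSE))
}

#' Closed-form global maximum likelihood estimate for a three-leaf CFN tree
#'
#' Computes the full maximizer set of the CFN log-likelihood over the closed
#' cube \eqn{[0,1]^3} from observed pattern counts, in closed form.  Writing
#' \eqn{B_{\pi_1} < B_{\pi_2} < B_{\pi_3}} for the sorted pair correlations,
#' exactly one of four regimes applies:
#'
#' * `interior` — \eqn{B \in \mathcal{D}}: the unique maximizer of
#'   [interior_mle()]; all branch lengths positive and finite.
#' * `face_theta_one` — \eqn{B \notin \mathcal{D}} but \eqn{B_{\pi_2} > 0}: a
#'   singleton with the branch opposite the two largest correlations pinned
#'   to length zero (\eqn{\theta = 1}) and the remaining coordinates equal to
#'   their pair correlation with that leaf.
#' * `curve_theta_zero` — \eqn{B_{\pi_2} < 0 < B_{\pi_3}}: a one-dimensional
#'   maximizer set with one branch infinitely long (\eqn{\theta = 0}) and the
#'   two free coordinates constrained only through their product
#'   \eqn{\theta_i\theta_j = B_{\pi_3}} (reported representative: the
#'   balanced point \eqn{\sqrt{B_{\pi_3}}} on both).
#' * `independence_union` — \eqn{B_{\pi_3} < 0}: all pairs negatively
#'   correlated; the maximizers are every parameter vector with at least two
#'   coordinates zero (complete independence), with log-likelihood
#'   \eqn{-N\log 8}.
#'
#' All regime decisions (signs, sorting, region membership) are made in exact
#' integer arithmetic on \eqn{N B_{ij}}.  The solver refuses data violating
#' the genericity assumptions A.1/A.2 (see [check_genericity()]) unless
#' `force_numeric = TRUE`, in which case the numerical oracle
#' [cfn_numeric_oracle()] is run instead and its point estimate returned with
#' regime `"numeric"` — outside A.1/A.2 the closed-form theory does not
#' apply, and no set structure is claimed.
#'
#' @inheritParams cfn_loglik
#' @param force_numeric Fall back to the numerical oracle when genericity
#'   fails instead of raising an error.
#' @param seed Seed forwarded to the oracle in the `force_numeric` path.
#' @return An object of class `"cfn_mle"`: a list with elements `regime`,
#'   `theta` (representative point), `constraints` (tibble describing the
#'   maximizer set: one row per coordinate plus any product constraint),
#'   `loglik`, `b` (the [b_statistics()] tibble), `sbar`, `n`, `sorted`
#'   (pairs in increasing B order with their permutation labels), `region`,
#'   and `genericity`.  Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @examples
#' fit <- cfn_mle(c(21, 12, 9, 8, 7, 11, 17, 15))
#' fit
#' tidy(fit)
#' @export
cfn_mle <- function(counts, force_numeric = FALSE, seed = NULL) {
  s <- cfn_counts(counts)
  n <- sum(s)
  gen <- check_genericity(s)
  stats <- nb_statistics(s)
  b_tbl <- stats$b
  if (!gen$a1_holds || !gen$a2_holds) {
    if (!force_numeric) {
      stop(structure(class = c("cfn3_genericity_error", "error", "condition"),
        list(message = paste0(
          "Data violate the genericity assumptions of the closed-form solver:\n  - ",
          paste(gen$violations, collapse = "\n  - "),
          "\nUse force_numeric = TRUE for a numerical point estimate."),
          call = sys.call(-1), genericity = gen)))
    }
    oracle <- cfn_numeric_oracle(s, seed = seed)
    out <- list(regime = "numeric", theta = oracle$best_theta,
                constraints = tibble::tibble(
                  coordinate = paste0("theta", 1:3), role = "numeric",
                  value = oracle$best_theta),
                loglik = oracle$best_loglik, b = b_tbl,
                sbar = split_collapse(s), n = n, sorted = NULL,
                region = in_region_d(b_tbl), genericity = gen, oracle = oracle)
    class(out) <- "cfn_mle"
    return(out)
  }

  nb <- stats$nb
  bvals <- stats::setNames(b_tbl$b, b_tbl$pair)
  sbar <- sbar_vector(s)
  region <- in_region_d(b_tbl)

  ord <- order(nb)  # exact: integers, distinct under A.2
  sorted_pairs <- names(nb)[ord]
  perm_of_pair <- stats::setNames(names(cfn_perm_pairs()), cfn_perm_pairs())
  sorted <- tibble::tibble(
    rank = c("pi1", "pi2", "pi3"),
    pair = sorted_pairs,
    permutation = unname(perm_of_pair[sorted_pairs]),
    b = unname(bvals[sorted_pairs]))

  if (region$in_d) {
    regime <- "interior"
    theta <- unname(interior_mle(b_tbl))
    constraints <- tibble::tibble(
      coordinate = paste0("theta", 1:3), role = "fixed", value = theta)
    loglik <- boundary_loglik("interior", b_tbl, n, sbar = sbar)
  } else if (nb[[sorted_pairs[2]]] > 0) {
    regime <- "face_theta_one"
    min_pair <- sorted_pairs[1]
    k <- cfn_other_leaf(min_pair)      # leaf pinned to theta = 1
    ij <- cfn_pairs()[[min_pair]]
    theta <- numeric(3)
    theta[k] <- 1
    theta[ij[1]] <- bvals[[pair_label(ij[1], k)]]
    theta[ij[2]] <- bvals[[pair_label(ij[2], k)]]
    constraints <- tibble::tibble(
      coordinate = paste0("theta", 1:3), role = "fixed", value = theta)
    loglik <- boundary_loglik("face_theta_one", b_tbl, n,
                              face_pairs = c(pair_label(ij[1], k),
                                             pair_label(ij[2], k)))
  } else if (nb[[sorted_pairs[3]]] > 0) {
    regime <- "curve_theta_zero"
    max_pair <- sorted_pairs[3]
    k <- cfn_other_leaf(max_pair)      # leaf pinned to theta = 0
    ij <- cfn_pairs()[[max_pair]]
    bmax <- bvals[[max_pair]]
    theta <- numeric(3)
    theta[ij] <- sqrt(bmax)
    constraints <- tibble::tibble(
      coordinate = c(paste0("theta", 1:3),
                     sprintf("theta%d*theta%d", ij[1], ij[2])),
      role = c(ifelse(seq_len(3) == k, "fixed", "free"), "product"),
      value = c(ifelse(seq_len(3) == k, 0, NA_real_), bmax))
    loglik <- boundary_loglik("curve_theta_zero", b_tbl, n, curve_pair = max_pair)
  } else {
    regime <- "independence_union"
    theta <- c(0, 0, 0)
    constraints <- tibble::tibble(
      coordinate = paste0("theta", 1:3),
      role = "independence",
      value = NA_real_)
    loglik <- boundary_loglik("independence_union", b_tbl, n)
  }

  direct <- cfn_loglik(theta, s)
  if (!isTRUE(abs(direct - loglik) <= 1e-9 * max(1, abs(loglik)))) {
    stop(sprintf(
      "Internal inconsistency: closed-form value %.12g differs from direct evaluation %.12g.",
      loglik, direct), call. = FALSE)
  }

  out <- list(regime = regime, theta = theta, constraints = constraints,
              loglik = loglik, b = b_tbl, sbar = split_collapse(s), n = n,
              sorted = sorted, region = region, genericity = gen)
  class(out) <- "cfn_mle"
  out
}

pair_label <- function(i, j) paste0(min(i, j), max(i, j))

#' @export
print.cfn_mle <- function(x, ...) {
  cat("Three-leaf CFN maximum likelihood estimate\n")
  cat("  N =", x$n, "sites;  regime:", x$regime, "\n")
  b <- x$b
  cat(sprintf("  B statistics: B12 = %g, B13 = %g, B23 = %g\n",
              b$b[1], b$b[2], b$b[3]))
  cat("  theta (representative):", paste(signif(x$theta, 6), collapse = ", "), "\n")
  d <- lengths_from_theta(x$theta)
  cat("  branch lengths:", paste(signif(d, 6), collapse = ", "), "\n")
  if (x$regime == "curve_theta_zero") {
    pr <- x$constraints[x$constraints$role == "product", ]
    cat(sprintf("  maximizer set: %s = %g with one coordinate pinned to 0\n",
                pr$coordinate, pr$value))
  }
  if (x$regime == "independence_union") {
    cat("  maximizer set: every theta with at least two coordinates equal to 0\n")
  }
  cat("  log-likelihood:", format(x$loglik, digits = 10), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a three-leaf CFN fit
#'
#' One row per Hadamard coordinate with its estimate, role in the maximizer
#' set (`fixed`, `free`, `independence`, or `numeric`), and implied branch
#' length.
#'
#' @param x A [cfn_mle()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `role`, `branch_length`.
#' @export
tidy.cfn_mle <- function(x, ...) {
  role <- x$constraints$role[seq_len(3L)]
  tibble::tibble(
    term = paste0("theta", 1:3),
    estimate = x$theta,
    role = role,
    branch_length = lengths_from_theta(x$theta))
}

#' Glance at a three-leaf CFN fit
#'
#' @inheritParams tidy.cfn_mle
#' @return A one-row tibble with columns `regime`, `logLik`, `nobs`,
#'   `interior`, and `df_free` (dimension of the maximizer set).
#' @export
glance.cfn_mle <- function(x, ...) {
  tibble::tibble(
    regime = x$regime,
    logLik = x$loglik,
    nobs = x$n,
    interior = identical(x$regime, "interior"),
    df_free = sum(x$constraints$role == "free") -
      as.integer(any(x$constraints$role == "product")))
}

#' Plot observed versus fitted split-class frequencies
#'
#' Compares the observed relative frequency of each split class with the
#' fitted probability at the representative maximizer — a quick visual check
#' of model fit and of what the boundary regimes imply for the data.
#'
#' @param object A [cfn_mle()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cfn_mle <- function(object, ...) {
  fitted <- pbar_from_theta(object$theta)
  df <- tibble::tibble(
    split = factor(rep(cfn_split_labels(), 2L), levels = cfn_split_labels()),
    frequency = c(object$sbar$count / object$n, fitted),
    source = rep(c("observed", "fitted"), each = 4L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$split, y = .data$frequency,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "split class", y = "relative frequency",
                  title = sprintf("CFN fit (%s regime)", object$regime)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Serialize a CFN fit to JSON
#'
#' @param x A [cfn_mle()] object.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string; infinite branch lengths are rendered as `"inf"`.
#' @export
cfn_mle_json <- function(x, pretty = TRUE) {
  stopifnot(inherits(x, "cfn_mle"))
  d <- lengths_from_theta(x$theta)
  payload <- list(
    regime = x$regime,
    theta = x$theta,
    branch_lengths = ifelse(is.finite(d), d, "inf"),
    constraints = x$constraints,
    loglik = x$loglik,
    B = stats::setNames(as.list(x$b$b), paste0("B", x$b$pair)),
    genericity = list(a1_holds = x$genericity$a1_holds,
                      a2_holds = x$genericity$a2_holds,
                      violations = x$genericity$violations),
    n = x$n)
  jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = pretty, digits = NA,
                   dataframe = "rows")
}
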