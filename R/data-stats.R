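#' Construct and validate a site-frequency vector
#'
#' The sufficient data summary for three aligned binary sequences: the counts
#' \eqn{s_\sigma} of the eight leaf-state patterns
#' \eqn{\sigma \in \{-1,+1\}^3}, in binary order `"---"`, `"--+"`, ...,
#' `"+++"`.
#'
#' @param x One of: a numeric vector of eight nonnegative integer counts; a
#'   data frame with a `count` column (and optionally a `pattern` column in
#'   the fixed order); or an existing `cfn_counts` object.
#' @return A named integer vector of length 8 with class `"cfn_counts"`.
#' @examples
#' cfn_counts(c(17, 5, 27, 5, 16, 5, 19, 6))
#' @export
cfn_counts <- function(x) {
  if (inherits(x, "cfn_counts")) return(x)
  if (is.data.frame(x)) {
    if (!"count" %in% names(x)) {
      stop("A data-frame input must have a `count` column.", call. = FALSE)
    }
    if ("pattern" %in% names(x)) {
      idx <- match(cfn_pattern_labels(), x$pattern)
      if (anyNA(idx)) {
        stop("`pattern` column must contain the eight patterns \"---\" ... \"+++\".",
             call. = FALSE)
      }
      x <- x$count[idx]
    } else {
      x <- x$count
    }
  }
  if (!is.numeric(x)) {
    stop("Counts must be numeric.", call. = FALSE)
  }
  if (length(x) != 8L) {
    stop(sprintf("Expected 8 pattern counts, got %d.", length(x)), call. = FALSE)
  }
  bad <- which(is.na(x) | x < 0 | x != round(x))
  if (length(bad)) {
    stop(sprintf("Counts must be nonnegative integers; offending entries: %s (pattern %s).",
                 paste(x[bad], collapse = ", "),
                 paste(cfn_pattern_labels()[bad], collapse = ", ")), call. = FALSE)
  }
  s <- as.integer(round(x))
  names(s) <- cfn_pattern_labels()
  class(s) <- "cfn_counts"
  s
}

#' @export
print.cfn_counts <- function(x, ...) {
  cat("CFN site-frequency vector (N =", sum(x), "sites)\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Read a site-frequency vector from text, JSON, or a file
#'
#' Accepts eight nonnegative integers as a comma/whitespace separated string,
#' a JSON array or `{"counts": [...]}` object, a path to a file containing
#' either, or a bare numeric vector.
#'
#' @param source Character scalar (inline text, JSON, or file path) or a
#'   numeric vector of eight counts.
#' @return A [cfn_counts] object.
#' @examples
#' read_counts("17,5,27,5,16,5,19,6")
#' read_counts('{"counts": [21, 12, 9, 8, 7, 11, 17, 15]}')
#' @export
read_counts <- function(source) {
  if (is.numeric(source) || is.data.frame(source) || inherits(source, "cfn_counts")) {
    return(cfn_counts(source))
  }
  if (!is.character(source) || length(source) != 1L) {
    stop("`source` must be a numeric vector or a single character string.",
         call. = FALSE)
  }
  text <- if (file.exists(source) && !grepl("[,{\\[]", source)) {
    paste(readLines(source, warn = FALSE), collapse = " ")
  } else {
    source
  }
  text <- trimws(text)
  if (grepl("^[\\[{]", text)) {
    parsed <- tryCatch(jsonlite::fromJSON(text),
                       error = function(e) stop("Could not parse JSON counts: ",
                                                conditionMessage(e), call. = FALSE))
    if (is.list(parsed) && !is.null(parsed$counts)) parsed <- parsed$counts
    return(cfn_counts(as.numeric(unlist(parsed))))
  }
  fields <- strsplit(text, "[,;[:space:]]+")[[1]]
  fields <- fields[nzchar(fields)]
  vals <- suppressWarnings(as.numeric(fields))
  if (anyNA(vals)) {
    stop(sprintf("Non-numeric count field(s): %s.",
                 paste(fields[is.na(vals)], collapse = ", ")), call. = FALSE)
  }
  cfn_counts(vals)
}

#' Read a 3-sequence alignment and tally site patterns
#'
#' Reads a FASTA file with exactly three equal-length sequences over a binary
#' alphabet and tallies the eight column patterns.  Recognized alphabets
#' (auto-detected per character): purine/pyrimidine codes `R`/`Y`, raw DNA
#' (`A`,`G` are purines, mapped to \eqn{-1}; `C`,`T`,`U` pyrimidines, mapped
#' to \eqn{+1}), binary `0`/`1`, and sign characters `-`/`+`.
#'
#' @param path Path to a FASTA file with exactly three records.
#' @param ambiguous Policy for columns containing unrecognized characters
#'   (gaps, `N`, ...): `"drop"` (default) removes the column with a message,
#'   `"error"` aborts.
#' @return A [cfn_counts] object; the number of dropped columns is attached
#'   as attribute `"dropped"`.
#' @export
read_alignment <- function(path, ambiguous = c("drop", "error")) {
  ambiguous <- match.arg(ambiguous)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 3L) {
    stop(sprintf("Expected exactly 3 sequences, found %d in %s.",
                 length(seqs), path), call. = FALSE)
  }
  if (length(unique(Biostrings::width(seqs))) != 1L) {
    stop("Sequences must be aligned (equal lengths).", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  purine <- c("A", "G", "R", "0", "-")
  pyrimidine <- c("C", "T", "U", "Y", "1", "+")
  code <- matrix(NA_integer_, nrow(chars), ncol(chars))
  code[chars %in% purine] <- -1L
  code[chars %in% pyrimidine] <- +1L
  ok <- colSums(is.na(code)) == 0L
  if (any(!ok)) {
    if (ambiguous == "error") {
      stop(sprintf("%d column(s) contain unrecognized characters.", sum(!ok)),
           call. = FALSE)
    }
    message(sprintf("Dropped %d column(s) with ambiguous or gap characters.",
                    sum(!ok)))
  }
  code <- code[, ok, drop = FALSE]
  if (ncol(code) == 0L) {
    stop("No usable alignment columns remain.", call. = FALSE)
  }
  sig <- cfn_sigma_matrix()
  idx <- apply(code, 2L, function(col) {
    which(sig[, 1] == col[1] & sig[, 2] == col[2] & sig[, 3] == col[3])
  })
  s <- tabulate(idx, nbins = 8L)
  out <- cfn_counts(s)
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Collapse a site-frequency vector to split-class counts
#'
#' Pools each pattern with its global sign flip, giving the four split-class
#' counts \eqn{\bar s_\alpha} for
#' \eqn{\alpha \in \{\emptyset, \{1\}, \{2\}, \{1,2\}\}}.  This 4-vector is a
#' sufficient statistic for the CFN likelihood.
#'
#' @param counts Anything accepted by [cfn_counts()].
#' @return A tibble with columns `split` and `count`; counts sum to the total
#'   number of sites.
#' @examples
#' split_collapse(c(17, 5, 27, 5, 16, 5, 19, 6))
#' @export
split_collapse <- function(counts) {
  s <- cfn_counts(counts)
  sbar <- as.integer(rowsum(as.integer(s), cfn_split_index()))
  tibble::tibble(split = cfn_split_labels(), count = sbar)
}

# internal: plain integer sbar in split order
sbar_vector <- function(counts) {
  s <- cfn_counts(counts)
  as.integer(rowsum(as.integer(s), cfn_split_index()))
}

#' Leaf-pair agreement statistics B
#'
#' For each leaf pair \eqn{(i,j)}, `m_plus` counts the sites where leaves
#' \eqn{i} and \eqn{j} agree, `m_minus` the sites where they differ, and
#' \eqn{B_{ij} = (M^+_{ij} - M^-_{ij})/N} is the empirical state correlation
#' — a consistent estimator of the Fourier coordinate \eqn{\theta_i\theta_j}.
#' The triple \eqn{(B_{12}, B_{13}, B_{23})} drives the closed-form maximum
#' likelihood solution.
#'
#' Two algebraically equivalent routes are computed — the direct sum over
#' patterns with \eqn{\sigma_i\sigma_j = \pm 1} and the signed combination of
#' split-class counts — and checked for exact agreement.
#'
#' @param counts Anything accepted by [cfn_counts()]; the total site count
#'   must be positive.
#' @return A tibble with columns `pair` (`"12"`, `"13"`, `"23"`), `m_plus`,
#'   `m_minus` (integers), and `b`.
#' @examples
#' b_statistics(c(17, 5, 27, 5, 16, 5, 19, 6))
#' @export
b_statistics <- function(counts) {
  s <- cfn_counts(counts)
  n <- sum(s)
  if (n == 0L) {
    stop("Empty data: the site-frequency vector sums to zero.", call. = FALSE)
  }
  sig <- cfn_sigma_matrix()
  pairs <- cfn_pairs()
  m_plus <- vapply(pairs, function(ij) {
    sum(s[sig[, ij[1]] * sig[, ij[2]] == 1L])
  }, integer(1))
  m_minus <- n - m_plus
  # Eq.-20 route from the split collapse; must agree exactly on integers
  sbar <- sbar_vector(s)
  nb_from_sbar <- as.integer(t(cfn_split_signs()) %*% sbar)
  stopifnot(identical(as.integer(m_plus - m_minus), nb_from_sbar))
  tibble::tibble(
    pair = names(pairs),
    m_plus = as.integer(m_plus),
    m_minus = as.integer(m_minus),
    b = (m_plus - m_minus) / n)
}

# internal: integer N*B values named by pair, plus N
nb_statistics <- function(counts) {
  b <- b_statistics(counts)
  list(nb = stats::setNames(b$m_plus - b$m_minus, b$pair),
       n = b$m_plus[1] + b$m_minus[1], b = b)
}

#' Genericity diagnostics for observed data
#'
#' The closed-form solver requires two genericity assumptions:
#' (A.1) every split class is observed at least once
#' (\eqn{\bar s_\alpha > 0} for all four \eqn{\alpha}), which guarantees all
#' \eqn{M^\pm_{ij} \in (0, N)} and keeps every boundary log-likelihood finite;
#' and (A.2) the three pair correlations \eqn{B_{12}, B_{13}, B_{23}} are
#' nonzero and pairwise distinct.  A.2 is evaluated in exact integer
#' arithmetic on the values \eqn{N B_{ij}} so that ties are detected without
#' floating-point comparisons.
#'
#' @inheritParams split_collapse
#' @return An object of class `"cfn_genericity"`: a list with logical flags
#'   `a1_holds`, `a2_holds` and a character vector `violations`.
#' @examples
#' check_genericity(c(17, 5, 27, 5, 16, 5, 19, 6))
#' @export
check_genericity <- function(counts) {
  s <- cfn_counts(counts)
  sbar <- sbar_vector(s)
  violations <- character()
  a1 <- all(sbar > 0L)
  if (!a1) {
    violations <- c(violations,
      sprintf("split class(es) %s unobserved (A.1)",
              paste(cfn_split_labels()[sbar == 0L], collapse = ", ")))
  }
  nb <- nb_statistics(s)$nb
  zero <- names(nb)[nb == 0]
  if (length(zero)) {
    violations <- c(violations,
      sprintf("B_%s equal to zero (A.2)", paste(zero, collapse = ", B_")))
  }
  ties <- list(c("12", "13"), c("13", "23"), c("12", "23"))
  for (tie in ties) {
    if (nb[[tie[1]]] == nb[[tie[2]]]) {
      violations <- c(violations,
        sprintf("B_%s and B_%s tied (A.2)", tie[1], tie[2]))
    }
  }
  a2 <- !length(zero) && !any(vapply(ties, function(tie)
    nb[[tie[1]]] == nb[[tie[2]]], logical(1)))
  structure(list(a1_holds = a1, a2_holds = a2, violations = violations),
            class = "cfn_genericity")
}

#' @export
print.cfn_genericity <- function(x, ...) {
  cat("CFN genericity diagnostics\n")
  cat("  A.1 (all split classes observed):", if (x$a1_holds) "holds" else "VIOLATED", "\n")
  cat("  A.2 (B statistics nonzero and distinct):",
      if (x$a2_holds) "holds" else "VIOLATED", "\n")
  for (v in x$violations) cat("  -", v, "\n")
  invisible(x)
}

#' Pairwise CFN distance estimates
#'
#' The method-of-moments distance estimate for each leaf pair,
#' \eqn{\tilde D_{ij} = -\tfrac{1}{2} \log B_{ij}}, the CFN analogue of the
#' Jukes-Cantor distance correction, with the convention
#' \eqn{\tilde D_{ij} = \infty} when \eqn{B_{ij} \le 0} (the observed
#' divergence is at or beyond saturation).
#'
#' @param x Anything accepted by [cfn_counts()], or a tibble as returned by
#'   [b_statistics()].
#' @return A tibble with columns `pair`, `b`, and `distance` (expected
#'   substitutions per site; may be `Inf`).
#' @examples
#' cfn_distances(c(17, 5, 27, 5, 16, 5, 19, 6))
#' @export
cfn_distances <- function(x) {
  b <- if (is.data.frame(x) && all(c("pair", "b") %in% names(x))) {
    x
  } else {
    b_statistics(x)
  }
  d <- rep(Inf, nrow(b))
  d[b$b > 0] <- -0.5 * log(b$b[b$b > 0])
  b |>
    dplyr::transmute(pair = .data$pair, b = .data$b, distance = d)
}
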