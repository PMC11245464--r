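# Internal bookkeeping for site patterns and split classes on three leaves.
#
# Patterns are ordered by binary counting with -1 before +1:
#   (-,-,-), (-,-,+), (-,+,-), (-,+,+), (+,-,-), (+,-,+), (+,+,-), (+,+,+).
# Split classes are ordered lexicographically: {}, {1}, {2}, {1,2}.  A pattern
# sigma belongs to split class alpha = { i in {1,2} : sigma_i != sigma_3 }, so
# each class contains a pattern and its global sign flip.

cfn_sigma_matrix <- function() {
  m <- matrix(c(
    -1L, -1L, -1L,
    -1L, -1L, +1L,
    -1L, +1L, -1L,
    -1L, +1L, +1L,
    +1L, -1L, -1L,
    +1L, -1L, +1L,
    +1L, +1L, -1L,
    +1L, +1L, +1L), ncol = 3L, byrow = TRUE)
  colnames(m) <- c("leaf1", "leaf2", "leaf3")
  m
}

cfn_pattern_labels <- function() {
  apply(cfn_sigma_matrix(), 1L, function(s) {
    paste(ifelse(s > 0, "+", "-"), collapse = "")
  })
}

cfn_split_labels <- function() c("{}", "{1}", "{2}", "{1,2}")

# index (into the split order) of the split class of each of the 8 patterns
cfn_split_index <- function() {
  s <- cfn_sigma_matrix()
  apply(s, 1L, function(row) {
    alpha <- unname(which(row[1:2] != row[3]))
    if (length(alpha) == 0L) 1L
    else if (identical(alpha, 1L)) 2L
    else if (identical(alpha, 2L)) 3L
    else 4L
  })
}

cfn_pairs <- function() list(`12` = c(1L, 2L), `13` = c(1L, 3L), `23` = c(2L, 3L))

# Sign of pair {i,j} in split class alpha: (-1)^{|{i,j} n alpha|}.
# Rows follow the split order, columns the pair order (12, 13, 23).
cfn_split_signs <- function() {
  matrix(c(
    +1, +1, +1,
    -1, -1, +1,
    -1, +1, -1,
    +1, -1, -1), ncol = 3L, byrow = TRUE,
    dimnames = list(cfn_split_labels(), c("12", "13", "23")))
}

# Leaf pair addressed by each element of Alt(3) = {(1), (123), (132)}:
# pi maps to the pair (pi(1), pi(2)).
cfn_perm_pairs <- function() {
  c(`(1)` = "12", `(123)` = "23", `(132)` = "13")
}

# The leaf excluded from a pair, e.g. "12" -> 3
cfn_other_leaf <- function(pair) {
  c(`12` = 3L, `13` = 2L, `23` = 1L)[[pair]]
}

assert_theta <- function(theta, arg = "theta") {
  if (!is.numeric(theta) || length(theta) != 3L || anyNA(theta)) {
    stop(sprintf("`%s` must be a numeric vector of three values in [0, 1].", arg),
         call. = FALSE)
  }
  if (any(theta < 0) || any(theta > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]^3 (got %s).", arg,
                 paste(signif(theta, 6), collapse = ", ")), call. = FALSE)
  }
  as.numeric(theta)
}
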