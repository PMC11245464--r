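---
title: "Analytic maximum likelihood for three-leaf trees under the CFN model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic maximum likelihood for three-leaf trees under the CFN model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfn3)
```

## The model

The Cavender–Farris–Neyman (CFN) model is the two-state symmetric Markov
model of site substitution on a tree: states are $\pm 1$ (purine /
pyrimidine), the root state is uniform, and along an edge $e$ of length
$d_e$ (expected substitutions per site) a state is preserved with
probability $\tfrac12(1 + \theta_e)$, where
$\theta_e = e^{-2 d_e} \in [0,1]$ is the *Hadamard parameter* of the edge —
the correlation of the states at its endpoints. For the unrooted three-leaf
tree (a star with one internal vertex) the leaf-state vector
$X \in \{-1,+1\}^3$ has distribution

$$
P[X = \sigma] \;=\; \tfrac18\bigl(1 + \sigma_1\sigma_2\,\theta_1\theta_2
 + \sigma_1\sigma_3\,\theta_1\theta_3 + \sigma_2\sigma_3\,\theta_2\theta_3\bigr).
$$

Because $P[X=\sigma] = P[X=-\sigma]$, the eight patterns collapse to four
*split classes* $\{\emptyset, \{1\}, \{2\}, \{1,2\}\}$ (a pattern belongs
to the class of leaves in $\{1,2\}$ that disagree with leaf 3), and the
split-class counts $\bar s_\alpha$ of an $N$-column alignment are a
sufficient statistic. Two classical change-of-coordinate tools are
implemented alongside the polynomial form: *Hadamard conjugation*
$\bar p = H^{-1}\exp(H\gamma)$ mapping the edge spectrum
$\gamma = (-(d_1{+}d_2{+}d_3), d_1, d_2, d_3)$ to the split-class
probabilities, and the *Fourier coordinates* $q = H_2\,\bar p =
(1, \theta_1\theta_3, \theta_2\theta_3, \theta_1\theta_2)$, the pairwise
covariances of the leaf states. Deliberately *not* assumed here is the
usual restriction $\theta \in (0,1)^3$: the closed cube $[0,1]^3$ is kept,
so zero-length and infinitely long branches are legal parameter values and
a global likelihood maximizer always exists.

## Sufficient statistics and genericity

For each leaf pair, $M^\pm_{ij}$ count agreeing/disagreeing sites and
$B_{ij} = (M^+_{ij} - M^-_{ij})/N$ is the empirical state correlation, a
consistent estimator of $\theta_i\theta_j$. Two mild assumptions make the
closed-form solution valid:

* **A.1** — every split class is observed ($\bar s_\alpha > 0$), which
  keeps all boundary log-likelihood formulas finite;
* **A.2** — the three $B_{ij}$ are nonzero and pairwise distinct.

Both are checked by `check_genericity()`. A.2 is decided on the integers
$N B_{ij} = M^+_{ij} - M^-_{ij}$, never by floating-point comparison, so
exact ties are detected reliably. When either assumption fails the solver
refuses (the theory does not cover that stratum and we do not guess its
set structure); `force_numeric = TRUE` substitutes the numerical oracle's
point estimate, flagged with regime `"numeric"`.

## The closed-form solution

Let $B_{\pi_1} < B_{\pi_2} < B_{\pi_3}$ be the sorted pair correlations and
$\mathcal D$ the open region where all $B_{ij} \in (0,1)$ and
$B_iB_j < B_k$ for every labeling — the empirical counterpart of the
model's semi-algebraic constraints, equivalently the triangle inequality on
the pairwise distance estimates $-\tfrac12\log B_{ij}$. The global
maximizer set over $[0,1]^3$ falls into exactly one of four regimes:

1. **interior** ($B \in \mathcal D$): the unique maximizer
   $\theta^* = \bigl(\sqrt{B_{12}B_{13}/B_{23}},
   \sqrt{B_{12}B_{23}/B_{13}}, \sqrt{B_{13}B_{23}/B_{12}}\bigr)$, the
   inverse of the monomial map $\theta \mapsto (\theta_1\theta_2,
   \theta_1\theta_3, \theta_2\theta_3)$ at the data; its value is the
   entropy-like form $\sum_\alpha \bar s_\alpha\log(\bar s_\alpha/N) -
   N\log 2$.
2. **face_theta_one** ($B \notin \mathcal D$, $B_{\pi_2} > 0$): a
   singleton; the leaf opposite the smallest correlation has its branch
   pinned to length zero ($\theta = 1$) and the other two coordinates equal
   their correlation with that leaf.
3. **curve_theta_zero** ($B_{\pi_2} < 0 < B_{\pi_3}$): the leaf outside
   the only positive pair gets an infinite branch ($\theta = 0$), and the
   two remaining parameters are identified only through their product
   $\theta_i\theta_j = B_{\pi_3}$ — a one-dimensional maximizer set. The
   reported representative is the balanced point
   $(\sqrt{B_{\pi_3}}, \sqrt{B_{\pi_3}})$.
4. **independence_union** ($B_{\pi_3} < 0$): every parameter vector with
   at least two coordinates zero maximizes the likelihood, all with value
   $-N\log 8$.

`cfn_mle()` returns the regime, a representative point, a constraints
table describing the full maximizer set, and the maximal log-likelihood
(natural log). Every regime decision — signs, sorting, membership in
$\mathcal D$ — is branched on integer quantities ($N B_{ij}$, and
$NB_i \cdot NB_j$ vs $N \cdot NB_k$; exact in doubles far beyond any
realistic $N$), so the classification is never float-dependent. As an
internal invariant, the closed-form value is re-checked against a direct
likelihood evaluation at the representative point to a relative $10^{-9}$
before the fit is returned.

```{r}
fit <- cfn_mle(c(17, 5, 27, 5, 16, 5, 19, 6))
fit
glance(fit)
```

## Direct likelihood evaluation and the numerical oracle

`cfn_loglik()` evaluates
$\ell(\theta) = \sum_\alpha \bar s_\alpha \log \bar p_\alpha(\theta) -
N\log 2$ with the conventions required for the closed cube: a split class
with positive count and zero probability makes $\ell = -\infty$ (a value,
not an error; $\ell$ is upper semicontinuous), and under A.1 no
$0\cdot\log 0$ terms can arise.

The solver is validated against `cfn_numeric_oracle()`, a deliberately
independent maximizer: a dense grid scan over $[0,1]^3$ (`grid_n = 11`
points per axis, boundary included) followed by bounded L-BFGS-B
refinement with the analytic gradient from the eight best grid points and
from random interior restarts, plus two-dimensional refinements on each of
the six faces of the cube. The face refinements matter: the full
three-dimensional ascent can stall on the flat independence saddle at the
origin when the true maximum sits on a narrow ridge of a face, and the
likelihood surface is exactly flat along the curve-regime maximizer set,
so oracle agreement is asserted in *value* ($10^{-6}$) and in distance to
the maximizer *set* ($10^{-3}$), not pointwise.

## The simulator

`simulate_cfn()` draws i.i.d. sites by the generative recipe: a uniform
root state at the internal vertex, then each leaf copies it with
probability $(1+\theta_i)/2$. Draws are vectorized in a fixed documented
order (root states for all sites, then flip draws for leaves 1, 2, 3) with
an explicit seed, so streams are reproducible. The generator emulates
exactly the model's assumptions — independent, identically distributed
sites, no rate heterogeneity, no indels or alignment error, uniform root —
so passing recovery tests demonstrate correctness of the estimator under
the model, not robustness to real-data violations of it.

`boundary_scenario_counts()` builds deterministic fixtures landing exactly
in a requested regime by inverting
$\bar s_\alpha = \tfrac N4 (1 \pm B_{12} \pm B_{13} \pm B_{23})$ for an
integer-compatible target triple; infeasible requests (non-integer implied
counts) raise an error rather than rounding.

## Numerical choices and problem sizes

* Identity checks among the three forward-model routes (polynomial,
  Hadamard conjugation, Fourier) use absolute tolerances $10^{-10}$ to
  $10^{-12}$; all quantities are $O(1)$.
* Closed form vs direct evaluation: relative $10^{-9}$; closed form vs
  numerical oracle: $10^{-6}$ in value.
* The test suite exercises: hundreds of random parameter draws for the
  model identities; 500 random generic count vectors ($N$ between 100 and
  1000) for oracle equivalence; an exact lattice of $B$ triples (multiples
  of $1/25$ at $N = 100$) for regime exhaustiveness; and 50 simulation
  replicates at $\theta = (0.6, 0.7, 0.8)$, $N = 10^5$ for parameter
  recovery. These sizes give comfortable statistical resolution for every
  property tested while keeping the whole suite fast.
* `read_alignment()` maps DNA through the purine/pyrimidine partition
  (A, G $\mapsto -1$; C, T $\mapsto +1$) and also accepts `R`/`Y`, `0`/`1`
  and `-`/`+`; ambiguous columns are dropped with a message by default
  (policy `"error"` available). The paper-style analysis assumes clean
  binary data, so no attempt is made to impute ambiguity codes.

## Limitations

* Three leaves only: for $n \ge 4$ the likelihood equations no longer
  reduce to pairwise comparisons and closed forms of this type are not
  available; none of the solver logic generalizes as-is.
* Non-generic data (tied or zero $B$, unobserved split classes) fall
  outside the theory; the package surfaces the diagnosis and offers only a
  numerical point estimate, deliberately claiming no set structure there.
* The CFN model itself — two states, site-independence, uniform root — is
  a deliberately minimal setting chosen for exactness, not realism.
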