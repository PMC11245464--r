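# cfn3: closed-form maximum likelihood for three-leaf CFN trees

`cfn3` estimates the branch lengths of an unrooted three-leaf phylogenetic
tree from aligned binary sequence data under the Cavender–Farris–Neyman
(CFN) model — the two-state symmetric Markov substitution model with a
uniform root distribution, with states identified with purines (−1) and
pyrimidines (+1). Unlike hill-climbing likelihood software, the estimate
here is **analytic**: the global maximizer of the likelihood over the full
closed parameter cube is written down in closed form, including every
degenerate case in which the usual MLE fails to exist and branches are
driven to length zero or infinity. The package is aimed at researchers
studying the geometry of likelihood inference on trees (boundary estimates,
long-branch pathologies, semi-algebraic model constraints) and at anyone
needing exact, reproducible three-taxon estimates.

## The model and the estimator

Each edge `e` carries a branch length `d_e` (expected substitutions per
site), equivalently a Hadamard parameter `θ_e = exp(−2 d_e) ∈ [0, 1]`,
which is the correlation of the states at the endpoints of the edge
(`θ = 1`: zero-length branch; `θ = 0`: infinitely long branch). For the
three-leaf star tree the site-pattern distribution is

    P[X = σ] = (1/8) (1 + σ1σ2 θ1θ2 + σ1σ3 θ1θ3 + σ2σ3 θ2θ3),

and the data reduce to the empirical leaf-pair correlations

    B_ij = (M+_ij − M−_ij) / N,

where `M±_ij` count the sites at which leaves `i` and `j` agree/disagree.
`B_ij` estimates the Fourier coordinate `θ_i θ_j` (the covariance of the
states at leaves `i` and `j`). Writing `D` for the open region where all
`B_ij ∈ (0,1)` and `B_i B_j < B_k` for each labeling (the model's
semi-algebraic constraints — the triangle inequality on pairwise
distances in disguise), the global maximizer set is, for generic data:

| condition | maximizer | interpretation |
|---|---|---|
| `B ∈ D` | `θ* = (√(B12·B13/B23), √(B12·B23/B13), √(B13·B23/B12))` | all branches positive, finite |
| `B ∉ D`, second-largest `B > 0` | singleton with one `θ = 1` and the others equal to their `B` with that leaf | one branch estimated at length 0 |
| exactly one `B > 0` | curve `{θ_k = 0, θ_i θ_j = B_max}` | one branch infinite; only the product of the other two is identified |
| all `B < 0` | every `θ` with ≥ 2 coordinates 0 | complete independence, log-likelihood `−N log 8` |

All regime decisions are made in exact integer arithmetic on `N·B_ij`, so
no branch choice ever hinges on floating-point rounding. An independent
numerical maximizer (grid scan plus bounded quasi-Newton refinement over
the cube and its faces) is included for verification.

## Worked example

The count vector below (100 sites, pattern order `---`, `--+`, …, `+++`)
has two negatively correlated leaf pairs, so no tree with finite branch
lengths maximizes the likelihood:

```r
library(cfn3)
fit <- cfn_mle(c(17, 5, 27, 5, 16, 5, 19, 6))
fit
#> Three-leaf CFN maximum likelihood estimate
#>   N = 100 sites;  regime: curve_theta_zero
#>   B statistics: B12 = -0.06, B13 = 0.1, B23 = -0.12
#>   theta (representative): 0.316228, 0, 0.316228
#>   branch lengths: 0.575646, Inf, 0.575646
#>   maximizer set: theta1*theta3 = 0.1 with one coordinate pinned to 0
#>   log-likelihood: -207.4433175
```

The likelihood is maximized along a whole curve: leaf 2's branch is
infinitely long (`θ2 = 0`, `d2 = ∞`), and the two remaining parameters are
identified only through their product `θ1·θ3 = B13 = 0.1`. By contrast,
counts `c(21, 12, 9, 8, 7, 11, 17, 15)` have all pair correlations
positive, yet `B12·B13 = 0.036 > 0.02 = B23` violates the product
constraint, and the solver returns the unique boundary point
`θ = (1, 0.3, 0.12)` — a zero-length branch for leaf 1:

```r
tidy(cfn_mle(c(21, 12, 9, 8, 7, 11, 17, 15)))
#> # A tibble: 3 × 4
#>   term   estimate role  branch_length
#>   <chr>     <dbl> <chr>         <dbl>
#> 1 theta1     1    fixed         0
#> 2 theta2     0.3  fixed         0.602
#> 3 theta3     0.12 fixed         1.06
```

A shell front end wraps the same functions
(`Rscript inst/cli/cfn3.R estimate --counts 17,5,27,5,16,5,19,6 --json`),
with subcommands `estimate`, `distances`, `loglik`, `oracle`, `simulate`.

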