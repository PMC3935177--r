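# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths (gamma-function closed forms, Kahn's
# algorithm, C++ scoring): sequential predictive products, brute-force
# permutation checks and direct numerical integration.

# Dirichlet-multinomial marginal of an observation sequence via the chain
# rule of predictive probabilities.
dirmult_chain <- function(obs, levels, alpha = 1) {
  counts <- rep(0, levels)
  p <- 1
  for (o in obs) {
    p <- p * (alpha + counts[o + 1]) / (levels * alpha + sum(counts))
    counts[o + 1] <- counts[o + 1] + 1
  }
  p
}

# Joint marginal likelihood of two binary columns under the DAG a -> b,
# again by sequential predictives (b's counts kept per value of a).
dirmult_chain_joint <- function(a, b, alpha = 1) {
  ca <- rep(0, 2)
  cb <- matrix(0, 2, 2)  # rows: a value, cols: b value
  p <- 1
  for (t in seq_along(a)) {
    p <- p * (alpha + ca[a[t] + 1]) / (2 * alpha + sum(ca))
    p <- p * (alpha + cb[a[t] + 1, b[t] + 1]) / (2 * alpha + sum(cb[a[t] + 1, ]))
    ca[a[t] + 1] <- ca[a[t] + 1] + 1
    cb[a[t] + 1, b[t] + 1] <- cb[a[t] + 1, b[t] + 1] + 1
  }
  p
}

# Marginal likelihood of a continuous sample under Bayesian linear
# regression with a normal-inverse-gamma prior, by direct numerical
# integration over (intercept, slope, log-variance).  x = NULL drops the
# slope.  Limits are finite but generous: for the unit-scale tiny cases used
# in the tests the excluded tails are far below the asserted tolerance.
nig_marginal_numint <- function(y, x = NULL, mu = 0, mucoef = 0,
                                tau = 1, rho = 1, phi = 1) {
  dinvgamma <- function(s2) {
    a <- rho / 2; b <- phi / 2
    exp(a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2)
  }
  lik <- function(m, b, s2) {
    mu_i <- m + if (is.null(x)) 0 else b * x
    prod(stats::dnorm(y, mu_i, sqrt(s2)))
  }
  # integrate in prior-standardized coordinates (m = mu + sd * u, etc.) so
  # the integrand stays smooth across the whole variance range
  lim <- 12
  over_m <- function(b, s2) {
    sd <- sqrt(s2 / tau)
    stats::integrate(function(u) {
      vapply(u, function(uu) lik(mu + sd * uu, b, s2), numeric(1)) *
        stats::dnorm(u)
    }, -lim, lim, rel.tol = 1e-10)$value
  }
  per_s2 <- function(s2) {
    if (is.null(x)) return(over_m(0, s2) * dinvgamma(s2))
    sd <- sqrt(s2 / tau)
    fb <- function(v) {
      vapply(v, function(vv) over_m(mucoef + sd * vv, s2), numeric(1)) *
        stats::dnorm(v)
    }
    stats::integrate(fb, -lim, lim, rel.tol = 1e-9)$value * dinvgamma(s2)
  }
  # substitute s2 = exp(t) so the variance integral has finite limits
  stats::integrate(function(t) {
    vapply(t, function(tt) per_s2(exp(tt)) * exp(tt), numeric(1))
  }, -10, 10, rel.tol = 1e-8)$value
}

# Acyclicity by brute force: a digraph is acyclic iff some vertex ordering
# sends every edge forward.  Edges: two-column index matrix.
acyclic_by_permutation <- function(edges, k) {
  if (nrow(edges) == 0) return(TRUE)
  for (perm in asplit(permutations_of(k), 1)) {
    pos <- order(perm)
    if (all(pos[edges[, 1]] < pos[edges[, 2]])) return(TRUE)
  }
  FALSE
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- permutations_of(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# Count acyclic digraphs over a candidate edge list by subset enumeration.
count_acyclic_subsets <- function(cand, k) {
  m <- nrow(cand)
  n_ok <- 0
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L)
    if (acyclic_by_permutation(cand[sel, , drop = FALSE], k)) n_ok <- n_ok + 1
  }
  n_ok
}

# small helpers used across test files ---------------------------------------

# a cg_data with named genotype/expression columns from plain vectors
make_data <- function(..., phenotype = NULL, levels = 3L) {
  cols <- list(...)
  g <- cols[grepl("^L", names(cols))]
  e <- cols[grepl("^E", names(cols))]
  cg_data(
    genotypes = if (length(g)) do.call(cbind, g),
    expression = if (length(e)) do.call(cbind, e),
    phenotype = phenotype, levels = levels)
}

triplet_edges_named <- function(index, l = "L", e = "E", d = "D") {
  g <- triplet_catalog()[[index]]
  edges <- g$edges
  if (nrow(edges)) {
    map <- c(L = l, E = e, D = d)
    edges <- cbind(map[edges[, 1]], map[edges[, 2]])
  }
  edges
}
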