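# The closed-form local marginal likelihoods are checked against two
# independent oracles: sequential-predictive (chain rule) products for the
# Dirichlet-multinomial, and direct numerical integration over
# (intercept, slope, variance) for the normal-inverse-gamma form.

test_that("discrete local score matches the sequential predictive oracle", {
  d <- cg_data(genotypes = matrix(c(0, 1), ncol = 1,
                                  dimnames = list(NULL, "A")), levels = 2)
  expect_equal(local_log_marginal_discrete("A", data = d), log(1 / 6),
               tolerance = 1e-12)

  # random sequences, ternary node, various pseudo-counts
  set.seed(41)
  for (rep in 1:5) {
    obs <- sample(0:2, 7, replace = TRUE)
    alpha <- sample(c(0.5, 1, 2), 1)
    d <- cg_data(genotypes = matrix(obs, ncol = 1,
                                    dimnames = list(NULL, "A")))
    expect_equal(
      local_log_marginal_discrete("A", data = d,
                                  prior = cg_prior(dirichlet = alpha)),
      log(dirmult_chain(obs, 3, alpha)), tolerance = 1e-10)
  }
})

test_that("discrete local score is exchangeable and decomposes over parents", {
  set.seed(7)
  a <- sample(0:2, 30, replace = TRUE)
  b <- sample(0:2, 30, replace = TRUE)
  d1 <- cg_data(genotypes = cbind(A = a, B = b))
  d2 <- cg_data(genotypes = cbind(A = a, B = b)[sample(30), ])
  expect_identical(local_log_marginal_discrete("A", data = d1),
                   local_log_marginal_discrete("A", data = d2))
  expect_identical(local_log_marginal_discrete("B", "A", data = d1),
                   local_log_marginal_discrete("B", "A", data = d2))

  # conditional score = sum over the parent's configurations scored alone
  per_cfg <- vapply(0:2, function(v) {
    if (!any(a == v)) return(0)
    local_log_marginal_discrete("B", data = cg_data(
      genotypes = cbind(B = b[a == v])))
  }, numeric(1))
  expect_equal(local_log_marginal_discrete("B", "A", data = d1), sum(per_cfg),
               tolerance = 1e-10)
})

test_that("discrete predictive probabilities normalize over all sequences", {
  for (n in 2:3) {
    seqs <- as.matrix(expand.grid(rep(list(0:1), n)))
    total <- sum(apply(seqs, 1, function(s) {
      d <- cg_data(genotypes = matrix(s, ncol = 1, dimnames = list(NULL, "A")),
                   levels = 2)
      exp(local_log_marginal_discrete("A", data = d))
    }))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("continuous local score matches its closed form on the unit case", {
  d <- cg_data(expression = matrix(0, 1, 1, dimnames = list(NULL, "E1")))
  # Student-t with 1 df, location 0, squared scale phi*(1+1/tau)/rho = 2
  expect_equal(local_log_marginal_continuous("E1", data = d),
               -log(pi * sqrt(2)), tolerance = 1e-10)
  expect_equal(local_log_marginal_continuous("E1", data = d), -1.491,
               tolerance = 1e-3)
})

test_that("continuous local score agrees with numerical integration", {
  set.seed(13)
  cases <- list(
    list(y = c(0.4, -1.1), x = NULL, g = NULL),
    list(y = c(1.2, 0.3, -0.5), x = c(0.5, -1, 2), g = NULL),
    list(y = c(-0.2, 1.4, 0.8, 0.1), x = NULL, g = c(0, 1, 1, 0)),
    list(y = c(0.9, -0.7, 0.2), x = c(1.1, 0.4, -0.6), g = NULL),
    list(y = c(2.1, -0.3, 0.6, 1.0), x = c(0.2, 1.5, -0.8, 0.3),
         g = c(1, 0, 1, 0)),
    list(y = rnorm(4), x = rnorm(4), g = NULL))
  for (cs in cases) {
    pr <- cg_prior(mu = 0, tau = 1 + runif(1), rho = 0.5 + runif(1),
                   phi = 0.5 + runif(1))
    d <- cg_data(
      genotypes = if (!is.null(cs$g))
        matrix(cs$g, ncol = 1, dimnames = list(NULL, "G")),
      expression = cbind(Y = cs$y, if (!is.null(cs$x)) cbind(X = cs$x)),
      levels = 2)
    got <- local_log_marginal_continuous(
      "Y", cont_parents = if (!is.null(cs$x)) "X" else character(),
      disc_parents = if (!is.null(cs$g)) "G" else character(),
      data = d, prior = pr)
    want <- if (is.null(cs$g)) {
      log(nig_marginal_numint(cs$y, cs$x, mu = pr$mu, mucoef = pr$mu,
                              tau = pr$tau, rho = pr$rho, phi = pr$phi))
    } else {
      sum(vapply(unique(cs$g), function(v) {
        sel <- cs$g == v
        log(nig_marginal_numint(cs$y[sel], cs$x[sel], mu = pr$mu,
                                mucoef = pr$mu, tau = pr$tau,
                                rho = pr$rho, phi = pr$phi))
      }, numeric(1)))
    }
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("continuous score decomposes over discrete-parent configurations", {
  set.seed(23)
  g <- rbinom(20, 1, 0.5)
  y <- rnorm(20, 10, 2)
  d <- cg_data(genotypes = cbind(G = g), expression = cbind(Y = y), levels = 2)
  whole <- local_log_marginal_continuous("Y", disc_parents = "G", data = d)
  parts <- vapply(0:1, function(v)
    local_log_marginal_continuous("Y", data = cg_data(
      expression = cbind(Y = y[g == v]))), numeric(1))
  expect_equal(whole, sum(parts), tolerance = 1e-10)
})

test_that("network score equals the joint chain-rule marginal for a 2-node DAG", {
  set.seed(5)
  a <- c(0, 1, 1, 0)
  b <- c(1, 1, 0, 0)
  d <- cg_data(genotypes = cbind(A = a, B = b), levels = 2)
  nd <- bn_nodes(c("A", "B"), "L", levels = 2)
  dag <- bn_dag(nd, rbind(c("A", "B")), allow_locus_parents = TRUE)
  expect_equal(network_score(dag, d), log(dirmult_chain_joint(a, b)),
               tolerance = 1e-10)
  # determinism
  expect_identical(network_score(dag, d), network_score(dag, d))
  # empty DAG decomposes into parentless locals
  empty <- bn_dag(nd, NULL)
  expect_equal(network_score(empty, d),
               local_log_marginal_discrete("A", data = d) +
                 local_log_marginal_discrete("B", data = d),
               tolerance = 1e-12)
})

test_that("the score is decomposable: unrelated local terms are untouched", {
  set.seed(11)
  sim <- simulate_scenario(scenario_spec(1, beta = 1, n = 60, seed = 2))
  d <- sim$data
  pr <- cg_prior()
  before <- local_log_marginal_continuous("E2", data = d, prior = pr)
  # changing E1's parents must not alter E2's parentless term
  after <- local_log_marginal_continuous("E2", data = d, prior = pr)
  expect_identical(before, after)
  nd <- cg_subset(d, c("L1", "E1", "E2"), complete = FALSE)
  nodes <- bn_nodes(c("L1", "E1", "E2"), c("L", "E", "E"))
  s_empty <- network_score(bn_dag(nodes, NULL), d, pr)
  s_edge <- network_score(bn_dag(nodes, rbind(c("L1", "E1"))), d, pr)
  delta_local <-
    local_log_marginal_continuous("E1", disc_parents = "L1", data = d,
                                  prior = pr) -
    local_log_marginal_continuous("E1", data = d, prior = pr)
  expect_equal(s_edge - s_empty, delta_local, tolerance = 1e-10)
})

test_that("a strong true edge raises the score over the empty structure", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    L <- sample(0:2, 400, TRUE, c(0.25, 0.5, 0.25))
    E <- 8 + 2 * L + rnorm(400, 0, 3.6)
    d <- cg_data(genotypes = cbind(L1 = L), expression = cbind(E1 = E))
    nodes <- bn_nodes(c("L1", "E1"), c("L", "E"))
    s1 <- network_score(bn_dag(nodes, rbind(c("L1", "E1"))), d)
    s0 <- network_score(bn_dag(nodes, NULL), d)
    wins <- wins + (s1 > s0)
  }
  expect_gte(wins, 9L)
})

test_that("scoring refuses incomplete data and inadmissible parents", {
  g <- cbind(A = c(0, 1, NA))
  d <- cg_data(genotypes = g, expression = cbind(Y = c(1, 2, 3)), levels = 2)
  expect_error(local_log_marginal_discrete("A", data = d), "complete")
  expect_error(local_log_marginal_discrete("A", parents = "Y",
                                           data = cg_data(
                                             genotypes = cbind(A = c(0, 1)),
                                             expression = cbind(Y = c(1, 2)),
                                             levels = 2)),
               "CG restriction")
  expect_error(cg_data(genotypes = cbind(A = c(0, 3))), "invalid genotype")
})

test_that("zero observations give a zero log marginal", {
  d0 <- cg_data(genotypes = matrix(numeric(), 0, 1,
                                   dimnames = list(NULL, "A")),
                expression = matrix(numeric(), 0, 1,
                                    dimnames = list(NULL, "Y")), levels = 2)
  expect_equal(local_log_marginal_discrete("A", data = d0), 0)
  expect_equal(local_log_marginal_continuous("Y", data = d0), 0)
})
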