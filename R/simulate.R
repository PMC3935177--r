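# Scenario registry: wiring and generative models for the seven benchmark
# network scenarios.  Every simulated dataset has 5 SNP loci (genotypes
# 0/1/2 with probabilities 0.25/0.5/0.25), 5 transcripts and one continuous
# phenotype D; variables outside the truth network are noise (independent
# N(10, 3.6) expression).  All noise terms are N(0, 3.6); the second
# parameter of these normals is the standard deviation.
scenario_registry <- function() {
  e <- function(...) do.call(rbind, list(...))
  list(
    # central-dogma wiring: locus -> expression -> phenotype
    list(edges = e(c("L1", "E1"), c("L2", "E2"), c("E1", "D"), c("E2", "D")),
         expr = list(E1 = c("L1"), E2 = c("L2")),
         d = function(X, beta) beta^2 * X[, "E1"] + beta^2 * X[, "E2"]),
    # pleiotropic: L1 drives both transcripts, L2 its own transcript, so the
    # truth remains a five-node {L1, L2, E1, E2, D} structure
    list(edges = e(c("L1", "E1"), c("L1", "E2"), c("L2", "E2"),
                   c("E1", "D"), c("E2", "D")),
         expr = list(E1 = c("L1"), E2 = c("L1", "L2")),
         d = function(X, beta) beta^2 * X[, "E1"] + beta^2 * X[, "E2"]),
    # scenario 1 wiring plus a direct locus -> phenotype edge
    list(edges = e(c("L1", "E1"), c("L2", "E2"), c("E1", "D"), c("E2", "D"),
                   c("L1", "D")),
         expr = list(E1 = c("L1"), E2 = c("L2")),
         d = function(X, beta)
           beta * (X[, "L1"] == 1) + beta * (X[, "L1"] == 2) +
           beta * X[, "E1"] + beta * X[, "E2"]),
    # scenario 2 wiring plus a direct locus -> phenotype edge
    list(edges = e(c("L1", "E1"), c("L1", "E2"), c("L2", "E2"),
                   c("E1", "D"), c("E2", "D"), c("L1", "D")),
         expr = list(E1 = c("L1"), E2 = c("L1", "L2")),
         d = function(X, beta)
           beta * (X[, "L1"] == 1) + beta * (X[, "L1"] == 2) +
           beta * X[, "E1"] + beta * X[, "E2"]),
    # long connection L1 -> E1 -> E2 -> D; L2 drives its own transcript so
    # the truth remains five-node
    list(edges = e(c("L1", "E1"), c("L2", "E2"), c("E1", "E2"), c("E2", "D")),
         expr = list(E1 = c("L1"), E2 = c("L2", "E1")),
         d = function(X, beta) beta^2 * X[, "E2"]),
    # chain with a stronger direct effect on D
    list(edges = e(c("L1", "E1"), c("L2", "E2"), c("E1", "E2"), c("E2", "D")),
         expr = list(E1 = c("L1"), E2 = c("L2", "E1")),
         d = function(X, beta) 3 * beta * X[, "E2"]),
    # worst case: loci act on D directly, bypassing expression
    list(edges = e(c("L1", "D"), c("L2", "D"), c("E1", "D"), c("E2", "D")),
         expr = list(),
         d = function(X, beta)
           beta * (X[, "L1"] == 1) + beta * (X[, "L1"] == 2) +
           beta * (X[, "L2"] == 1) + beta * (X[, "L2"] == 2) +
           beta * X[, "E1"] + beta * X[, "E2"]))
}

#' Specify a simulation scenario
#'
#' @param id scenario identifier, 1 to 7.
#' @param beta edge-effect size.
#' @param n sample size.
#' @param seed integer seed for the generator.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, beta = 0.8, n = 200L, seed = 1L) {
  stopifnot(id %in% 1:7, n >= 1, is.finite(beta))
  structure(list(id = as.integer(id), beta = beta, n = as.integer(n),
                 seed = as.integer(seed)), class = "scenario_spec")
}

#' Truth network of a scenario
#'
#' @param id scenario identifier, 1 to 7.
#' @return list with `nodes` (character) and `edges` (parent/child matrix).
#' @export
scenario_truth <- function(id) {
  stopifnot(id %in% 1:7)
  reg <- scenario_registry()[[id]]
  edges <- as_edge_matrix(reg$edges)
  list(nodes = sort(unique(c(edges)), method = "radix"), edges = edges)
}

#' Simulate a benchmark scenario
#'
#' Generates 5 SNP loci (genotype codes 0/1/2 with probabilities
#' 0.25/0.5/0.25), 5 transcripts and one phenotype.  Truth-linked
#' expression follows `E = 8 + beta * parent + eps`; unlinked expression is
#' independent `Normal(10, 3.6)`; the phenotype follows the scenario's
#' linear model; all noise terms are `Normal(0, 3.6)` (standard
#' deviations).
#'
#' @param spec a [scenario_spec()].
#' @return list of class `scenario_sim` with components `data` (a
#'   [cg_data]), `truth` (nodes and edges) and `spec`.
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  reg <- scenario_registry()[[spec$id]]
  set.seed(spec$seed)
  n <- spec$n
  sd_e <- 3.6

  G <- matrix(sample(0:2, n * 5L, replace = TRUE, prob = c(0.25, 0.5, 0.25)),
              nrow = n, dimnames = list(NULL, paste0("L", 1:5)))
  E <- matrix(NA_real_, n, 5L, dimnames = list(NULL, paste0("E", 1:5)))
  X <- cbind(G, E)
  # linked transcripts in dependency order (a chain parent precedes its child)
  for (en in names(reg$expr)) {
    parent <- reg$expr[[en]]
    X[, en] <- 8 + spec$beta * rowSums(X[, parent, drop = FALSE]) +
      rnorm(n, 0, sd_e)
  }
  for (en in setdiff(colnames(E), names(reg$expr)))
    X[, en] <- rnorm(n, 10, sd_e)
  D <- reg$d(X, spec$beta) + rnorm(n, 0, sd_e)

  data <- cg_data(genotypes = X[, colnames(G), drop = FALSE],
                  expression = X[, colnames(E), drop = FALSE],
                  phenotype = D)
  structure(list(data = data, truth = scenario_truth(spec$id), spec = spec),
            class = "scenario_sim")
}

metric_result <- function(tp, fp, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
  list(tp = tp, fp = fp, fn = fn, sensitivity = sens, fdr = fdr)
}

#' Node recovery metrics of a reported network
#'
#' Compares the reported node set against the truth nodes:
#' `sensitivity = tp / (tp + fn)` and `FDR = fp / (tp + fp)`, with the
#' `0/0` convention giving 0.
#'
#' @param reported character vector of reported node names.
#' @param truth a truth network (list with `nodes`), e.g. from
#'   [scenario_truth()].
#' @param universe all node names in the dataset; `reported` must be a
#'   subset.
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `fdr`.
#' @export
node_metrics <- function(reported, truth, universe) {
  reported <- unique(reported)
  if (length(setdiff(reported, universe)))
    stop("reported nodes outside the universe")
  metric_result(tp = length(intersect(reported, truth$nodes)),
                fp = length(setdiff(reported, truth$nodes)),
                fn = length(setdiff(truth$nodes, reported)))
}

#' Edge recovery metrics of a reported network
#'
#' Directed exact-match comparison: a reported edge counts as a true
#' positive only if the truth contains the same ordered pair; a reversed
#' edge is a false positive, and its true counterpart a false negative.
#'
#' @param reported two-column (parent, child) matrix of reported edges.
#' @param truth a truth network (list with `edges`).
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `fdr`.
#' @export
edge_metrics <- function(reported, truth) {
  reported <- as_edge_matrix(reported)
  te <- as_edge_matrix(truth$edges)
  rk <- unique(paste(reported[, 1L], reported[, 2L], sep = "\r"))
  tk <- paste(te[, 1L], te[, 2L], sep = "\r")
  metric_result(tp = length(intersect(rk, tk)),
                fp = length(setdiff(rk, tk)),
                fn = length(setdiff(tk, rk)))
}

run_algorithm <- function(algorithm, data, prior, lambda, config) {
  if (algorithm == "npars") {
    # an empty survivor set is a legitimate outcome here, not worth a warning
    fit <- suppressWarnings(
      npars(data, prior = prior, lambda = lambda, k1 = Inf, k2 = 1))
    rep <- reported_network(fit)
    list(nodes = rep$nodes, edges = rep$edges)
  } else if (algorithm == "exh") {
    res <- exhaustive_search(data, prior, lambda)
    list(nodes = res$reported_nodes, edges = res$dag$edges)
  } else if (algorithm == "greedy") {
    res <- greedy_search(data, prior, config, lambda)
    list(nodes = res$reported_nodes, edges = res$dag$edges)
  } else if (algorithm == "greedy_e") {
    res <- greedy_e(data, prior, config, lambda = lambda)
    list(nodes = res$reported_nodes, edges = res$dag$edges)
  } else stop("unknown algorithm: ", algorithm)
}

#' Run the simulation comparison harness
#'
#' For every combination of scenario, sample size and replicate, simulates
#' a dataset, runs each requested algorithm on it and evaluates node and
#' edge recovery against the scenario's truth network.  Fully seeded: the
#' same master seed reproduces identical tables.
#'
#' @param scenario_ids scenarios to include (default 1:7).
#' @param algorithms subset of `c("npars", "exh", "greedy", "greedy_e")`.
#' @param n sample size(s).
#' @param beta edge-effect size(s).
#' @param replicates replicates per cell (default 25).
#' @param seed master seed.
#' @param prior a [cg_prior]; `NULL` (default) derives an [empirical_prior()]
#'   from each simulated dataset with the calibrated imaginary sample size;
#'   alternatively a `function(data)` returning a prior, evaluated per
#'   dataset (e.g. `function(d) empirical_prior(d, nu = 50)` for the
#'   strongly informative regime).
#' @param lambda improvement-score weight (default 0.5).
#' @param config a [search_config()] for the greedy algorithms.
#' @return list with `results` (one row per scenario x algorithm x n x
#'   beta x replicate: node/edge sensitivity and FDR) and `summary`
#'   (per-cell means over replicates), plus a `failures` count of
#'   replicates excluded due to errors.
#' @export
run_comparison <- function(scenario_ids = 1:7,
                           algorithms = c("npars", "greedy"),
                           n = 200L, beta = 0.8, replicates = 25L, seed = 1L,
                           prior = NULL, lambda = 0.5,
                           config = search_config()) {
  stopifnot(replicates >= 1)
  algorithms <- match.arg(algorithms,
                          c("npars", "exh", "greedy", "greedy_e"),
                          several.ok = TRUE)
  grid <- expand.grid(scenario = scenario_ids, n = n, beta = beta,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  universe <- c(paste0("L", 1:5), paste0("E", 1:5), "D")
  rows <- list()
  failures <- 0L
  for (g in seq_len(nrow(grid))) {
    sc <- grid$scenario[g]
    data_seed <- (as.integer(seed) + 7919L * as.integer(sc) +
                    104729L * grid$replicate[g] + 611L * grid$n[g]) %% 2147483647L
    sim <- simulate_scenario(scenario_spec(sc, beta = grid$beta[g],
                                           n = grid$n[g], seed = data_seed))
    pr <- if (is.function(prior)) prior(sim$data) else prior
    for (alg in algorithms) {
      set.seed((data_seed + 31L) %% 2147483647L)  # search RNG (greedy restarts)
      res <- tryCatch(
        run_algorithm(alg, sim$data, pr, lambda, config),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- failures + 1L
        next
      }
      nm <- node_metrics(res$nodes, sim$truth, universe)
      em <- edge_metrics(res$edges, sim$truth)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, algorithm = alg, n = grid$n[g], beta = grid$beta[g],
        replicate = grid$replicate[g],
        node_sensitivity = nm$sensitivity, node_fdr = nm$fdr,
        edge_sensitivity = em$sensitivity, edge_fdr = em$fdr,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    results[, c("node_sensitivity", "node_fdr",
                "edge_sensitivity", "edge_fdr")],
    by = results[, c("scenario", "algorithm", "n", "beta")], FUN = mean)
  summary <- summary[order(summary$scenario, summary$algorithm, summary$n,
                           summary$beta), , drop = FALSE]
  rownames(summary) <- NULL
  list(results = results, summary = summary, failures = failures)
}
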