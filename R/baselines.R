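#' Configuration for the greedy hill-climbing searches
#'
#' @param restarts number of random restarts (default 10).
#' @param max_iterations maximum accepted edge modifications per restart
#'   (default 100); the search also stops at a local optimum, i.e. when no
#'   single-edge move strictly improves the objective.
#' @param node_cap optional cap on the number of connected (degree >= 1)
#'   nodes; moves that would exceed it are disallowed.  `NULL` for none.
#' @param seed optional integer seed applied before the search.
#' @param objective `"S"` (network score, default) or `"phi"`.
#' @param init_prob inclusion probability of each admissible edge in the
#'   random initial DAG (default 0.2; 0 starts from the empty structure).
#' @return an object of class `search_config`.
#' @export
search_config <- function(restarts = 10L, max_iterations = 100L,
                          node_cap = NULL, seed = NULL,
                          objective = c("S", "phi"), init_prob = 0.2) {
  objective <- match.arg(objective)
  stopifnot(restarts >= 1, max_iterations >= 0,
            is.null(node_cap) || node_cap >= 1,
            init_prob >= 0, init_prob <= 1)
  structure(list(restarts = as.integer(restarts),
                 max_iterations = as.integer(max_iterations),
                 node_cap = if (is.null(node_cap)) 0L else as.integer(node_cap),
                 seed = seed, objective = objective, init_prob = init_prob),
            class = "search_config")
}

run_greedy <- function(data, prior, config, lambda) {
  stopifnot(inherits(data, "cg_data"), inherits(config, "search_config"))
  prior <- default_prior(prior, data)
  if (anyNA(data$X)) stop("scoring requires complete data; filter or impute first")
  if (!is.null(config$seed)) set.seed(config$seed)
  mc <- cg_meta_cpp(data)
  allowed <- allowed_parent_masks(cg_nodes(data))
  res <- cpp_greedy(data$X, mc$disc, mc$levels, as.integer(allowed),
                    mc$d_index, resolve_prior(prior, data$meta), lambda, config$objective,
                    config$restarts, config$max_iterations, config$node_cap,
                    config$init_prob)
  nm <- data$meta$name
  edges <- mask_to_edges(res$parent_masks, nm)
  dag <- bn_dag(cg_nodes(data), edges, check = FALSE)
  reported <- sort(unique(c(edges)), method = "radix")
  structure(list(dag = dag, reported_nodes = reported,
                 S = res$S, S0 = res$S0, phi = res$phi,
                 objective = res$objective,
                 restart_log = as.data.frame(res$restart_log),
                 config = config), class = "cg_search")
}

#' Greedy hill-climbing network search with random restarts
#'
#' Each restart starts from a sparse random admissible DAG (random
#' topological order, each admissible edge included independently with
#' probability `init_prob`) and repeatedly applies the best single-edge
#' modification -- add, delete or reverse, admissibility preserved -- while
#' the objective strictly improves.  The best restart's structure is
#' returned; its reported node set is the nodes of degree at least one.
#'
#' @param data a complete [cg_data].
#' @param prior a [cg_prior]; `NULL` (default) derives an [empirical_prior()]
#'   from the data with the calibrated imaginary sample size.
#' @param config a [search_config()].
#' @param lambda weight used when `objective = "phi"` (default 0.5).
#' @return an object of class `cg_search` with components `dag`,
#'   `reported_nodes`, `S`, `S0`, `phi`, `objective` and `restart_log`
#'   (iterations and final objective per restart).
#' @export
greedy_search <- function(data, prior = NULL, config = search_config(),
                          lambda = 0.5) {
  config$node_cap <- 0L
  run_greedy(data, prior, config, lambda)
}

#' Node-capped greedy search
#'
#' Identical to [greedy_search()] except that any move that would raise the
#' number of connected (degree >= 1) nodes above `node_cap` (default 5) is
#' excluded from the move set, so reported networks stay small.
#'
#' @inheritParams greedy_search
#' @param node_cap maximum number of connected nodes (default 5).
#' @return an object of class `cg_search`.
#' @export
greedy_e <- function(data, prior = NULL, config = search_config(),
                     node_cap = 5L, lambda = 0.5) {
  if (config$node_cap == 0L) config$node_cap <- as.integer(node_cap)
  run_greedy(data, prior, config, lambda)
}

#' @export
print.cg_search <- function(x, ...) {
  if (is.null(x$restart_log)) {
    cat("Exhaustive CG network search (", x$combinations_examined,
        " five-node combinations)\n", sep = "")
  } else {
    cat("Greedy CG network search (", nrow(x$restart_log), " restarts)\n", sep = "")
  }
  cat(sprintf("  objective (%s): %.4f;  S = %.4f, S0 = %.4f, phi = %.4f\n",
              x$config$objective, x$objective, x$S, x$S0, x$phi))
  cat("  reported nodes:", paste(x$reported_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive five-node search
#'
#' The gold-standard comparator: every choice of two loci and two
#' transcripts is combined with the phenotype into a five-node set, all
#' admissible DAGs on each set are enumerated and scored, and the global
#' maximizer of the improvement score `phi` is returned.  Ties go to the
#' canonically earlier node set (input column order).
#'
#' @param data a complete [cg_data] with at least two loci and two
#'   transcripts.
#' @param prior a [cg_prior]; `NULL` (default) derives an [empirical_prior()]
#'   from the data with the calibrated imaginary sample size.
#' @param lambda weight in `phi` (default 0.5).
#' @param max_combinations capacity guard on the number of five-node
#'   variable combinations (default 5000).
#' @return an object of class `cg_search` with the extra component
#'   `combinations_examined`.
#' @export
exhaustive_search <- function(data, prior = NULL, lambda = 0.5,
                              max_combinations = 5000) {
  stopifnot(inherits(data, "cg_data"))
  prior <- default_prior(prior, data)
  if (anyNA(data$X)) stop("scoring requires complete data; filter or impute first")
  loci <- data$meta$name[data$meta$role == "L"]
  transcripts <- data$meta$name[data$meta$role == "E"]
  pheno <- data$meta$name[data$meta$role == "D"]
  if (length(loci) < 2L || length(transcripts) < 2L || length(pheno) != 1L)
    stop("exhaustive search needs >= 2 loci, >= 2 transcripts and a phenotype")
  lp <- utils::combn(loci, 2L)
  ep <- utils::combn(transcripts, 2L)
  n_comb <- ncol(lp) * ncol(ep)
  if (n_comb > max_combinations)
    stop("combinatorial size ", n_comb, " exceeds the capacity guard (",
         max_combinations, "); reduce the variable set")
  best <- NULL
  for (i in seq_len(ncol(lp))) {
    for (j in seq_len(ncol(ep))) {
      cols <- c(lp[, i], ep[, j], pheno)
      res <- best_structure_cols(data, cols, prior, lambda, "phi")
      if (is.null(res)) next
      if (is.null(best) || res$phi > best$phi) { best <- res; best$cols <- cols }
    }
  }
  if (is.null(best)) stop("no scorable five-node combination")
  nm <- best$names
  edges <- if (nrow(best$edges))
    as_edge_matrix(cbind(nm[best$edges[, 1L]], nm[best$edges[, 2L]]))
  else as_edge_matrix(NULL)
  edges <- edges[order(edges[, 1L], edges[, 2L], method = "radix"), , drop = FALSE]
  nodes <- bn_nodes(best$cols,
                    data$meta$role[match(best$cols, data$meta$name)])
  dag <- bn_dag(nodes, edges, check = FALSE)
  structure(list(dag = dag,
                 reported_nodes = sort(best$cols, method = "radix"),
                 S = best$S, S0 = best$S0, phi = best$phi, objective = best$phi,
                 restart_log = NULL, combinations_examined = n_comb,
                 config = list(objective = "phi")), class = "cg_search")
}
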