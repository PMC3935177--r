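#' Log marginal likelihood of a discrete node given discrete parents
#'
#' Dirichlet-multinomial closed form, summed over discrete-parent
#' configurations: within each configuration the node's counts are scored
#' under a symmetric Dirichlet prior.  The value is order-invariant in the
#' samples, and zero for empty data (an empty product of predictives).
#'
#' @param node name of a discrete column of `data`.
#' @param parents character vector of discrete parent column names.
#' @param data a [cg_data] dataset with no missing values in the used columns.
#' @param prior a [cg_prior].
#' @return the natural-log marginal likelihood.
#' @export
local_log_marginal_discrete <- function(node, parents = character(),
                                        data, prior = cg_prior()) {
  stopifnot(inherits(data, "cg_data"))
  sub <- cg_subset(data, c(node, parents), complete = FALSE)
  if (anyNA(sub$X)) stop("scoring requires complete data; filter or impute first")
  if (sub$meta$kind[1L] != "discrete") stop("'node' must be a discrete column")
  if (length(parents) && any(sub$meta$kind[-1L] != "discrete"))
    stop("continuous parent of a discrete node violates the CG restriction")
  if (nrow(sub$X) == 0L) return(0)
  cpp_local_score(sub$X, as.integer(sub$meta$kind == "discrete"),
                  as.integer(ifelse(is.na(sub$meta$levels), 0L, sub$meta$levels)),
                  0L, seq_along(parents), resolve_prior(prior, sub$meta))
}

#' Log marginal likelihood of a continuous node given mixed parents
#'
#' Normal-inverse-gamma closed form: within each discrete-parent
#' configuration, the node's values are scored under Bayesian linear
#' regression on (intercept, continuous parents) with prior
#' `(m, b) | sigma2 ~ Normal(mu, sigma2 / tau)` and
#' `sigma2 ~ InverseGamma(rho / 2, phi / 2)` -- a multivariate Student-t
#' predictive -- and the per-configuration log marginals are summed.
#'
#' @param node name of a continuous column of `data`.
#' @param cont_parents character vector of continuous parent column names.
#' @param disc_parents character vector of discrete parent column names.
#' @inheritParams local_log_marginal_discrete
#' @return the natural-log marginal likelihood; 0 for empty data.
#' @export
local_log_marginal_continuous <- function(node, cont_parents = character(),
                                          disc_parents = character(),
                                          data, prior = cg_prior()) {
  stopifnot(inherits(data, "cg_data"))
  cols <- c(node, cont_parents, disc_parents)
  sub <- cg_subset(data, cols, complete = FALSE)
  if (anyNA(sub$X)) stop("scoring requires complete data; filter or impute first")
  if (sub$meta$kind[1L] != "continuous") stop("'node' must be a continuous column")
  if (length(cont_parents) &&
      any(sub$meta$kind[match(cont_parents, sub$meta$name)] != "continuous"))
    stop("'cont_parents' must be continuous columns")
  if (length(disc_parents) &&
      any(sub$meta$kind[match(disc_parents, sub$meta$name)] != "discrete"))
    stop("'disc_parents' must be discrete columns")
  if (nrow(sub$X) == 0L) return(0)
  cpp_local_score(sub$X, as.integer(sub$meta$kind == "discrete"),
                  as.integer(ifelse(is.na(sub$meta$levels), 0L, sub$meta$levels)),
                  0L, seq_len(length(cols) - 1L), resolve_prior(prior, sub$meta))
}

dag_parent_masks <- function(dag, names) {
  masks <- integer(length(names))
  if (nrow(dag$edges)) {
    for (k in seq_len(nrow(dag$edges))) {
      u <- match(dag$edges[k, 1L], names)
      v <- match(dag$edges[k, 2L], names)
      masks[v] <- bitwOr(masks[v], bitwShiftL(1L, u - 1L))
    }
  }
  masks
}

#' Network score of a structure
#'
#' The decomposable log marginal-likelihood score: the sum over the DAG's
#' nodes of their local log marginal likelihoods given their parents.  The
#' structure prior is uniform over the admissible space, contributing an
#' additive constant taken as zero, so scores are comparable only across
#' structures on the same node set and data.
#'
#' @param dag a [bn_dag] whose nodes are columns of `data`.
#' @param data a [cg_data] with no missing values in the DAG's columns.
#' @param prior a [cg_prior].
#' @return the network score `S` (natural log scale).
#' @export
network_score <- function(dag, data, prior = cg_prior()) {
  stopifnot(inherits(dag, "bn_dag"), inherits(data, "cg_data"))
  sub <- cg_subset(data, dag$nodes$name, complete = FALSE)
  if (anyNA(sub$X)) stop("scoring requires complete data; filter or impute first")
  mc <- cg_meta_cpp(sub)
  res <- cpp_network_score(sub$X, mc$disc, mc$levels,
                           dag_parent_masks(dag, sub$meta$name),
                           mc$d_index, resolve_prior(prior, sub$meta))
  res$S
}
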