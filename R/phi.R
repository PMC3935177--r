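#' Average network improvement score
#'
#' Balances the improvement a structure gains from its edges to the
#' phenotype against its overall fit, per node:
#' `phi = (lambda * (S - S0) + (1 - lambda) * S) / alpha`,
#' where `S` is the network score of the structure, `S0` the score of its
#' null network (all edges incident to the phenotype removed), `lambda` a
#' weight in `[0, 1]` (default 0.5, weighting the two parts equally) and
#' `alpha` the number of nodes in the candidate network's node set,
#' including isolated nodes.
#'
#' @param S network score of the candidate structure.
#' @param S0 network score of its null network.
#' @param lambda weight in `[0, 1]` (default 0.5).
#' @param alpha node count, at least 1.
#' @return the improvement score.
#' @examples
#' phi_score(-5558.75, -5757.38, 0.5, 3)  # -893.35
#' @export
phi_score <- function(S, S0, lambda = 0.5, alpha) {
  if (any(lambda < 0 | lambda > 1)) stop("lambda must be in [0, 1]")
  if (any(alpha < 1)) stop("alpha must be at least 1")
  (lambda * (S - S0) + (1 - lambda) * S) / alpha
}

#' Null network of a structure
#'
#' Removes every edge incident to the phenotype node (either direction),
#' retaining all nodes.  Its score `S0` anchors the improvement term of
#' [phi_score()]: `S - S0` measures what the structure gains from linking
#' the phenotype at all.
#'
#' @param dag a [bn_dag].
#' @param phenotype name of the phenotype node; defaults to the node with
#'   role `"D"`.
#' @return a [bn_dag] with no edge touching the phenotype.
#' @export
null_network <- function(dag, phenotype = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  if (is.null(phenotype)) {
    phenotype <- dag$nodes$name[dag$nodes$role == "D"]
    if (length(phenotype) != 1L)
      stop("dag has no unique phenotype node; supply 'phenotype'")
  }
  if (!phenotype %in% dag$nodes$name)
    stop("phenotype node '", phenotype, "' not in the dag")
  keep <- dag$edges[, "parent"] != phenotype & dag$edges[, "child"] != phenotype
  bn_dag(dag$nodes, dag$edges[keep, , drop = FALSE], check = FALSE)
}
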