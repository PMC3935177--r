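# internal: exhaustive structure search on a subset of columns
best_structure_cols <- function(data, cols, prior, lambda, objective,
                                allow_locus_parents = FALSE, return_all = FALSE) {
  sub <- cg_subset(data, cols, complete = TRUE)
  n_used <- nrow(sub$X)
  if (n_used == 0L) return(NULL)
  mc <- cg_meta_cpp(sub)
  allowed <- allowed_parent_masks(cg_nodes(sub), allow_locus_parents)
  res <- cpp_best_structure(sub$X, mc$disc, mc$levels, as.integer(allowed),
                            mc$d_index, resolve_prior(prior, sub$meta), lambda,
                            length(cols), objective, return_all)
  res$names <- sub$meta$name
  res$n_used <- n_used
  res
}

edges_to_strings <- function(edges, names) {
  if (!nrow(edges)) return("")
  paste(sort(paste0(names[edges[, 1L]], "->", names[edges[, 2L]]),
             method = "radix"), collapse = ";")
}

# map a triplet structure (edges over actual names) to its catalog index
catalog_index_map <- function() {
  vapply(triplet_catalog(), function(g) edge_key(g$edges), character(1))
}

#' Number of triplets in the partition stage
#'
#' The partition stage decomposes the network space into one
#' (locus, expression, phenotype) triplet per locus-transcript pair, so the
#' plan size is simply their product.
#'
#' @param n_loci number of SNP loci.
#' @param n_transcripts number of transcripts.
#' @return the triplet count (as a double, to accommodate large studies).
#' @examples
#' plan_partition(2330, 3554)
#' @export
plan_partition <- function(n_loci, n_transcripts) {
  stopifnot(n_loci >= 0, n_transcripts >= 0)
  as.numeric(n_loci) * as.numeric(n_transcripts)
}

#' Score every (locus, expression, phenotype) triplet
#'
#' Stage one of the partition-and-reassembly search: for each
#' locus-transcript pair, all 12 admissible triplet structures are scored
#' and the structure with the highest network score `S` is reported,
#' together with its null-network score `S0` and improvement score `phi`.
#' Rows with a missing value in the triplet's columns are dropped for that
#' triplet only; a triplet with no usable samples is flagged (`NA` scores),
#' not dropped.
#'
#' @param data a [cg_data] with locus, expression and phenotype columns.
#' @param prior a [cg_prior]; `NULL` (default) derives an [empirical_prior()]
#'   from the data with the calibrated imaginary sample size.
#' @param lambda weight of the improvement term in `phi` (default 0.5).
#' @return a data frame of class `npars_triplets`: one row per pair, with
#'   columns `locus`, `transcript`, `structure` (sorted edge list),
#'   `catalog_index`, `n_edges`, `S`, `S0`, `phi`, `n_used`.
#' @export
score_all_triplets <- function(data, prior = NULL, lambda = 0.5) {
  stopifnot(inherits(data, "cg_data"))
  prior <- default_prior(prior, data)
  loci <- data$meta$name[data$meta$role == "L"]
  transcripts <- data$meta$name[data$meta$role == "E"]
  pheno <- data$meta$name[data$meta$role == "D"]
  if (!length(loci) || !length(transcripts) || length(pheno) != 1L)
    stop("data must contain loci, transcripts and one phenotype column")
  cmap <- catalog_index_map()
  rows <- vector("list", length(loci) * length(transcripts))
  k <- 0L
  for (l in loci) {
    for (e in transcripts) {
      k <- k + 1L
      res <- best_structure_cols(data, c(l, e, pheno), prior, lambda, "S")
      if (is.null(res)) {
        rows[[k]] <- data.frame(locus = l, transcript = e,
                                structure = NA_character_,
                                catalog_index = NA_integer_, n_edges = NA_integer_,
                                S = NA_real_, S0 = NA_real_, phi = NA_real_,
                                n_used = 0L, stringsAsFactors = FALSE)
        next
      }
      generic <- c("L", "E", "D")
      rows[[k]] <- data.frame(
        locus = l, transcript = e,
        structure = edges_to_strings(res$edges, res$names),
        catalog_index = match(edge_key(as_edge_matrix(
          if (nrow(res$edges)) cbind(generic[res$edges[, 1L]],
                                     generic[res$edges[, 2L]]) else NULL)), cmap),
        n_edges = nrow(res$edges),
        S = res$S, S0 = res$S0, phi = res$phi, n_used = res$n_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$triplet_id <- seq_len(nrow(out))
  class(out) <- c("npars_triplets", "data.frame")
  out
}

#' Select the top triplets by improvement score
#'
#' Stage two: triplets whose best structure contains a degree-zero node
#' (equivalently, has fewer than two edges) are excluded so that only
#' adequately connected subnetworks survive; the rest are ranked by `phi`
#' descending (stable, ties by triplet id) and the top `k1` are returned.
#' If only one triplet survives it is the search's final answer.
#'
#' @param results an `npars_triplets` table from [score_all_triplets()].
#' @param k1 number of triplets to keep (default all survivors).
#' @return the selected rows, ranked, of class `npars_triplets`.
#' @export
select_triplets <- function(results, k1 = Inf) {
  stopifnot(inherits(results, "data.frame"), k1 >= 1)
  keep <- !is.na(results$n_edges) & results$n_edges >= 2L
  survivors <- results[keep, , drop = FALSE]
  if (nrow(survivors) == 0L) {
    warning("no triplet survives the degree-zero filter")
    return(survivors)
  }
  survivors <- survivors[order(-survivors$phi, survivors$triplet_id), , drop = FALSE]
  out <- utils::head(survivors, n = if (is.finite(k1)) k1 else nrow(survivors))
  class(out) <- c("npars_triplets", "data.frame")
  out
}

#' Pairings examined by the reassembly stage
#'
#' @param selected a ranked `npars_triplets` table.
#' @return a two-column matrix of row indices, one row per unordered pair.
#' @export
plan_reassembly <- function(selected) {
  if (nrow(selected) < 2L)
    return(matrix(integer(), ncol = 2L))
  t(utils::combn(nrow(selected), 2L))
}

#' Reassemble selected triplets into four- and five-node networks
#'
#' Stage three: every unordered pair of selected triplets is merged into
#' the union of its nodes (four nodes if the pair shares a locus or a
#' transcript, else five); each union's structure is rebuilt from scratch
#' by enumerating all admissible DAGs and keeping the structure with the
#' largest improvement score `phi` (network score `S` by
#' `objective = "S"`).  Unions arising from more than one pair are scored
#' once, keeping the first pair's identity.  Networks are ranked by `phi`
#' and the top `k2` returned.
#'
#' @param selected a ranked `npars_triplets` table with at least two rows.
#' @param data the [cg_data] the triplets were scored on.
#' @param prior a [cg_prior]; `NULL` (default) derives an [empirical_prior()]
#'   from the data with the calibrated imaginary sample size.
#' @param k2 number of networks to report (default 20).
#' @param lambda weight in `phi` (default 0.5).
#' @param objective structure-selection objective within a node set,
#'   `"phi"` (default) or `"S"`.
#' @return a data frame of class `npars_networks` with columns `nodes`
#'   (comma-separated node set), `loci`, `transcripts`, `edges`, `n_nodes`,
#'   `S`, `S0`, `phi`, `parent_triplets`.
#' @export
reassemble_pairs <- function(selected, data, prior = NULL, k2 = 20,
                             lambda = 0.5, objective = c("phi", "S")) {
  objective <- match.arg(objective)
  stopifnot(inherits(data, "cg_data"))
  if (nrow(selected) < 2L) stop("reassembly needs at least two selected triplets")
  prior <- default_prior(prior, data)
  pheno <- data$meta$name[data$meta$role == "D"]
  pairs <- plan_reassembly(selected)
  seen <- character()
  rows <- list()
  dup <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    nodes <- unique(c(selected$locus[c(i, j)], selected$transcript[c(i, j)], pheno))
    nodes <- data$meta$name[data$meta$name %in% nodes]  # column order
    key <- paste(nodes, collapse = ",")
    if (key %in% seen) { dup <- dup + 1L; next }
    seen <- c(seen, key)
    res <- best_structure_cols(data, nodes, prior, lambda, objective)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      nodes = key,
      loci = paste(unique(selected$locus[c(i, j)]), collapse = ","),
      transcripts = paste(unique(selected$transcript[c(i, j)]), collapse = ","),
      edges = edges_to_strings(res$edges, res$names),
      n_nodes = length(nodes), S = res$S, S0 = res$S0, phi = res$phi,
      parent_triplets = paste(selected$triplet_id[c(i, j)], collapse = ","),
      n_used = res$n_used, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (dup > 0L)
    attr(out, "duplicate_unions") <- dup
  out <- out[order(-out$phi, out$nodes), , drop = FALSE]
  out <- utils::head(out, n = if (is.finite(k2)) k2 else nrow(out))
  rownames(out) <- NULL
  class(out) <- c("npars_networks", "data.frame")
  out
}

#' Grow reported networks by one additional triplet
#'
#' One optional growth round: each base network's node set is merged with
#' each remaining selected triplet and re-searched exhaustively while the
#' union stays within the capacity guard.  Unions adding no new node, or
#' exceeding the guard, are skipped (with a message).  Exhaustive re-search
#' grows exponentially in the union size, so this round is expensive and
#' off by default in the pipeline.
#'
#' @param bases an `npars_networks` table from [reassemble_pairs()].
#' @param selected the ranked `npars_triplets` table.
#' @param data the [cg_data] the triplets were scored on.
#' @param prior a [cg_prior]; `NULL` (default) derives an [empirical_prior()]
#'   from the data with the calibrated imaginary sample size.
#' @param lambda weight in `phi` (default 0.5).
#' @param k2 number of grown networks to report (default 20).
#' @param max_nodes capacity guard on the union size (default 6).
#' @return re-ranked grown networks (class `npars_networks`), or `bases`
#'   unchanged if nothing could be grown.
#' @export
grow_networks <- function(bases, selected, data, prior = NULL,
                          lambda = 0.5, k2 = 20, max_nodes = 6L) {
  stopifnot(nrow(bases) >= 1L)
  prior <- default_prior(prior, data)
  pheno <- data$meta$name[data$meta$role == "D"]
  rows <- list(); seen <- character(); skipped <- 0L
  for (b in seq_len(nrow(bases))) {
    base_nodes <- strsplit(bases$nodes[b], ",")[[1L]]
    base_tr <- strsplit(bases$parent_triplets[b], ",")[[1L]]
    for (i in seq_len(nrow(selected))) {
      if (as.character(selected$triplet_id[i]) %in% base_tr) next
      nodes <- unique(c(base_nodes, selected$locus[i], selected$transcript[i], pheno))
      if (length(nodes) == length(base_nodes)) next  # nothing new
      if (length(nodes) > max_nodes) { skipped <- skipped + 1L; next }
      nodes <- data$meta$name[data$meta$name %in% nodes]
      key <- paste(nodes, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      res <- best_structure_cols(data, nodes, prior, lambda, "phi")
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        nodes = key, loci = NA_character_, transcripts = NA_character_,
        edges = edges_to_strings(res$edges, res$names),
        n_nodes = length(nodes), S = res$S, S0 = res$S0, phi = res$phi,
        parent_triplets = paste(c(base_tr, selected$triplet_id[i]), collapse = ","),
        n_used = res$n_used, stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    message(skipped, " union(s) exceeded the ", max_nodes, "-node capacity guard")
  if (!length(rows)) return(bases)
  out <- do.call(rbind, rows)
  out <- out[order(-out$phi, out$nodes), , drop = FALSE]
  out <- utils::head(out, n = if (is.finite(k2)) k2 else nrow(out))
  rownames(out) <- NULL
  class(out) <- c("npars_networks", "data.frame")
  out
}

#' Fit phenotype-linked networks by partition and reassembly
#'
#' The top-level fitter.  Runs the three-stage search: (1) score all
#' (locus, expression, phenotype) triplets exhaustively, (2) drop triplets
#' whose best structure leaves a node unconnected and keep the `k1` with
#' the largest improvement scores, (3) reassemble every pair of kept
#' triplets into a four- or five-node network by constrained exhaustive
#' search and report the `k2` best.
#'
#' @param genotypes samples x SNPs matrix of genotype codes `0/1/2` (or
#'   `NA`), or a [cg_data] (in which case `expression`/`phenotype` are
#'   ignored).
#' @param expression samples x transcripts numeric matrix.
#' @param phenotype numeric vector, one value per sample.
#' @param prior a [cg_prior]; `NULL` (default) derives an [empirical_prior()]
#'   from the data with the calibrated imaginary sample size.
#' @param lambda weight of the phenotype-improvement term (default 0.5).
#' @param k1 triplets kept at the selection stage (default 100; use `Inf`
#'   to keep every survivor, as in the simulation studies).
#' @param k2 networks reported (default 20; the simulation studies use 1).
#' @param objective structure objective within a reassembled node set
#'   (default `"phi"`).
#' @return an object of class `npars` with components `triplets`,
#'   `selected`, `networks`, `params` and `call`.
#' @examples
#' sim <- simulate_scenario(scenario_spec(1, beta = 1.2, n = 200, seed = 1))
#' fit <- npars(sim$data, k1 = Inf, k2 = 1)
#' print(fit)
#' @export
npars <- function(genotypes, expression = NULL, phenotype = NULL,
                  prior = NULL, lambda = 0.5, k1 = 100, k2 = 20,
                  objective = c("phi", "S")) {
  objective <- match.arg(objective)
  data <- if (inherits(genotypes, "cg_data")) genotypes
          else cg_data(genotypes, expression, phenotype)
  prior <- default_prior(prior, data)
  triplets <- score_all_triplets(data, prior, lambda)
  selected <- select_triplets(triplets, k1)
  networks <- if (nrow(selected) >= 2L) {
    reassemble_pairs(selected, data, prior, k2, lambda, objective)
  } else {
    selected  # zero or one survivor: that is the final answer
  }
  structure(list(
    triplets = triplets, selected = selected, networks = networks,
    data = data,
    params = list(prior = prior, lambda = lambda, k1 = k1, k2 = k2,
                  objective = objective),
    call = match.call()), class = "npars")
}

# node set and edge matrix of the top-ranked reported network; the node set
# is the assembled union (isolated nodes included), as the search reports it
reported_network <- function(fit) {
  nw <- fit$networks
  if (is.null(nw) || nrow(nw) == 0L)
    return(list(nodes = character(), edges = as_edge_matrix(NULL)))
  if (inherits(nw, "npars_networks")) {
    es <- nw$edges[1L]
    nodes <- strsplit(nw$nodes[1L], ",")[[1L]]
  } else {  # single surviving triplet
    es <- nw$structure[1L]
    nodes <- c(nw$locus[1L], nw$transcript[1L],
               fit$data$meta$name[fit$data$meta$role == "D"])
  }
  edges <- if (!is.na(es) && nzchar(es)) {
    as_edge_matrix(do.call(rbind,
      strsplit(strsplit(es, ";")[[1L]], "->", fixed = TRUE)))
  } else as_edge_matrix(NULL)
  list(nodes = sort(nodes, method = "radix"), edges = edges)
}

#' @export
print.npars <- function(x, ...) {
  cat("nPARS network search\n")
  cat(sprintf("  %d triplets scored, %d selected (k1 = %s), %d networks reported\n",
              nrow(x$triplets), nrow(x$selected), format(x$params$k1),
              if (is.null(x$networks)) 0L else nrow(x$networks)))
  rep <- reported_network(x)
  if (length(rep$nodes)) {
    cat("  top network nodes:", paste(rep$nodes, collapse = ", "), "\n")
    cat("  top network edges:", paste(rep$edges[, 1L], "->", rep$edges[, 2L],
                                      collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.npars <- function(object, n = 10L, ...) {
  cat("nPARS network search\n\n")
  cat("Top selected triplets (by phi):\n")
  print(utils::head(as.data.frame(object$selected)[
    , c("locus", "transcript", "structure", "S", "S0", "phi")], n))
  cat("\nTop reassembled networks (by phi):\n")
  if (inherits(object$networks, "npars_networks")) {
    print(utils::head(as.data.frame(object$networks)[
      , c("nodes", "edges", "S", "S0", "phi")], n))
  } else {
    print(as.data.frame(object$networks))
  }
  invisible(object)
}

#' @export
plot.npars <- function(x, which = 1L, ...) {
  nw <- x$networks
  if (is.null(nw) || nrow(nw) < which) stop("no reported network to plot")
  es <- if (inherits(nw, "npars_networks")) nw$edges[which] else nw$structure[which]
  nodes <- strsplit(if (inherits(nw, "npars_networks")) nw$nodes[which] else
    paste(nw$locus[which], nw$transcript[which],
          x$data$meta$name[x$data$meta$role == "D"], sep = ","), ",")[[1L]]
  edges <- if (nzchar(es))
    do.call(rbind, strsplit(strsplit(es, ";")[[1L]], "->", fixed = TRUE))
  else matrix(character(), ncol = 2L)
  p <- length(nodes)
  theta <- 2 * pi * seq_len(p) / p
  xs <- cos(theta); ys <- sin(theta)
  graphics::plot(xs, ys, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4),
                 axes = FALSE, xlab = "", ylab = "", pch = 21, cex = 4,
                 bg = ifelse(nodes %in% x$data$meta$name[x$data$meta$role == "L"],
                             "grey30", "white"), ...)
  graphics::text(1.2 * xs, 1.2 * ys, nodes)
  if (nrow(edges)) {
    i <- match(edges[, 1L], nodes); j <- match(edges[, 2L], nodes)
    graphics::arrows(xs[i] + 0.12 * (xs[j] - xs[i]), ys[i] + 0.12 * (ys[j] - ys[i]),
                     xs[j] - 0.12 * (xs[j] - xs[i]), ys[j] - 0.12 * (ys[j] - ys[i]),
                     length = 0.1)
  }
  invisible(x)
}
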