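#' Construct a typed node set
#'
#' Nodes carry a role: `"L"` for a SNP locus (discrete, genotype levels
#' coded `0..levels-1`), `"E"` for a transcript and `"D"` for the phenotype
#' (both continuous).  The role determines the kind: loci are discrete,
#' expression and phenotype nodes continuous.
#'
#' @param name character vector of unique node names.
#' @param role character vector (recycled) of roles, each `"L"`, `"E"` or `"D"`.
#' @param levels integer number of levels for discrete nodes (SNP genotypes
#'   have 3); ignored for continuous nodes.
#' @return a data frame of class `bn_nodes` with columns `name`, `role`,
#'   `kind` and `levels`.
#' @examples
#' bn_nodes(c("rs1", "GENE1", "D"), c("L", "E", "D"))
#' @export
bn_nodes <- function(name, role, levels = 3L) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("node names must be unique")
  role <- rep_len(as.character(role), length(name))
  if (!all(role %in% c("L", "E", "D"))) stop("roles must be 'L', 'E' or 'D'")
  if (sum(role == "D") > 1L) stop("at most one phenotype node")
  levels <- rep_len(as.integer(levels), length(name))
  kind <- ifelse(role == "L", "discrete", "continuous")
  levels[kind == "continuous"] <- NA_integer_
  if (any(kind == "discrete" & levels < 2L)) stop("discrete nodes need >= 2 levels")
  structure(
    data.frame(name = name, role = role, kind = kind, levels = levels,
               stringsAsFactors = FALSE),
    class = c("bn_nodes", "data.frame"))
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      length(edges) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child"))))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop("edges must be a two-column (parent, child) matrix")
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  edges
}

#' Test a directed edge set for acyclicity
#'
#' @param edges two-column (parent, child) character matrix (may have zero
#'   rows).
#' @param nodes character vector of node names, or a [bn_nodes] set.
#' @return `TRUE` if the directed graph has no cycle.
#' @examples
#' is_acyclic(rbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
#' @export
is_acyclic <- function(edges, nodes) {
  if (inherits(nodes, "bn_nodes")) nodes <- nodes$name
  edges <- as_edge_matrix(edges)
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown))
    stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
  remaining <- nodes
  repeat {
    parents_of <- edges[edges[, "child"] %in% remaining &
                          edges[, "parent"] %in% remaining, , drop = FALSE]
    leaves <- setdiff(remaining, unique(parents_of[, "child"]))
    if (!length(leaves)) break
    remaining <- setdiff(remaining, leaves)
  }
  length(remaining) == 0L
}

# Bitmask of admissible parents for each node.  Edges into loci are forbidden
# entirely by default (genotype is fixed at conception); allow_locus_parents
# re-admits locus -> locus edges.  The CG restriction bars continuous parents
# of discrete nodes in any case.
allowed_parent_masks <- function(nodes, allow_locus_parents = FALSE) {
  p <- nrow(nodes)
  vapply(seq_len(p), function(v) {
    mask <- 0L
    for (u in seq_len(p)) {
      if (u == v) next
      if (nodes$role[v] == "L") {
        if (!allow_locus_parents || nodes$role[u] != "L") next
      }
      mask <- bitwOr(mask, bitwShiftL(1L, u - 1L))
    }
    mask
  }, integer(1))
}

mask_to_edges <- function(masks, names) {
  out <- NULL
  for (v in seq_along(masks)) {
    for (u in seq_along(names)) {
      if (bitwAnd(bitwShiftR(masks[v], u - 1L), 1L))
        out <- rbind(out, c(names[u], names[v]))
    }
  }
  e <- as_edge_matrix(out)
  e[order(e[, 1L], e[, 2L], method = "radix"), , drop = FALSE]
}

#' Construct a directed acyclic graph over a typed node set
#'
#' Validates acyclicity and admissibility: no edges into loci (unless
#' `allow_locus_parents` admits locus-to-locus edges) and no continuous
#' parent of a discrete node.
#'
#' @param nodes a [bn_nodes] node set.
#' @param edges two-column (parent, child) character matrix; `NULL` for the
#'   empty graph.
#' @param allow_locus_parents admit locus-to-locus edges (default `FALSE`).
#' @param check validate the structure (default `TRUE`).
#' @return an object of class `bn_dag`.
#' @examples
#' nd <- bn_nodes(c("L", "E", "D"), c("L", "E", "D"))
#' bn_dag(nd, rbind(c("L", "E"), c("E", "D")))
#' @export
bn_dag <- function(nodes, edges = NULL, allow_locus_parents = FALSE, check = TRUE) {
  stopifnot(inherits(nodes, "bn_nodes"))
  edges <- as_edge_matrix(edges)
  if (check) {
    unknown <- setdiff(c(edges), nodes$name)
    if (length(unknown))
      stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
    if (nrow(edges)) {
      role <- setNames(nodes$role, nodes$name)
      kind <- setNames(nodes$kind, nodes$name)
      bad_child <- role[edges[, "child"]] == "L" &
        !(allow_locus_parents & role[edges[, "parent"]] == "L")
      if (any(bad_child))
        stop("edges into a locus node are not admissible")
      if (any(kind[edges[, "parent"]] == "continuous" &
              kind[edges[, "child"]] == "discrete"))
        stop("continuous parent of a discrete node violates the CG restriction")
      if (anyDuplicated(paste(edges[, 1L], edges[, 2L], sep = "\r")))
        stop("duplicate edges")
    }
    if (!is_acyclic(edges, nodes$name)) stop("edge set contains a directed cycle")
  }
  structure(list(nodes = nodes, edges = edges), class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("Conditional-Gaussian DAG:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L]), sep = "\n")
  invisible(x)
}

#' Does a DAG contain a node of degree zero?
#'
#' Triplet subnetworks containing an isolated node are excluded from the
#' selection stage, so that only adequately connected subnetworks survive.
#'
#' @param dag a [bn_dag].
#' @return `TRUE` if some node has no incident edge.
#' @export
has_isolated_node <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  !all(dag$nodes$name %in% c(dag$edges))
}

edge_key <- function(edges) {
  if (!nrow(edges)) return("")
  paste(sort(paste0(edges[, 1L], "->", edges[, 2L]), method = "radix"),
        collapse = ";")
}

# order a list of sorted edge-label vectors lexicographically, empty-prefix
# first; uses radix (C-locale) ordering so the result is platform-stable
order_edge_lists <- function(edge_lists) {
  len <- max(c(0L, lengths(edge_lists)))
  if (len == 0L) return(seq_along(edge_lists))
  padded <- vapply(seq_len(len), function(k) {
    vapply(edge_lists, function(e) if (length(e) >= k) e[k] else "", character(1))
  }, character(length(edge_lists)))
  padded <- matrix(padded, nrow = length(edge_lists))
  do.call(order, c(lapply(seq_len(len), function(k) padded[, k]),
                   list(method = "radix")))
}

#' Enumerate all admissible DAGs on a node set
#'
#' Generates every acyclic subset of the admissible edges (no edges into
#' loci, no continuous parent of a discrete node), each exactly once, in the
#' canonical order: lexicographic on the sorted edge-label lists.
#'
#' @param nodes a [bn_nodes] node set.
#' @param allow_locus_parents admit locus-to-locus edges (default `FALSE`).
#' @param max_nodes capacity guard on the node count (default 6).
#' @return list of [bn_dag] objects.
#' @examples
#' length(enumerate_dags(bn_nodes(c("L", "E", "D"), c("L", "E", "D"))))  # 12
#' @export
enumerate_dags <- function(nodes, allow_locus_parents = FALSE, max_nodes = 6L) {
  stopifnot(inherits(nodes, "bn_nodes"))
  if (nrow(nodes) > max_nodes)
    stop("node set exceeds the enumeration capacity guard (", max_nodes, " nodes)")
  nm <- nodes$name
  masks <- allowed_parent_masks(nodes, allow_locus_parents)
  cand <- NULL
  for (u in seq_along(nm)) {
    for (v in seq_along(nm)) {
      if (bitwAnd(bitwShiftR(masks[v], u - 1L), 1L)) cand <- rbind(cand, c(u, v))
    }
  }
  m <- if (is.null(cand)) 0L else nrow(cand)
  if (m > 20L) stop("candidate edge set too large for exhaustive enumeration")

  results <- list()
  reach <- function(adj, from, to) {
    # is `to` reachable from `from`?
    stack <- from
    seen <- logical(length(nm))
    while (length(stack)) {
      cur <- stack[[1L]]; stack <- stack[-1L]
      if (cur == to) return(TRUE)
      if (seen[cur]) next
      seen[cur] <- TRUE
      stack <- c(stack, which(adj[cur, ]))
    }
    FALSE
  }
  adj <- matrix(FALSE, length(nm), length(nm))
  sel <- logical(m)
  recurse <- function(k) {
    if (k > m) {
      e <- if (any(sel)) cand[sel, , drop = FALSE] else NULL
      em <- if (is.null(e)) as_edge_matrix(NULL) else
        as_edge_matrix(cbind(nm[e[, 1L]], nm[e[, 2L]]))
      results[[length(results) + 1L]] <<- em
      return(invisible())
    }
    recurse(k + 1L)  # exclude candidate k
    u <- cand[k, 1L]; v <- cand[k, 2L]
    if (!reach(adj, v, u)) {  # include candidate k keeps graph acyclic
      adj[u, v] <<- TRUE; sel[k] <<- TRUE
      recurse(k + 1L)
      adj[u, v] <<- FALSE; sel[k] <<- FALSE
    }
    invisible()
  }
  recurse(1L)

  keys <- lapply(results, function(e)
    if (nrow(e)) sort(paste0(e[, 1L], "->", e[, 2L]), method = "radix") else character())
  ord <- order_edge_lists(keys)
  lapply(results[ord], function(e)
    bn_dag(nodes, e, allow_locus_parents = allow_locus_parents, check = FALSE))
}

#' The catalog of the 12 admissible triplet structures
#'
#' For a (locus, expression, phenotype) triplet, forbidding edges into the
#' locus leaves 12 admissible DAGs.  Indices are stable: 1 is the empty
#' structure, 2 is `{L->E}` (the null network of the fully linked
#' structures), 3--5 are the remaining single-edge structures and 6--12 the
#' seven structures without a degree-zero node, in lexicographic order of
#' their sorted edge lists.  Node names are the generic `"L"`, `"E"`, `"D"`.
#'
#' @return list of 12 `bn_dag` objects with an `index` attribute each.
#' @export
triplet_catalog <- function() {
  nd <- bn_nodes(c("L", "E", "D"), c("L", "E", "D"))
  e <- function(...) as_edge_matrix(do.call(rbind, list(...)))
  LE <- c("L", "E"); LD <- c("L", "D"); ED <- c("E", "D"); DE <- c("D", "E")
  sets <- list(
    e(),            # G1
    e(LE),          # G2 (pinned: the null of the fully linked structures)
    e(LD),          # G3
    e(ED),          # G4
    e(DE),          # G5
    e(DE, LD),      # G6
    e(DE, LD, LE),  # G7
    e(DE, LE),      # G8
    e(ED, LD),      # G9
    e(ED, LD, LE),  # G10
    e(ED, LE),      # G11
    e(LD, LE))      # G12
  lapply(seq_along(sets), function(i) {
    d <- bn_dag(nd, sets[[i]])
    attr(d, "index") <- i
    d
  })
}

#' Write a network as a tab-separated edge list
#'
#' The file carries `#`-prefixed header lines naming each node's role and
#' kind, followed by a `parent<TAB>child` edge table.
#'
#' @param dag a [bn_dag].
#' @param file path to write to.
#' @export
write_network <- function(dag, file) {
  stopifnot(inherits(dag, "bn_dag"))
  con <- file(file, "w")
  on.exit(close(con))
  with(dag$nodes, writeLines(sprintf("# node\t%s\t%s\t%s\t%s", name, role, kind,
                                     ifelse(is.na(levels), "", levels)), con))
  writeLines("parent\tchild", con)
  if (nrow(dag$edges))
    writeLines(paste(dag$edges[, 1L], dag$edges[, 2L], sep = "\t"), con)
  invisible(file)
}

#' Read a network written by [write_network()]
#' @param file path to read.
#' @return a [bn_dag].
#' @export
read_network <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# node\t", lines, value = TRUE)
  parts <- strsplit(sub("^# node\t", "", hdr), "\t")
  nodes <- bn_nodes(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
                    vapply(parts, function(x)
                      if (length(x) >= 4L && nzchar(x[4L])) as.integer(x[4L]) else 3L,
                      integer(1)))
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1L]  # column header
  edges <- if (length(body)) {
    do.call(rbind, strsplit(body, "\t"))
  } else NULL
  bn_dag(nodes, edges)
}

#' Export a network in DOT format for visualization
#' @param dag a [bn_dag].
#' @param file optional path; if `NULL` the DOT text is returned.
#' @return the DOT source, invisibly if written to a file.
#' @export
dag_to_dot <- function(dag, file = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  shape <- ifelse(dag$nodes$kind == "discrete", "box", "ellipse")
  lines <- c(
    "digraph network {",
    sprintf("  \"%s\" [shape=%s];", dag$nodes$name, shape),
    if (nrow(dag$edges))
      sprintf("  \"%s\" -> \"%s\";", dag$edges[, 1L], dag$edges[, 2L]),
    "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
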