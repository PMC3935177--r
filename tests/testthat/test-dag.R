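test_that("acyclicity detection matches simple cases and rejects unknown nodes", {
  expect_true(is_acyclic(NULL, c("A", "B")))
  expect_false(is_acyclic(rbind(c("A", "B"), c("B", "A")), c("A", "B")))
  expect_true(is_acyclic(rbind(c("A", "B"), c("B", "C"), c("A", "C")),
                         c("A", "B", "C")))
  expect_false(is_acyclic(rbind(c("A", "B"), c("B", "C"), c("C", "A")),
                          c("A", "B", "C")))
  expect_error(is_acyclic(rbind(c("A", "Z")), c("A", "B")), "unknown node")
})

test_that("node and DAG constructors enforce typing and admissibility", {
  nd <- bn_nodes(c("rs1", "G1", "D"), c("L", "E", "D"))
  expect_equal(nd$kind, c("discrete", "continuous", "continuous"))
  expect_equal(nd$levels, c(3L, NA_integer_, NA_integer_))
  expect_error(bn_nodes(c("a", "a"), "E"), "unique")
  expect_error(bn_nodes("a", "L", levels = 1), "levels")

  expect_error(bn_dag(nd, rbind(c("G1", "rs1"))), "locus")
  expect_error(bn_dag(nd, rbind(c("D", "rs1"))), "locus")
  expect_error(bn_dag(nd, rbind(c("G1", "D"), c("D", "G1"))), "cycle")
  expect_error(bn_dag(nd, rbind(c("G1", "D"), c("G1", "D"))), "duplicate")

  # locus-to-locus edges only under the explicit flag
  nd2 <- bn_nodes(c("rs1", "rs2", "D"), c("L", "L", "D"))
  expect_error(bn_dag(nd2, rbind(c("rs1", "rs2"))), "locus")
  expect_silent(bn_dag(nd2, rbind(c("rs1", "rs2")), allow_locus_parents = TRUE))
})

test_that("constrained enumeration yields the documented counts", {
  nd <- bn_nodes(c("L", "E", "D"), c("L", "E", "D"))
  expect_length(enumerate_dags(nd), 12L)
  expect_length(enumerate_dags(bn_nodes("x", "E")), 1L)
  expect_length(enumerate_dags(bn_nodes(c("a", "b", "c"), "E")), 25L)
  # five-node role-constrained space (regression fixture)
  nd5 <- bn_nodes(c("L1", "L2", "E1", "E2", "D"), c("L", "L", "E", "E", "D"))
  expect_length(enumerate_dags(nd5), 1600L)
  expect_error(enumerate_dags(bn_nodes(paste0("x", 1:7), "E")), "capacity")
})

test_that("enumeration counts for unconstrained nodes match a brute-force oracle", {
  for (k in 2:4) {
    cand <- do.call(rbind, lapply(seq_len(k), function(u)
      do.call(rbind, lapply(setdiff(seq_len(k), u), function(v) c(u, v)))))
    oracle <- count_acyclic_subsets(cand, k)
    nd <- bn_nodes(paste0("x", seq_len(k)), "E")
    expect_equal(length(enumerate_dags(nd)), oracle)
  }
})

test_that("enumerated DAGs are unique, acyclic and admissible", {
  for (nd in list(bn_nodes(c("L", "E", "D"), c("L", "E", "D")),
                  bn_nodes(c("L1", "L2", "E1", "E2", "D"),
                           c("L", "L", "E", "E", "D")))) {
    dags <- enumerate_dags(nd)
    keys <- vapply(dags, function(d) npars:::edge_key(d$edges), character(1))
    expect_false(anyDuplicated(keys) > 0)
    role <- setNames(nd$role, nd$name)
    for (d in dags) {
      expect_true(is_acyclic(d$edges, nd$name))
      if (nrow(d$edges))
        expect_false(any(role[d$edges[, "child"]] == "L"))
    }
    # canonical order: sorted edge-label lists are non-decreasing
    expect_equal(keys, keys[npars:::order_edge_lists(
      lapply(dags, function(d) sort(paste0(d$edges[, 1], "->", d$edges[, 2]))))])
  }
})

test_that("the triplet catalog has 12 stable members with the pinned indices", {
  cat12 <- triplet_catalog()
  expect_length(cat12, 12L)
  expect_equal(vapply(cat12, attr, 1L, "index"), 1:12)
  expect_equal(nrow(cat12[[1]]$edges), 0L)  # empty structure is a member
  expect_equal(npars:::edge_key(cat12[[2]]$edges), "L->E")  # pinned null

  # degree-zero filter: exactly 7 survivors, and the no-isolated-node
  # predicate coincides with having at least two edges
  iso <- vapply(cat12, has_isolated_node, logical(1))
  ne <- vapply(cat12, function(g) nrow(g$edges), integer(1))
  expect_equal(sum(!iso), 7L)
  expect_equal(!iso, ne >= 2L)

  # catalog members are exactly the admissible triplet DAGs
  nd <- bn_nodes(c("L", "E", "D"), c("L", "E", "D"))
  enum_keys <- sort(vapply(enumerate_dags(nd), function(d)
    npars:::edge_key(d$edges), character(1)))
  cat_keys <- sort(vapply(cat12, function(g) npars:::edge_key(g$edges),
                          character(1)))
  expect_equal(cat_keys, enum_keys)
})

test_that("isolated-node detection covers the catalog's selection rule", {
  nd <- bn_nodes(c("L", "E", "D"), c("L", "E", "D"))
  expect_true(has_isolated_node(bn_dag(nd, rbind(c("L", "E")))))
  expect_false(has_isolated_node(bn_dag(nd, rbind(c("L", "E"), c("E", "D")))))
  expect_true(has_isolated_node(bn_dag(nd, NULL)))
})

test_that("network serialization round-trips and DOT export lists edges", {
  nd <- bn_nodes(c("rs9", "CCL20", "auc"), c("L", "E", "D"))
  dag <- bn_dag(nd, rbind(c("rs9", "CCL20"), c("CCL20", "auc")))
  f <- tempfile(fileext = ".tsv")
  write_network(dag, f)
  back <- read_network(f)
  expect_equal(back$nodes, dag$nodes)
  expect_equal(back$edges, dag$edges)

  dot <- dag_to_dot(dag)
  expect_match(dot, "\"rs9\" -> \"CCL20\"", fixed = TRUE)
  expect_match(dot, "shape=box")
})
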