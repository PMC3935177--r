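sim_data <- function(id = 1, beta = 1.2, n = 150, seed = 9) {
  simulate_scenario(scenario_spec(id, beta = beta, n = n, seed = seed))$data
}

test_that("the partition planner counts one triplet per locus-transcript pair", {
  expect_equal(plan_partition(4, 2), 8)
  expect_equal(plan_partition(2330, 3554), 8280820)
  expect_equal(plan_partition(0, 10), 0)
})

test_that("triplet scoring reports one catalog structure per pair", {
  d <- sim_data()
  # restrict to 4 loci x 2 transcripts: 8 triplets, as in the worked diagram
  d4 <- npars:::cg_subset(d, c(paste0("L", 1:4), "E1", "E2", "D"),
                          complete = FALSE)
  res <- score_all_triplets(d4)
  expect_s3_class(res, "npars_triplets")
  expect_equal(nrow(res), 8L)
  expect_true(all(res$catalog_index %in% 1:12))
  expect_true(all(is.finite(res$S) & is.finite(res$S0) & is.finite(res$phi)))
  expect_equal(res$phi, phi_score(res$S, res$S0, 0.5, 3), tolerance = 1e-12)
  # determinism
  expect_identical(res, score_all_triplets(d4))
})

test_that("the reported triplet structure maximizes S over the whole catalog", {
  d <- sim_data(seed = 21)
  pr <- empirical_prior(d, nu = 3)
  res <- score_all_triplets(d, prior = pr)
  for (row in c(1L, 7L, 13L, 25L)) {
    l <- res$locus[row]; e <- res$transcript[row]
    nodes <- bn_nodes(c(l, e, "D"), c("L", "E", "D"))
    scores <- vapply(seq_len(12), function(i) {
      edges <- triplet_edges_named(i, l, e, "D")
      network_score(bn_dag(nodes, edges), d, pr)
    }, numeric(1))
    expect_equal(res$S[row], max(scores), tolerance = 1e-9)
  }
})

test_that("selection filters isolated-node structures and ranks by phi", {
  tab <- data.frame(
    locus = paste0("L", 1:5), transcript = "E1",
    structure = "x", catalog_index = c(2L, 10L, 11L, 12L, 9L),
    n_edges = c(1L, 3L, 2L, 2L, 2L),
    S = -(1:5), S0 = -(2:6), phi = c(-9, -5, -1, -3, -1),
    n_used = 10L, stringsAsFactors = FALSE)
  tab$triplet_id <- seq_len(nrow(tab))
  sel <- select_triplets(tab, k1 = 10)
  expect_equal(nrow(sel), 4L)             # the 1-edge row is gone
  expect_equal(sel$phi, c(-1, -1, -3, -5))  # non-increasing
  expect_equal(sel$triplet_id[1:2], c(3L, 5L))  # stable tie-break by id
  expect_equal(nrow(select_triplets(tab, k1 = 2)), 2L)
  empty <- tab[tab$n_edges > 5, ]
  expect_warning(out <- select_triplets(empty), "no triplet")
  expect_equal(nrow(out), 0L)
})

test_that("reassembly enumerates each unordered pair once", {
  sel <- data.frame(locus = paste0("L", 1:100), transcript = "E1")
  pairs <- plan_reassembly(sel)
  expect_equal(nrow(pairs), 4950L)
  expect_false(anyDuplicated(paste(pairs[, 1], pairs[, 2])) > 0)
  expect_true(all(pairs[, 1] < pairs[, 2]))
  expect_equal(nrow(plan_reassembly(sel[1, , drop = FALSE])), 0L)
})

test_that("reassembled networks have 4-5 nodes and are ranked by phi", {
  d <- sim_data(seed = 33)
  trip <- score_all_triplets(d)
  sel <- select_triplets(trip, k1 = 6)
  skip_if(nrow(sel) < 2, "too few survivors in this fixture")
  nets <- reassemble_pairs(sel, d, k2 = 20)
  expect_s3_class(nets, "npars_networks")
  expect_true(all(nets$n_nodes %in% 4:5))
  expect_true(all(diff(nets$phi) <= 0))
  expect_equal(nets$phi, phi_score(nets$S, nets$S0, 0.5, nets$n_nodes),
               tolerance = 1e-12)
  # a pair sharing its locus yields a 4-node union
  shared <- sel[1:2, ]
  shared$locus <- shared$locus[1]
  shared$transcript <- c("E1", "E2")
  nets4 <- reassemble_pairs(shared, d, k2 = 1)
  expect_equal(nets4$n_nodes, 4L)
})

test_that("growth by one triplet respects the capacity guard", {
  d <- sim_data(seed = 33)
  # hand-built ranked selection: three mutually disjoint triplets
  sel <- data.frame(locus = c("L1", "L2", "L3"),
                    transcript = c("E1", "E2", "E3"),
                    triplet_id = 1:3, stringsAsFactors = FALSE)
  bases <- reassemble_pairs(sel[1:2, ], d, k2 = 1)
  expect_equal(bases$n_nodes, 5L)

  # a disjoint extra triplet would make a 7-node union: skipped under the
  # default guard, grown once the guard admits it
  expect_message(unchanged <- grow_networks(bases, sel, d), "capacity guard")
  expect_identical(unchanged, bases)
  grown <- grow_networks(bases, rbind(sel[1:2, ],
                                      data.frame(locus = "L3",
                                                 transcript = "E1",
                                                 triplet_id = 4L)), d,
                         max_nodes = 6)
  expect_equal(grown$n_nodes, 6L)

  # nothing new to add: bases returned unchanged
  expect_identical(grow_networks(bases, sel[1:2, ], d), bases)
})

test_that("the fitter recovers a strongly linked five-node network", {
  sim <- simulate_scenario(scenario_spec(1, beta = 1.5, n = 400, seed = 4))
  fit <- npars(sim$data, k1 = Inf, k2 = 3)
  expect_s3_class(fit, "npars")
  rep <- npars:::reported_network(fit)
  expect_setequal(rep$nodes, sim$truth$nodes)
  expect_output(print(fit), "nPARS network search")
  expect_output(summary(fit), "Top selected triplets")
})

test_that("the fitter accepts raw matrices and falls back gracefully", {
  set.seed(17)
  g <- matrix(sample(0:2, 120, TRUE), 40, dimnames = list(NULL, c("r1", "r2", "r3")))
  e <- matrix(rnorm(80, 10, 3), 40, dimnames = list(NULL, c("t1", "t2")))
  ph <- rnorm(40)
  fit <- suppressWarnings(npars(g, e, ph, k1 = 10, k2 = 5))
  expect_s3_class(fit, "npars")
  expect_equal(nrow(fit$triplets), 6L)
})
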