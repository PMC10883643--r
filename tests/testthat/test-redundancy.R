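# Redundancy criteria, graph construction, greedy pruning, updates

test_that("sequence redundancy uses strict 60%/1e-30 cutoffs", {
  hits <- data.frame(identity = c(1.00, 0.60, 0.95, 0.601),
                     e_value = c(1e-80, 1e-80, 1e-20, 1e-31))
  expect_equal(sequence_redundant(hits), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("complex redundancy needs all chain types plus RMSD below 5", {
  expect_true(complex_redundant(c(TRUE, TRUE, TRUE), 3.2))
  expect_false(complex_redundant(c(TRUE, TRUE, TRUE), 8.0))
  expect_false(complex_redundant(c(TRUE, FALSE, TRUE), 1.0))
  expect_false(complex_redundant(c(TRUE, TRUE, TRUE), 5.0))
  expect_error(complex_redundant(c(TRUE, TRUE), NA), "RMSD")
})

test_that("graph construction preserves isolated nodes and collapses duplicates", {
  nodes <- letters[1:5]
  g0 <- build_graph(data.frame(case_a = character(0),
                               case_b = character(0),
                               redundant = logical(0)), nodes)
  expect_equal(igraph::vcount(g0), 5)
  expect_equal(igraph::ecount(g0), 0)
  v <- data.frame(case_a = c("a", "b", "a"), case_b = c("b", "a", "c"),
                  redundant = c(TRUE, TRUE, FALSE))
  g <- build_graph(v, nodes)
  expect_equal(igraph::ecount(g), 1)  # (a,b)+(b,a) collapse; (a,c) not redundant
})

test_that("edge count on a larger verdict fixture matches a direct recount", {
  set.seed(7)
  n <- 40
  ids <- sprintf("c%02d", 1:n)
  pairs <- t(combn(ids, 2))
  red <- runif(nrow(pairs)) < 0.1
  v <- data.frame(case_a = pairs[, 1], case_b = pairs[, 2], redundant = red)
  g <- build_graph(v, ids)
  expect_equal(igraph::ecount(g), sum(red))
})

test_that("pruning a triangle keeps one node, a star keeps its leaves", {
  tri <- build_graph(data.frame(case_a = c("a", "a", "b"),
                                case_b = c("b", "c", "c"),
                                redundant = TRUE), c("a", "b", "c"))
  pr <- prune_max_degree(tri)
  expect_equal(length(pr$retained), 1L)
  expect_equal(nrow(pr$log), 2L)

  star <- build_graph(data.frame(case_a = "c", case_b = paste0("l", 1:5),
                                 redundant = TRUE), c("c", paste0("l", 1:5)))
  ps <- prune_max_degree(star)
  expect_equal(ps$log$removed[1], "c")       # max degree removed first
  expect_equal(ps$log$degree[1], 5L)
  expect_setequal(ps$retained, paste0("l", 1:5))
})

test_that("an edgeless graph is already non-redundant: nothing is removed", {
  g <- build_graph(data.frame(case_a = character(0), case_b = character(0),
                              redundant = logical(0)), letters[1:4])
  pr <- prune_max_degree(g)
  expect_setequal(pr$retained, letters[1:4])
  expect_equal(nrow(pr$log), 0L)
})

test_that("pruned sets are independent and match brute force on all graphs up to 5 nodes", {
  for (n in 2:5) {
    ids <- letters[seq_len(n)]
    for (code in 0:(2^choose(n, 2) - 1)) {
      adj <- graph_from_code(code, n)
      g <- build_graph(adj_to_verdicts(adj, ids), ids)
      pr <- prune_max_degree(g)
      expect_true(is_independent(pr$retained, adj, ids))
      expect_identical(pr$retained, brute_prune(adj, ids))
      expect_true(all(pr$log$degree >= 1))
    }
  }
})

test_that("pruning is deterministic per tie-break mode", {
  set.seed(31)
  adj <- graph_from_code(sample(0:(2^21 - 1), 1), 7)
  ids <- letters[1:7]
  g <- build_graph(adj_to_verdicts(adj, ids), ids)
  expect_identical(prune_max_degree(g), prune_max_degree(g))
  r1 <- prune_max_degree(g, seed = 5)
  r2 <- prune_max_degree(g, seed = 5)
  expect_identical(r1, r2)
  expect_true(is_independent(r1$retained, adj, ids))
})

test_that("synthetic families produce the redundancy graph they were built for", {
  # identical copies: one edge, one survivor
  fam <- generate_redundant_family(n_copies = 2, seed = 5)
  dd <- dedupe_cases(fam$cases)
  expect_true(all(dd$verdicts$redundant == fam$expected_edges$redundant))
  expect_equal(length(dd$retained), 1L)

  # identical sequences, large conformational change: no edge
  fam2 <- generate_redundant_family(n_copies = 2,
                                    divergent = c(FALSE, TRUE), seed = 5)
  dd2 <- dedupe_cases(fam2$cases)
  expect_false(any(dd2$verdicts$redundant))
  expect_true(all(dd2$verdicts$sequence_redundant))
  expect_gt(dd2$verdicts$rmsd[1], 5)
  expect_equal(length(dd2$retained), 2L)

  # chain of 4 near-duplicates: retained count equals brute-force pruning
  fam4 <- generate_redundant_family(
    n_copies = 4, identity_targets = c(1, 0.95, 0.9, 0.85), seed = 8)
  dd4 <- dedupe_cases(fam4$cases)
  ids <- vapply(fam4$cases, function(x) x$case_id, character(1))
  adj <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  for (r in seq_len(nrow(fam4$expected_edges)))
    if (fam4$expected_edges$redundant[r]) {
      i <- fam4$expected_edges$case_a[r]; j <- fam4$expected_edges$case_b[r]
      adj[i, j] <- adj[j, i] <- 1L
    }
  expect_identical(dd4$retained, brute_prune(adj, ids))
})

test_that("updating with nothing new changes nothing", {
  fam <- generate_redundant_family(n_copies = 2,
                                   identity_targets = c(1, 0.3), seed = 2)
  res <- update_benchmark(fam$cases, list())
  expect_setequal(res$retained,
                  vapply(fam$cases, function(x) x$case_id, character(1)))
  expect_equal(res$added, character(0))
})

test_that("a dissimilar new case is added as its own group", {
  fam <- generate_redundant_family(n_copies = 3,
                                   identity_targets = c(1, 1, 0.5), seed = 4)
  ids <- vapply(fam$cases, function(x) x$case_id, character(1))
  stored <- dedupe_cases(fam$cases[1:2])$retained
  res <- update_benchmark(fam$cases[ids %in% stored],
                          new_cases = fam$cases[3])
  expect_equal(res$added, ids[3])
  expect_equal(length(res$retained), 2L)
})

test_that("a new case redundant with one stored case leaves one survivor", {
  fam <- generate_redundant_family(n_copies = 2, seed = 6)
  res <- update_benchmark(fam$cases[1], new_cases = fam$cases[2])
  expect_equal(length(res$retained), 1L)
  expect_equal(nrow(res$log), 1L)
})

test_that("incremental update matches rebuilding from scratch on small families", {
  for (seed in c(3, 11)) {
    fam <- generate_redundant_family(
      n_copies = 5, identity_targets = c(1, 0.97, 0.94, 0.75, 0.72),
      seed = seed)
    ids <- vapply(fam$cases, function(x) x$case_id, character(1))
    full <- dedupe_cases(fam$cases)$retained
    stored0 <- dedupe_cases(fam$cases[1:3])$retained
    inc <- update_benchmark(fam$cases[ids %in% stored0],
                            new_cases = fam$cases[4:5])$retained
    expect_identical(inc, full)
  }
})

test_that("an RMSD provider failure flags the case unresolved, not added", {
  fam <- generate_redundant_family(n_copies = 2, seed = 9)
  res <- update_benchmark(
    fam$cases[1], new_cases = fam$cases[2],
    rmsd_provider = function(a, b) stop("no structure"))
  expect_equal(res$unresolved, fam$cases[[2]]$case_id)
  expect_false(fam$cases[[2]]$case_id %in% res$retained)
  expect_true(fam$cases[[1]]$case_id %in% res$retained)
})
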