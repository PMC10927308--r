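test_that("proportional thresholding keeps the expected edge count", {
  set.seed(20)
  m <- random_weights(64)
  adj <- proportional_threshold(m, 0.10)
  expect_equal(sum(adj) / 2, 202)         # round(0.10 * 2016)
  full <- proportional_threshold(m, 1.0)
  expect_equal(sum(full) / 2, 64 * 63 / 2)
  expect_warning(proportional_threshold(random_weights(4), 0.01), "no edges")
})

test_that("threshold ties break deterministically and edge sets nest", {
  flat <- matrix(1, 10, 10); diag(flat) <- 0
  a1 <- proportional_threshold(flat, 0.05)
  a2 <- proportional_threshold(flat, 0.05)
  expect_identical(unclass(a1), unclass(a2))
  set.seed(21)
  m <- random_weights(20)
  prev <- proportional_threshold(m, 0.05)
  for (p in c(0.1, 0.2, 0.4, 0.8)) {
    nxt <- proportional_threshold(m, p)
    expect_true(all(nxt[prev == 1] == 1))   # nestedness
    prev <- nxt
  }
})

test_that("hand-checkable graph values are exact", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(global_efficiency(k4), 1.0)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(unname(nodal_efficiency(path3)), c(0.75, 1, 0.75))

  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  expect_equal(graph_transitivity(k3), 1.0)
  expect_equal(unname(nodal_clustering(k3)), rep(1, 3))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(graph_transitivity(star), 0)
  expect_equal(unname(nodal_clustering(star)[1]), 0)

  empty <- matrix(0, 5, 5)
  expect_equal(global_efficiency(empty), 0)
  expect_equal(graph_transitivity(empty), 0)
})

test_that("metrics agree exactly with brute-force enumeration", {
  set.seed(22)
  cases <- 0L
  for (p in c(0.2, 0.5, 0.8)) {
    for (rep in 1:35) {
      n <- sample(5:20, 1)
      adj <- random_adjacency(n, p)
      expect_equal(unname(nodal_efficiency(adj)), bf_nodal_efficiency(adj))
      expect_equal(graph_transitivity(adj), bf_transitivity(adj))
      expect_equal(unname(nodal_clustering(adj)), bf_clustering(adj))
      expect_equal(unname(node_degree(adj)), rowSums(adj))
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 100)
})

test_that("metric ranges hold on arbitrary graphs", {
  set.seed(23)
  for (rep in 1:20) {
    adj <- random_adjacency(sample(4:16, 1), runif(1, 0.1, 0.9))
    expect_true(global_efficiency(adj) >= 0 && global_efficiency(adj) <= 1)
    tr <- graph_transitivity(adj)
    expect_true(tr >= 0 && tr <= 1)
    ci <- nodal_clustering(adj)
    expect_true(all(ci >= 0 & ci <= 1))
  }
})

test_that("AUC integrates trapezoidally over the threshold axis", {
  th <- seq(0.05, 0.40, by = 0.01)
  expect_equal(metric_auc(th, rep(0.6, length(th))), 0.35 * 0.6)
  ramp <- seq(0, 1, length.out = length(th))
  expect_equal(metric_auc(th, ramp), 0.175)
  expect_equal(metric_auc(c(0.05, 0.40), c(0, 1)), 0.175)
  expect_error(metric_auc(0.05, 1), "2 threshold")
})

test_that("the default sweep has 36 nested thresholds and monotone efficiency", {
  set.seed(24)
  m <- random_weights(30)
  sw <- threshold_sweep(m)
  expect_length(sw$thresholds, 36)
  eff <- sw$global$global_efficiency
  expect_true(all(diff(eff) >= 0))        # nested edge sets
  sw2 <- threshold_sweep(m)
  expect_identical(sw, sw2)               # determinism
  auc <- sweep_auc(sw)
  expect_true(auc$global$global_efficiency >= 0 &&
                auc$global$global_efficiency <= 0.35)
  expect_equal(dim(sw$nodal$nodal_efficiency), c(30, 36))
})
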