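test_that("pair costs are the inverse sum of normalized endpoint scores", {
  inter <- inter_network("a", "b", rbind(c("u1", "v1"), c("u2", "v2")))
  mk <- function(label, scores) {
    structure(list(cell_label = label, metric = "pagerank", raw = scores,
                   normalized = scores, contributions = NULL),
              class = "iis_table")
  }
  iis1 <- mk("a", c(u1 = 1.0, u2 = 0.5))
  iis2 <- mk("b", c(v1 = 1.0, v2 = 0.5))
  s <- pair_costs(inter, iis1, iis2)
  expect_equal(s, c(0.5, 1.0))

  floor <- 1e-9
  iis1$normalized[["u1"]] <- floor
  iis2$normalized[["v1"]] <- floor
  s2 <- pair_costs(inter, iis1, iis2)
  expect_equal(s2[1L], 1 / (2 * floor))
  expect_true(all(is.finite(s2)))

  iis2$normalized <- iis2$normalized["v1"]
  expect_error(pair_costs(inter, iis1, iis2), "missing")
})

test_that("coverage is shared-endpoint, cell-respecting, and reflexive", {
  inter <- inter_network("a", "b",
                         rbind(c("u", "v"), c("u", "w"), c("p", "q")))
  cv <- coverage_relation(inter)
  pairs <- apply(inter$edges, 1L, paste, collapse = "-")
  dimnames(cv) <- list(pairs, pairs)
  expect_true(all(diag(cv)))
  expect_true(cv["u-v", "u-w"])   # shared cell-1 endpoint
  expect_false(cv["u-v", "p-q"])  # all four distinct

  # shared symbol across cells must not match across sides
  inter2 <- inter_network("a", "b", rbind(c("X", "Y"), c("Z", "X")))
  cv2 <- coverage_relation(inter2)
  expect_false(cv2[1L, 2L])
  expect_false(cv2[2L, 1L])
})

test_that("single-edge and star problems have the obvious optima", {
  single <- bridge_problem(inter_network("a", "b", rbind(c("u", "v"))),
                           alpha = 1, cost = 0.7)
  for (a in c(0.1, 1)) {
    s <- solve_bridges(single, a)
    expect_equal(s$selected, 1L)
    expect_equal(s$objective, 0.7)
  }

  # one cell-1 hub: any single pair covers all three edges
  star <- bridge_problem(
    inter_network("a", "b", rbind(c("u", "v1"), c("u", "v2"), c("u", "v3"))),
    alpha = 1, cost = c(0.9, 0.4, 0.6))
  s <- solve_bridges(star, 1)
  expect_equal(length(s$selected), 1L)
  expect_equal(s$objective, 0.4)
  expect_equal(length(s$covered), 3L)
})

test_that("solver and exhaustive oracle agree including tie-breaks", {
  set.seed(31)
  for (r in 1:30) {
    pb <- random_bridge_instance(n_pairs = sample(3:12, 1L))
    for (a in c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0)) {
      s <- solve_bridges(pb, a)
      b <- brute_force_bridges(pb, a)
      expect_equal(s$objective, b$objective, tolerance = 1e-9)
      expect_identical(s$selected, b$selected)
    }
  }
})

test_that("tie-break prefers fewer pairs then lexicographic order", {
  # two disjoint edges plus a duplicate-cost structure: equal-cost optima
  inter <- inter_network("a", "b",
                         rbind(c("u1", "v1"), c("u2", "v2"), c("u3", "v3")))
  pb <- bridge_problem(inter, alpha = 1 / 3, cost = c(1, 1, 1))
  s <- solve_bridges(pb)            # any single pair is optimal; pick pair 1
  expect_identical(s$selected, 1L)
  expect_identical(brute_force_bridges(pb, 1 / 3)$selected, 1L)
})

test_that("returned solutions are feasible and internally consistent", {
  set.seed(32)
  for (r in 1:10) {
    pb <- random_bridge_instance(n_pairs = sample(4:12, 1L))
    a <- sample(c(0.1, 0.2, 0.4, 0.6, 0.8, 1), 1L)
    s <- solve_bridges(pb, a)
    K <- ceiling(a * nrow(pb$pairs) - 1e-9)
    expect_gte(length(s$covered), K)
    # recompute coverage from the selected pairs, independent of the solver
    hit <- which(colSums(pb$coverage[s$selected, , drop = FALSE]) > 0L)
    expect_identical(s$covered, hit)
    expect_equal(s$objective, sum(pb$cost[s$selected]), tolerance = 1e-9)
  }
})

test_that("objective is non-decreasing in alpha and scale-invariant in cost", {
  set.seed(33)
  grid <- c(0.1, 0.2, 0.4, 0.6, 0.8, 1)
  for (r in 1:5) {
    pb <- random_bridge_instance(n_pairs = 10L)
    obj <- vapply(grid, function(a) solve_bridges(pb, a)$objective, numeric(1))
    expect_true(all(diff(obj) >= -1e-12))

    pb_scaled <- pb
    pb_scaled$cost <- pb$cost * 7.5
    expect_identical(solve_bridges(pb_scaled, 0.6)$selected,
                     solve_bridges(pb, 0.6)$selected)
  }
})

test_that("alpha sweep reports one row per alpha with matching counts", {
  set.seed(34)
  pb <- random_bridge_instance(n_pairs = 10L)
  sw <- alpha_sweep(pb)
  expect_equal(sw$summary$alpha, c(0.1, 0.2, 0.4, 0.6, 0.8))
  expect_true(all(sw$summary$n_covered >= sw$summary$coverage_target))
  for (i in seq_along(sw$solutions)) {
    expect_equal(sw$summary$objective[i], sw$solutions[[i]]$objective)
    bf <- brute_force_bridges(pb, sw$summary$alpha[i])
    expect_equal(sw$summary$objective[i], bf$objective, tolerance = 1e-9)
  }
})

test_that("the coverage target guards against binary-float overshoot", {
  # 0.1 * 30 is slightly above 3 in double arithmetic; the target must be 3
  inter <- inter_network("a", "b",
                         cbind(sprintf("u%02d", 1:30), sprintf("v%02d", 1:30)))
  pb <- bridge_problem(inter, alpha = 0.1, cost = rep(1, 30))
  s <- solve_bridges(pb, 0.1)
  expect_equal(length(s$selected), 3L)
})

test_that("the exhaustive oracle rejects oversized instances and empty selections", {
  inter <- inter_network("a", "b", cbind(sprintf("u%02d", 1:21),
                                         sprintf("v%02d", 1:21)))
  pb <- bridge_problem(inter, alpha = 0.5, cost = rep(1, 21))
  expect_error(brute_force_bridges(pb, 0.5), "20")

  small <- bridge_problem(inter_network("a", "b", rbind(c("u", "v"))),
                          alpha = 1, cost = 1)
  b <- brute_force_bridges(small, 1)
  expect_gte(length(b$selected), 1L)  # empty selection infeasible for alpha > 0
})
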