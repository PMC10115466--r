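test_that("pagerank satisfies its contract on degenerate and symmetric graphs", {
  single <- cell_network("c", proteins = "A")
  expect_equal(pagerank_centrality(single)$scores, c(A = 1))

  tri <- cell_network("c", rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  pr <- pagerank_centrality(tri)$scores
  expect_equal(unname(pr), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(pr), 1, tolerance = 1e-6)

  star <- cell_network("c", rbind(c("H", "L1"), c("H", "L2"), c("H", "L3")))
  prs <- pagerank_centrality(star)$scores
  expect_true(all(prs["H"] > prs[c("L1", "L2", "L3")]))
  expect_equal(prs, oracle_pagerank(star)[names(prs)], tolerance = 1e-9)
})

test_that("pagerank matches the dense power-iteration oracle on random graphs", {
  set.seed(21)
  for (r in 1:10) {
    net <- random_cell_net(n = sample(5:15, 1L))
    pr <- pagerank_centrality(net)$scores
    expect_equal(pr, oracle_pagerank(net)[names(pr)], tolerance = 1e-9)
    expect_equal(sum(pr), 1, tolerance = 1e-6)
    expect_true(all(pr >= 0))
  }
})

test_that("pagerank is equivariant under node relabeling", {
  set.seed(22)
  net <- random_cell_net(10L)
  perm <- sample(net$proteins)
  relabel <- stats::setNames(perm, net$proteins)
  em <- cbind(relabel[net$edges[, 1L]], relabel[net$edges[, 2L]])
  net_p <- cell_network("c", em, proteins = unname(perm))
  pr <- pagerank_centrality(net)$scores
  pr_p <- pagerank_centrality(net_p)$scores
  expect_equal(unname(pr_p[relabel[names(pr)]]), unname(pr), tolerance = 1e-12)
})

test_that("betweenness matches single-geodesic intuition and the enumeration oracle", {
  path3 <- cell_network("c", rbind(c("A", "B"), c("B", "C")))
  bt <- betweenness_centrality(path3)$scores
  expect_equal(bt[["B"]], 1)
  expect_equal(unname(bt[c("A", "C")]), c(0, 0))

  k4 <- cell_network("c", t(utils::combn(c("A", "B", "C", "D"), 2L)))
  expect_equal(unname(betweenness_centrality(k4)$scores), rep(0, 4))

  set.seed(23)
  for (r in 1:3) {
    net <- random_cell_net(8L, p_edge = 0.35)
    bt <- betweenness_centrality(net)$scores
    expect_equal(bt, oracle_betweenness(net)[names(bt)], tolerance = 1e-9)
  }
})

test_that("pruned distance graphs split contact-contact from the rest", {
  net <- cell_network("c", rbind(c("c1", "n1"), c("n1", "c2"), c("c1", "c2")),
                      contacts = c("c1", "c2"))
  pg <- pruned_distance_graphs(net)
  expect_equal(pg$noncontact_paths$edges,
               rbind(c("c1", "n1"), c("c2", "n1")))
  expect_equal(pg$contact_only$edges, rbind(c("c1", "c2")))
  expect_setequal(pg$contact_only$proteins, c("c1", "c2"))

  no_cc <- cell_network("c", rbind(c("c1", "n1"), c("n1", "c2")),
                        contacts = c("c1", "c2"))
  expect_identical(pruned_distance_graphs(no_cc)$noncontact_paths$edges,
                   no_cc$edges)

  all_contact <- cell_network("c", rbind(c("c1", "c2"), c("c2", "c3")),
                              contacts = c("c1", "c2", "c3"))
  pg2 <- pruned_distance_graphs(all_contact)
  expect_equal(nrow(pg2$noncontact_paths$edges), 0L)
  expect_identical(pg2$contact_only$edges, all_contact$edges)
})

test_that("IIS combines centrality over distance on the two pruned graphs", {
  # triangle c1-c2-n1: c2 is at distance 1 in the contact-only graph and n1
  # at distance 1 with the contact-contact edge removed
  net <- cell_network("c", rbind(c("c1", "n1"), c("n1", "c2"), c("c1", "c2")),
                      contacts = c("c1", "c2"))
  pr <- pagerank_centrality(net)$scores
  iis <- compute_iis(net, pagerank_centrality(net))
  expect_equal(iis$raw[["c1"]], pr[["n1"]] / 1 + pr[["c2"]] / 1,
               tolerance = 1e-12)
  expect_equal(sum(iis$contributions[["c1"]]), iis$raw[["c1"]],
               tolerance = 1e-9)

  # without the direct c1-c2 edge, c2 is unreachable on the contact-only
  # graph: the path through n1 must not be used for the contact term
  net2 <- cell_network("c", rbind(c("c1", "n1"), c("n1", "c2")),
                       contacts = c("c1", "c2"))
  pr2 <- pagerank_centrality(net2)$scores
  iis2 <- compute_iis(net2, pagerank_centrality(net2))
  expect_equal(iis2$raw[["c1"]], pr2[["n1"]] / 1, tolerance = 1e-12)

  # an intracellularly isolated contact scores 0
  net3 <- cell_network("c", rbind(c("A", "B")), proteins = c("A", "B", "c0"),
                       contacts = "c0")
  iis3 <- compute_iis(net3, pagerank_centrality(net3))
  expect_equal(iis3$raw[["c0"]], 0)
})

test_that("IIS matches the first-principles BFS oracle on random networks", {
  set.seed(24)
  for (r in 1:12) {
    net <- random_cell_net(n = sample(6:20, 1L))
    ct <- pagerank_centrality(net)
    iis <- compute_iis(net, ct)
    expect_equal(iis$raw, oracle_iis(net, ct$scores)[names(iis$raw)],
                 tolerance = 1e-9)
  }
})

test_that("adding a disconnected component leaves existing IIS unchanged", {
  set.seed(25)
  net <- random_cell_net(10L)
  ct <- pagerank_centrality(net)
  iis <- compute_iis(net, ct)
  extra <- cell_network(net$cell_label,
                        rbind(net$edges, c("ZZ1", "ZZ2"), c("ZZ2", "ZZ3")),
                        proteins = c(net$proteins, "ZZ1", "ZZ2", "ZZ3"),
                        contacts = net$contacts)
  # reuse the same per-protein centrality values for the original nodes
  ct2 <- ct
  ct2$scores <- c(ct$scores, ZZ1 = 0.01, ZZ2 = 0.01, ZZ3 = 0.01)
  iis2 <- compute_iis(extra, ct2)
  expect_equal(iis2$raw[names(iis$raw)], iis$raw, tolerance = 1e-12)
})

test_that("normalization scales to the per-cell max and applies the floor", {
  tab <- structure(list(cell_label = "c", metric = "pagerank",
                        raw = c(p1 = 2, p2 = 4), normalized = NULL,
                        contributions = list(p1 = numeric(0), p2 = numeric(0))),
                   class = "iis_table")
  out <- normalize_iis(tab)
  expect_equal(out$normalized, c(p1 = 0.5, p2 = 1.0))

  tab$raw <- c(p1 = 0, p2 = 5)
  out <- normalize_iis(tab, floor = 1e-9)
  expect_equal(out$normalized, c(p1 = 1e-9, p2 = 1.0))

  tab$raw <- c(p1 = 3)
  expect_equal(normalize_iis(tab)$normalized, c(p1 = 1.0))

  tab$raw <- c(p1 = 0, p2 = 0)
  expect_error(normalize_iis(tab), "positive")
})

test_that("top contributors sort by term, break ties lexicographically, cap at k", {
  tab <- structure(list(cell_label = "c", metric = "pagerank",
                        raw = c(c1 = 0.6), normalized = NULL,
                        contributions = list(
                          c1 = c(n2 = 0.1, n1 = 0.3, n3 = 0.1, n4 = 0.1))),
                   class = "iis_table")
  tc <- top_contributors(tab, "c1")
  expect_equal(tc$contributor, c("n1", "n2", "n3", "n4"))
  expect_equal(top_contributors(tab, "c1", k = 2L)$contributor, c("n1", "n2"))
  expect_error(top_contributors(tab, "zz"), "unknown")
})

test_that("IIS tables round-trip through TSV export", {
  set.seed(26)
  net <- random_cell_net(10L)
  iis <- normalize_iis(compute_iis(net, pagerank_centrality(net)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_iis_table(iis, f)
  back <- read_iis_table(f)
  prot <- sort(names(iis$raw))
  expect_equal(back$raw[prot], iis$raw[prot], tolerance = 1e-10)
  expect_equal(back$normalized[prot], iis$normalized[prot], tolerance = 1e-10)
})
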