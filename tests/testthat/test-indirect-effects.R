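toy <- toy_disease_network()
net <- toy$network

test_that("one-step and pathway effects follow receiver-degree reciprocals", {
  expect_equal(one_step_effect(net, "red", "green"), 1 / 2)
  expect_equal(one_step_effect(net, "green", "black"), 1 / 7)
  expect_equal(one_step_effect(net, "red", "black"), 0) # not adjacent
  expect_error(one_step_effect(net, "red", "nosuch"), "unknown node")

  expect_equal(pathway_effect(net, "red", "green", "black"), 1 / 14)
  expect_equal(pathway_effect(net, "red", "yellow", "black"), 1 / 35)
  expect_equal(pathway_effect(net, "red", "blue1", "black"), 0)
  expect_error(pathway_effect(net, "red", "red", "black"), "distinct")
})

test_that("two-step effect matrix reproduces the toy arithmetic in both directions", {
  em <- effect_matrix(net, 2)
  expect_equal(effect_value(em, "red", "black"), 1 / 10, tolerance = 1e-12)
  expect_equal(effect_value(em, "black", "red"), 7 / 30, tolerance = 1e-12)
  expect_equal(mutual_dependence(net, "red", "black"), 1 / 3,
               tolerance = 1e-12)
  expect_error(mutual_dependence(net, "red", "red"), "distinct")
  expect_error(effect_matrix(net, 0), "n must be >= 1")
})

test_that("every receiver row of a^n sums to one for connected nodes", {
  graphs <- c(list(list(network = net)), random_graph_pool(n_graphs = 10L))
  for (fix in graphs) {
    g <- fix$network
    d <- node_degree(g)
    for (n in 1:4) {
      a <- effect_matrix(g, n)$values
      rs <- rowSums(a)
      expect_true(all(abs(rs[d > 0] - 1) <= 1e-12))
      expect_true(all(rs[d == 0] == 0))
      expect_true(all(a >= 0 & a <= 1 + 1e-15))
    }
  }
})

test_that("matrix power agrees with explicit walk enumeration", {
  for (fix in random_graph_pool(n_graphs = 6L, n_max = 8L)) {
    g <- fix$network
    ids <- igraph::V(g)$name
    for (n in 1:3) {
      a <- effect_matrix(g, n)$values
      for (src in ids) {
        for (rec in ids) {
          expect_equal(a[rec, src], brute_force_effect(g, src, rec, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("sparse and dense effect matrices are identical", {
  for (n in 1:3) {
    dense <- effect_matrix(net, n, sparse = FALSE)$values
    sparse <- as.matrix(effect_matrix(net, n, sparse = TRUE)$values)
    expect_equal(dense, sparse, tolerance = 1e-15)
  }
})

test_that("topological importance sums effects on other nodes, in both modes", {
  # green's receivers in one step: red (D=3) and black (D=7)
  expect_equal(topological_importance(net, "green", 1), 1 / 3 + 1 / 7,
               tolerance = 1e-12)
  iso <- net_from("A-B", nodes = "C")
  expect_equal(topological_importance(iso, "C", 3), 0)
  # cumulative mean averages the per-step totals
  ti1 <- topological_importance(net, "yellow", 1)
  ti2 <- topological_importance(net, "yellow", 2)
  expect_equal(topological_importance(net, "yellow", 2, "cumulative_mean"),
               (ti1 + ti2) / 2, tolerance = 1e-12)
  # oracle check on a random graph
  g <- random_graph_pool(n_graphs = 1L)[[1]]$network
  j <- igraph::V(g)$name[1L]
  others <- setdiff(igraph::V(g)$name, j)
  oracle <- sum(vapply(others, function(i) brute_force_effect(g, j, i, 2),
                       numeric(1)))
  expect_equal(topological_importance(g, j, 2), oracle, tolerance = 1e-12)
})

test_that("TI^1 of a newly connected node never decreases", {
  for (fix in random_graph_pool(n_graphs = 5L)) {
    g <- fix$network
    iso <- "NEWNODE"
    g0 <- interaction_network(igraph::as_edgelist(g, names = TRUE),
                              nodes = c(igraph::V(g)$name, iso))
    before <- topological_importance(g0, iso, 1)
    expect_equal(before, 0)
    partner <- igraph::V(g)$name[1L]
    g1 <- interaction_network(rbind(igraph::as_edgelist(g, names = TRUE),
                                    c(iso, partner)))
    expect_gte(topological_importance(g1, iso, 1), before)
  }
})

test_that("aggregate set effect sums cross-pair effects and skips self-pairs", {
  pe <- set_effect(net, sources = "red", receivers = "black", n = 2)
  expect_equal(pe$value, 1 / 10, tolerance = 1e-12)
  expect_equal(dim(pe$contributions), c(1L, 1L))

  # sets with no two-step walk between them (blue1 and white1 sit at
  # distance 3, so no common neighbour links them)
  far <- set_effect(net, sources = "blue1", receivers = "white1", n = 2)
  expect_equal(far$value, 0)

  # shared protein contributes no self-effect
  both <- set_effect(net, sources = c("red", "green"),
                     receivers = c("green", "black"), n = 2)
  em <- effect_matrix(net, 2)
  manual <- effect_value(em, "red", "green") + effect_value(em, "red", "black") +
    effect_value(em, "green", "black")
  expect_equal(both$value, manual, tolerance = 1e-12)

  same <- set_effect(net, sources = "red", receivers = "red", n = 2)
  expect_equal(same$value, 0)
  expect_error(set_effect(net, character(), "black"), "non-empty")
})

test_that("mediator contributions count both directions through a common neighbour", {
  expect_equal(mediator_contribution(net, "yellow", "red", "black"),
               1 / 15 + 1 / 35, tolerance = 1e-12)
  expect_equal(mediator_contribution(net, "green", "red", "black"),
               5 / 21, tolerance = 1e-12)
  expect_equal(mediator_contribution(net, "blue1", "red", "black"), 0)
  expect_error(mediator_contribution(net, "red", "red", "black"), "distinct")
})

test_that("mediator table decomposes the two-direction two-step effects exactly", {
  mt <- mediator_table(net, "red", "black", "X", "Y")
  expect_setequal(mt$totals$mediator, c("green", "yellow"))
  expect_equal(mt$totals$M2_total[mt$totals$mediator == "green"], 5 / 21,
               tolerance = 1e-12)
  expect_equal(mt$totals$M2_total[mt$totals$mediator == "yellow"],
               1 / 15 + 1 / 35, tolerance = 1e-12)

  # distance >= 3: no mediator rows
  far <- mediator_table(net, "blue1", "white1")
  expect_equal(nrow(far$pairs), 0L)

  # decomposition identity against the matrix-power route, random graphs
  for (fix in random_graph_pool(n_graphs = 6L)) {
    g <- fix$network
    ids <- igraph::V(g)$name
    half <- length(ids) %/% 2
    mt <- mediator_table(g, ids[1:half], ids[(half + 1):length(ids)])
    a2 <- effect_matrix(g, 2)$values
    for (r in seq_len(nrow(mt$pair_strengths))) {
      i <- mt$pair_strengths$i[r]; j <- mt$pair_strengths$j[r]
      m2_sum <- sum(mt$pairs$M2[mt$pairs$i == i & mt$pairs$j == j])
      expect_equal(m2_sum, a2[i, j] + a2[j, i], tolerance = 1e-12)
      expect_equal(mt$pair_strengths$total[r], a2[i, j] + a2[j, i],
                   tolerance = 1e-12)
    }
  }

  expect_warning(mediator_table(net, c("red", "green"), c("green", "black")),
                 "overlap")
})
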