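test_that("elementary graph reproduces all four pairwise energies", {
  term <- pairwise_term(0, 1, 1, 0)
  eg <- elementary_graph(term, 1, 2)
  expect_equal(eg$cap_ij, 2)
  # enumeration over the four assignments via a 2-node network
  net <- flow_network(2)
  net <- add_pairwise(net, 1, 2, 0, 1, 1, 0)
  for (xi in 0:1) for (xj in 0:1) {
    want <- c(0, 1, 1, 0)[xi * 2 + xj + 1]
    # clamp both nodes to (xi, xj) with large unaries on the other label;
    # the minimum energy is then the represented pairwise energy
    netc <- add_unary(net, 1:2, cost0 = 1e4 * c(xi, xj),
                      cost1 = 1e4 * c(1 - xi, 1 - xj))
    expect_equal(max_flow(netc)$energy, want, tolerance = 1e-9)
  }
})

test_that("null and constant pairwise terms produce no structural edges", {
  eg0 <- elementary_graph(pairwise_term(0, 0, 0, 0), 1, 2)
  expect_equal(unlist(eg0[c("d_cap_source_i", "d_cap_sink_i",
                            "d_cap_source_j", "d_cap_sink_j",
                            "cap_ij", "d_constant")]),
               c(d_cap_source_i = 0, d_cap_sink_i = 0, d_cap_source_j = 0,
                 d_cap_sink_j = 0, cap_ij = 0, d_constant = 0))
  eg5 <- elementary_graph(pairwise_term(5, 5, 5, 5), 1, 2)
  expect_equal(eg5$d_constant, 5)
  expect_equal(eg5$cap_ij, 0)
  expect_equal(eg5$d_cap_source_i + eg5$d_cap_sink_i +
                 eg5$d_cap_source_j + eg5$d_cap_sink_j, 0)
})

test_that("non-submodular terms are rejected with the violation margin", {
  err <- tryCatch(pairwise_term(2, 0, 0, 2), error = identity)
  expect_s3_class(err, "phaseflow_nonsubmodular")
  expect_equal(err$margin, 4)
  expect_error(add_pairwise(flow_network(2), 1, 2, 2, 0, 0, 2),
               "not submodular|non-submodular")
})

test_that("max_flow solves toy networks exactly", {
  # one node with raw terminal caps s->v = 3, v->t = 5: flow min(3, 5),
  # cheaper to cut the source arc, so the node ends sink-side (label 1)
  net1 <- flow_network(1)
  net1$cap_source[1] <- 3; net1$cap_sink[1] <- 5
  r1 <- max_flow(net1)
  expect_equal(r1$flow_value, 3)
  expect_equal(r1$labels, 1L)
  # the equivalent unary (cost0 = 5, cost1 = 3) absorbs min(3, 5) into the
  # offset; the minimum energy is the same
  expect_equal(max_flow(add_unary(flow_network(1), 1, 5, 3))$energy, 3)
  # two nodes, s->a = 2, b->t = 2, edge a<->b cap 1: min cut 1
  r2 <- cpp_flow <- phaseflow:::cpp_maxflow(2L, c(2, 0), c(0, 2), 1L, 2L, 1, 0)
  expect_equal(r2$flow, 1)
  expect_error(max_flow(flow_network(0)), "n_nodes|empty")
})

test_that("graph-cut minimum equals exhaustive enumeration on random MRFs", {
  set.seed(42)
  for (rep in 1:500) {
    n <- sample(2:12, 1)
    m <- random_submodular_mrf(n)
    got <- max_flow(m$net)$energy
    want <- enum_min(m$u0, m$u1, m$pe)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("constrained solves equal constrained enumeration and reuse
           matches cold re-solves", {
  set.seed(43)
  for (rep in 1:100) {
    n <- 8
    m <- random_submodular_mrf(n)
    mm <- min_marginals_all(m$net)
    for (v in seq_len(n)) {
      for (l in 0:1) {
        want <- enum_constrained(m$u0, m$u1, m$pe, v, l)
        psi <- if (l == 0) mm$psi0[v] else mm$psi1[v]
        expect_equal(psi, want, tolerance = 1e-8)
        expect_equal(solve_constrained(m$net, v, l, method = "cold"), want,
                     tolerance = 1e-8)
        expect_equal(solve_constrained(m$net, v, l, method = "reuse"), want,
                     tolerance = 1e-8)
      }
    }
    # monotonicity and MAP consistency of min-marginals
    expect_true(all(pmin(mm$psi0, mm$psi1) - mm$energy > -1e-9))
    expect_equal(pmin(mm$psi0, mm$psi1), rep(mm$energy, n),
                 tolerance = 1e-8)
  }
})

test_that("disconnected node min-marginals differ by the terminal gap", {
  net <- add_unary(flow_network(3), 2, cost0 = 7, cost1 = 2)
  mm <- min_marginals_all(net)
  expect_equal(mm$psi1[2] - mm$psi0[2], 2 - 7)
  expect_equal(mm$psi0[1], mm$psi1[1])   # untouched node: no preference
})

test_that("energies are invariant to node insertion order", {
  set.seed(44)
  u0 <- rnorm(6); u1 <- rnorm(6)
  pe <- rbind(c(1, 2, 0, 2, 2, 0), c(3, 4, 1, 3, 2, 0.5),
              c(5, 6, 0, 1, 1, 0), c(2, 5, 0.2, 2, 1, 0.1))
  build <- function(order_nodes, order_edges) {
    net <- flow_network(6)
    for (i in order_nodes) net <- add_unary(net, i, u0[i], u1[i])
    for (r in order_edges)
      net <- add_pairwise(net, pe[r, 1], pe[r, 2], pe[r, 3], pe[r, 4],
                          pe[r, 5], pe[r, 6])
    net
  }
  e1 <- max_flow(build(1:6, 1:4))$energy
  e2 <- max_flow(build(6:1, 4:1))$energy
  expect_equal(e1, e2, tolerance = 1e-10)
})
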