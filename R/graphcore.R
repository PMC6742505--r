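#' Pairwise energy term of a binary MRF
#'
#' Energies of the four assignments of a pair of binary variables. Exact
#' graph-cut minimisation requires submodularity,
#' `e00 + e11 <= e01 + e10`; violating terms are rejected with the margin of
#' violation so callers that handle non-submodular terms (by zeroing the
#' edge) can inspect it.
#'
#' @param e00,e01,e10,e11 energies of assignments (0,0), (0,1), (1,0), (1,1).
#' @param tol numerical slack allowed on the submodularity inequality.
#' @return An object of class `pairwise_term`.
#' @export
pairwise_term <- function(e00, e01, e10, e11, tol = 1e-9) {
  margin <- (e00 + e11) - (e01 + e10)
  if (margin > tol) {
    cond <- structure(
      class = c("phaseflow_nonsubmodular", "error", "condition"),
      list(message = sprintf(
             "pairwise term is not submodular (violation margin %.6g)", margin),
           call = sys.call(-1), margin = margin))
    stop(cond)
  }
  structure(list(e00 = e00, e01 = e01, e10 = e10, e11 = e11),
            class = "pairwise_term")
}

#' Flow network for a binary MRF
#'
#' An s/t flow network whose minimum cut, plus `constant_offset`, equals the
#' minimum of the represented binary energy. Convention: nodes on the source
#' side of the minimum cut take label 0, sink side label 1; `cap_source[i]`
#' (the arc s -> i) is therefore the cost charged when node i takes label 1,
#' and `cap_sink[i]` (arc i -> t) the cost of label 0.
#'
#' @param n_nodes number of MRF variables.
#' @return An object of class `flow_network`.
#' @export
flow_network <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L) stop("n_nodes must be >= 1")
  structure(list(n_nodes = n_nodes,
                 cap_source = numeric(n_nodes),
                 cap_sink = numeric(n_nodes),
                 edge_i = integer(0), edge_j = integer(0),
                 cap_ij = numeric(0), cap_ji = numeric(0),
                 constant_offset = 0),
            class = "flow_network")
}

#' Add unary terms to a flow network
#'
#' @param net a `flow_network`.
#' @param nodes node indices (1-based), recycled against the costs.
#' @param cost0,cost1 energies of labelling each node 0 resp. 1.
#' @return The updated network.
#' @export
add_unary <- function(net, nodes, cost0, cost1) {
  stopifnot(inherits(net, "flow_network"))
  m <- max(length(nodes), length(cost0), length(cost1))
  nodes <- rep_len(as.integer(nodes), m)
  cost0 <- rep_len(cost0, m); cost1 <- rep_len(cost1, m)
  if (any(nodes < 1L | nodes > net$n_nodes)) stop("node index out of range")
  # shift each pair so both capacities are nonnegative
  base <- pmin(cost0, cost1)
  net$constant_offset <- net$constant_offset + sum(base)
  net$cap_sink <- net$cap_sink + accum(net$n_nodes, nodes, cost0 - base)
  net$cap_source <- net$cap_source + accum(net$n_nodes, nodes, cost1 - base)
  net
}

#' Elementary graph of a single pairwise term
#'
#' Reparameterises one submodular pairwise term into terminal-capacity
#' increments for its two nodes, one pairwise arc capacity, and a constant:
#' `e00` is absorbed into the constant, `e10 - e00` goes on a terminal arc of
#' node i, `e11 - e10` on node j (negative parts swap terminal and move into
#' the constant), and the pairwise arc i -> j carries
#' `e01 + e10 - e00 - e11 >= 0`. For every assignment, cut cost plus constant
#' equals the term energy.
#'
#' @param term a [pairwise_term()].
#' @param i,j node indices.
#' @return A list with entries `i`, `j`, `d_cap_source_i`, `d_cap_sink_i`,
#'   `d_cap_source_j`, `d_cap_sink_j`, `cap_ij`, `d_constant`.
#' @export
elementary_graph <- function(term, i, j) {
  stopifnot(inherits(term, "pairwise_term"))
  gap <- max(term$e01 + term$e10 - term$e00 - term$e11, 0)
  a <- term$e10 - term$e00
  b <- term$e11 - term$e10
  list(i = i, j = j,
       d_cap_source_i = max(a, 0), d_cap_sink_i = max(-a, 0),
       d_cap_source_j = max(b, 0), d_cap_sink_j = max(-b, 0),
       cap_ij = gap,
       d_constant = term$e00 + min(a, 0) + min(b, 0))
}

#' Add pairwise terms to a flow network (vectorised)
#'
#' Applies the [elementary_graph()] reparameterisation to each term and
#' merges the increments into the network.
#'
#' @param net a `flow_network`.
#' @param i,j node index vectors.
#' @param e00,e01,e10,e11 energy vectors (recycled).
#' @param tol submodularity slack; terms violating it raise an error carrying
#'   the maximum margin.
#' @return The updated network.
#' @export
add_pairwise <- function(net, i, j, e00, e01, e10, e11, tol = 1e-9) {
  stopifnot(inherits(net, "flow_network"))
  m <- max(length(i), length(j), length(e00), length(e01),
           length(e10), length(e11))
  i <- rep_len(as.integer(i), m); j <- rep_len(as.integer(j), m)
  e00 <- rep_len(e00, m); e01 <- rep_len(e01, m)
  e10 <- rep_len(e10, m); e11 <- rep_len(e11, m)
  if (any(i < 1L | i > net$n_nodes | j < 1L | j > net$n_nodes))
    stop("node index out of range")
  margin <- (e00 + e11) - (e01 + e10)
  if (any(margin > tol)) {
    cond <- structure(
      class = c("phaseflow_nonsubmodular", "error", "condition"),
      list(message = sprintf(
             "non-submodular pairwise term(s); worst violation margin %.6g",
             max(margin)),
           call = sys.call(-1), margin = max(margin)))
    stop(cond)
  }
  gap <- pmax(e01 + e10 - e00 - e11, 0)
  a <- e10 - e00
  b <- e11 - e10
  net$constant_offset <- net$constant_offset +
    sum(e00) + sum(pmin(a, 0)) + sum(pmin(b, 0))
  net$cap_source <- net$cap_source + accum(net$n_nodes, i, pmax(a, 0)) +
    accum(net$n_nodes, j, pmax(b, 0))
  net$cap_sink <- net$cap_sink + accum(net$n_nodes, i, pmax(-a, 0)) +
    accum(net$n_nodes, j, pmax(-b, 0))
  keep <- gap > 0
  net$edge_i <- c(net$edge_i, i[keep])
  net$edge_j <- c(net$edge_j, j[keep])
  net$cap_ij <- c(net$cap_ij, gap[keep])
  net$cap_ji <- c(net$cap_ji, numeric(sum(keep)))
  net
}

#' Solve a flow network by max-flow / min-cut
#'
#' Finds the global minimum cut with an exact augmenting-path max-flow
#' solver. `flow_value` is the cut cost; adding `constant_offset` gives the
#' minimum energy of the represented MRF. Per-node labels on exact energy
#' ties are implementation-defined (source-reachable nodes take 0); energies
#' are not.
#'
#' @param net a `flow_network`.
#' @return An object of class `cut_result`: `flow_value`, `labels` (integer
#'   0/1 per node, 0 = source side), and `energy` (= flow + offset).
#' @export
max_flow <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  if (net$n_nodes < 1L) stop("empty graph")
  res <- cpp_maxflow(net$n_nodes, net$cap_source, net$cap_sink,
                     net$edge_i, net$edge_j, net$cap_ij, net$cap_ji)
  structure(list(flow_value = res$flow, labels = res$labels,
                 energy = res$flow + net$constant_offset),
            class = "cut_result")
}

#' Minimum energy with one node constrained to a label
#'
#' Returns the min-marginal energy: the minimum of the represented energy
#' over all labellings in which `node` is fixed to `label`. The default
#' `"reuse"` method re-solves on the residual flow of the unconstrained
#' optimum (constraining a node amounts to an infinite-capacity terminal
#' arc, so the extra flow is the residual flow between the node and the
#' opposite terminal); `"cold"` adds a finite sentinel capacity (greater
#' than the total finite capacity of the network) and re-solves from
#' scratch. Both are value-identical.
#'
#' @param net a `flow_network`.
#' @param node node index (1-based).
#' @param label 0 or 1.
#' @param method `"reuse"` or `"cold"`.
#' @return The constrained minimum energy (including `constant_offset`).
#' @export
solve_constrained <- function(net, node, label,
                              method = c("reuse", "cold")) {
  stopifnot(inherits(net, "flow_network"))
  method <- match.arg(method)
  node <- as.integer(node)
  if (is.na(node) || node < 1L || node > net$n_nodes)
    stop("invalid node index ", node)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  if (method == "reuse") {
    res <- cpp_min_marginals(net$n_nodes, net$cap_source, net$cap_sink,
                             net$edge_i, net$edge_j, net$cap_ij, net$cap_ji,
                             node, Inf)
    psi <- if (label == 0L) res$psi0[1] else res$psi1[1]
    return(psi + net$constant_offset)
  }
  sentinel <- sum(net$cap_source) + sum(net$cap_sink) +
    sum(net$cap_ij) + sum(net$cap_ji) + 1
  # forcing label 0 makes label 1 prohibitively expensive, and vice versa
  if (label == 0L) net$cap_source[node] <- net$cap_source[node] + sentinel
  else net$cap_sink[node] <- net$cap_sink[node] + sentinel
  max_flow(net)$energy
}

#' Min-marginal energies of every node
#'
#' For each node, the minimum energy with that node constrained to label 0
#' and to label 1. The minimum of the two equals the unconstrained minimum
#' (MAP consistency). Constrained solves reuse the residual flow of the
#' single unconstrained solve.
#'
#' @param net a `flow_network`.
#' @param nodes node indices to evaluate (default all).
#' @param cutoff optional bound on the min-marginal *gap*: the constrained
#'   re-solve of a node stops once its extra energy reaches `cutoff`, and
#'   the reported value is then a lower bound at least `cutoff` above the
#'   minimum. `Inf` (default) is exact; a finite cutoff speeds up large
#'   volumes where only gaps small enough to matter for a softmax are of
#'   interest.
#' @return A list: `psi0`, `psi1` (energies including `constant_offset`),
#'   `labels` (MAP labels), `energy` (unconstrained minimum), `nodes`.
#' @export
min_marginals_all <- function(net, nodes = seq_len(net$n_nodes),
                              cutoff = Inf) {
  stopifnot(inherits(net, "flow_network"))
  nodes <- as.integer(nodes)
  res <- cpp_min_marginals(net$n_nodes, net$cap_source, net$cap_sink,
                           net$edge_i, net$edge_j, net$cap_ij, net$cap_ji,
                           nodes, cutoff)
  list(psi0 = res$psi0 + net$constant_offset,
       psi1 = res$psi1 + net$constant_offset,
       labels = res$labels, energy = res$flow + net$constant_offset,
       nodes = nodes)
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("<flow_network %d nodes, %d pairwise arcs, offset %.4g>\n",
              x$n_nodes, length(x$edge_i), x$constant_offset))
  invisible(x)
}

#' @export
print.cut_result <- function(x, ...) {
  cat(sprintf("<cut_result flow %.6g, energy %.6g, %d/%d nodes sink-side>\n",
              x$flow_value, x$energy, sum(x$labels), length(x$labels)))
  invisible(x)
}

# debug helper: dump a network as an edge-list text block
format_flow_network <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  c(sprintf("n %d offset %.12g", net$n_nodes, net$constant_offset),
    sprintf("t %d %.12g %.12g", seq_len(net$n_nodes), net$cap_source,
            net$cap_sink),
    if (length(net$edge_i))
      sprintf("e %d %d %.12g %.12g", net$edge_i, net$edge_j, net$cap_ij,
              net$cap_ji))
}
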