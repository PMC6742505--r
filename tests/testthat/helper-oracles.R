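# Brute-force oracles for binary MRFs, independent of the flow engine.

# all binary labellings of n variables, one row per configuration
all_labellings <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

# energies of every configuration of an MRF given as unaries (u0, u1) and a
# pairwise table pe with columns i, j, e00, e01, e10, e11
enum_energies <- function(u0, u1, pe) {
  n <- length(u0)
  X <- all_labellings(n)
  E <- X %*% u1 + (1 - X) %*% u0
  if (!is.null(pe) && nrow(pe)) {
    for (r in seq_len(nrow(pe))) {
      xi <- X[, pe[r, 1]]; xj <- X[, pe[r, 2]]
      E <- E + pe[r, 3 + xi * 2 + xj]
    }
  }
  list(X = X, E = as.numeric(E))
}

enum_min <- function(u0, u1, pe) min(enum_energies(u0, u1, pe)$E)

enum_constrained <- function(u0, u1, pe, v, l) {
  en <- enum_energies(u0, u1, pe)
  min(en$E[en$X[, v] == l])
}

# random MRF with submodular pairwise terms; returns components and the
# equivalent flow network built through the graphcore API
random_submodular_mrf <- function(n, with_unary = TRUE) {
  u0 <- if (with_unary) rnorm(n, sd = 2) else numeric(n)
  u1 <- if (with_unary) rnorm(n, sd = 2) else numeric(n)
  ne <- sample(0:(2 * n), 1)
  pe <- matrix(0, 0, 7)
  for (k in seq_len(ne)) {
    ij <- sample(n, 2)
    e <- rnorm(4, sd = 2)
    viol <- (e[1] + e[4]) - (e[2] + e[3])
    if (viol > 0) e[c(2, 3)] <- e[c(2, 3)] + viol + runif(1)
    pe <- rbind(pe, c(ij, e, 0))
  }
  pe <- pe[, 1:6, drop = FALSE]
  net <- flow_network(n)
  if (with_unary) net <- add_unary(net, seq_len(n), u0, u1)
  if (nrow(pe))
    net <- add_pairwise(net, pe[, 1], pe[, 2], pe[, 3], pe[, 4], pe[, 5],
                        pe[, 6])
  list(u0 = u0, u1 = u1, pe = pe, net = net)
}

# enumeration oracle for the unwrapping energy over small grids with
# wrap counts restricted to a given set
enum_unwrap_min <- function(wrapped, counts_set = -1:1) {
  phi <- wrapped$data
  n <- length(phi)
  cfg <- unwrap_config(quality_weighting = "none")
  grids <- expand.grid(rep(list(counts_set), n))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    k <- array(as.numeric(grids[r, ]), dim(phi))
    best <- min(best, unwrap_energy(k, wrapped, config = cfg))
  }
  best
}
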