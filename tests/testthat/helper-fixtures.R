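# Shared fixtures (computed once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

pancreas_net <- function() cached("net", pancreas_network())

pancreas_atlas_n4 <- function() {
  cached("atlas4", find_equilibria(pancreas_net(), hill_params(n = 4)))
}

pancreas_catalog <- function() {
  cached("catalog", catalog_from_atlas(pancreas_atlas_n4()))
}

toy_fixtures <- function() cached("toys", generate_toy_networks())

# --- independent oracles (deliberately avoid the package's solvers) ---

# All roots of the 1-gene self-activator ODE by dense sign scan + bisection.
toy_roots_bisect <- function(n, tol = 1e-12) {
  f <- function(x) 2^n * x^n / (1 + 2^n * x^n) - x
  xs <- seq(1e-4, 1, by = 1e-4)
  fx <- f(xs)
  roots <- c(0, xs[fx == 0])  # f(0) = 0 analytically; exact grid hits
  sgn <- sign(fx)
  for (i in which(sgn[-1] * sgn[-length(sgn)] < 0)) {
    lo <- xs[i]; hi <- xs[i + 1]
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  sort(roots)
}

# Brute-force Boolean fixed points straight from the regulator sets
# (independent of boolean_weights / enumerate_fixed_points internals).
brute_boolean_fixed_points <- function(network) {
  G <- length(network$genes)
  out <- list()
  for (id in 0:(2^G - 1)) {
    s <- as.integer(intToBits(id)[seq_len(G)])
    nxt <- integer(G)
    for (i in seq_len(G)) {
      w <- sum(s[match(network$activators[[i]], network$genes)]) -
        100 * sum(s[match(network$inhibitors[[i]], network$genes)])
      nxt[i] <- as.integer(w > 0)
    }
    if (all(nxt == s)) out[[length(out) + 1L]] <- s
  }
  m <- do.call(rbind, out)
  colnames(m) <- network$genes
  m
}

# Central finite-difference Jacobian from hill_rhs.
fd_jacobian <- function(network, x, params, h = 1e-6) {
  G <- length(x)
  J <- matrix(0, G, G)
  for (j in seq_len(G)) {
    e <- numeric(G); e[j] <- h
    J[, j] <- (hill_rhs(network, x + e, params, permissive = TRUE) -
               hill_rhs(network, x - e, params, permissive = TRUE)) / (2 * h)
  }
  J
}

# Quasi-potential barrier of the 1-gene toy between two roots, by
# adaptive quadrature of -f (the 1-D gradient-system barrier).
toy_barrier <- function(n, from, to) {
  stats::integrate(function(x) x - 2^n * x^n / (1 + 2^n * x^n),
                   from, to, rel.tol = 1e-10)$value
}

# Permute the genes of a network (relabeling helper).
permute_network <- function(network, perm) {
  genes <- network$genes[perm]
  edges <- list()
  for (g in network$genes) {
    for (a in network$activators[[g]]) {
      edges[[length(edges) + 1L]] <- data.frame(source = a, target = g,
                                                sign = "+1")
    }
    for (i in network$inhibitors[[g]]) {
      edges[[length(edges) + 1L]] <- data.frame(source = i, target = g,
                                                sign = "-1")
    }
  }
  load_network(do.call(rbind, edges), genes = genes)
}
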