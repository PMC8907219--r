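# Small hand-built networks with known closed-form steady states.

# A --> B (single activating edge); A is a source node.
chain_net <- function(sign = "+") {
  regnet(edges = data.frame(source = "A", target = "B", sign = sign))
}

# Mutual-inhibition toggle with self-activation: two exact attractors
# (1,0) and (0,1).
toggle_net <- function() {
  regnet(edges = data.frame(
    source = c("A", "B", "A", "B"),
    target = c("A", "A", "B", "B"),
    sign = c("+", "-", "-", "+")))
}

# The sigmoid activation recomputed independently of the package, term by
# term (oracle for activation()).
phi_oracle <- function(omega, h) {
  a <- exp(0.5 * h)
  e <- exp(-h * (omega - 0.5))
  (-a + e) / ((1 - a) * (1 + e))
}

# Interior fixed points of x' = phi(A(x)) - x for a node self-activated with
# weight 1 and inhibited by a frozen level xi, found by bisection on the
# closed form (oracle for the toggle attractors).
toggle_fixed_points <- function(xi, h = 10) {
  g <- function(x) {
    A <- 2 * x / (1 + x)
    I <- 2 * xi / (1 + xi)
    phi_oracle(max(0, min(1, A * (1 - I))), h) - x
  }
  roots <- c()
  if (abs(g(0)) < 1e-12) roots <- c(roots, 0)
  if (abs(g(1)) < 1e-12) roots <- c(roots, 1)
  grid <- seq(0, 1, by = 1e-3)
  vals <- vapply(grid, g, numeric(1))
  for (i in seq_len(length(grid) - 1)) {
    if (vals[i] == 0) roots <- c(roots, grid[i])
    else if (vals[i] * vals[i + 1] < 0)
      roots <- c(roots, stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root)
  }
  unique(round(roots, 9))
}

random_small_net <- function(seed, n = 8, density = 0.25) {
  generate_network(synthetic_spec(n_nodes = n, edge_density = density,
                                  n_experiments = 1, seed = seed))
}
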