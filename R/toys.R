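#' Toy and canonical network fixtures
#'
#' Ready-made networks with documented dynamical properties, used
#' throughout the package tests and useful as minimal worked examples:
#'
#' * `one_gene`: a single self-activating gene. At Hill coefficient
#'   `n = 4` its equilibria are `x = 0` (stable), `x = 0.5` (saddle; the
#'   half-maximum point, by construction of `K = 0.5`) and a high stable
#'   state at the root of `16 x^3 (1 - x) = 1` on (0.75, 1),
#'   approximately 0.9201.
#' * `toggle`: two self-activating, mutually inhibiting genes. Because
#'   expression requires self-activation here, the off-off origin is also
#'   an attractor: at `n = 4` the system has three stable states (origin
#'   plus the two mirror-image single-gene-high states) separated by the
#'   mirror-symmetric saddle pair (0.5, 0) and (0, 0.5); the diagonal
#'   `x1 = x2` carries no interior equilibrium (the reduced 1-D flow
#'   `16a^4/(1+16a^4)^2 - a` is negative for all `a > 0`).
#' * `pancreas`, `pancreas_plus_ptf1a_pdx1`, `pancreas_plus_nkx61_arx`:
#'   the canonical eight-factor pancreas network and its two single-edge
#'   variants (see [pancreas_network()]).
#'
#' @return named list; each element has `network` (a `gene_network`) and
#'   `expected` (a list of documented properties, e.g. the one-gene
#'   equilibrium set at `n = 4` and Boolean fixed-point counts).
#' @export
generate_toy_networks <- function() {
  one_gene <- load_network(data.frame(source = "A", target = "A",
                                      sign = "+1"))
  toggle <- load_network(data.frame(
    source = c("A", "B", "A", "B"),
    target = c("A", "A", "B", "B"),
    sign = c("+1", "-1", "-1", "+1")), genes = c("A", "B"))
  # high fixed point of the one-gene self-activator at n = 4
  x_hi <- stats::uniroot(function(x) 16 * x^3 * (1 - x) - 1,
                         c(0.75, 1), tol = 1e-12)$root
  list(
    one_gene = list(
      network = one_gene,
      expected = list(equilibria_n4 = c(0, 0.5, x_hi),
                      classes = c("stable", "transition", "stable"),
                      boolean_fixed_points = rbind(0L, 1L))),
    toggle = list(
      network = toggle,
      expected = list(n_stable_n4 = 3L, n_saddle_n4 = 2L,
                      mirror_symmetric = TRUE,
                      diagonal_interior_root = FALSE)),
    pancreas = list(
      network = pancreas_network(),
      expected = list(n_activations = 12L, n_inhibitions = 10L)),
    pancreas_plus_ptf1a_pdx1 = list(
      network = pancreas_network("plus_ptf1a_pdx1"),
      expected = list(n_activations = 13L, n_inhibitions = 10L)),
    pancreas_plus_nkx61_arx = list(
      network = pancreas_network("plus_nkx61_arx"),
      expected = list(n_activations = 12L, n_inhibitions = 11L)))
}
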