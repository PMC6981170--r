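#' Dominant-inhibition Boolean model of a regulatory network
#'
#' The parameter-free counterpart of the Hill ODE model: each gene is on
#' (1) or off (0) and is updated synchronously by thresholding a weighted
#' sum of its regulators, with inhibition dominant — any active inhibitor
#' (weight -100) overrides all activators (weight +1):
#' \deqn{x_i(t+1) = 1 \iff \textstyle\sum_j w_{ij} x_j(t) > 0 .}
#'
#' @param network a `gene_network`.
#' @param inhibition_weight weight of an inhibiting regulator. The default
#'   -100 guarantees dominance for networks with fewer than 100 activators
#'   per gene; overriding it (e.g. to -1) can lose dominant inhibition and
#'   triggers a warning.
#' @return object of class `boolean_model`: `genes` and the weight matrix
#'   `W` (rows = targets, columns = regulators, entries in
#'   `{0, 1, inhibition_weight}`).
#' @examples
#' bm <- boolean_weights(pancreas_network())
#' table(bm$W)
#' @export
boolean_weights <- function(network, inhibition_weight = -100) {
  stopifnot(inherits(network, "gene_network"))
  if (inhibition_weight != -100) {
    warning("inhibition_weight != -100: dominant inhibition is no longer ",
            "guaranteed")
  }
  W <- network$act_mat + inhibition_weight * network$inh_mat
  structure(list(genes = network$genes, W = W), class = "boolean_model")
}

#' Synchronous Boolean update
#'
#' Applies one synchronous step: every gene switches on iff its weighted
#' regulator sum is strictly positive (a sum of zero maps to off).
#'
#' @param model a `boolean_model`.
#' @param state 0/1 vector, one bit per gene.
#' @return the successor 0/1 vector.
#' @export
boolean_step <- function(model, state) {
  stopifnot(inherits(model, "boolean_model"))
  state <- as.integer(state)
  if (length(state) != length(model$genes)) stop("state length mismatch")
  if (any(!state %in% c(0L, 1L))) stop("state bits must be 0 or 1")
  stats::setNames(as.integer(drop(model$W %*% state) > 0), model$genes)
}

#' Exhaustive fixed-point enumeration of a Boolean model
#'
#' Enumerates all `2^G` states and keeps those invariant under
#' [boolean_step()]. Enumeration is exact and refuses more than
#' `max_genes` genes (use a sampling approach beyond that).
#'
#' @param model a `boolean_model`.
#' @param max_genes exhaustive-enumeration guard (default 24).
#' @return integer matrix, one fixed point per row, with attribute
#'   `"n_candidates"` recording how many states were enumerated.
#' @examples
#' fp <- enumerate_fixed_points(boolean_weights(pancreas_network()))
#' attr(fp, "n_candidates")  # 256
#' @export
enumerate_fixed_points <- function(model, max_genes = 24L) {
  stopifnot(inherits(model, "boolean_model"))
  G <- length(model$genes)
  if (G > max_genes) {
    stop("exhaustive enumeration over 2^", G, " states refused; ",
         "use a sampling mode for networks this large")
  }
  total <- 2^G
  chunk <- 2^min(G, 16L)
  fixed <- list()
  for (off in seq(0, total - 1, by = chunk)) {
    ids <- off + seq_len(min(chunk, total - off)) - 1
    # bits of each id, one state per row, gene 1 = least significant bit
    S <- vapply(seq_len(G), function(b) (ids %/% 2^(b - 1)) %% 2,
                numeric(length(ids)))
    S <- matrix(S, ncol = G)
    nxt <- (S %*% t(model$W) > 0) * 1
    keep <- rowSums(nxt != S) == 0
    if (any(keep)) fixed[[length(fixed) + 1L]] <- S[keep, , drop = FALSE]
  }
  fp <- do.call(rbind, fixed)
  fp <- matrix(as.integer(fp), ncol = G, dimnames = list(NULL, model$genes))
  attr(fp, "n_candidates") <- total
  fp
}

#' Consistency of ODE attractors with the Boolean model
#'
#' Binarizes every stable state of the atlas at `threshold` and checks
#' whether each on/off pattern is a fixed point of the Boolean model. Full
#' agreement means the attractor repertoire is a model-independent property
#' of the network wiring rather than an artifact of the Hill kinetics.
#'
#' @param atlas an `equilibrium_atlas`.
#' @param fixed_points matrix from [enumerate_fixed_points()].
#' @param threshold binarization threshold (default 0.5).
#' @return list with `per_state` (data frame: label, pattern,
#'   `is_fixed_point`), `unmatched_fixed_points` (Boolean fixed points with
#'   no ODE counterpart) and the overall flag `all_consistent`.
#' @export
compare_ode_boolean <- function(atlas, fixed_points, threshold = 0.5) {
  stopifnot(inherits(atlas, "equilibrium_atlas"), nrow(fixed_points) >= 0)
  stable <- Filter(function(s) s$class == "stable", atlas$states)
  if (length(stable) == 0L) stop("atlas has no stable states")
  fp_key <- apply(fixed_points, 1, paste, collapse = "")
  pat <- vapply(stable, function(s)
    paste(.binarize(s$x, threshold), collapse = ""), "")
  per_state <- data.frame(
    label = vapply(stable, `[[`, "", "label"),
    pattern = pat,
    is_fixed_point = pat %in% fp_key)
  list(per_state = per_state,
       unmatched_fixed_points =
         fixed_points[!fp_key %in% pat, , drop = FALSE],
       all_consistent = all(per_state$is_fixed_point))
}
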