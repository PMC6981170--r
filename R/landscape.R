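#' Configuration of the topological landscape construction
#'
#' Saddles of the Hill ODE system are probed by tiny perturbations confined
#' to their unstable subspace; each perturbed state is integrated forward
#' and the equilibrium its trajectory reaches is recorded. `delta1` bounds
#' the *squared* Euclidean amplitude of a perturbation (default 0.25e-8,
#' i.e. norm below 5e-5, small enough that the local linearization is
#' faithful), and `delta2` bounds the squared distance at which a
#' trajectory point counts as having reached an equilibrium (default 1e-6).
#'
#' @param delta1 squared perturbation-amplitude bound.
#' @param delta2 squared reachability bound.
#' @param dt integration step of the fixed-step integrator.
#' @param t_max maximum integration time per trajectory.
#' @param speed_tol trajectory termination tolerance on the max-norm
#'   velocity.
#' @param n_directions extra seeded random unit combinations within the
#'   unstable subspace for saddles with two or more unstable directions.
#' @param seed RNG seed for those random combinations.
#' @param integrator `"rk4"` (default) or `"euler"`.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(delta1 = 0.25e-8, delta2 = 1e-6,
                             dt = 0.01, t_max = 500, speed_tol = 1e-8,
                             n_directions = 8L, seed = 1L,
                             integrator = c("rk4", "euler")) {
  stopifnot(delta1 > 0, delta2 > 0, dt > 0, t_max > 0, speed_tol > 0,
            n_directions >= 0)
  structure(list(delta1 = delta1, delta2 = delta2, dt = dt, t_max = t_max,
                 speed_tol = speed_tol, n_directions = as.integer(n_directions),
                 seed = seed, integrator = match.arg(integrator)),
            class = "landscape_config")
}

#' Perturbation start points on the unstable subspace of a saddle
#'
#' Builds a real orthonormal basis of the unstable subspace (the span of
#' Jacobian eigenvectors whose eigenvalues have positive real part; real
#' and imaginary parts are used for complex pairs) and returns perturbed
#' copies of the saddle: plus/minus each basis vector, plus, for saddles
#' with two or more unstable directions, `n_directions` seeded random unit
#' combinations within the subspace. Every perturbation `dp` satisfies
#' `<dp, dp> < delta1`.
#'
#' @param state one element of `equilibrium_atlas$states` with
#'   `unstable_dim >= 1`.
#' @param config a `landscape_config`.
#' @return matrix of start points (rows), one per perturbation direction,
#'   with attribute `"directions"` holding the unit perturbation vectors.
#' @export
unstable_perturbations <- function(state, config = landscape_config()) {
  if (state$unstable_dim < 1L) {
    stop("state ", state$label %||% "", " is stable: no unstable subspace")
  }
  pos <- Re(state$eigenvalues) > 0
  V <- state$vectors[, pos, drop = FALSE]
  basis <- qr.Q(qr(cbind(Re(V), Im(V))))
  keep <- sqrt(colSums(abs(cbind(Re(V), Im(V)))^2)) > 1e-12
  basis <- qr.Q(qr(cbind(Re(V), Im(V))[, keep, drop = FALSE]))
  k <- min(ncol(basis), state$unstable_dim)
  basis <- basis[, seq_len(k), drop = FALSE]

  dirs <- cbind(basis, -basis)
  if (state$unstable_dim >= 2L && config$n_directions > 0L) {
    extra <- .with_seed(config$seed, {
      co <- matrix(stats::rnorm(k * config$n_directions), k)
      co <- sweep(co, 2, sqrt(colSums(co^2)), "/")
      basis %*% co
    })
    dirs <- cbind(dirs, extra)
  }
  amp <- 0.99 * sqrt(config$delta1)
  starts <- t(unname(state$x) + amp * dirs)
  attr(starts, "directions") <- t(dirs)
  starts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate the Hill ODE flow from a state
#'
#' Fixed-step integration (classical RK4 by default; forward Euler
#' available) until the max-norm velocity drops below `speed_tol` or
#' `t_max` is reached. A state already at rest yields a single-point
#' trajectory.
#'
#' @param network a `gene_network`.
#' @param x0 numeric initial state.
#' @param params a `hill_params`.
#' @param config a `landscape_config`.
#' @return list of class `ode_trajectory`: `states` (time-ordered matrix,
#'   one row per recorded step), `times`, `converged` flag and
#'   `terminal_speed`.
#' @export
integrate_trajectory <- function(network, x0, params = hill_params(),
                                 config = landscape_config()) {
  stopifnot(inherits(network, "gene_network"))
  x <- .check_state(network, x0, permissive = TRUE)
  ops <- .hill_ops(network, params)
  f1 <- function(x) drop(ops$f(matrix(x)))
  dt <- config$dt
  n_max <- ceiling(config$t_max / dt)
  euler <- identical(config$integrator, "euler")

  out <- matrix(NA_real_, n_max + 1L, length(x))
  out[1L, ] <- x
  speed <- max(abs(f1(x)))
  k <- 1L
  while (speed >= config$speed_tol && k <= n_max) {
    if (euler) {
      x <- x + dt * f1(x)
    } else {
      k1 <- f1(x)
      k2 <- f1(x + dt / 2 * k1)
      k3 <- f1(x + dt / 2 * k2)
      k4 <- f1(x + dt * k3)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(x))) {
      stop("non-finite state during integration: reduce dt")
    }
    k <- k + 1L
    out[k, ] <- x
    speed <- max(abs(f1(x)))
  }
  structure(list(states = out[seq_len(k), , drop = FALSE],
                 times = (seq_len(k) - 1L) * dt,
                 converged = speed < config$speed_tol,
                 terminal_speed = speed),
            class = "ode_trajectory")
}

#' First atlas equilibrium reached by a trajectory
#'
#' A state counts as reached when some trajectory point lies within squared
#' distance `delta2` of it; the equilibrium hit earliest along the
#' trajectory is returned (nearest state on ties).
#'
#' @param trajectory an `ode_trajectory`.
#' @param atlas an `equilibrium_atlas`.
#' @param config a `landscape_config` (supplies `delta2`).
#' @param exclude atlas labels to ignore (the landscape construction
#'   excludes the perturbed saddle itself, whose `delta2`-ball contains
#'   the start of its own trajectories).
#' @return the label of the reached equilibrium, or `NA_character_`.
#' @export
reachable_state <- function(trajectory, atlas, config = landscape_config(),
                            exclude = NULL) {
  P <- trajectory$states
  stopifnot(nrow(P) >= 1L)
  best_i <- Inf; best_d <- Inf; best_lab <- NA_character_
  for (s in atlas$states) {
    if (!is.null(exclude) && s$label %in% exclude) next
    d2 <- rowSums((P - rep(unname(s$x), each = nrow(P)))^2)
    hit <- which(d2 < config$delta2)
    if (length(hit) == 0L) next
    i <- hit[1L]
    if (i < best_i || (i == best_i && d2[i] < best_d)) {
      best_i <- i; best_d <- d2[i]; best_lab <- s$label
    }
  }
  best_lab
}

#' Build the topological adaptive landscape graph
#'
#' For every saddle in the atlas, perturbs it along its unstable subspace
#' ([unstable_perturbations()]), integrates each perturbed state
#' ([integrate_trajectory()]) and records the equilibrium reached
#' ([reachable_state()]). The result is a directed graph from saddles to
#' the equilibria their unstable manifolds flow into: the adaptive
#' landscape on which attractors are valleys and transition states are the
#' saddles connecting them. Edges that originate at hyper-transition states
#' are computed but flagged (`from_hyper`), since paths through them
#' connect multiple attractors at once and are conventionally excluded
#' from the main landscape.
#'
#' @param network a `gene_network`.
#' @param atlas an `equilibrium_atlas` containing at least one saddle.
#' @param params a `hill_params`.
#' @param config a `landscape_config`.
#' @param include_hyper also perturb hyper-transition states (default
#'   `TRUE`).
#' @return object of class `landscape_graph`: `nodes` (label/class data
#'   frame), `edges` (from, to, direction index, `from_hyper`), `runs`
#'   (per-trajectory outcomes) and `config`.
#' @export
build_landscape_graph <- function(network, atlas, params = hill_params(),
                                  config = landscape_config(),
                                  include_hyper = TRUE) {
  classes <- vapply(atlas$states, `[[`, "", "class")
  take <- classes == "transition" | (include_hyper & classes == "hyper_transition")
  if (!any(take)) stop("atlas contains no saddle states")

  edges <- list(); runs <- list()
  for (s in atlas$states[take]) {
    starts <- unstable_perturbations(s, config)
    for (d in seq_len(nrow(starts))) {
      tr <- integrate_trajectory(network, starts[d, ], params, config)
      target <- reachable_state(tr, atlas, config, exclude = s$label)
      runs[[length(runs) + 1L]] <- data.frame(
        from = s$label, direction = d, converged = tr$converged,
        target = target)
      if (is.na(target) || target == s$label) next
      edges[[length(edges) + 1L]] <- data.frame(
        from = s$label, to = target, direction = d,
        from_hyper = s$class == "hyper_transition")
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), direction = integer(),
               from_hyper = logical())
  edges <- edges[!duplicated(edges[c("from", "to")]), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(
    label = vapply(atlas$states, `[[`, "", "label"),
    class = classes)
  structure(list(nodes = nodes, edges = edges,
                 runs = do.call(rbind, runs), config = config),
            class = "landscape_graph")
}

#' @export
print.landscape_graph <- function(x, ...) {
  cat("landscape_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(%d from transition, %d from hyper-transition states)\n",
              sum(!x$edges$from_hyper), sum(x$edges$from_hyper)))
  invisible(x)
}

#' Convert / export a landscape graph
#'
#' `as_igraph()` returns an [igraph::graph_from_data_frame()] object with
#' node class and edge direction attributes; `write_landscape_graph()`
#' writes GraphML or DOT.
#'
#' @param graph a `landscape_graph`.
#' @param atlas optional atlas; when given, per-gene state values are
#'   attached as node attributes.
#' @return an igraph object.
#' @export
as_igraph <- function(graph, atlas = NULL) {
  stopifnot(inherits(graph, "landscape_graph"))
  nodes <- graph$nodes
  if (!is.null(atlas)) {
    xs <- do.call(rbind, lapply(atlas$states, function(s) unname(s$x)))
    colnames(xs) <- make.names(atlas$genes)
    nodes <- cbind(nodes, xs[match(nodes$label,
                                   vapply(atlas$states, `[[`, "", "label")), ,
                             drop = FALSE])
  }
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = nodes)
}

#' @param path output file path.
#' @param format `"graphml"` or `"dot"`.
#' @rdname as_igraph
#' @export
write_landscape_graph <- function(graph, path, format = c("graphml", "dot"),
                                  atlas = NULL) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(graph, atlas), path, format = format)
  invisible(path)
}
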