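#' Configuration of the most-probable-path computation
#'
#' Noise-driven transitions between attractors concentrate on the path
#' minimizing the Freidlin–Wentzell action
#' \deqn{S_{T_1T_2}(x) = \tfrac14 \int_{T_1}^{T_2}
#'   \langle \dot x - f(x),\, D^{-1} [\dot x - f(x)] \rangle\, ds}
#' with diffusion matrix `D = I`. On a mesh of `N` equal subintervals of a
#' duration-`T` window the action is discretized with trapezoidal drift
#' averaging (see [path_action()]) and minimized over the interior mesh
#' points with clamped endpoints. The defaults `T = 10`, `N = 100` resolve
#' the transitions of switch-like Hill networks; refining to e.g.
#' `(20, 200)` should change converged action values by well under 0.01
#' ([refinement_check()]).
#'
#' Underlying theory (not computed here): for an A-type stochastic
#' interpretation of `dx = f dt + B dW` with `B B' = 2 eps D`, the
#' steady-state distribution is `exp(-U/eps)` with potential
#' `U(x) = min S(x)`, the drift decomposing through symmetric `D` and
#' antisymmetric `Q` matrices. Only the `D = I` action minimization is
#' implemented, which is what the most probable paths require.
#'
#' @param total_time path duration `T` (default 10).
#' @param n_intervals number of equal subintervals `N` (default 100; the
#'   mesh has `N + 1` points and step `dt = T/N`).
#' @param maxit optimizer iteration cap.
#' @param factr,pgtol L-BFGS-B convergence controls (see [stats::optim()]).
#' @return an object of class `mpp_config`.
#' @export
mpp_config <- function(total_time = 10, n_intervals = 100L,
                       maxit = 5000L, factr = 1e7, pgtol = 0) {
  stopifnot(total_time > 0, n_intervals >= 2)
  structure(list(total_time = total_time,
                 n_intervals = as.integer(n_intervals),
                 dt = total_time / n_intervals,
                 maxit = as.integer(maxit), factr = factr, pgtol = pgtol),
            class = "mpp_config")
}

#' Discretized Freidlin–Wentzell action of a path
#'
#' \deqn{S = \tfrac14\,\Delta t \sum_{k=1}^{N}\sum_i
#'   \Big\| \frac{x_i^{k+1} - x_i^k}{\Delta t}
#'        - \frac{f_i^{k+1} + f_i^k}{2} \Big\|^2}
#' with `f` the Hill ODE velocity field. The action is nonnegative and
#' vanishes exactly on paths satisfying the discrete flow equation, so
#' "downhill" relaxation paths are nearly free while "uphill" barrier
#' crossings pay the quasi-potential difference.
#'
#' @param points path matrix, one state per row (`N + 1` rows).
#' @param network a `gene_network`.
#' @param params a `hill_params`.
#' @param dt mesh step.
#' @return scalar action value.
#' @export
path_action <- function(points, network, params = hill_params(), dt) {
  stopifnot(is.matrix(points), nrow(points) >= 2L, dt > 0)
  if (any(!is.finite(points))) stop("non-finite path values")
  ops <- .hill_ops(network, params)
  X <- t(points)                       # G x (N+1)
  Fv <- ops$f(X)
  N1 <- ncol(X)
  Rr <- (X[, -1L, drop = FALSE] - X[, -N1, drop = FALSE]) / dt -
    (Fv[, -1L, drop = FALSE] + Fv[, -N1, drop = FALSE]) / 2
  dt / 4 * sum(Rr^2)
}

# Action and analytic gradient over interior points, vectorized.
# X is G x (N+1) with clamped first/last columns.
.action_env <- function(network, params, x_start, x_end, config) {
  ops <- .hill_ops(network, params)
  G <- length(network$genes)
  N <- config$n_intervals
  dt <- config$dt
  fn <- function(par) {
    X <- cbind(x_start, matrix(par, nrow = G), x_end)
    Fv <- ops$f(X)
    Rr <- (X[, -1L, drop = FALSE] - X[, -(N + 1L), drop = FALSE]) / dt -
      (Fv[, -1L, drop = FALSE] + Fv[, -(N + 1L), drop = FALSE]) / 2
    dt / 4 * sum(Rr^2)
  }
  gr <- function(par) {
    X <- cbind(x_start, matrix(par, nrow = G), x_end)
    Fv <- ops$f(X)
    Rr <- (X[, -1L, drop = FALSE] - X[, -(N + 1L), drop = FALSE]) / dt -
      (Fv[, -1L, drop = FALSE] + Fv[, -(N + 1L), drop = FALSE]) / 2
    # for interior point k (2..N): segments k-1 and k touch it
    Rl <- Rr[, -N, drop = FALSE]       # r_{k-1} for k = 2..N
    Rc <- Rr[, -1L, drop = FALSE]      # r_k
    Xi <- X[, 2:N, drop = FALSE]
    Jt <- ops$jtv(Xi, Rl + Rc)
    Gm <- dt / 2 * ((Rl - Rc) / dt - Jt / 2)
    as.numeric(Gm)
  }
  list(fn = fn, gr = gr)
}

#' Minimize the discretized action between two states
#'
#' Optimizes the interior mesh points of a path from `x_start` to `x_end`
#' (endpoints hard-clamped) with L-BFGS-B, starting from the straight line
#' segment joining the endpoints. The minimizer is the most probable
#' (least action) transition path; its action approximates the
#' quasi-potential barrier for uphill transitions and is ~0 for downhill
#' relaxations.
#'
#' @param network a `gene_network`.
#' @param params a `hill_params`.
#' @param x_start,x_end endpoint states (typically atlas equilibria; a
#'   warning is emitted when an endpoint is not at rest).
#' @param config an `mpp_config`.
#' @return object of class `path_solution`: `points` (`N + 1` rows, named
#'   gene columns), `times`, `action`, `initial_action` (of the line
#'   segment), `converged`, and optimizer diagnostics in `opt`.
#' @export
minimize_action <- function(network, params = hill_params(),
                            x_start, x_end, config = mpp_config()) {
  x_start <- .check_state(network, x_start, permissive = TRUE)
  x_end <- .check_state(network, x_end, permissive = TRUE)
  if (max(abs(x_start - x_end)) < 1e-12) {
    stop("degenerate request: x_start equals x_end")
  }
  for (e in list(x_start, x_end)) {
    if (max(abs(hill_rhs(network, e, params, permissive = TRUE))) > 1e-6) {
      warning("path endpoint is not an equilibrium (||rhs|| > 1e-6)")
    }
  }
  G <- length(network$genes)
  N <- config$n_intervals
  lam <- seq(0, 1, length.out = N + 1L)
  line <- outer(x_start, 1 - lam) + outer(x_end, lam)  # G x (N+1)
  env <- .action_env(network, params, x_start, x_end, config)
  par0 <- as.numeric(line[, 2:N, drop = FALSE])
  s0 <- env$fn(par0)
  opt <- stats::optim(par0, env$fn, env$gr, method = "L-BFGS-B",
                      control = list(maxit = config$maxit,
                                     factr = config$factr,
                                     pgtol = config$pgtol))
  pts <- t(cbind(x_start, matrix(opt$par, nrow = G), x_end))
  colnames(pts) <- network$genes
  structure(list(points = pts,
                 times = lam * config$total_time,
                 action = opt$value,
                 initial_action = s0,
                 converged = opt$convergence == 0L,
                 opt = opt[c("convergence", "counts", "message")],
                 config = config,
                 genes = network$genes),
            class = "path_solution")
}

#' @export
print.path_solution <- function(x, ...) {
  cat(sprintf(
    "path_solution: %d points over T = %g, action = %.6g (line segment %.6g)%s\n",
    nrow(x$points), x$config$total_time, x$action, x$initial_action,
    if (x$converged) "" else "  [optimizer not converged]"))
  invisible(x)
}

#' @export
as.data.frame.path_solution <- function(x, ...) {
  data.frame(time = x$times, x$points, check.names = FALSE)
}

#' Discretization-convergence check for a most probable path
#'
#' Solves the same endpoint problem under a base and a refined mesh and
#' reports the change in minimized action together with the maximum
#' pointwise path deviation after rescaling both paths to a common time
#' fraction grid. Converged solutions should move by well under 0.01.
#'
#' @param network a `gene_network`.
#' @param params a `hill_params`.
#' @param x_start,x_end endpoint states.
#' @param base_config,refined_config `mpp_config`s; the refinement must
#'   not decrease `T` or `N`.
#' @return list with `delta_action`, `max_path_deviation`, and the two
#'   `path_solution`s.
#' @export
refinement_check <- function(network, params = hill_params(), x_start, x_end,
                             base_config = mpp_config(10, 100),
                             refined_config = mpp_config(20, 200)) {
  stopifnot(refined_config$total_time >= base_config$total_time,
            refined_config$n_intervals >= base_config$n_intervals)
  base <- minimize_action(network, params, x_start, x_end, base_config)
  refined <- minimize_action(network, params, x_start, x_end, refined_config)
  frac <- refined$times / refined_config$total_time
  base_i <- vapply(seq_len(ncol(base$points)), function(j) {
    stats::approx(base$times / base_config$total_time, base$points[, j],
                  xout = frac)$y
  }, numeric(length(frac)))
  list(delta_action = abs(refined$action - base$action),
       max_path_deviation = max(abs(base_i - refined$points)),
       base = base, refined = refined)
}

#' Most probable paths along named lineage maturation chains
#'
#' Computes one minimized path per consecutive stage pair of each chain
#' (e.g. the endocrine chain MP -> TrP -> EEP -> LEP -> Ibeta), taking the
#' stage states from the atlas through a label map. Complex multi-well
#' transitions are deliberately solved stagewise, matching how lineage
#' maturation proceeds through intermediate phenotypes.
#'
#' @param network a `gene_network`.
#' @param atlas an `equilibrium_atlas`.
#' @param state_map named character vector mapping stage names (e.g.
#'   `"MP"`, `"TrP"`) to atlas labels (e.g. `"T2"`, `"S3"`); see
#'   [annotate_pancreas_atlas()].
#' @param config an `mpp_config`.
#' @param chains named list of stage-name vectors; defaults to
#'   [pancreas_lineage_chains()].
#' @param params a `hill_params` (defaults to the atlas parameters).
#' @return list of class `mpp_suite`: per chain a list of `path_solution`s
#'   (named `"A->B"`), plus `trajectories`, a long data frame (chain,
#'   segment, time, gene, value) for plotting TF dynamics.
#' @export
lineage_mpp_suite <- function(network, atlas, state_map,
                              config = mpp_config(),
                              chains = pancreas_lineage_chains(),
                              params = atlas$params) {
  labels <- vapply(atlas$states, `[[`, "", "label")
  need <- unique(unlist(chains))
  miss <- setdiff(need, names(state_map))
  if (length(miss)) {
    stop("state_map is missing lineage label(s): ", paste(miss, collapse = ", "))
  }
  get_x <- function(nm) {
    lab <- state_map[[nm]]
    i <- match(lab, labels)
    if (is.na(i)) stop("atlas has no state labelled ", lab, " (for ", nm, ")")
    unname(atlas$states[[i]]$x)
  }
  out <- list(); rows <- list()
  for (cn in names(chains)) {
    stages <- chains[[cn]]
    segs <- list()
    for (i in seq_len(length(stages) - 1L)) {
      a <- stages[i]; b <- stages[i + 1L]
      sol <- minimize_action(network, params, get_x(a), get_x(b), config)
      segs[[paste0(a, "->", b)]] <- sol
      long <- as.data.frame(sol)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = cn, segment = paste0(a, "->", b),
        time = rep(long$time, length(sol$genes)),
        gene = rep(sol$genes, each = nrow(long)),
        value = as.numeric(as.matrix(long[, sol$genes])))
    }
    out[[cn]] <- segs
  }
  structure(list(chains = out, trajectories = do.call(rbind, rows),
                 config = config),
            class = "mpp_suite")
}

#' Lineage maturation chains of the pancreas network
#'
#' Stage sequences of the four maturation chains read off the adaptive
#' landscape: the endocrine beta chain through the trunk progenitor and
#' the early/later endocrine progenitors, the ductal chain through the
#' trunk state, and the two alternative acinar chains through AciP or
#' AciP2.
#'
#' @return named list of stage-name vectors understood by
#'   [lineage_mpp_suite()].
#' @export
pancreas_lineage_chains <- function() {
  list(endocrine = c("MP", "TrP", "EEP", "LEP", "Ibeta"),
       ductal = c("MP", "TrP", "trunk", "ductal"),
       acinar_AciP = c("MP", "TiP", "AciP", "acinar"),
       acinar_AciP2 = c("MP", "TiP", "AciP2", "acinar"))
}
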