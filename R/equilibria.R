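#' Classify an equilibrium point by its Jacobian spectrum
#'
#' An equilibrium is *stable* (an attractor, interpreted as a stable cell
#' phenotype) when all eigenvalue real parts are negative, a *transition*
#' state (saddle with one unstable direction, an intermediate phenotype
#' mediating the transition between two attractors) when exactly one real
#' part is positive, and a *hyper-transition* state when two or more are
#' positive. Real parts within `sign_tol` of zero make the classification
#' unreliable; such points are flagged `degenerate` rather than silently
#' assigned a class.
#'
#' @param eigenvalues complex (or numeric) vector of Jacobian eigenvalues.
#' @param sign_tol tolerance on the sign of a real part (default 1e-8).
#' @return list with elements `class` (one of `"stable"`, `"transition"`,
#'   `"hyper_transition"`, `"degenerate"`) and `unstable_dim` (number of
#'   real parts greater than `sign_tol`).
#' @export
classify_equilibrium <- function(eigenvalues, sign_tol = 1e-8) {
  if (length(eigenvalues) == 0L) stop("empty eigenvalue list")
  re <- Re(eigenvalues)
  unstable_dim <- sum(re > sign_tol)
  cls <- if (any(abs(re) <= sign_tol)) {
    "degenerate"
  } else if (unstable_dim == 0L) {
    "stable"
  } else if (unstable_dim == 1L) {
    "transition"
  } else {
    "hyper_transition"
  }
  list(class = cls, unstable_dim = as.integer(unstable_dim))
}

# Damped Newton iteration for f(x) = 0; returns the root or NULL.
.newton_root <- function(fops, x0, root_tol = 1e-10, maxit = 200L,
                         max_halvings = 50L) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- drop(fops$f(matrix(x)))
    if (max(abs(fx)) < root_tol) return(x)
    J <- fops$jac(x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    f0 <- max(abs(fx))
    accepted <- FALSE
    for (h in seq_len(max_halvings)) {
      cand <- x + lam * step
      fc <- drop(fops$f(matrix(cand)))
      if (all(is.finite(fc)) && max(abs(fc)) < f0) {
        x <- cand
        accepted <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!accepted) x <- x + step  # escape flat regions with a full step
  }
  if (max(abs(drop(fops$f(matrix(x))))) < root_tol) x else NULL
}

#' Find and classify all equilibrium points of the Hill ODE model
#'
#' Runs a damped multivariate Newton search from a deterministic multistart
#' grid (default `{0, 0.5, 1}` per gene, i.e. every on/half/off
#' combination), optionally augmented with seeded uniform random starts.
#' Converged roots are deduplicated, filtered to a small margin around the
#' forward-invariant unit box, classified via [classify_equilibrium()] and
#' sorted by class and then decreasing lexicographic state, which fixes the
#' `S*/T*/H*` labels deterministically.
#'
#' @param network a `gene_network`.
#' @param params a `hill_params`.
#' @param grid_points per-gene start levels (default `c(0, 0.5, 1)`; the
#'   full grid has `length(grid_points)^G` starts).
#' @param random_starts number of additional uniform random starts.
#' @param seed RNG seed for the random starts.
#' @param root_tol Newton convergence tolerance on the max-norm of the
#'   velocity (default 1e-10).
#' @param dedup_tol Euclidean distance below which two roots are merged.
#' @param box_margin roots outside `[-box_margin, 1 + box_margin]` in any
#'   coordinate are discarded as numerical artifacts.
#' @param sign_tol eigenvalue sign tolerance for classification.
#' @param maxit maximum Newton iterations per start.
#' @return an object of class `equilibrium_atlas`: a list with `states` (a
#'   list of equilibrium states, each carrying `x`, `residual_norm`,
#'   `eigenvalues`, eigenvector matrix `vectors`, `class`, `unstable_dim`
#'   and `label`), `params`, `genes` and search metadata `meta` (start and
#'   convergence counts, per-class counts, tolerances).
#' @examples
#' \donttest{
#' atlas <- find_equilibria(pancreas_network(), hill_params(n = 4))
#' atlas  # 11 stable, 16 transition, 8 hyper-transition states
#' }
#' @export
find_equilibria <- function(network, params = hill_params(),
                            grid_points = c(0, 0.5, 1),
                            random_starts = 0L, seed = 1L,
                            root_tol = 1e-10, dedup_tol = 1e-6,
                            box_margin = 0.05, sign_tol = 1e-8,
                            maxit = 200L) {
  stopifnot(inherits(network, "gene_network"), inherits(params, "hill_params"),
            length(grid_points) >= 1L, root_tol > 0, dedup_tol > 0)
  G <- length(network$genes)
  ops <- .hill_ops(network, params)

  starts <- as.matrix(expand.grid(rep(list(grid_points), G),
                                  KEEP.OUT.ATTRS = FALSE))
  if (random_starts > 0L) {
    rs <- .with_seed(seed, matrix(stats::runif(random_starts * G),
                                  nrow = random_starts, ncol = G))
    starts <- rbind(starts, rs)
  }

  roots <- list()
  n_conv <- 0L
  for (s in seq_len(nrow(starts))) {
    r <- .newton_root(ops, as.numeric(starts[s, ]),
                      root_tol = root_tol, maxit = maxit)
    if (is.null(r)) next
    n_conv <- n_conv + 1L
    if (any(r < -box_margin | r > 1 + box_margin)) next
    dup <- FALSE
    for (q in roots) {
      if (sqrt(sum((q - r)^2)) <= dedup_tol) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (length(roots) == 0L) {
    stop("no equilibria found; the origin always exists, so this signals ",
         "a misconfigured search")
  }

  states <- lapply(roots, function(x) {
    eg <- eigen(ops$jac(x))
    cl <- classify_equilibrium(eg$values, sign_tol = sign_tol)
    list(x = stats::setNames(x, network$genes),
         residual_norm = max(abs(drop(ops$f(matrix(x))))),
         eigenvalues = eg$values,
         vectors = eg$vectors,
         class = cl$class,
         unstable_dim = cl$unstable_dim)
  })

  # deterministic order: class rank, then decreasing lexicographic state
  cls <- vapply(states, `[[`, "", "class")
  rank <- match(cls, c("stable", "transition", "hyper_transition", "degenerate"))
  xs <- do.call(rbind, lapply(states, function(s) round(unname(s$x), 6)))
  ord <- do.call(order, c(list(rank), as.data.frame(-xs)))
  states <- states[ord]
  cls <- cls[ord]

  prefix <- c(stable = "S", transition = "T", hyper_transition = "H",
              degenerate = "D")[cls]
  idx <- stats::ave(seq_along(cls), cls, FUN = seq_along)
  for (i in seq_along(states)) states[[i]]$label <- paste0(prefix[i], idx[i])

  counts <- table(factor(cls, levels = c("stable", "transition",
                                         "hyper_transition", "degenerate")))
  structure(
    list(states = states, params = params, genes = network$genes,
         meta = list(n_starts = nrow(starts), n_converged = n_conv,
                     counts = counts, grid_points = grid_points,
                     random_starts = random_starts, seed = seed,
                     root_tol = root_tol, dedup_tol = dedup_tol,
                     box_margin = box_margin, sign_tol = sign_tol)),
    class = "equilibrium_atlas")
}

#' @export
print.equilibrium_atlas <- function(x, ...) {
  ct <- x$meta$counts
  cat("equilibrium_atlas:", length(x$states), "states at n =", x$params$n,
      sprintf("(%d stable, %d transition, %d hyper-transition, %d degenerate)\n",
              ct[["stable"]], ct[["transition"]], ct[["hyper_transition"]],
              ct[["degenerate"]]))
  invisible(x)
}

#' @export
as.data.frame.equilibrium_atlas <- function(x, ...) {
  xs <- do.call(rbind, lapply(x$states, function(s) unname(s$x)))
  colnames(xs) <- x$genes
  data.frame(
    label = vapply(x$states, `[[`, "", "label"),
    class = vapply(x$states, `[[`, "", "class"),
    unstable_dim = vapply(x$states, `[[`, 0L, "unstable_dim"),
    residual_norm = vapply(x$states, `[[`, 0, "residual_norm"),
    max_re_eigenvalue = vapply(x$states, function(s) max(Re(s$eigenvalues)), 0),
    xs,
    check.names = FALSE)
}

#' Export an atlas as CSV / JSON
#'
#' The CSV has one row per equilibrium (label, class, unstable dimension,
#' residual, leading eigenvalue real part and the per-gene values); the JSON
#' additionally carries the full complex spectra.
#'
#' @param atlas an `equilibrium_atlas`.
#' @param path output file path.
#' @export
write_atlas_csv <- function(atlas, path) {
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_csv
#' @export
atlas_to_json <- function(atlas, path = NULL) {
  obj <- list(
    params = unclass(atlas$params),
    genes = atlas$genes,
    states = lapply(atlas$states, function(s) {
      list(label = s$label, class = s$class, unstable_dim = s$unstable_dim,
           residual_norm = s$residual_norm,
           x = as.list(s$x),
           eigenvalues_re = Re(s$eigenvalues),
           eigenvalues_im = Im(s$eigenvalues))
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# Binarized on/off pattern of a state at a threshold.
.binarize <- function(x, threshold = 0.5) as.integer(x >= threshold)

#' Equilibrium persistence across Hill coefficients
#'
#' Recomputes the atlas for each Hill coefficient and matches the stable
#' states of consecutive `n` by nearest-neighbour distance, reporting
#' whether each state persists with the same binarized on/off pattern. The
#' multistable backbone of a well-posed core network should be insensitive
#' to the steepness parameter.
#'
#' @param network a `gene_network`.
#' @param n_values Hill coefficients to sweep (each `>= 2`).
#' @param threshold binarization threshold for pattern matching.
#' @param ... passed on to [find_equilibria()].
#' @return list with `atlases` (one per `n`) and `report`, a data frame
#'   with one row per stable state and consecutive-`n` pair: the matched
#'   distance and whether the binarized pattern is preserved.
#' @export
robustness_sweep <- function(network, n_values, threshold = 0.5, ...) {
  stopifnot(length(n_values) >= 1L, all(n_values >= 2))
  atlases <- lapply(n_values, function(nv) {
    find_equilibria(network, hill_params(n = nv), ...)
  })
  names(atlases) <- paste0("n", n_values)

  rows <- list()
  if (length(n_values) == 1L) {
    a <- atlases[[1L]]
    for (s in a$states) {
      if (s$class != "stable") next
      rows[[length(rows) + 1L]] <- data.frame(
        n_from = n_values[1L], n_to = n_values[1L], label = s$label,
        matched_label = s$label, distance = 0, preserved = TRUE)
    }
  } else {
    for (i in seq_len(length(n_values) - 1L)) {
      a <- atlases[[i]]; b <- atlases[[i + 1L]]
      b_stable <- Filter(function(s) s$class == "stable", b$states)
      if (length(b_stable) == 0L) stop("no stable states at n = ", n_values[i + 1L])
      bx <- do.call(rbind, lapply(b_stable, function(s) unname(s$x)))
      for (s in a$states) {
        if (s$class != "stable") next
        d <- sqrt(rowSums((bx - rep(unname(s$x), each = nrow(bx)))^2))
        j <- which.min(d)
        rows[[length(rows) + 1L]] <- data.frame(
          n_from = n_values[i], n_to = n_values[i + 1L], label = s$label,
          matched_label = b_stable[[j]]$label, distance = d[j],
          preserved = identical(.binarize(s$x, threshold),
                                .binarize(b_stable[[j]]$x, threshold)))
      }
    }
  }
  list(atlases = atlases, report = do.call(rbind, rows))
}

#' Scan for limit cycles by long-time integration from random states
#'
#' Integrates the flow from seeded uniform random initial states and checks
#' that every trajectory settles onto a known equilibrium (terminal speed
#' below tolerance and within the squared-distance bound `delta2` of an
#' atlas state). Trajectories that do neither are flagged non-convergent
#' and would indicate a limit cycle or an unresolved attractor.
#'
#' @param network a `gene_network`.
#' @param params a `hill_params`.
#' @param atlas an `equilibrium_atlas` for the same network/params; computed
#'   on the fly if missing.
#' @param n_starts number of random initial states (default 200).
#' @param t_max maximum integration time per trajectory.
#' @param seed RNG seed for the starts.
#' @param config a [landscape_config()] supplying integrator settings.
#' @return list with `n_converged`, `n_nonconvergent` and a data frame
#'   `detail` (per-start terminal state label or `NA`).
#' @export
limit_cycle_scan <- function(network, params = hill_params(), atlas = NULL,
                             n_starts = 200L, t_max = 500, seed = 1L,
                             config = landscape_config(t_max = t_max)) {
  stopifnot(t_max > 0)
  if (is.null(atlas)) atlas <- find_equilibria(network, params)
  G <- length(network$genes)
  starts <- .with_seed(seed, matrix(stats::runif(n_starts * G), n_starts, G))
  lab <- character(n_starts)
  for (s in seq_len(n_starts)) {
    tr <- integrate_trajectory(network, starts[s, ], params, config)
    hit <- reachable_state(tr, atlas, config)
    lab[s] <- if (tr$converged && !is.na(hit)) hit else NA_character_
  }
  list(n_converged = sum(!is.na(lab)),
       n_nonconvergent = sum(is.na(lab)),
       detail = data.frame(start = seq_len(n_starts), terminal = lab))
}

# Evaluate expr with a temporary RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
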