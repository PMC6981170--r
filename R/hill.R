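#' Parameters of the coarse-grained Hill ODE model
#'
#' The regulatory dynamics of a core network are coarse-grained into one ODE
#' per gene: a shared sigmoidal production term driven by the summed
#' activator concentrations, multiplied by a sigmoidal repression factor
#' driven by the summed inhibitor concentrations, minus first-order decay,
#'
#' \deqn{\dot x_i = \eta\,
#'   \frac{\sum_{u \in act(i)} x_u^n}{K^n + \sum_{u \in act(i)} x_u^n}\cdot
#'   \frac{K^n}{K^n + \sum_{r \in inh(i)} x_r^n} - \tau x_i .}
#'
#' Concentrations are normalized to \[0, 1\]. With the default normalization
#' `eta = tau = 1` the maximal steady-state expression is 1, and `K = 0.5`
#' places the half-maximal response at half-maximal regulator expression, so
#' the production term reduces to
#' \eqn{2^n \Sigma x^n / (1 + 2^n \Sigma x^n)}. The Hill coefficient `n`
#' sets the steepness of regulation; `n >= 4` keeps the response close to
#' switch-like, which is the regime in which the model is intended to be
#' used. A gene with no activators has zero production (it can only decay);
#' a gene with no inhibitors has repression factor 1.
#'
#' @param n Hill coefficient (dimensionless, `>= 2`; default 4).
#' @param K dissociation constant (default 0.5, the normalized half-level).
#' @param eta production rate (default 1).
#' @param tau decay rate (default 1).
#' @return an object of class `hill_params`.
#' @export
hill_params <- function(n = 4, K = 0.5, eta = 1, tau = 1) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n), n >= 2,
            is.numeric(K), K > 0, is.numeric(eta), eta > 0,
            is.numeric(tau), tau > 0)
  structure(list(n = n, K = K, eta = eta, tau = tau), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("hill_params: n = %g, K = %g, eta = %g, tau = %g\n",
              x$n, x$K, x$eta, x$tau))
  invisible(x)
}

# Internal fast evaluators. Returns closures over the incidence matrices so
# repeated calls (Newton iterations, trajectory steps, action evaluations)
# skip validation. X is G x m (states in columns).
.hill_ops <- function(network, params) {
  A <- unname(network$act_mat)
  R <- unname(network$inh_mat)
  n <- params$n; Kn <- params$K^params$n
  eta <- params$eta; tau <- params$tau
  f <- function(X) {
    Xn <- X^n
    sa <- A %*% Xn
    sr <- R %*% Xn
    eta * (sa / (Kn + sa)) * (Kn / (Kn + sr)) - tau * X
  }
  # Jacobian at a single state vector x
  jac <- function(x) {
    xn <- x^n
    sa <- drop(A %*% xn); sr <- drop(R %*% xn)
    g <- n * x^(n - 1)
    P <- sa / (Kn + sa); Q <- Kn / (Kn + sr)
    J <- eta * ((Q * Kn / (Kn + sa)^2) * A - (P * Kn / (Kn + sr)^2) * R)
    J <- J * rep(g, each = nrow(J))
    diag(J) <- diag(J) - tau
    J
  }
  # t(J(x_col)) %*% y_col for every column pair of X, Y (used by the
  # analytic action gradient); returns a matrix of the same shape.
  jtv <- function(X, Y) {
    Xn <- X^n
    sa <- A %*% Xn; sr <- R %*% Xn
    P <- sa / (Kn + sa); Q <- Kn / (Kn + sr)
    C1 <- Q * Kn / (Kn + sa)^2
    C2 <- P * Kn / (Kn + sr)^2
    eta * (n * X^(n - 1)) * (crossprod(A, C1 * Y) - crossprod(R, C2 * Y)) - tau * Y
  }
  list(f = f, jac = jac, jtv = jtv)
}

.check_state <- function(network, x, permissive = FALSE) {
  x <- as.numeric(x)
  if (length(x) != length(network$genes)) {
    stop("state length ", length(x), " does not match ",
         length(network$genes), " genes")
  }
  if (any(!is.finite(x))) stop("non-finite state values")
  if (!permissive && any(x < 0)) {
    stop("negative concentrations are outside the model domain ",
         "(use permissive = TRUE to override)")
  }
  x
}

#' Velocity field of the Hill ODE model
#'
#' Evaluates \eqn{\dot x} at one state (see [hill_params()] for the model).
#' Both regulation factors lie in \[0, 1\], so each component satisfies
#' \eqn{\dot x_i \in [-x_i, 1 - x_i]} under the default normalization: the
#' unit box is forward-invariant.
#'
#' @param network a `gene_network`.
#' @param x numeric state vector, one normalized concentration per gene.
#' @param params a `hill_params`.
#' @param permissive allow negative concentrations (default `FALSE`).
#' @return numeric velocity vector, named by gene.
#' @examples
#' net <- pancreas_network()
#' hill_rhs(net, rep(0, 8))  # the origin is an equilibrium
#' @export
hill_rhs <- function(network, x, params = hill_params(), permissive = FALSE) {
  stopifnot(inherits(network, "gene_network"), inherits(params, "hill_params"))
  x <- .check_state(network, x, permissive)
  ops <- .hill_ops(network, params)
  stats::setNames(drop(ops$f(matrix(x))), network$genes)
}

#' Analytic Jacobian of the Hill ODE model
#'
#' Partial derivatives of the velocity field with respect to every gene
#' concentration. At the origin all Hill derivatives vanish for `n >= 2`
#' and the Jacobian is `-tau * I`.
#'
#' @inheritParams hill_rhs
#' @return a genes-by-genes numeric matrix.
#' @export
hill_jacobian <- function(network, x, params = hill_params(),
                          permissive = FALSE) {
  stopifnot(inherits(network, "gene_network"), inherits(params, "hill_params"))
  x <- .check_state(network, x, permissive)
  ops <- .hill_ops(network, params)
  J <- ops$jac(x)
  dimnames(J) <- list(network$genes, network$genes)
  J
}
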