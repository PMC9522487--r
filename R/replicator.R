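#' Normalized Hawk-Dove payoff matrix for the leu / c.leu contest
#'
#' Interactions between cells of the same type are neutral, so the diagonal
#' is zero; the cross payoffs are normalized to a single loss constant for
#' the Hawk (c.leu) row and a single gain constant for the Dove (leu) row:
#' \deqn{A = \begin{pmatrix} 0 & -a \\ b & 0 \end{pmatrix}.}
#'
#' @param a positive payoff constant lost by c.leu against leu.
#' @param b positive payoff constant gained by leu against c.leu.
#' @return 2x2 numeric matrix with dimnames `c("c.leu", "leu")`.
#' @examples
#' hawkdove_payoff_matrix(1, 1)
#' @export
hawkdove_payoff_matrix <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("payoff constants `a` and `b` must be positive and finite",
         call. = FALSE)
  }
  matrix(c(0, -a, b, 0), nrow = 2, byrow = TRUE,
         dimnames = list(c("c.leu", "leu"), c("c.leu", "leu")))
}

#' Strategy frequencies from absolute cell counts
#'
#' Converts counts of cancerous (`P_L`) and healthy (`P_I`) leukocytes to
#' frequencies on the simplex: \eqn{x_1 = P_L/p}, \eqn{x_2 = P_I/p} with
#' \eqn{p = P_L + P_I}.
#'
#' @param P_L c.leu count (cells/liter), non-negative.
#' @param P_I leu count (cells/liter), non-negative.
#' @return numeric vector `c(x1, x2)` summing to 1.
#' @examples
#' frequencies_from_counts(30e9, 70e9)  # c(0.3, 0.7)
#' @export
frequencies_from_counts <- function(P_L, P_I) {
  if (P_L < 0 || P_I < 0) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  p <- P_L + P_I
  if (p == 0) {
    stop("total cell count is zero; frequencies are undefined",
         call. = FALSE)
  }
  c(x1 = P_L / p, x2 = P_I / p)
}

#' Per-strategy fitness under a payoff matrix
#'
#' The fitness of strategy i in population state x is its average payoff
#' \eqn{H_i = (Ax)_i = \sum_j a_{ij} x_j}.
#'
#' @param A square payoff matrix.
#' @param x frequency vector of matching length.
#' @return numeric fitness vector H.
#' @export
strategy_fitness <- function(A, x) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || length(x) != nrow(A)) {
    stop("`A` must be square with dimension matching `x`", call. = FALSE)
  }
  drop(A %*% x)
}

#' Population mean fitness
#'
#' The mean payoff over the whole population,
#' \eqn{\bar H = \sum_i x_i H_i = x^T A x}.
#'
#' @inheritParams strategy_fitness
#' @return scalar mean fitness.
#' @export
mean_fitness <- function(A, x) {
  sum(x * strategy_fitness(A, x))
}

#' General n-strategy replicator vector field
#'
#' A strategy grows at its fitness excess over the population mean:
#' \eqn{\dot x_i = x_i (H_i - \bar H)}. The components always sum to zero,
#' so the simplex is invariant.
#'
#' @inheritParams strategy_fitness
#' @param tol tolerance for the on-simplex check on `x`.
#' @return velocity vector of the same length as `x`.
#' @examples
#' replicator_rhs(diag(c(2, 1)), c(0.5, 0.5))  # c(0.125, -0.125)
#' @export
replicator_rhs <- function(A, x, tol = 1e-9) {
  if (any(x < -tol) || abs(sum(x) - 1) > tol) {
    stop("`x` is not on the frequency simplex", call. = FALSE)
  }
  H <- strategy_fitness(A, x)
  x * (H - sum(x * H))
}

#' Hawk-Dove replicator velocity of the c.leu frequency
#'
#' The one-dimensional flow obtained from the normalized two-strategy game
#' by eliminating \eqn{x_2 = 1 - x_1}:
#' \deqn{\dot x_1 = (a x_1 - b x_2)\, x_1 x_2.}
#' The companion leu velocity is exactly the negation.
#'
#' @inheritParams hawkdove_payoff_matrix
#' @param x1 c.leu frequency in `[0, 1]` (vectorised).
#' @return velocity of `x1` (same length as `x1`).
#' @examples
#' hawkdove_rhs(2, 1, 0.5)    # 0.125
#' hawkdove_rhs(2, 1, 1 / 3)  # interior fixed point, 0
#' @export
hawkdove_rhs <- function(a, b, x1) {
  if (any(x1 < 0 | x1 > 1)) {
    stop("`x1` must lie in [0, 1]", call. = FALSE)
  }
  (a * x1 - b * (1 - x1)) * x1 * (1 - x1)
}

hawkdove_rhs_derivative <- function(a, b, x1) {
  # d/dx of ((a+b)x - b) x (1-x), used for the stability sign test
  (a + b) * x1 * (1 - x1) + ((a + b) * x1 - b) * (1 - 2 * x1)
}

#' Fixed points of the Hawk-Dove replicator flow
#'
#' The flow has exactly three stationary points: the two monomorphic
#' boundary states \eqn{x_1 = 0} (only leu) and \eqn{x_1 = 1} (only c.leu),
#' and the interior mixed state \eqn{x^* = b/(a+b)}, the unique root of
#' \eqn{a x_1 = b x_2}. Each point is annotated with the derivative-sign
#' stability label from [classify_fixed_point_1d()].
#'
#' @inheritParams hawkdove_payoff_matrix
#' @return data.frame with columns `x`, `kind`
#'   (`monomorphic_0` / `monomorphic_1` / `interior`), `stability` and
#'   `derivative`.
#' @examples
#' hawkdove_fixed_points(1, 3)  # interior point at 0.75
#' @export
hawkdove_fixed_points <- function(a, b) {
  if (a <= 0 || b <= 0) {
    stop("payoff constants `a` and `b` must be positive", call. = FALSE)
  }
  x <- c(0, 1, b / (a + b))
  data.frame(
    x = x,
    kind = c("monomorphic_0", "monomorphic_1", "interior"),
    stability = vapply(x, function(xs) classify_fixed_point_1d(a, b, xs), ""),
    derivative = hawkdove_rhs_derivative(a, b, x),
    stringsAsFactors = FALSE
  )
}

#' Derivative-sign stability of a Hawk-Dove fixed point
#'
#' One-dimensional linear stability: the fixed point is stable when the
#' derivative of the velocity field is negative there, unstable when
#' positive, and degenerate when the derivative vanishes to within
#' `deg_tol`.
#'
#' @inheritParams hawkdove_payoff_matrix
#' @param x_star a fixed point of the Hawk-Dove flow (residual below
#'   `res_tol`).
#' @param res_tol fixed-point residual tolerance (default `1e-9`).
#' @param deg_tol derivative degeneracy tolerance (default `1e-12`).
#' @return `"stable"`, `"unstable"` or `"degenerate"`.
#' @export
classify_fixed_point_1d <- function(a, b, x_star, res_tol = 1e-9,
                                    deg_tol = 1e-12) {
  if (abs(hawkdove_rhs(a, b, x_star)) > res_tol) {
    stop("`x_star` is not a fixed point of the Hawk-Dove flow",
         call. = FALSE)
  }
  d <- hawkdove_rhs_derivative(a, b, x_star)
  if (abs(d) < deg_tol) return("degenerate")
  if (d < 0) "stable" else "unstable"
}
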