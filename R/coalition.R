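#' Payoff constants of the two-coalition transplantation game
#'
#' After a hematopoietic stem-cell (HSC) transplant, the three cell
#' players (HSC, leu, c.leu) reduce to two coupled two-strategy games:
#' (i) the favourable coalition (HSC, leu) against c.leu with normalized
#' payoff constants `a1`, `a2`, and (ii) leu against the unfavourable
#' coalition (c.leu, HSC) with constants `b1`, `b2`. The derived sums
#' `m = a1 + a2` and `n = b1 + b2` appear throughout the analysis.
#'
#' @param a1,a2 payoff constants of coalition game (i), finite.
#' @param b1,b2 payoff constants of coalition game (ii), finite.
#' @return object of class `coalition_payoffs`: list with `a1`, `a2`,
#'   `b1`, `b2`, `m`, `n`.
#' @export
coalition_payoffs <- function(a1, a2, b1, b2) {
  vals <- c(a1, a2, b1, b2)
  if (!all(is.finite(vals))) {
    stop("payoff constants must be finite", call. = FALSE)
  }
  structure(list(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 m = a1 + a2, n = b1 + b2),
            class = "coalition_payoffs")
}

#' Two-population replicator field of the coalition game
#'
#' Coupled one-dimensional replicator equations on the unit square:
#' \deqn{\dot x_1 = x_1 (1 - x_1)(a_1 - m x_2), \qquad
#'       \dot x_2 = x_2 (1 - x_2)(b_1 - n x_1),}
#' where \eqn{x_1}, \eqn{x_2} are the frequencies of favourable play in
#' the two populations.
#'
#' @param p a [coalition_payoffs()] object.
#' @param s numeric `c(x1, x2)` in the unit square.
#' @return numeric `c(dx1, dx2)`.
#' @export
coalition_rhs <- function(p, s) {
  x1 <- s[[1]]; x2 <- s[[2]]
  if (x1 < 0 || x1 > 1 || x2 < 0 || x2 > 1) {
    stop("state must lie in the unit square [0,1]^2", call. = FALSE)
  }
  c(dx1 = x1 * (1 - x1) * (p$a1 - p$m * x2),
    dx2 = x2 * (1 - x2) * (p$b1 - p$n * x1))
}

#' Fixed points of the coalition replicator system
#'
#' The four corners of the unit square are always stationary; when both
#' coordinates of the mixed point \eqn{(x_1^*, x_2^*) = (b_1/n,\; a_1/m)}
#' lie strictly inside (0, 1) it is returned as a fifth, interior fixed
#' point. Degenerate `m = 0` or `n = 0` suppresses the interior point with
#' a warning.
#'
#' @param p a [coalition_payoffs()] object.
#' @return data.frame with columns `x1`, `x2`, `kind`
#'   (`"corner"` or `"interior"`).
#' @examples
#' coalition_fixed_points(coalition_payoffs(1, 1, 1, 1))
#' @export
coalition_fixed_points <- function(p) {
  pts <- data.frame(x1 = c(0, 1, 1, 0), x2 = c(0, 1, 0, 1),
                    kind = "corner", stringsAsFactors = FALSE)
  if (p$m == 0 || p$n == 0) {
    warning("degenerate payoffs (m = 0 or n = 0): no interior fixed point",
            call. = FALSE)
    return(pts)
  }
  x1s <- p$b1 / p$n
  x2s <- p$a1 / p$m
  if (x1s > 0 && x1s < 1 && x2s > 0 && x2s < 1) {
    pts <- rbind(pts, data.frame(x1 = x1s, x2 = x2s, kind = "interior",
                                 stringsAsFactors = FALSE))
  }
  pts
}

#' Jacobian at the interior fixed point of the coalition game
#'
#' At the mixed equilibrium the diagonal vanishes identically and
#' \deqn{J^*_{12} = -x_1^*(1 - x_1^*)\, m, \qquad
#'       J^*_{21} = -x_2^*(1 - x_2^*)\, n,}
#' so the eigenvalues are \eqn{\pm\sqrt{J_{12} J_{21}}}: a real pair
#' (saddle) when the product is positive, a pure imaginary pair (center)
#' when negative.
#'
#' @param p a [coalition_payoffs()] object with an interior fixed point.
#' @return 2x2 numeric antidiagonal matrix.
#' @export
coalition_jacobian <- function(p) {
  fp <- coalition_fixed_points(p)
  int <- fp[fp$kind == "interior", ]
  if (nrow(int) == 0) {
    stop("no interior fixed point for these payoffs", call. = FALSE)
  }
  x1s <- int$x1[1]; x2s <- int$x2[1]
  matrix(c(0, -x1s * (1 - x1s) * p$m,
           -x2s * (1 - x2s) * p$n, 0),
         nrow = 2, byrow = TRUE)
}

#' Classify the interior fixed point of the coalition game
#'
#' Saddle when the off-diagonal product \eqn{J_{12} J_{21}} is positive
#' (which happens exactly when `a1` and `b1` share a sign), center
#' (closed orbits) when negative, degenerate when it vanishes to within
#' `tol`.
#'
#' @inheritParams coalition_jacobian
#' @param tol degeneracy tolerance (default `1e-12`).
#' @return `"saddle"`, `"center"` or `"degenerate"`.
#' @export
classify_interior <- function(p, tol = 1e-12) {
  J <- coalition_jacobian(p)
  prod_off <- J[1, 2] * J[2, 1]
  if (abs(prod_off) < tol) return("degenerate")
  if (prod_off > 0) "saddle" else "center"
}

#' Post-transplant payoff-matrix fixtures
#'
#' The two interaction matrices built from post-chemotherapy cell counts
#' (see [transplant_counts()]): `"leu_vs_hsc_cleu"` describes leu against
#' the unfavourable (c.leu, HSC) coalition, `"hsc_leu_vs_cleu"` the
#' favourable (HSC, leu) coalition against residual c.leu. Both are stored
#' verbatim; the apparent additive constructions from the raw counts
#' (e.g. 9.2247e6 = 9.19e6 infused CD34+ plus 3.47e4 CD34+ number) are
#' documented but not enforced.
#'
#' @param which fixture name, `"leu_vs_hsc_cleu"` or `"hsc_leu_vs_cleu"`.
#' @return 2x2 numeric antidiagonal matrix.
#' @examples
#' transplant_payoff_fixture("leu_vs_hsc_cleu")
#' @export
transplant_payoff_fixture <- function(which = c("leu_vs_hsc_cleu",
                                                "hsc_leu_vs_cleu")) {
  which <- match.arg(which)
  switch(which,
         leu_vs_hsc_cleu = matrix(c(0, 5e8, 9.2247e6, 0),
                                  nrow = 2, byrow = TRUE),
         hsc_leu_vs_cleu = matrix(c(0, 1009224700, 0.431001, 0),
                                  nrow = 2, byrow = TRUE))
}

#' Saddle analysis of an interaction matrix
#'
#' Full [stability_report()] of a 2x2 matrix; a negative determinant means
#' real eigenvalues of opposite signs, i.e. a saddle. Used on the
#' transplantation fixtures, whose antidiagonal structure forces a zero
#' trace.
#'
#' @param M 2x2 numeric matrix with finite entries.
#' @return a `stability_report`.
#' @examples
#' saddle_report(transplant_payoff_fixture("leu_vs_hsc_cleu"))
#' @export
saddle_report <- function(M) {
  stability_report(M)
}
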