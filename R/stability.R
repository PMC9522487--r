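#' Eigenvalues of a 2x2 matrix from its trace and determinant
#'
#' Closed-form roots of the characteristic polynomial
#' \eqn{\lambda^2 - \tau\lambda + \Delta} where \eqn{\tau} is the trace and
#' \eqn{\Delta} the determinant. Returned sorted by real part, then by
#' imaginary part, so reports are deterministic.
#'
#' @param J numeric 2x2 matrix with finite entries.
#' @return complex vector of length 2.
#' @examples
#' eigenvalues_2x2(diag(c(2, 3)))
#' eigenvalues_2x2(matrix(c(0, 1, 1, 0), 2))
#' @export
eigenvalues_2x2 <- function(J) {
  J <- check_matrix_2x2(J)
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * dt
  if (disc >= 0) {
    s <- sqrt(disc)
    ev <- complex(real = c((tr - s) / 2, (tr + s) / 2), imaginary = c(0, 0))
  } else {
    s <- sqrt(-disc)
    ev <- complex(real = c(tr / 2, tr / 2), imaginary = c(-s / 2, s / 2))
  }
  ev[order(Re(ev), Im(ev))]
}

#' Trace-determinant classification of a 2x2 Jacobian
#'
#' Standard trace-determinant-plane taxonomy: negative determinant gives a
#' saddle; positive determinant gives a node (non-negative discriminant) or
#' a focus (negative discriminant), stable when the trace is negative; a
#' positive determinant with vanishing trace and negative discriminant is a
#' center. Sign tests use the tolerance `tol`; boundary cases are reported
#' as `"degenerate"` rather than guessed.
#'
#' @param J numeric 2x2 matrix.
#' @param tol tolerance for sign tests (default `1e-12`).
#' @return one of `"saddle"`, `"stable node"`, `"unstable node"`,
#'   `"stable focus"`, `"unstable focus"`, `"center"`, `"degenerate"`.
#' @examples
#' classify_2x2(matrix(c(-1, 0, 0, -2), 2))   # stable node
#' classify_2x2(matrix(c(0, 1, 1, 0), 2))     # saddle
#' classify_2x2(matrix(c(0, 1, -1, 0), 2))    # center
#' @export
classify_2x2 <- function(J, tol = 1e-12) {
  J <- check_matrix_2x2(J)
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * dt
  if (dt < -tol) return("saddle")
  if (dt > tol) {
    if (disc >= tol) {
      return(if (tr < 0) "stable node" else "unstable node")
    }
    if (disc < -tol) {
      if (abs(tr) <= tol) return("center")
      return(if (tr < 0) "stable focus" else "unstable focus")
    }
  }
  "degenerate"
}

#' Full stability report for an equilibrium of a planar system
#'
#' Bundles the Jacobian with its trace, determinant, discriminant
#' (\eqn{\tau^2 - 4\Delta}), eigenvalues and trace-determinant class label.
#'
#' @param J numeric 2x2 Jacobian.
#' @param point optional equilibrium coordinates (numeric vector).
#' @param tol sign-test tolerance passed to [classify_2x2()].
#' @return an object of class `stability_report`: a list with elements
#'   `point`, `jacobian`, `trace`, `det`, `discriminant`, `eigenvalues`
#'   (complex pair) and `label`.
#' @seealso [saddle_report()], [leslie_stability_report()]
#' @examples
#' stability_report(matrix(c(0, 1, 1, 0), 2))
#' @export
stability_report <- function(J, point = NULL, tol = 1e-12) {
  J <- check_matrix_2x2(J)
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  rep <- list(
    point        = point,
    jacobian     = J,
    trace        = tr,
    det          = dt,
    discriminant = tr^2 - 4 * dt,
    eigenvalues  = eigenvalues_2x2(J),
    label        = classify_2x2(J, tol = tol)
  )
  class(rep) <- "stability_report"
  rep
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report\n")
  if (!is.null(x$point)) {
    cat("  equilibrium :", paste(signif(x$point, 6), collapse = ", "), "\n")
  }
  cat("  trace       :", format(x$trace), "\n")
  cat("  det         :", format(x$det), "\n")
  cat("  discriminant:", format(x$discriminant), "\n")
  cat("  eigenvalues :", paste(format(x$eigenvalues), collapse = ", "), "\n")
  cat("  label       :", x$label, "\n")
  invisible(x)
}

check_matrix_2x2 <- function(J) {
  J <- as.matrix(J)
  if (!all(dim(J) == c(2L, 2L))) {
    stop("`J` must be a 2x2 matrix", call. = FALSE)
  }
  storage.mode(J) <- "double"
  if (!all(is.finite(J))) {
    stop("`J` must have finite entries", call. = FALSE)
  }
  J
}
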