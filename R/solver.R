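#' Solve a linear or mixed-integer linear program
#'
#' Low-level interface to the GLPK solver used by all constraint-based
#' analyses in the package. The problem is
#' \deqn{\max / \min\; c^\top x \quad \textrm{s.t.}\quad
#'       rlb \le A x \le rub,\; clb \le x \le cub,}
#' optionally with a subset of variables restricted to \{0, 1\}.
#'
#' @param obj numeric objective coefficients (length = number of columns).
#' @param A constraint matrix: any \pkg{Matrix} sparse matrix, a dense matrix,
#'   or a list with triplet components `i`, `j`, `x` and `nrow`.
#' @param rlb,rub row (constraint) lower/upper bounds; use `-Inf`/`Inf` for
#'   one-sided constraints, equal values for equalities.
#' @param clb,cub column (variable) bounds.
#' @param maximize logical; maximize (default) or minimize.
#' @param binary integer indices (1-based) of binary variables; when nonempty
#'   the problem is solved with GLPK's branch-and-cut.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"undefined"`), `objective` and the primal solution `x`.
#' @keywords internal
#' @export
solve_lp <- function(obj, A, rlb, rub, clb, cub, maximize = TRUE,
                     binary = integer(0)) {
  if (is.list(A) && !inherits(A, "Matrix")) {
    ai <- as.integer(A$i); aj <- as.integer(A$j); ax <- as.double(A$x)
    m <- as.integer(A$nrow)
  } else {
    At <- as(as(as(A, "dMatrix"), "generalMatrix"), "TsparseMatrix")
    ai <- At@i + 1L; aj <- At@j + 1L; ax <- At@x
    m <- nrow(At)
  }
  keep <- ax != 0
  n <- length(obj)
  stopifnot(length(clb) == n, length(cub) == n,
            length(rlb) == m, length(rub) == m)
  res <- .Call(C_glpk_solve, as.double(obj), isTRUE(maximize), m,
               ai[keep], aj[keep], ax[keep],
               as.double(rlb), as.double(rub),
               as.double(clb), as.double(cub),
               as.integer(binary))
  # GLPK status codes: 1 undefined, 2 feasible, 3 infeasible, 4 no feasible,
  # 5 optimal, 6 unbounded
  status <- switch(as.character(res$status),
                   "5" = "optimal",
                   "3" = "infeasible",
                   "4" = "infeasible",
                   "6" = "unbounded",
                   "undefined")
  list(status = status, objective = res$objval, x = res$x)
}
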