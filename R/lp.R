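#' Solve a linear program
#'
#' Minimal solver-agnostic LP interface used by the proteome-constrained
#' engine: `min/max obj'x` subject to `A x (sense) rhs` and `lb <= x <= ub`.
#' The backend is a dense two-phase primal simplex (compiled); for the model
#' sizes this package targets (a few hundred variables) it is exact and fast.
#'
#' Lower bounds are handled by shifting (`x = lb + y`), finite upper bounds
#' become explicit rows, so the core always sees `y >= 0`.
#'
#' @param obj numeric objective coefficients (length `n`).
#' @param A dense constraint matrix (`m x n`).
#' @param sense character vector of row senses: `"<="`, `"="` or `">="`.
#' @param rhs numeric right-hand sides (length `m`).
#' @param lb,ub variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param maximize maximize instead of minimize.
#' @param tol pivot tolerance of the simplex core.
#' @param feas_tol feasibility tolerance (phase-1 acceptance).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x`, and `obj` (objective value, on the original
#'   min/max scale).
#' @keywords internal
#' @export
solve_lp <- function(obj, A, sense, rhs, lb = NULL, ub = NULL,
                     maximize = FALSE, tol = 1e-9, feas_tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(sense) == m)
  if (is.null(lb)) lb <- numeric(n)
  if (is.null(ub)) ub <- rep(Inf, n)
  if (any(!is.finite(lb))) stop("solve_lp: lower bounds must be finite")
  if (any(ub < lb - 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), obj = NA_real_))
  }
  scode <- match(sense, c("<=", "=", ">="))
  if (anyNA(scode)) stop("solve_lp: sense must be one of <=, =, >=")

  ## shift lower bounds
  rhs2 <- rhs - as.numeric(A %*% lb)
  ubs <- ub - lb
  fin <- which(is.finite(ubs))
  if (length(fin)) {
    Aub <- matrix(0, length(fin), n)
    Aub[cbind(seq_along(fin), fin)] <- 1
    A2 <- rbind(A, Aub)
    rhs2 <- c(rhs2, ubs[fin])
    scode <- c(scode, rep(1L, length(fin)))
  } else {
    A2 <- A
  }
  cvec <- if (maximize) -obj else obj
  res <- .simplex_core(A2, rhs2, cvec, c(-1L, 0L, 1L)[scode],
                       tol = tol, feas_tol = feas_tol)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "2" = "infeasible",
                   "3" = "unbounded", "4" = "iteration_limit")
  if (status != "optimal") {
    return(list(status = status, x = rep(NA_real_, n), obj = NA_real_))
  }
  x <- res$x + lb
  objval <- sum(obj * x)
  list(status = status, x = x, obj = objval)
}
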