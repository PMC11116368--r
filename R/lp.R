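# LP/MILP layer used by all constraint-based computations.
#
# LPs are solved by a self-contained two-phase dense tableau simplex:
# Dantzig pricing by default, with an automatic retry under Bland's rule if
# the iteration cap is hit (anti-cycling). Problem sizes here are desk
# scale (tens of variables), where a dense tableau is simple and fast.
# The gap-filling MILP is solved exactly by branch-and-bound on the binary
# indicator variables with the LP relaxation as bound.

MAX_LP_BOUND <- 1e6

simplex_pivot <- function(Tb, row, col) {
  piv <- Tb[row, col]
  Tb[row, ] <- Tb[row, ] / piv
  other <- setdiff(seq_len(nrow(Tb)), row)
  fac <- Tb[other, col]
  Tb[other, ] <- Tb[other, ] - outer(fac, Tb[row, ])
  Tb
}

# minimize cost . x  s.t.  A x = b (b >= 0), x >= 0, starting from the given
# basis (identity columns). Last tableau row is the reduced-cost row.
simplex_core <- function(Tb, basis, bland = FALSE, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(Tb) - 1L
  ncols <- ncol(Tb) - 1L
  zr <- nrow(Tb)
  bc <- ncol(Tb)
  for (it in seq_len(max_iter)) {
    red <- Tb[zr, seq_len(ncols)]
    neg <- which(red < -tol)
    if (!length(neg))
      return(list(status = "optimal", Tb = Tb, basis = basis))
    enter <- if (bland) neg[1] else neg[which.min(red[neg])]
    col <- Tb[seq_len(m), enter]
    pos <- which(col > tol)
    if (!length(pos))
      return(list(status = "unbounded", Tb = Tb, basis = basis))
    ratios <- Tb[pos, bc] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    leave <- cand[which.min(basis[cand])]
    Tb <- simplex_pivot(Tb, leave, enter)
    basis[leave] <- enter
  }
  list(status = "iteration_limit", Tb = Tb, basis = basis)
}

# two-phase simplex on  min cost . x, A x (dir) b, x >= 0
simplex_two_phase <- function(cost, A, dir, b, bland = FALSE, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  # normalize rhs signs
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    dir[flip] <- vapply(dir[flip], function(d)
      switch(d, "<=" = ">=", ">=" = "<=", "==" = "=="), character(1))
  }
  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  ncols <- n + n_slack + n_surp + n_art
  M <- matrix(0, m, ncols)
  M[, seq_len(n)] <- A
  basis <- integer(m)
  si <- n; ui <- n + n_slack; ai <- n + n_slack + n_surp
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      si <- si + 1L; M[i, si] <- 1; basis[i] <- si
    } else {
      if (dir[i] == ">=") { ui <- ui + 1L; M[i, ui] <- -1 }
      ai <- ai + 1L; M[i, ai] <- 1; basis[i] <- ai
    }
  }
  art_cols <- seq(n + n_slack + n_surp + 1L, length.out = n_art)
  run <- function(cvec, Tb, basis, bland) {
    # canonicalize reduced-cost row for the given basis
    zrow <- c(cvec, 0)
    for (i in seq_len(nrow(Tb) - 1L))
      if (cvec[basis[i]] != 0) zrow <- zrow - cvec[basis[i]] * Tb[i, ]
    Tb[nrow(Tb), ] <- zrow
    simplex_core(Tb, basis, bland = bland, tol = tol)
  }
  Tb <- rbind(cbind(M, b), 0)
  if (n_art > 0) {
    c1 <- numeric(ncols); c1[art_cols] <- 1
    r1 <- run(c1, Tb, basis, bland)
    if (r1$status == "iteration_limit" && !bland)
      return(simplex_two_phase(cost, A, dir, b, bland = TRUE, tol = tol))
    if (r1$status != "optimal") return(list(status = "infeasible"))
    if (-r1$Tb[nrow(r1$Tb), ncol(r1$Tb)] > 1e-7 * (1 + max(abs(b))))
      return(list(status = "infeasible"))
    Tb <- r1$Tb; basis <- r1$basis
    # drive basic artificials out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      row <- Tb[i, seq_len(n + n_slack + n_surp)]
      j <- which(abs(row) > tol)[1]
      if (!is.na(j)) {
        Tb <- simplex_pivot(Tb, i, j)
        basis[i] <- j
      }
    }
    # forbid re-entry of artificial columns
    Tb[, art_cols] <- 0
  }
  c2 <- numeric(ncols); c2[seq_len(n)] <- cost
  r2 <- run(c2, Tb, basis, bland)
  if (r2$status == "iteration_limit" && !bland)
    return(simplex_two_phase(cost, A, dir, b, bland = TRUE, tol = tol))
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  if (r2$status != "optimal") return(list(status = "failed"))
  x <- numeric(ncols)
  x[r2$basis] <- r2$Tb[seq_len(m), ncol(r2$Tb)]
  list(status = "optimal", x = x[seq_len(n)],
       objective = sum(cost * x[seq_len(n)]))
}

#' Solve a bounded linear program
#'
#' Maximize (or minimize) `obj . v` subject to `A v (dir) rhs` and
#' `lb <= v <= ub`. All bounds must be finite (they are clamped to +/-1e6).
#'
#' @param obj Objective coefficient vector.
#' @param A Constraint matrix (may have zero rows, or `NULL`).
#' @param dir Character vector of `"<="`, `">="`, `"=="` per row.
#' @param rhs Right-hand sides.
#' @param lb,ub Variable bounds.
#' @param maximize Logical.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"failed"`), `objective`, and `solution`.
#' @keywords internal
#' @export
solve_lp <- function(obj, A, dir, rhs, lb, ub, maximize = TRUE) {
  n <- length(obj)
  lb <- pmax(lb, -MAX_LP_BOUND); ub <- pmin(ub, MAX_LP_BOUND)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  if (is.null(A)) A <- matrix(0, 0, n)
  if (!is.matrix(A)) A <- matrix(A, ncol = n)
  # shift x = v - lb so x >= 0; add explicit upper-bound rows
  rhs2 <- rhs - as.numeric(A %*% lb)
  span <- ub - lb
  A_all <- rbind(A, diag(n))
  dir_all <- c(dir, rep("<=", n))
  rhs_all <- c(rhs2, span)
  cost <- if (maximize) -obj else obj
  res <- simplex_two_phase(cost, A_all, dir_all, rhs_all)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, solution = NULL))
  v <- res$x + lb
  list(status = "optimal", objective = sum(obj * v), solution = v)
}

#' Solve a mixed-integer linear program by branch-and-bound
#'
#' Exact branch-and-bound over the variables listed in `int_idx` (binary in
#' the gap-filling use), with the LP relaxation via [solve_lp()] as the
#' bounding function.
#'
#' @inheritParams solve_lp
#' @param int_idx Indices of integer-constrained variables.
#' @param int_tol Integrality tolerance.
#' @return As [solve_lp()]; `solution` is integral on `int_idx`.
#' @keywords internal
#' @export
solve_milp <- function(obj, A, dir, rhs, lb, ub, int_idx,
                       maximize = FALSE, int_tol = 1e-6) {
  best <- list(status = "infeasible", objective = if (maximize) -Inf else Inf,
               solution = NULL)
  better <- function(a, b) if (maximize) a > b + 1e-9 else a < b - 1e-9
  nodes <- list(list(lb = lb, ub = ub))
  while (length(nodes)) {
    node <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    rel <- solve_lp(obj, A, dir, rhs, node$lb, node$ub, maximize = maximize)
    if (rel$status != "optimal") next
    if (!is.null(best$solution) && !better(rel$objective, best$objective)) next
    frac <- abs(rel$solution[int_idx] - round(rel$solution[int_idx]))
    if (all(frac <= int_tol)) {
      sol <- rel$solution
      sol[int_idx] <- round(sol[int_idx])
      if (is.null(best$solution) || better(rel$objective, best$objective))
        best <- list(status = "optimal", objective = rel$objective, solution = sol)
      next
    }
    j <- int_idx[which.max(frac)]
    xj <- rel$solution[j]
    down <- node; down$ub[j] <- floor(xj)
    up <- node; up$lb[j] <- ceiling(xj)
    nodes <- c(nodes, list(down, up))
  }
  if (is.null(best$solution))
    best <- list(status = "infeasible", objective = NA_real_, solution = NULL)
  best
}
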