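#' Construct a linear (or mixed-integer linear) problem
#'
#' A thin container for the LP/MILP systems assembled from community models.
#' Rows are linear constraints `a'x {=,<=,>=} rhs`; variables carry box
#' bounds; an optional set of variable names is declared binary.
#'
#' @param objective named numeric vector of objective coefficients (names must
#'   be a subset of `vars`; missing variables get coefficient 0).
#' @param sense `"max"` or `"min"`.
#' @param A constraint matrix (dense or `Matrix`), columns ordered as `vars`.
#'   May have zero rows.
#' @param row_sense character vector, one of `"E"`, `"L"`, `"G"` per row.
#' @param rhs numeric right-hand sides.
#' @param lb,ub variable bounds (may be `-Inf`/`Inf`).
#' @param vars variable names.
#' @param integers character vector of binary variable names (bounds must lie
#'   inside `[0, 1]`).
#' @return an object of class `lp_problem`.
#' @export
lp_problem <- function(objective, sense = c("max", "min"), A, row_sense, rhs,
                       lb, ub, vars, integers = character()) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- length(vars)
  if (ncol(A) != n) stop("A has ", ncol(A), " columns but ", n, " variables")
  if (length(rhs) != nrow(A) || length(row_sense) != nrow(A))
    stop("row_sense/rhs length must equal nrow(A)")
  if (!all(row_sense %in% c("E", "L", "G"))) stop("row_sense must be E, L or G")
  if (length(lb) != n || length(ub) != n) stop("bounds must have length ", n)
  if (anyDuplicated(vars)) stop("duplicate variable names")
  bad <- setdiff(names(objective), vars)
  if (length(bad)) stop("objective references unknown variables: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(integers, vars)
  if (length(bad)) stop("integers references unknown variables: ",
                        paste(bad, collapse = ", "))
  obj <- stats::setNames(numeric(n), vars)
  obj[names(objective)] <- objective
  names(lb) <- names(ub) <- vars
  if (any(lb > ub + 1e-12)) stop("lb > ub for some variable")
  if (length(integers)) {
    if (any(lb[integers] < -1e-9) || any(ub[integers] > 1 + 1e-9))
      stop("binary variables must have bounds within [0, 1]")
  }
  structure(list(objective = obj, sense = sense, A = A,
                 row_sense = row_sense, rhs = rhs, lb = lb, ub = ub,
                 vars = vars, integers = integers),
            class = "lp_problem")
}

#' @export
print.lp_problem <- function(x, ...) {
  cat("<lp_problem> ", length(x$vars), " variables (",
      length(x$integers), " binary), ", nrow(x$A), " rows, sense ",
      x$sense, "\n", sep = "")
  invisible(x)
}

# convert to  min c'x, A x = b, l <= x <= u  (slacks appended)
standardize_lp <- function(p) {
  c0 <- if (p$sense == "max") -p$objective else p$objective
  A <- p$A
  rhs <- p$rhs
  # flip G rows to L
  g <- p$row_sense == "G"
  if (any(g)) {
    A[g, , drop = FALSE] -> Ag
    A[g, ] <- -Ag
    rhs[g] <- -rhs[g]
  }
  ineq <- which(p$row_sense != "E")
  nslack <- length(ineq)
  n <- ncol(A)
  if (nslack) {
    S <- matrix(0, nrow(A), nslack)
    S[cbind(ineq, seq_len(nslack))] <- 1
    A <- cbind(A, S)
  }
  list(A = A, b = rhs,
       c = c(c0, numeric(nslack)),
       lb = c(p$lb, numeric(nslack)),
       ub = c(p$ub, rep(Inf, nslack)),
       n = n)
}

finite_inf <- function(v) {
  v[v == Inf] <- 1e30
  v[v == -Inf] <- -1e30
  v
}

solve_result <- function(status, objective_value, fluxes, membership = NULL,
                         message = NULL) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes, membership = membership, message = message),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat("<solve_result> status: ", x$status, sep = "")
  if (identical(x$status, "optimal"))
    cat(", objective: ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' Solve a linear program
#'
#' The default backend is the package's dense bounded-variable two-phase
#' simplex (compiled); `"scipy"` shells out to Python's HiGHS via
#' `scipy.optimize.linprog` and exists for cross-checking.
#'
#' @param p an [lp_problem] without binary variables.
#' @param backend `"simplex"` (default, set via option `minicom.solver`) or
#'   `"scipy"`.
#' @return a `solve_result` with fields `status`
#'   (`optimal`/`infeasible`/`unbounded`/`error`), `objective_value` and
#'   `fluxes` (named vector over the problem variables).
#' @export
solve_lp <- function(p, backend = getOption("minicom.solver", "simplex")) {
  stopifnot(inherits(p, "lp_problem"))
  if (length(p$integers)) stop("problem has integer variables; use solve_milp()")
  if (backend == "scipy") return(scipy_solve(list(p))[[1]])
  s <- standardize_lp(p)
  if (nrow(s$A) == 0L) return(solve_boxed(p))
  r <- cpp_solve_lp(s$A, s$b, s$c, finite_inf(s$lb), finite_inf(s$ub))
  status <- switch(as.character(r$status), "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "error")
  obj <- if (status == "optimal") {
    if (p$sense == "max") -r$obj else r$obj
  } else NA_real_
  fx <- stats::setNames(r$x[seq_len(s$n)], p$vars)
  solve_result(status, obj, fx,
               message = if (status == "error")
                 paste("simplex failure, code", r$status))
}

# LP with no rows: each variable sits at its objective-optimal bound
solve_boxed <- function(p) {
  c0 <- if (p$sense == "max") -p$objective else p$objective
  x <- ifelse(c0 > 0, p$lb, ifelse(c0 < 0, p$ub, pmax(p$lb, pmin(p$ub, 0))))
  if (any(!is.finite(x) & c0 != 0))
    return(solve_result("unbounded", NA_real_,
                        stats::setNames(rep(NA_real_, length(p$vars)), p$vars)))
  x[!is.finite(x)] <- 0
  obj <- sum(p$objective * x)
  solve_result("optimal", obj, stats::setNames(x, p$vars))
}

#' Solve a mixed-integer linear program
#'
#' Branch-and-bound over the binary variables with the package simplex for
#' the node relaxations.  When the objective is integral on integer-feasible
#' points (all binary coefficients integer, continuous coefficients zero) the
#' bound is tightened by rounding, so cardinality objectives prune quickly.
#'
#' @param p an [lp_problem] with a nonempty `integers` set.
#' @param backend passed to the node LP solves.
#' @param max_nodes guard on the branch-and-bound tree size.
#' @return a `solve_result`; `membership` holds the rounded binary values.
#' @export
solve_milp <- function(p, backend = getOption("minicom.solver", "simplex"),
                       max_nodes = 200000L) {
  stopifnot(inherits(p, "lp_problem"))
  if (!length(p$integers)) stop("no integer variables; use solve_lp()")
  if (backend == "scipy") return(scipy_solve(list(p))[[1]])
  ints <- p$integers
  minimize <- p$sense == "min"
  int_obj <- all(p$objective[ints] == round(p$objective[ints])) &&
    all(p$objective[setdiff(p$vars, ints)] == 0)

  relax <- p
  relax$integers <- character()
  best <- NULL
  best_obj <- Inf  # in minimization orientation
  nodes <- 0L
  itol <- 1e-6

  unbounded_seen <- FALSE

  rec <- function(fix) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) stop("branch-and-bound node limit exceeded")
    q <- relax
    if (length(fix)) {
      q$lb[names(fix)] <- fix
      q$ub[names(fix)] <- fix
    }
    r <- solve_lp(q, backend = backend)
    if (r$status == "unbounded") unbounded_seen <<- TRUE
    if (r$status != "optimal") return(invisible(NULL))
    obj <- if (minimize) r$objective_value else -r$objective_value
    bound <- if (int_obj) ceiling(obj - 1e-6) else obj
    if (bound >= best_obj - 1e-9) return(invisible(NULL))
    xi <- r$fluxes[ints]
    frac <- abs(xi - round(xi))
    if (all(frac < itol)) {
      best <<- r
      best_obj <<- obj
      return(invisible(NULL))
    }
    j <- ints[which.max(frac)]
    first <- if (xi[[j]] >= 0.5) 1 else 0
    for (v in c(first, 1 - first)) {
      f2 <- fix
      f2[j] <- v
      rec(f2)
    }
    invisible(NULL)
  }
  rec(stats::setNames(numeric(0), character(0)))

  if (is.null(best))
    return(solve_result(if (unbounded_seen) "unbounded" else "infeasible",
                        NA_real_,
                        stats::setNames(rep(NA_real_, length(p$vars)), p$vars)))
  mem <- round(best$fluxes[ints])
  solve_result("optimal", best$objective_value, best$fluxes, membership = mem)
}

# ---- scipy backend (HiGHS via the python interpreter on PATH) -------------

# Solve a list of lp_problems in one python invocation; returns a list of
# solve_results.  Used as the independent second backend in cross-checks.
scipy_solve <- function(problems) {
  script <- system.file("python", "lp_solve.py", package = "minicom")
  if (script == "") stop("bundled python helper not found")
  enc <- lapply(problems, function(p) {
    list(c = unname(p$objective), sense = p$sense,
         A = if (nrow(p$A)) unname(apply(p$A, 1, as.numeric, simplify = FALSE)) else list(),
         row_sense = as.list(p$row_sense), rhs = as.list(p$rhs),
         lb = unname(p$lb), ub = unname(p$ub),
         integers = as.list(match(p$integers, p$vars) - 1L))
  })
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(enc, fin, auto_unbox = TRUE, digits = NA, null = "null")
  rc <- system2("python", c(script, fin, fout), stdout = FALSE, stderr = "")
  if (rc != 0L || !file.exists(fout)) stop("scipy backend failed (exit ", rc, ")")
  out <- jsonlite::read_json(fout, simplifyVector = TRUE)
  lapply(seq_along(problems), function(i) {
    p <- problems[[i]]
    o <- if (is.data.frame(out)) out[i, ] else out[[i]]
    st <- as.character(o$status)
    fx <- stats::setNames(rep(NA_real_, length(p$vars)), p$vars)
    mem <- NULL
    if (st == "optimal") {
      xv <- if (is.data.frame(out)) unlist(o$x) else as.numeric(o$x)
      fx <- stats::setNames(xv, p$vars)
      if (length(p$integers)) mem <- round(fx[p$integers])
    }
    solve_result(st, if (st == "optimal") as.numeric(o$obj) else NA_real_,
                 fx, membership = mem)
  })
}
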