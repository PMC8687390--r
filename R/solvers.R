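#' Coupled system right-hand side
#'
#' Bundles the pair of real-valued functions \eqn{f_1(t, u, v)},
#' \eqn{f_2(t, u, v)} defining the coupled system
#' \eqn{{}^C D^{\beta_1} u = f_1}, \eqn{{}^C D^{\beta_2} v = f_2}.
#'
#' @param f1,f2 Functions of `(t, u, v)` returning a scalar.
#' @param label Short text label used in printing and manifests.
#' @return An object of class `"system_rhs"`.
#' @examples
#' rhs <- system_rhs(function(t, u, v) -u, function(t, u, v) 0, "decay")
#' @export
system_rhs <- function(f1, f2, label = "custom") {
  stopifnot(is.function(f1), is.function(f2))
  structure(list(f1 = f1, f2 = f2, label = as.character(label)[1]),
            class = "system_rhs")
}

#' @export
print.system_rhs <- function(x, ...) {
  cat(sprintf("<system_rhs> %s\n", x$label))
  invisible(x)
}

#' Uniform time grid
#'
#' Node `j` is `t0 + j * h`.  Exactly one of `steps` and `horizon` must be
#' given; with `horizon`, the number of steps is `round(horizon / h)` and the
#' horizon must be an integer multiple of `h` to within rounding.
#'
#' @param h Step size, positive.  Default `0.1`.
#' @param steps Number of steps (positive integer), or `NULL`.
#' @param horizon Final time `T` relative to `t0`, or `NULL`.
#' @param t0 Initial time.
#' @return An object of class `"time_grid"` with fields `t0`, `h`, `steps`,
#'   `times` (length `steps + 1`).
#' @examples
#' time_grid(h = 0.1, horizon = 2)
#' @export
time_grid <- function(h = 0.1, steps = NULL, horizon = NULL, t0 = 0) {
  stopifnot(is.numeric(h), length(h) == 1L, h > 0, is.finite(h))
  if (is.null(steps) == is.null(horizon)) {
    stop("give exactly one of `steps` and `horizon`", call. = FALSE)
  }
  if (is.null(steps)) {
    stopifnot(is.numeric(horizon), horizon > 0)
    steps <- round(horizon / h)
    if (abs(steps * h - horizon) > 1e-8 * max(1, horizon)) {
      stop("horizon must be an integer multiple of h", call. = FALSE)
    }
  }
  steps <- as.integer(steps)
  stopifnot(steps >= 1L || steps == 0L)
  structure(list(t0 = t0, h = h, steps = steps,
                 times = t0 + h * seq.int(0L, steps)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> t0 = %g, h = %g, %d steps (T = %g)\n",
              x$t0, x$h, x$steps, x$times[length(x$times)]))
  invisible(x)
}

#' One fractional Euler (FEM) step
#'
#' Advances `(u, v)` by one step of the fractional Euler method:
#' \deqn{u' = u + \frac{h^{\beta_1}}{\Gamma(\beta_1+1)} f_1(t, u, v), \quad
#'       v' = v + \frac{h^{\beta_2}}{\Gamma(\beta_2+1)} f_2(t, u, v),}
#' both components advanced from the same `(u, v)`.  At
#' \eqn{\beta_1 = \beta_2 = 1} this is one classical forward-Euler step.
#'
#' @param rhs A [system_rhs()].
#' @param t Current time.
#' @param u,v Current state.
#' @param h Step size.
#' @param beta1,beta2 Fractional orders in `(0, 1]`.
#' @return Named numeric vector `c(u = ..., v = ...)`.
#' @export
fem_step <- function(rhs, t, u, v, h, beta1, beta2 = beta1) {
  k1 <- rhs$f1(t, u, v)
  k2 <- rhs$f2(t, u, v)
  if (!is.finite(k1) || !is.finite(k2)) {
    stop("non-finite right-hand side at t = ", t, call. = FALSE)
  }
  c(u = u + euler_coefficient(h, beta1) * k1,
    v = v + euler_coefficient(h, beta2) * k2)
}

#' One fractional modified Euler step
#'
#' The midpoint-style improvement of the fractional Euler method: each
#' component's increment is the FEM coefficient times the right-hand side
#' evaluated at the predictor point offset by
#' \eqn{X_1 = \Gamma(\beta_1+1) h^{\beta_1} / \Gamma(2\beta_1+1)} (for
#' \eqn{\Delta u}) and \eqn{Y_1} (likewise from \eqn{\beta_2}, for
#' \eqn{\Delta v}).
#'
#' Two predictor conventions are provided:
#' * `mode = "corrected"` (default): the predictor state shifts each
#'   component by its own slope — `u` by \eqn{X_1 f_1(t,u,v)} and `v` by
#'   \eqn{X_1 f_2(t,u,v)} inside \eqn{\Delta u} (and with \eqn{Y_1} inside
#'   \eqn{\Delta v}).  This is the unique reading under which
#'   \eqn{\beta_1=\beta_2=1} recovers the classical explicit-midpoint (RK2)
#'   step for the system.
#' * `mode = "as_printed"`: both predictor shifts inside \eqn{\Delta u} use
#'   \eqn{f_1(t,u,v)} and both inside \eqn{\Delta v} use \eqn{f_2(t,u,v)}.
#'   Kept for fidelity to the scheme as it is sometimes typeset; it does not
#'   reduce to the system midpoint rule at \eqn{\beta = 1}.
#'
#' @inheritParams fem_step
#' @param mode Predictor convention, `"corrected"` or `"as_printed"`.
#' @return Named numeric vector `c(u = ..., v = ...)`.
#' @export
modified_euler_step <- function(rhs, t, u, v, h, beta1, beta2 = beta1,
                                mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  k1 <- rhs$f1(t, u, v)
  k2 <- rhs$f2(t, u, v)
  if (!is.finite(k1) || !is.finite(k2)) {
    stop("non-finite right-hand side at t = ", t, call. = FALSE)
  }
  X1 <- midpoint_offset(h, beta1)
  Y1 <- midpoint_offset(h, beta2)
  if (mode == "corrected") {
    du <- euler_coefficient(h, beta1) * rhs$f1(t + X1, u + X1 * k1, v + X1 * k2)
    dv <- euler_coefficient(h, beta2) * rhs$f2(t + Y1, u + Y1 * k1, v + Y1 * k2)
  } else {
    du <- euler_coefficient(h, beta1) * rhs$f1(t + X1, u + X1 * k1, v + X1 * k1)
    dv <- euler_coefficient(h, beta2) * rhs$f2(t + Y1, u + Y1 * k2, v + Y1 * k2)
  }
  if (!is.finite(du) || !is.finite(dv)) {
    stop("non-finite predictor-stage right-hand side at t = ", t,
         call. = FALSE)
  }
  c(u = u + du, v = v + dv)
}

#' Solve a crisp two-component system
#'
#' Applies the chosen one-step scheme repeatedly from `(u0, v0)` over a
#' uniform grid.  Both schemes are memoryless (local generalised-Taylor)
#' one-step methods: the full Caputo history integral is **not** accumulated,
#' so for \eqn{\beta < 1} the numerical solution does not converge to the
#' exact fractional solution as \eqn{h \to 0} (see the package vignette); at
#' \eqn{\beta = 1} they are the classical forward-Euler and explicit-midpoint
#' methods with their usual orders 1 and 2.
#'
#' @param rhs A [system_rhs()].
#' @param u0,v0 Initial state.
#' @param grid A [time_grid()].
#' @param beta1,beta2 Fractional orders in `(0, 1]`.
#' @param method `"fem"` or `"modified"`.
#' @param mode Predictor convention for `method = "modified"`.
#' @return A data frame with columns `t`, `u`, `v` of class
#'   `c("crisp_trajectory", "data.frame")`, carrying the solver settings as
#'   attributes.  A classed warning (`ffde_negative_state`) is raised if any
#'   state becomes negative; states are never clipped.
#' @examples
#' rhs <- make_lv_rhs(5, 1, 2)
#' traj <- solve_crisp(rhs, 0.25, 0.2, time_grid(h = 0.1, horizon = 2),
#'                     beta1 = 1)
#' head(traj)
#' @export
solve_crisp <- function(rhs, u0, v0, grid, beta1, beta2 = beta1,
                        method = c("modified", "fem"),
                        mode = c("corrected", "as_printed")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "time_grid"))
  check_order(beta1); check_order(beta2)
  n <- grid$steps
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  u[1] <- u0; v[1] <- v0
  step_fun <- if (method == "fem") {
    function(t, u, v) fem_step(rhs, t, u, v, grid$h, beta1, beta2)
  } else {
    function(t, u, v) modified_euler_step(rhs, t, u, v, grid$h, beta1, beta2,
                                          mode = mode)
  }
  for (j in seq_len(n)) {
    st <- tryCatch(step_fun(grid$times[j], u[j], v[j]),
                   error = function(e) {
                     stop("step failed at node ", j - 1L, " (t = ",
                          grid$times[j], "): ", conditionMessage(e),
                          call. = FALSE)
                   })
    u[j + 1L] <- st[["u"]]
    v[j + 1L] <- st[["v"]]
  }
  if (any(u < 0) || any(v < 0)) {
    first <- min(c(which(u < 0), which(v < 0)))
    warning(warningCondition(
      paste0("state became negative at node ", first - 1L, " (t = ",
             grid$times[first], "); populations are not clipped"),
      class = "ffde_negative_state"))
  }
  structure(data.frame(t = grid$times, u = u, v = v),
            class = c("crisp_trajectory", "data.frame"),
            rhs_label = rhs$label, method = method, mode = mode,
            beta1 = beta1, beta2 = beta2, h = grid$h)
}

#' @export
print.crisp_trajectory <- function(x, ...) {
  cat(sprintf("<crisp_trajectory> %s | %s%s | beta = (%g, %g) | h = %g | %d nodes\n",
              attr(x, "rhs_label"), attr(x, "method"),
              if (attr(x, "method") == "modified")
                paste0("/", attr(x, "mode")) else "",
              attr(x, "beta1"), attr(x, "beta2"), attr(x, "h"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more nodes\n")
  invisible(x)
}

#' Solve a system with fuzzy initial conditions by r-cut propagation
#'
#' For each membership grade `r` in `r_grid` independently, the fuzzy initial
#' conditions are reduced to their r-cut intervals and the interval endpoints
#' are advanced in time:
#'
#' * `coupling = "endpoint"` (default): the lower endpoints of `u` and `v`
#'   are advanced together as one crisp run, and the upper endpoints as
#'   another — lower-with-lower, upper-with-upper.  This is the classical
#'   parametric stepping scheme for fuzzy initial conditions, but because a
#'   predator-prey right-hand side is not monotone in its arguments it is not
#'   a guaranteed interval enclosure; violations of interval ordering are
#'   detected and reported (see [check_nesting()]), never silently repaired.
#' * `coupling = "extension"` (diagnostic): each step advances the interval
#'   by taking the min/max of the step map over the four corner combinations
#'   of (u lower/upper) x (v lower/upper) — a corner approximation of the
#'   Zadeh extension principle.
#'
#' @inheritParams solve_crisp
#' @param u0_fuzzy,v0_fuzzy Fuzzy numbers ([triangular_fuzzy()] or
#'   [exponential_fuzzy()]); they need not be the same shape.
#' @param r_grid Membership grades, each within the valid range of both
#'   fuzzy-number shapes used.
#' @param coupling `"endpoint"` or `"extension"`.
#' @return An object of class `"fuzzy_trajectory"`: a list with fields
#'   `times`, `r_grid`, and `(time x grade)` matrices `u_lower`, `u_upper`,
#'   `v_lower`, `v_upper`, plus solver settings.  Interval-ordering
#'   violations are counted in the `ordering_violations` field and flagged
#'   with a classed warning (`ffde_ordering_violation`).
#' @examples
#' p <- preset("lotka_volterra")
#' ft <- solve_fuzzy(p$rhs, p$u0$triangular, p$v0$triangular,
#'                   r_grid = c(0, 0.5, 1),
#'                   grid = time_grid(h = 0.1, horizon = 1), beta1 = 0.9)
#' ft
#' @export
solve_fuzzy <- function(rhs, u0_fuzzy, v0_fuzzy, r_grid, grid,
                        beta1, beta2 = beta1,
                        method = c("modified", "fem"),
                        mode = c("corrected", "as_printed"),
                        coupling = c("endpoint", "extension")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  coupling <- match.arg(coupling)
  stopifnot(inherits(u0_fuzzy, "fuzzy_number"),
            inherits(v0_fuzzy, "fuzzy_number"),
            inherits(grid, "time_grid"),
            is.numeric(r_grid), length(r_grid) >= 1L)
  check_order(beta1); check_order(beta2)

  nt <- grid$steps + 1L
  nr <- length(r_grid)
  u_lower <- u_upper <- v_lower <- v_upper <- matrix(NA_real_, nt, nr)

  step_fun <- if (method == "fem") {
    function(t, u, v) fem_step(rhs, t, u, v, grid$h, beta1, beta2)
  } else {
    function(t, u, v) modified_euler_step(rhs, t, u, v, grid$h, beta1, beta2,
                                          mode = mode)
  }

  for (i in seq_len(nr)) {
    r <- r_grid[i]
    cu <- rcut(u0_fuzzy, r)
    cv <- rcut(v0_fuzzy, r)
    if (coupling == "endpoint") {
      lo <- solve_crisp(rhs, cu$lower, cv$lower, grid, beta1, beta2,
                        method = method, mode = mode)
      hi <- solve_crisp(rhs, cu$upper, cv$upper, grid, beta1, beta2,
                        method = method, mode = mode)
      u_lower[, i] <- lo$u; v_lower[, i] <- lo$v
      u_upper[, i] <- hi$u; v_upper[, i] <- hi$v
    } else {
      ul <- cu$lower; uu <- cu$upper; vl <- cv$lower; vu <- cv$upper
      u_lower[1, i] <- ul; u_upper[1, i] <- uu
      v_lower[1, i] <- vl; v_upper[1, i] <- vu
      for (j in seq_len(grid$steps)) {
        tj <- grid$times[j]
        corners <- rbind(step_fun(tj, ul, vl), step_fun(tj, ul, vu),
                         step_fun(tj, uu, vl), step_fun(tj, uu, vu))
        ul <- min(corners[, "u"]); uu <- max(corners[, "u"])
        vl <- min(corners[, "v"]); vu <- max(corners[, "v"])
        u_lower[j + 1L, i] <- ul; u_upper[j + 1L, i] <- uu
        v_lower[j + 1L, i] <- vl; v_upper[j + 1L, i] <- vu
      }
    }
  }

  viol <- sum(u_lower > u_upper) + sum(v_lower > v_upper)
  if (viol > 0) {
    warning(warningCondition(
      paste0(viol, " interval-ordering violation(s) (lower > upper); ",
             "results are reported as computed, not repaired"),
      class = "ffde_ordering_violation"))
  }

  structure(list(times = grid$times, r_grid = r_grid,
                 u_lower = u_lower, u_upper = u_upper,
                 v_lower = v_lower, v_upper = v_upper,
                 rhs_label = rhs$label, method = method, mode = mode,
                 coupling = coupling, beta1 = beta1, beta2 = beta2,
                 h = grid$h, ordering_violations = viol),
            class = "fuzzy_trajectory")
}

#' @export
print.fuzzy_trajectory <- function(x, ...) {
  cat(sprintf("<fuzzy_trajectory> %s | %s/%s | coupling = %s\n",
              x$rhs_label, x$method, x$mode, x$coupling))
  cat(sprintf("  beta = (%g, %g), h = %g, %d nodes x %d grades (r: %s)\n",
              x$beta1, x$beta2, x$h, length(x$times), length(x$r_grid),
              paste(format(x$r_grid, trim = TRUE), collapse = ", ")))
  if (x$ordering_violations > 0) {
    cat("  ", x$ordering_violations, "interval-ordering violation(s)\n")
  }
  invisible(x)
}

#' @export
summary.fuzzy_trajectory <- function(object, ...) {
  tn <- length(object$times)
  cat(sprintf("Fuzzy trajectory of '%s' over t in [%g, %g]\n",
              object$rhs_label, object$times[1], object$times[tn]))
  cat(sprintf("  method %s (%s), coupling %s, beta = (%g, %g)\n",
              object$method, object$mode, object$coupling,
              object$beta1, object$beta2))
  wid_u <- object$u_upper - object$u_lower
  wid_v <- object$v_upper - object$v_lower
  cat(sprintf("  terminal u envelope width: %s\n",
              paste(format(wid_u[tn, ], digits = 4), collapse = ", ")))
  cat(sprintf("  terminal v envelope width: %s\n",
              paste(format(wid_v[tn, ], digits = 4), collapse = ", ")))
  nest <- check_nesting(object)
  print(nest)
  invisible(object)
}

#' Long-format view of a fuzzy trajectory
#'
#' @param x A `fuzzy_trajectory`.
#' @param ... Unused.
#' @return A data frame with columns `t`, `r`, `u_lower`, `u_upper`,
#'   `v_lower`, `v_upper`, ordered by grade then time.
#' @export
as.data.frame.fuzzy_trajectory <- function(x, ...) {
  nt <- length(x$times); nr <- length(x$r_grid)
  data.frame(t = rep(x$times, nr),
             r = rep(x$r_grid, each = nt),
             u_lower = as.vector(x$u_lower),
             u_upper = as.vector(x$u_upper),
             v_lower = as.vector(x$v_lower),
             v_upper = as.vector(x$v_upper))
}

#' Interval-ordering and cross-grade nesting diagnostics
#'
#' Verifies, per time node, that each interval satisfies lower <= upper, and
#' that cuts at higher grades are nested inside cuts at lower grades
#' (fuzzy-number cuts are nested at `t0`; the endpoint-coupled stepping does
#' not guarantee that this survives propagation, which is exactly what this
#' report measures).
#'
#' @param traj A [solve_fuzzy()] result.
#' @param tol Absolute slack for the comparisons.
#' @return A list of class `"nesting_report"`: counts of ordering and nesting
#'   violations, total comparisons, and the (time index, grade index)
#'   location of the first violation of each kind (`NULL` when none).
#' @export
check_nesting <- function(traj, tol = 0) {
  stopifnot(inherits(traj, "fuzzy_trajectory"))
  ord_bad_u <- traj$u_lower > traj$u_upper + tol
  ord_bad_v <- traj$v_lower > traj$v_upper + tol
  ordering_violations <- sum(ord_bad_u) + sum(ord_bad_v)
  first_ordering <- NULL
  if (ordering_violations > 0) {
    idx <- which(ord_bad_u | ord_bad_v, arr.ind = TRUE)[1, ]
    first_ordering <- c(time_index = unname(idx[1]),
                        grade_index = unname(idx[2]))
  }

  nesting_violations <- 0L
  nesting_checks <- 0L
  first_nesting <- NULL
  ord <- order(traj$r_grid)
  if (length(ord) >= 2L) {
    for (a in seq_len(length(ord) - 1L)) {
      i <- ord[a]; j <- ord[a + 1L]   # r_i < r_j: cut(r_j) must sit inside cut(r_i)
      bad <- (traj$u_lower[, j] < traj$u_lower[, i] - tol) |
             (traj$u_upper[, j] > traj$u_upper[, i] + tol) |
             (traj$v_lower[, j] < traj$v_lower[, i] - tol) |
             (traj$v_upper[, j] > traj$v_upper[, i] + tol)
      nesting_checks <- nesting_checks + length(bad)
      nesting_violations <- nesting_violations + sum(bad)
      if (is.null(first_nesting) && any(bad)) {
        first_nesting <- c(time_index = which(bad)[1], grade_index = j)
      }
    }
  }
  structure(list(ordering_violations = ordering_violations,
                 first_ordering = first_ordering,
                 nesting_violations = nesting_violations,
                 nesting_checks = nesting_checks,
                 first_nesting = first_nesting,
                 n_grades = length(traj$r_grid),
                 n_times = length(traj$times)),
            class = "nesting_report")
}

#' @export
print.nesting_report <- function(x, ...) {
  cat(sprintf("Nesting report: %d grade(s) x %d node(s)\n",
              x$n_grades, x$n_times))
  cat(sprintf("  interval ordering violations: %d\n", x$ordering_violations))
  if (!is.null(x$first_ordering)) {
    cat(sprintf("    first at time index %d, grade index %d\n",
                x$first_ordering[["time_index"]],
                x$first_ordering[["grade_index"]]))
  }
  if (x$n_grades >= 2L) {
    cat(sprintf("  cross-grade nesting violations: %d of %d checks\n",
                x$nesting_violations, x$nesting_checks))
    if (!is.null(x$first_nesting)) {
      cat(sprintf("    first at time index %d, grade index %d\n",
                  x$first_nesting[["time_index"]],
                  x$first_nesting[["grade_index"]]))
    }
  } else {
    cat("  (single grade: ordering check only)\n")
  }
  invisible(x)
}
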