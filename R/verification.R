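#' Analytic benchmark problems
#'
#' Fixture problems with exact or high-accuracy reference solutions, used to
#' verify the steppers:
#' * `"constant_rhs"`: \eqn{{}^C D^\beta u = c}, exact solution
#'   \eqn{u_0 + c\,t^\beta/\Gamma(\beta+1)} — the one problem the memoryless
#'   schemes solve exactly at the first node for every order;
#' * `"linear_decay_beta1"`: \eqn{u' = -u}, exact \eqn{u_0 e^{-t}};
#' * `"lv_beta1"`: the Lotka-Volterra preset at \eqn{\beta = 1} from crisp
#'   cores (0.25, 0.2); the reference is a fine-grid corrected modified-Euler
#'   run (`h_ref`), adequate for order estimation;
#' * `"caputo_linear"`: \eqn{{}^C D^\beta u = -u}, reference
#'   \eqn{u_0 E_\beta(-t^\beta)} via the Mittag-Leffler series — first-step
#'   diagnostics only, since the one-step schemes do not track the history
#'   integral.
#'
#' @param name Benchmark name.
#' @param c Constant right-hand side value (for `"constant_rhs"`).
#' @param beta Fractional order (for `"constant_rhs"` and `"caputo_linear"`).
#' @param u0,v0 Initial state (the second component is inert except for
#'   `"lv_beta1"`).
#' @param h_ref Reference-grid step for `"lv_beta1"`.
#' @return A list of class `"benchmark_problem"` with fields `name`, `rhs`,
#'   `beta`, `u0`, `v0`, and `reference(t)` returning the exact/reference
#'   value of `u` at `t`.
#' @examples
#' bp <- make_benchmark("linear_decay_beta1")
#' bp$reference(1)  # exp(-1)
#' @export
make_benchmark <- function(name = c("constant_rhs", "linear_decay_beta1",
                                    "lv_beta1", "caputo_linear"),
                           c = 1, beta = 1, u0 = 1, v0 = 0, h_ref = 1e-4) {
  name <- match.arg(name)
  force(c); force(beta); force(u0); force(v0)
  out <- switch(
    name,
    constant_rhs = {
      check_order(beta)
      list(rhs = system_rhs(function(t, u, v) c, function(t, u, v) 0,
                            label = sprintf("constant_rhs(c=%g)", c)),
           beta = beta, u0 = u0, v0 = v0,
           reference = function(t) u0 + c * t^beta / gamma(beta + 1))
    },
    linear_decay_beta1 = list(
      rhs = system_rhs(function(t, u, v) -u, function(t, u, v) 0,
                       label = "linear_decay"),
      beta = 1, u0 = u0, v0 = v0,
      reference = function(t) u0 * exp(-t)),
    lv_beta1 = {
      rhs <- make_lv_rhs(5, 1, 2)
      u0 <- 0.25; v0 <- 0.2
      list(rhs = rhs, beta = 1, u0 = u0, v0 = v0,
           reference = function(t) {
             if (t == 0) return(u0)
             tr <- solve_crisp(rhs, u0, v0,
                               time_grid(h = t / ceiling(t / h_ref),
                                         horizon = t),
                               beta1 = 1, method = "modified",
                               mode = "corrected")
             tr$u[nrow(tr)]
           })
    },
    caputo_linear = {
      check_order(beta)
      list(rhs = system_rhs(function(t, u, v) -u, function(t, u, v) 0,
                            label = sprintf("caputo_linear(beta=%g)", beta)),
           beta = beta, u0 = u0, v0 = v0,
           reference = function(t) u0 * mittag_leffler(-t^beta, beta))
    })
  out$name <- name  # (base::c is shadowed by the argument `c` here)
  structure(out, class = "benchmark_problem")
}

#' @export
print.benchmark_problem <- function(x, ...) {
  cat(sprintf("<benchmark_problem> %s (beta = %g, u0 = %g)\n",
              x$name, x$beta, x$u0))
  invisible(x)
}

#' Empirical convergence order of a stepper
#'
#' Runs the chosen scheme over a ladder of step sizes on a benchmark problem,
#' records the terminal absolute error of `u` against the benchmark's
#' reference, and fits the log-log slope by least squares.  Order claims are
#' meaningful only for \eqn{\beta = 1} problems: for \eqn{\beta < 1} the
#' memoryless one-step schemes do not converge to the exact Caputo solution
#' as \eqn{h \to 0}, so requesting an order estimate there is rejected.
#'
#' @param method `"fem"` or `"modified"`.
#' @param mode Predictor convention (for `"modified"`).
#' @param problem A [make_benchmark()] problem with `beta = 1`.
#' @param h_list At least three step sizes, each dividing `horizon`.
#' @param horizon Final time at which the error is measured.
#' @return A list of class `"convergence_report"`: a table of `h` and
#'   terminal errors, the fitted `slope`, and the run identifiers.
#' @examples
#' rep <- convergence_order("fem", problem = make_benchmark("linear_decay_beta1"),
#'                          h_list = c(0.1, 0.05, 0.025), horizon = 1)
#' rep$slope  # about 1
#' @export
convergence_order <- function(method = c("fem", "modified"),
                              mode = c("corrected", "as_printed"),
                              problem, h_list, horizon = 1) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(inherits(problem, "benchmark_problem"))
  if (problem$beta != 1) {
    stop("convergence-order estimation requires a beta = 1 benchmark: the ",
         "one-step schemes are not globally consistent for beta < 1",
         call. = FALSE)
  }
  if (length(h_list) < 3L) {
    stop("need at least 3 step sizes", call. = FALSE)
  }
  ref <- problem$reference(horizon)
  errors <- vapply(h_list, function(h) {
    tr <- solve_crisp(problem$rhs, problem$u0, problem$v0,
                      time_grid(h = h, horizon = horizon),
                      beta1 = 1, method = method, mode = mode)
    abs(tr$u[nrow(tr)] - ref)
  }, numeric(1))
  if (any(errors <= 0)) {
    stop("zero terminal error: cannot fit a log-log slope", call. = FALSE)
  }
  fit <- stats::lm(log(errors) ~ log(h_list))
  structure(list(method = method, mode = mode, problem = problem$name,
                 horizon = horizon,
                 table = data.frame(h = h_list, error = errors),
                 slope = unname(stats::coef(fit)[2])),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence report: %s%s on %s, T = %g\n", x$method,
              if (x$method == "modified") paste0("/", x$mode) else "",
              x$problem, x$horizon))
  print(x$table, row.names = FALSE)
  cat(sprintf("  fitted log-log slope: %.4f\n", x$slope))
  invisible(x)
}

#' Side-by-side FEM vs modified-Euler comparison at one grade
#'
#' Runs both steppers on identical inputs (a model preset with its fuzzy
#' initial conditions, or a crisp benchmark problem) and tabulates the four
#' envelope branches per node for each method together with their pairwise
#' differences (modified minus FEM) — the tabular analogue of a
#' time-series method-comparison figure.
#'
#' @param x A preset name (see [preset()]) or a [make_benchmark()] problem.
#' @param r Membership grade for the fuzzy envelope (presets only).
#' @param beta1,beta2 Fractional orders.
#' @param h Step size.
#' @param horizon Final time.
#' @param shape `"triangular"` or `"exponential"` initial conditions
#'   (presets only).
#' @param mode Predictor convention for the modified scheme.
#' @return A list of class `"method_comparison"` with the long table
#'   (`$table`) holding columns `t`, per-branch values suffixed `_fem` and
#'   `_mod`, and difference columns suffixed `_diff`.
#' @examples
#' cmp <- compare_methods("fppm_case1", r = 0.9, beta1 = 0.9, h = 0.1,
#'                        horizon = 1)
#' head(cmp$table)
#' @export
compare_methods <- function(x, r = 0.9, beta1 = 0.9, beta2 = beta1,
                            h = 0.1, horizon = 5,
                            shape = c("triangular", "exponential"),
                            mode = c("corrected", "as_printed")) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  grid <- time_grid(h = h, horizon = horizon)
  branches <- c("u_lower", "u_upper", "v_lower", "v_upper")

  if (inherits(x, "benchmark_problem")) {
    run1 <- function(method) {
      tr <- solve_crisp(x$rhs, x$u0, x$v0, grid, beta1, beta2,
                        method = method, mode = mode)
      data.frame(u_lower = tr$u, u_upper = tr$u,
                 v_lower = tr$v, v_upper = tr$v)
    }
    label <- x$name
  } else {
    p <- preset(x)
    run1 <- function(method) {
      ft <- solve_fuzzy(p$rhs, p$u0[[shape]], p$v0[[shape]], r_grid = r,
                        grid = grid, beta1 = beta1, beta2 = beta2,
                        method = method, mode = mode)
      data.frame(u_lower = ft$u_lower[, 1], u_upper = ft$u_upper[, 1],
                 v_lower = ft$v_lower[, 1], v_upper = ft$v_upper[, 1])
    }
    label <- p$name
  }

  fem <- run1("fem")
  mod <- run1("modified")
  tab <- data.frame(t = grid$times)
  for (b in branches) {
    tab[[paste0(b, "_fem")]] <- fem[[b]]
    tab[[paste0(b, "_mod")]] <- mod[[b]]
    tab[[paste0(b, "_diff")]] <- mod[[b]] - fem[[b]]
  }
  structure(list(label = label, r = r, beta1 = beta1, beta2 = beta2,
                 h = h, horizon = horizon, mode = mode, table = tab),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison (FEM vs modified/%s): %s, r = %g, beta = (%g, %g), h = %g\n",
              x$mode, x$label, x$r, x$beta1, x$beta2, x$h))
  cat(sprintf("  max |modified - FEM| per branch over [0, %g]:\n", x$horizon))
  for (b in c("u_lower", "u_upper", "v_lower", "v_upper")) {
    cat(sprintf("    %s: %.6g\n", b, max(abs(x$table[[paste0(b, "_diff")]]))))
  }
  invisible(x)
}
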