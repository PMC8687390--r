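#' Time-varying-coefficient predator-prey right-hand side
#'
#' Builds the coupled system
#' \deqn{f_1 = w(t)\,u - x(t)\,u v, \qquad f_2 = y(t)\,u v - z(t)\,v}
#' for one of the two printed coefficient cases:
#' * Case 1: \eqn{w(t) = t,\; x(t) = 1,\; y(t) = 1,\; z(t) = t}
#'   (time-growing prey birth and predator death rates);
#' * Case 2: \eqn{w(t) = 1,\; x(t) = t,\; y(t) = t,\; z(t) = 1}
#'   (time-growing interaction rates).
#'
#' @param case `1` or `2`.
#' @return A [system_rhs()].
#' @examples
#' rhs <- make_case_rhs(1)
#' rhs$f1(1, 1.3, 0.6)  # 1*1.3 - 1.3*0.6 = 0.52
#' @export
make_case_rhs <- function(case) {
  if (!(length(case) == 1L && case %in% c(1, 2))) {
    stop("case must be 1 or 2", call. = FALSE)
  }
  co <- if (case == 1) {
    list(w = function(t) t, x = function(t) 1,
         y = function(t) 1, z = function(t) t)
  } else {
    list(w = function(t) 1, x = function(t) t,
         y = function(t) t, z = function(t) 1)
  }
  fppm_rhs(co$w, co$x, co$y, co$z, label = paste0("fppm_case", case))
}

#' General coefficient-function predator-prey right-hand side
#'
#' The family \eqn{f_1 = w(t) u - x(t) u v}, \eqn{f_2 = y(t) u v - z(t) v}
#' with arbitrary coefficient callables; [make_case_rhs()] provides the two
#' named presets.
#'
#' @param w,x,y,z Functions of `t`: prey birth, predation, conversion and
#'   predator death coefficients.
#' @param label Text label.
#' @return A [system_rhs()].
#' @export
fppm_rhs <- function(w, x, y, z, label = "fppm_custom") {
  stopifnot(is.function(w), is.function(x), is.function(y), is.function(z))
  system_rhs(
    f1 = function(t, u, v) w(t) * u - x(t) * u * v,
    f2 = function(t, u, v) y(t) * u * v - z(t) * v,
    label = label)
}

#' Non-dimensionalised Lotka-Volterra right-hand side
#'
#' The three-parameter reduced system
#' \deqn{f_1 = u\,(l - k u - v), \qquad f_2 = v\,(-1 + \alpha u),}
#' prey growth rate `l`, intra-specific competition `k` and predation
#' efficiency `alpha` (all positive, dimensionless).  Its interior
#' equilibrium is \eqn{u^* = 1/\alpha}, \eqn{v^* = l - k/\alpha}.
#'
#' @param l,k,alpha Positive reals.
#' @return A [system_rhs()] with the parameters attached in
#'   `$params`.
#' @examples
#' rhs <- make_lv_rhs(5, 1, 2)
#' rhs$f1(0, 0.25, 0.2)  # 1.1375
#' @export
make_lv_rhs <- function(l, k, alpha) {
  stopifnot(is.numeric(l), is.numeric(k), is.numeric(alpha),
            length(l) == 1L, length(k) == 1L, length(alpha) == 1L)
  if (l <= 0 || k <= 0 || alpha <= 0) {
    stop("Lotka-Volterra parameters l, k, alpha must be positive",
         call. = FALSE)
  }
  out <- system_rhs(
    f1 = function(t, u, v) u * (l - k * u - v),
    f2 = function(t, u, v) v * (-1 + alpha * u),
    label = sprintf("lotka_volterra(l=%g,k=%g,alpha=%g)", l, k, alpha))
  out$params <- list(l = l, k = k, alpha = alpha)
  out
}

#' Non-dimensionalisation of the five-parameter Lotka-Volterra model
#'
#' Reduces the dimensional system
#' \deqn{P' = P\,(a - b P - c Q), \qquad Q' = Q\,(-\rho + c e P)}
#' (prey birth rate `a`, prey competition `b`, predation `c`, conversion
#' efficiency `e`, predator death rate `rho`) to the three-parameter form of
#' [make_lv_rhs()] via the scalings
#' \eqn{u = (e a/\rho) P}, \eqn{v = (c/\rho) Q}, \eqn{t = \rho T}, giving
#' \eqn{l = a/\rho}, \eqn{k = b/(a e)}, \eqn{\alpha = c/a}.
#'
#' @param a,b,c,e,rho Positive reals.
#' @return A list with the reduced parameters `l`, `k`, `alpha` and the
#'   scale factors `u_scale` (= e a / rho), `v_scale` (= c / rho),
#'   `t_scale` (= rho), such that `u = u_scale * P`, `v = v_scale * Q`,
#'   `t = t_scale * T`.
#' @examples
#' nondimensionalize(a = 5, b = 5, c = 10, e = 1, rho = 1)  # l=5, k=1, alpha=2
#' @export
nondimensionalize <- function(a, b, c, e, rho) {
  vals <- c(a = a, b = b, c = c, e = e, rho = rho)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all parameters a, b, c, e, rho must be positive", call. = FALSE)
  }
  list(l = a / rho, k = b / (a * e), alpha = c / a,
       u_scale = e * a / rho, v_scale = c / rho, t_scale = rho)
}

#' Model presets with their printed fuzzy initial conditions
#'
#' Bundles each study system with its fuzzy initial conditions and default
#' fractional orders:
#' * `"fppm_case1"`, `"fppm_case2"`: the time-varying-coefficient model with
#'   triangular u(0) = (1.2, 1.3, 1.4), v(0) = (0.5, 0.6, 0.7) and
#'   exponential variants on the same triples;
#' * `"lotka_volterra"`: the reduced system with (l, k, alpha) = (5, 1, 2),
#'   triangular u(0) = (0.15, 0.25, 0.35), v(0) = (0.1, 0.2, 0.3) and
#'   exponential variants on the same triples.
#'
#' @param name Preset name.
#' @return A list with fields `name`, `rhs`, `u0` and `v0` (each a list with
#'   `triangular` and `exponential` members), and `beta` (default fractional
#'   order 9/10 for both components).
#' @examples
#' p <- preset("lotka_volterra")
#' rcut(p$u0$triangular, 0.9)
#' @export
preset <- function(name = c("fppm_case1", "fppm_case2", "lotka_volterra")) {
  name <- match.arg(name)
  if (name == "lotka_volterra") {
    rhs <- make_lv_rhs(5, 1, 2)
    u_pts <- c(0.15, 0.25, 0.35)
    v_pts <- c(0.1, 0.2, 0.3)
  } else {
    rhs <- make_case_rhs(if (name == "fppm_case1") 1 else 2)
    u_pts <- c(1.2, 1.3, 1.4)
    v_pts <- c(0.5, 0.6, 0.7)
  }
  list(name = name, rhs = rhs,
       u0 = list(triangular = triangular_fuzzy(u_pts[1], u_pts[2], u_pts[3]),
                 exponential = exponential_fuzzy(u_pts[1], u_pts[2], u_pts[3])),
       v0 = list(triangular = triangular_fuzzy(v_pts[1], v_pts[2], v_pts[3]),
                 exponential = exponential_fuzzy(v_pts[1], v_pts[2], v_pts[3])),
       beta = c(beta1 = 0.9, beta2 = 0.9))
}

#' @rdname preset
#' @return `preset_names()`: character vector of available preset names.
#' @export
preset_names <- function() c("fppm_case1", "fppm_case2", "lotka_volterra")
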