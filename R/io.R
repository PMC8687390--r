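#' Build and validate a run configuration
#'
#' Normalises a flat list of run settings into a validated configuration.
#' Either `preset` names a built-in model (see [preset_names()]) or a custom
#' model is given via `model`: a list with `family = "lotka_volterra"` and
#' `l`, `k`, `alpha`, or `family = "fppm"` with coefficient choices `w`, `x`,
#' `y`, `z`, each either a constant number or the string `"t"` for the
#' identity coefficient function.
#'
#' Fuzzy initial conditions are given as `u0`/`v0` lists
#' `{shape: triangular|exponential, points: [m, n, o]}`; when a preset is
#' used they default to its printed initial conditions with the chosen
#' `shape`.  The default r-grid is `0, 0.1, ..., 1` for triangular shapes
#' and `0.05, 0.1, ..., 1` for exponential ones (the exponential cut needs
#' `r > 0`).  A `seed` field is accepted and echoed into the manifest for
#' provenance; the solvers are fully deterministic and never draw random
#' numbers.
#'
#' @param x A named list (e.g. from [read_config()]), or nothing to start
#'   from defaults.
#' @return A validated list of class `"run_config"`.
#' @examples
#' cfg <- run_config(list(preset = "fppm_case1", beta1 = 0.9, horizon = 1,
#'                        r_grid = 0.9))
#' @export
run_config <- function(x = list()) {
  stopifnot(is.list(x))
  bad <- setdiff(names(x),
                 c("preset", "model", "u0", "v0", "shape", "beta1", "beta2",
                   "h", "steps", "horizon", "r_grid", "method", "mode",
                   "coupling", "out_prefix", "seed"))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(
    preset = x[["preset"]], model = x[["model"]], u0 = x[["u0"]], v0 = x[["v0"]],
    shape = if (is.null(x[["shape"]])) "triangular" else x[["shape"]],
    beta1 = if (is.null(x[["beta1"]])) 0.9 else as.numeric(x[["beta1"]]),
    beta2 = if (is.null(x[["beta2"]])) NULL else as.numeric(x[["beta2"]]),
    h = if (is.null(x[["h"]])) 0.1 else as.numeric(x[["h"]]),
    steps = x[["steps"]], horizon = x[["horizon"]],
    r_grid = x[["r_grid"]], method = if (is.null(x[["method"]])) "modified" else x[["method"]],
    mode = if (is.null(x[["mode"]])) "corrected" else x[["mode"]],
    coupling = if (is.null(x[["coupling"]])) "endpoint" else x[["coupling"]],
    out_prefix = if (is.null(x[["out_prefix"]])) "ffde_run" else x[["out_prefix"]],
    seed = x[["seed"]])
  if (is.null(cfg$beta2)) cfg$beta2 <- cfg$beta1
  cfg$shape <- match.arg(cfg$shape, c("triangular", "exponential"))
  cfg$method <- match.arg(cfg$method, c("modified", "fem"))
  cfg$mode <- match.arg(cfg$mode, c("corrected", "as_printed"))
  cfg$coupling <- match.arg(cfg$coupling, c("endpoint", "extension"))
  check_order(cfg$beta1); check_order(cfg$beta2)

  if (is.null(cfg$preset) == is.null(cfg$model)) {
    stop("config must give exactly one of `preset` and `model`",
         call. = FALSE)
  }
  if (!is.null(cfg$preset)) {
    cfg$preset <- match.arg(cfg$preset, preset_names())
  }
  if (!is.null(cfg$steps) && !is.null(cfg$horizon)) {
    stop("config field error at steps/horizon: give exactly one",
         call. = FALSE)
  }
  if (is.null(cfg$steps) && is.null(cfg$horizon)) cfg$horizon <- 5
  if (is.null(cfg$r_grid)) {
    cfg$r_grid <- if (cfg$shape == "exponential") seq(0.05, 1, by = 0.05)
                  else seq(0, 1, by = 0.1)
  }
  cfg$r_grid <- as.numeric(cfg$r_grid)
  if (cfg$shape == "exponential" && any(cfg$r_grid <= 0)) {
    stop("config field error at r_grid: exponential shape requires r > 0",
         call. = FALSE)
  }
  if (any(cfg$r_grid < 0 | cfg$r_grid > 1)) {
    stop("config field error at r_grid: grades must lie in [0, 1]",
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a flat YAML file of [run_config()] fields.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

fuzzy_from_spec <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$shape), !is.null(spec$points),
            length(spec$points) == 3L)
  pts <- as.numeric(spec$points)
  switch(match.arg(spec$shape, c("triangular", "exponential")),
         triangular = triangular_fuzzy(pts[1], pts[2], pts[3]),
         exponential = exponential_fuzzy(pts[1], pts[2], pts[3]))
}

rhs_from_config <- function(cfg) {
  if (!is.null(cfg$preset)) return(preset(cfg$preset)$rhs)
  m <- cfg$model
  fam <- match.arg(m$family, c("lotka_volterra", "fppm"))
  if (fam == "lotka_volterra") {
    make_lv_rhs(m$l, m$k, m$alpha)
  } else {
    coef_fun <- function(v) {
      if (identical(v, "t")) function(t) t
      else { v <- as.numeric(v); function(t) v }
    }
    fppm_rhs(coef_fun(m$w), coef_fun(m$x), coef_fun(m$y), coef_fun(m$z))
  }
}

#' Execute a configured run
#'
#' Resolves the model and fuzzy initial conditions from a [run_config()],
#' solves with [solve_fuzzy()] (or [solve_crisp()] when both initial
#' conditions are zero-width), and writes two files under `out_dir`: a
#' trajectory table `<out_prefix>_trajectory.tsv` (see
#' [write_trajectory()]) and a JSON manifest `<out_prefix>_manifest.json`
#' echoing every parameter, the package version and a timestamp.  The
#' manifest alone suffices to re-execute the run and reproduce the table
#' bit-exactly, since the solvers are deterministic.
#'
#' @param config A `run_config` (or plain list coerced through
#'   [run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the `fuzzy_trajectory` and the two paths.
#' @export
run <- function(config, out_dir = ".") {
  if (!inherits(config, "run_config")) config <- run_config(config)
  rhs <- rhs_from_config(config)
  if (!is.null(config$preset)) {
    p <- preset(config$preset)
    u0 <- if (is.null(config$u0)) p$u0[[config$shape]]
          else fuzzy_from_spec(config$u0)
    v0 <- if (is.null(config$v0)) p$v0[[config$shape]]
          else fuzzy_from_spec(config$v0)
  } else {
    if (is.null(config$u0) || is.null(config$v0)) {
      stop("custom model config requires u0 and v0 fuzzy specs",
           call. = FALSE)
    }
    u0 <- fuzzy_from_spec(config$u0)
    v0 <- fuzzy_from_spec(config$v0)
  }
  grid <- time_grid(h = config$h, steps = config$steps,
                    horizon = config$horizon)
  ft <- solve_fuzzy(rhs, u0, v0, r_grid = config$r_grid, grid = grid,
                    beta1 = config$beta1, beta2 = config$beta2,
                    method = config$method, mode = config$mode,
                    coupling = config$coupling)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  traj_path <- file.path(out_dir, paste0(config$out_prefix,
                                         "_trajectory.tsv"))
  manifest_path <- file.path(out_dir, paste0(config$out_prefix,
                                             "_manifest.json"))
  write_trajectory(ft, traj_path)
  manifest <- unclass(config)
  manifest$package_version <- as.character(utils::packageVersion("ffde"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$ordering_violations <- ft$ordering_violations
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(trajectory = ft, trajectory_path = traj_path,
                 manifest_path = manifest_path))
}

#' Write / read a trajectory table
#'
#' Serialises a trajectory to tab-separated text with a header row and a
#' fixed column order (`t`, `r`, `u_lower`, `u_upper`, `v_lower`,
#' `v_upper`), every value printed with 17 significant digits so that the
#' round trip through text is bit-exact for doubles.
#'
#' @param x A `fuzzy_trajectory`, `crisp_trajectory`, or a data frame in
#'   the long layout.
#' @param path Output file path.
#' @return `write_trajectory()`: `path`, invisibly.  `read_trajectory()`:
#'   a data frame with the six columns above.
#' @export
write_trajectory <- function(x, path) {
  df <- if (inherits(x, "fuzzy_trajectory")) {
    as.data.frame(x)
  } else if (inherits(x, "crisp_trajectory")) {
    data.frame(t = x$t, r = 1, u_lower = x$u, u_upper = x$u,
               v_lower = x$v, v_upper = x$v)
  } else {
    as.data.frame(x)
  }
  need <- c("t", "r", "u_lower", "u_upper", "v_lower", "v_upper")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trajectory table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  lines <- c(paste(need, collapse = "\t"),
             do.call(sprintf,
                     c(list(fmt = paste(rep("%.17g", 6), collapse = "\t")),
                       df)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.delim(path, colClasses = "numeric")
}

#' Plot a fuzzy trajectory
#'
#' Base-graphics views of a [solve_fuzzy()] result:
#' * `kind = "envelope"`: time-series bands `[lower, upper]` for each state
#'   and grade (darker bands at higher membership grades);
#' * `kind = "phase"`: prey-vs-predator curves, lower- and upper-branch per
#'   grade.
#'
#' @param x A `fuzzy_trajectory`.
#' @param kind `"envelope"` or `"phase"`.
#' @param ... Passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.fuzzy_trajectory <- function(x, kind = c("envelope", "phase"), ...) {
  kind <- match.arg(kind)
  nr <- length(x[["r_grid"]])
  if (kind == "envelope") {
    old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    for (comp in c("u", "v")) {
      lo <- x[[paste0(comp, "_lower")]]
      hi <- x[[paste0(comp, "_upper")]]
      graphics::matplot(x$times, cbind(lo, hi), type = "n",
                        xlab = "t", ylab = comp,
                        main = sprintf("%s envelope (%s)", comp,
                                       x$rhs_label), ...)
      shade <- grDevices::gray(seq(0.85, 0.4, length.out = nr))
      for (i in order(x[["r_grid"]])) {
        graphics::polygon(c(x$times, rev(x$times)),
                          c(lo[, i], rev(hi[, i])),
                          col = grDevices::adjustcolor(shade[i], 0.5),
                          border = NA)
      }
      core <- which.max(x[["r_grid"]])
      graphics::lines(x$times, lo[, core], lwd = 2)
      graphics::lines(x$times, hi[, core], lwd = 2, lty = 2)
    }
  } else {
    graphics::matplot(cbind(x$u_lower, x$u_upper),
                      cbind(x$v_lower, x$v_upper),
                      type = "l", lty = rep(c(1, 2), each = nr),
                      col = rep(seq_len(nr), 2),
                      xlab = "prey u", ylab = "predator v",
                      main = sprintf("phase portrait (%s)", x$rhs_label),
                      ...)
  }
  invisible(x)
}

#' @export
plot.crisp_trajectory <- function(x, kind = c("series", "phase"), ...) {
  kind <- match.arg(kind)
  if (kind == "series") {
    graphics::matplot(x$t, cbind(x$u, x$v), type = "l", lty = 1:2,
                      xlab = "t", ylab = "state",
                      main = attr(x, "rhs_label"), ...)
    graphics::legend("topright", legend = c("u", "v"), lty = 1:2,
                     col = 1:2, bty = "n")
  } else {
    graphics::plot(x$u, x$v, type = "l", xlab = "prey u",
                   ylab = "predator v", main = attr(x, "rhs_label"), ...)
  }
  invisible(x)
}

#' Plot a method comparison
#'
#' Overlays the FEM and modified-Euler envelope branches from
#' [compare_methods()]: solid lines for the modified scheme, dashed for FEM,
#' one colour per branch.
#'
#' @param x A `method_comparison`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.method_comparison <- function(x, ...) {
  branches <- c("u_lower", "u_upper", "v_lower", "v_upper")
  mod <- as.matrix(x$table[paste0(branches, "_mod")])
  fem <- as.matrix(x$table[paste0(branches, "_fem")])
  graphics::matplot(x$table$t, cbind(mod, fem), type = "l",
                    lty = rep(c(1, 2), each = 4), col = rep(1:4, 2),
                    xlab = "t", ylab = "state",
                    main = sprintf("%s: modified (solid) vs FEM (dashed), r = %g",
                                   x$label, x$r), ...)
  graphics::legend("topleft", legend = branches, col = 1:4, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
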