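#' Built-in simulation scenarios
#'
#' The four canonical parameter regimes, each a baseline parameter set
#' with tip rates overridden, all starting from the 10 um characteristic
#' length:
#' \describe{
#'   \item{`disassembly`}{baseline rates (`beta_plus = 0.05`,
#'     `beta_minus = 0.0006`, `gamma = 0.01`): rapid shrinkage driven by
#'     the plus end, slow sustained growth at the minus end.}
#'   \item{`treadmilling`}{`beta_plus = 0.0116`: length held at ~10 um
#'     while both tips translate; run for 600 s to show the state is
#'     sustained.}
#'   \item{`fixed-ends`}{`beta_plus = 0.011`, `beta_minus = 0.00117`:
#'     both tip speeds vanish — the constrained fixed-end equilibrium.}
#'   \item{`patronin-rnai`}{`beta_plus = 0.0116`, `gamma_minus = 0.05`:
#'     knockdown of the minus-end protector modeled as amplified
#'     motor-driven minus-end depolymerization.}
#' }
#'
#' @param name Scenario name (see above).
#' @param k_off_minus Passed to [default_params()].
#' @return An [scenario_config()] object.
#' @export
#' @examples
#' builtin_scenario("treadmilling")$params$tips$beta_plus  # 0.0116
builtin_scenario <- function(name = c("disassembly", "treadmilling",
                                      "fixed-ends", "patronin-rnai"),
                             k_off_minus = 1.2) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("disassembly", "treadmilling", "fixed-ends", "patronin-rnai"))
    stop("invalid-scenario: unknown scenario name '", paste(name, collapse = ","),
         "'", call. = FALSE)
  params <- default_params(k_off_minus = k_off_minus)
  t_end <- 300
  if (name == "treadmilling") {
    params$tips$beta_plus <- 0.0116
    t_end <- 600
  } else if (name == "fixed-ends") {
    params$tips$beta_plus <- 0.011
    params$tips$beta_minus <- 0.00117
  } else if (name == "patronin-rnai") {
    params$tips$beta_plus <- 0.0116
    params$tips$gamma_minus <- 0.05
  }
  scenario_config(params, L0 = 10, t_end = t_end, name = name)
}

#' Classify a trajectory into a qualitative regime
#'
#' Labels a simulated trajectory by its late-time behavior, using
#' diagnostics averaged over the trailing `window_frac` of the run:
#' \itemize{
#'   \item `disassembly` — the run terminated at the disassembly cutoff
#'     (or the final length is at/below it);
#'   \item `treadmilling` — length change below `length_tol` while at
#'     least one tip still moves at `tip_tol` or faster;
#'   \item `fixed-ends` — both tip speeds below `tip_tol`;
#'   \item `growing` — mean `dL/dt` at or above `length_tol`;
#'   \item `indeterminate` — anything else (e.g. still shrinking toward
#'     an equilibrium when the horizon ends).
#' }
#'
#' @param traj An `mt_trajectory`.
#' @param length_tol Length-rate tolerance (um/s); default 1e-3.
#' @param tip_tol Tip-speed tolerance (um/s); default 1e-3.
#' @param window_frac Trailing fraction of the run used for the
#'   diagnostics; default 0.2.
#' @return An object of class `mt_regime`: list with `label` and
#'   `diagnostics` (window-averaged `|dL/dt|`, `|dL_plus/dt|`,
#'   `|dL_minus/dt|`, mean length).
#' @export
classify_trajectory <- function(traj, length_tol = 1e-3, tip_tol = 1e-3,
                                window_frac = 0.2) {
  if (!inherits(traj, "mt_trajectory"))
    stop("invalid-input: expected an 'mt_trajectory'", call. = FALSE)
  tr <- traj$trajectory
  if (is.null(tr) || nrow(tr) == 0)
    stop("invalid-input: empty trajectory", call. = FALSE)
  if (nrow(tr) < 10 && !identical(traj$termination, "disassembled"))
    stop("invalid-input: need >= 10 saved points or a termination flag",
         call. = FALSE)
  t1 <- max(tr$time)
  win <- tr$time >= t1 - window_frac * t1
  dLdt <- mean(tr$dLplus_dt[win] - tr$dLminus_dt[win])
  tip_p <- mean(abs(tr$dLplus_dt[win]))
  tip_m <- mean(abs(tr$dLminus_dt[win]))
  diagnostics <- c(dL_dt = abs(dLdt), dLplus_dt = tip_p, dLminus_dt = tip_m,
                   mean_length = mean(tr$length[win]))
  L_min <- if (!is.null(traj$scenario)) 0.1 else 0.1
  label <-
    if (identical(traj$termination, "disassembled") ||
        tr$length[nrow(tr)] <= L_min) "disassembly"
    else if (abs(dLdt) < length_tol && max(tip_p, tip_m) >= tip_tol) "treadmilling"
    else if (tip_p < tip_tol && tip_m < tip_tol) "fixed-ends"
    else if (dLdt >= length_tol) "growing"
    else "indeterminate"
  structure(list(label = label, diagnostics = diagnostics),
            class = "mt_regime")
}

#' @export
print.mt_regime <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Regime: %s\n", x$label))
  cat(sprintf("  window-averaged |dL/dt| = %.3g, |dL+/dt| = %.3g, |dL-/dt| = %.3g um/s; mean length = %.4g um\n",
              d["dL_dt"], d["dLplus_dt"], d["dLminus_dt"], d["mean_length"]))
  invisible(x)
}

# Resolve a sweep axis name to a location inside an mt_params object.
.set_param <- function(params, axis, value) {
  tip_names <- names(unclass(params$tips))
  if (axis %in% tip_names) {
    params$tips[[axis]] <- value
    return(params)
  }
  parts <- strsplit(axis, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2 &&
      parts[1] %in% c("plus_motor", "minus_motor") &&
      parts[2] %in% c("v", "D_on", "D_off", "k_on", "k_off")) {
    params[[parts[1]]][[parts[2]]] <- value
    return(params)
  }
  stop("invalid-parameter: unknown sweep axis '", axis, "'", call. = FALSE)
}

#' One-dimensional parameter sweep
#'
#' Varies a single parameter over a grid. For `model = "reduced"` each
#' point records the adiabatic equilibrium (existence flag and length
#' `L_dagger`) from [equilibrium_length()]; for `model = "full"` each
#' point runs [simulate_full()] and records the regime label and the
#' final length. A point whose solve fails is marked `failed` rather
#' than aborting the sweep.
#'
#' @param base An [mt_params()] object giving the unswept values.
#' @param axis Parameter name: a tip rate (`"alpha_plus"`, ...,
#'   `"gamma_minus"`) or a motor field as `"plus_motor.k_on"` etc.
#' @param values Numeric grid for the axis.
#' @param model `"reduced"` or `"full"`.
#' @param L0,t_end Scenario settings for full-model points.
#' @param solver A [solver_config()] for full-model points.
#' @return A data frame of class `mt_sweep` with one row per grid point:
#'   `axis`, `value`, and per-model result columns (`exists`,
#'   `L_dagger`; or `label`, `final_length`), plus `failed`.
#' @export
parameter_sweep <- function(base, axis, values, model = c("reduced", "full"),
                            L0 = 10, t_end = 300, solver = solver_config()) {
  model <- match.arg(model)
  stopifnot(inherits(base, "mt_params"), is.numeric(values), length(values) >= 1)
  if (any(!is.finite(values)))
    stop("invalid-parameter: sweep values must be finite", call. = FALSE)
  rows <- lapply(values, function(v) {
    out <- data.frame(axis = axis, value = v, failed = FALSE,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      params <- .set_param(base, axis, v)
      if (model == "reduced") {
        eq <- equilibrium_length(params$tips, effective_params(params))
        data.frame(exists = eq$exists, L_dagger = eq$L_dagger)
      } else {
        sc <- scenario_config(params, L0 = L0, t_end = t_end,
                              name = paste0("sweep-", axis, "-", v))
        tr <- simulate_full(sc, solver)
        lab <- classify_trajectory(tr)
        data.frame(label = lab$label,
                   final_length = tr$trajectory$length[nrow(tr$trajectory)],
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      out$failed <- TRUE
      if (model == "reduced") {
        out$exists <- NA; out$L_dagger <- NA_real_
      } else {
        out$label <- NA_character_; out$final_length <- NA_real_
      }
    } else {
      out <- cbind(out, res)
    }
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  class(out) <- c("mt_sweep", class(out))
  out
}
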