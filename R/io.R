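.config_schema <- list(
  plus_motor = c("v", "D_on", "D_off", "k_on", "k_off"),
  minus_motor = c("v", "D_on", "D_off", "k_on", "k_off"),
  tips = c("alpha_plus", "alpha_minus", "beta_plus", "beta_minus",
           "gamma_plus", "gamma_minus"),
  scenario = c("name", "L0", "t_end", "ic_mode"),
  solver = c("n_cells", "rel_tol", "abs_tol", "L_min", "L_max", "save_every"),
  meta = NULL   # free-form annotations, ignored by the resolver
)

#' Read a scenario/solver configuration file
#'
#' Parses a YAML configuration with (all optional) sections
#' `plus_motor`, `minus_motor`, `tips`, `scenario`, `solver` and a
#' free-form `meta` section. Keys are named after the model symbols
#' (`v`, `D_on`, `D_off`, `k_on`, `k_off`, `alpha_plus`, ...); all
#' quantities are in um and s base units, with no in-file unit strings.
#' Unspecified keys fall back to [default_params()] and the
#' [solver_config()] defaults; unknown sections or keys are an error, so
#' typos cannot silently revert a parameter to its default.
#'
#' @param path Path to the configuration file.
#' @return A list with components `scenario` (an [scenario_config()])
#'   and `solver` (a [solver_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("configuration-error: no such file: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("configuration-error: cannot parse ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("configuration-error: top level must be a mapping", call. = FALSE)
  bad <- setdiff(names(raw), names(.config_schema))
  if (length(bad))
    stop("configuration-error: unknown section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in setdiff(names(raw), "meta")) {
    badkey <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(badkey))
      stop("configuration-error: unknown key(s) in '", sec, "': ",
           paste0(sec, ".", badkey, collapse = ", "), call. = FALSE)
  }
  params <- default_params()
  for (sec in c("plus_motor", "minus_motor"))
    for (k in names(raw[[sec]]))
      params[[sec]][[k]] <- as.numeric(raw[[sec]][[k]])
  for (k in names(raw$tips))
    params$tips[[k]] <- as.numeric(raw$tips[[k]])
  sc <- raw$scenario
  scenario <- scenario_config(
    params,
    L0 = if (is.null(sc$L0)) 10 else as.numeric(sc$L0),
    t_end = if (is.null(sc$t_end)) 300 else as.numeric(sc$t_end),
    name = if (is.null(sc$name)) "custom" else as.character(sc$name),
    ic_mode = if (is.null(sc$ic_mode)) "uniform-one" else sc$ic_mode)
  sv <- raw$solver
  defaults <- solver_config()
  args <- lapply(stats::setNames(nm = .config_schema$solver), function(k)
    if (is.null(sv[[k]])) defaults[[k]] else as.numeric(sv[[k]]))
  solver <- do.call(solver_config, args)
  list(scenario = scenario, solver = solver)
}

.config_as_list <- function(scenario, solver) {
  p <- scenario$params
  list(
    plus_motor = p$plus_motor[c("v", "D_on", "D_off", "k_on", "k_off")],
    minus_motor = p$minus_motor[c("v", "D_on", "D_off", "k_on", "k_off")],
    tips = unclass(p$tips),
    scenario = list(name = scenario$name, L0 = scenario$L0,
                    t_end = scenario$t_end, ic_mode = scenario$ic_mode),
    solver = unclass(solver))
}

#' Write trajectory, snapshots and a run record to a directory
#'
#' Serializes a simulation: `trajectory.tsv` (columns `t`, `L_minus`,
#' `L_plus`, `length`, `dLplus_dt`, `dLminus_dt`, `termination`),
#' `snapshots.tsv` (long format: `t`, `xi`, `x`, then one column per
#' field), a re-readable `config_echo.yaml`, and `run_record.json`
#' (resolved configuration, package version, wall time, termination,
#' output paths). Numbers are written at full double precision, so a
#' rerun from the echoed configuration reproduces the tables exactly.
#'
#' @param traj An `mt_trajectory` from [simulate_full()] or
#'   [simulate_reduced_pde()].
#' @param out_dir Output directory (created if missing).
#' @param solver The [solver_config()] used (echoed into the record);
#'   defaults are echoed if omitted.
#' @param wall_time Optional elapsed seconds to record.
#' @return The run record, invisibly (class `mt_run_record`).
#' @export
write_outputs <- function(traj, out_dir, solver = solver_config(),
                          wall_time = NA_real_) {
  stopifnot(inherits(traj, "mt_trajectory"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("io-error: cannot create directory ", out_dir, call. = FALSE)

  tr <- traj$trajectory
  tr_out <- data.frame(t = format(tr$time, digits = 17),
                       L_minus = format(tr$L_minus, digits = 17),
                       L_plus = format(tr$L_plus, digits = 17),
                       length = format(tr$length, digits = 17),
                       dLplus_dt = format(tr$dLplus_dt, digits = 17),
                       dLminus_dt = format(tr$dLminus_dt, digits = 17),
                       termination = traj$termination)
  traj_path <- file.path(out_dir, "trajectory.tsv")
  utils::write.table(tr_out, traj_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths <- c(trajectory = traj_path)
  if (!is.null(traj$snapshots)) {
    sn <- traj$snapshots
    fields <- setdiff(names(sn), c("xi", "times"))
    nt <- length(sn$times); nx <- length(sn$xi)
    Lm <- rep(tr$L_minus, each = nx)
    Lp <- rep(tr$L_plus, each = nx)
    long <- data.frame(t = rep(sn$times, each = nx),
                       xi = rep(sn$xi, times = nt),
                       x = Lm + rep(sn$xi, times = nt) * (Lp - Lm))
    for (f in fields) long[[f]] <- as.vector(t(sn[[f]]))
    snap_path <- file.path(out_dir, "snapshots.tsv")
    num <- vapply(long, is.numeric, logical(1))
    long[num] <- lapply(long[num], format, digits = 17)
    utils::write.table(long, snap_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, snapshots = snap_path)
  }

  cfg <- if (!is.null(traj$scenario)) .config_as_list(traj$scenario, solver)
         else list(solver = unclass(solver))
  echo_path <- file.path(out_dir, "config_echo.yaml")
  yaml::write_yaml(cfg, echo_path)
  paths <- c(paths, config_echo = echo_path)

  record <- list(config = cfg,
                 package_version = as.character(utils::packageVersion("mtlength")),
                 model = traj$model,
                 termination = traj$termination,
                 wall_time_s = wall_time,
                 outputs = as.list(paths))
  record_path <- file.path(out_dir, "run_record.json")
  jsonlite::write_json(record, record_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  record$path <- record_path
  class(record) <- "mt_run_record"
  invisible(record)
}

#' Read back a written trajectory table
#'
#' @param path Path to a `trajectory.tsv` written by [write_outputs()].
#' @return A data frame with numeric columns and the termination flag.
#' @export
read_trajectory <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Generate scenario and random-parameter fixture files
#'
#' Writes the four built-in scenario configurations plus `n_random`
#' random parameter sets drawn log-uniformly within one decade either
#' side of the baseline values (seeded, hence reproducible). Each random
#' file carries a `meta` section recording whether the adiabatic
#' equilibrium-existence condition `alpha_+ + alpha_- > gamma_+ +
#' gamma_-` holds for its parameters. Every generated set passes
#' [validate_params()] by construction.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_random Number of random parameter files (>= 0).
#' @param seed RNG seed.
#' @return Character vector of file paths, invisibly.
#' @export
generate_fixtures <- function(out_dir, n_random = 0, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("io-error: cannot create directory ", out_dir, call. = FALSE)
  stopifnot(n_random >= 0)
  paths <- character(0)
  for (nm in c("disassembly", "treadmilling", "fixed-ends", "patronin-rnai")) {
    sc <- builtin_scenario(nm)
    path <- file.path(out_dir, paste0("scenario-", nm, ".yaml"))
    yaml::write_yaml(.config_as_list(sc, solver_config()), path)
    paths <- c(paths, path)
  }
  if (n_random > 0) {
    rng <- local({
      set.seed(seed)
      function(base) base * 10^stats::runif(1, -1, 1)
    })
    base <- default_params()
    for (i in seq_len(n_random)) {
      p <- base
      for (side in c("plus_motor", "minus_motor"))
        for (k in c("D_on", "D_off", "k_on", "k_off"))
          p[[side]][[k]] <- rng(base[[side]][[k]])
      p$plus_motor$v <- rng(base$plus_motor$v)
      for (k in names(unclass(base$tips)))
        if (base$tips[[k]] > 0) p$tips[[k]] <- rng(base$tips[[k]])
      suppressWarnings(validate_params(p))  # invariants hold by construction
      exists <- p$tips$alpha_plus + p$tips$alpha_minus >
        p$tips$gamma_plus + p$tips$gamma_minus
      sc <- suppressWarnings(scenario_config(p, L0 = 10, t_end = 300,
                                             name = sprintf("random-%03d", i)))
      cfg <- .config_as_list(sc, solver_config())
      cfg$meta <- list(seed = seed, index = i, equilibrium_exists = exists)
      path <- file.path(out_dir, sprintf("random-%03d.yaml", i))
      yaml::write_yaml(cfg, path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' @export
print.mt_run_record <- function(x, ...) {
  cat(sprintf("Run record (mtlength %s): model %s, termination %s\n",
              x$package_version, x$model, x$termination))
  cat("  outputs:", paste(unlist(x$outputs), collapse = ", "), "\n")
  invisible(x)
}
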