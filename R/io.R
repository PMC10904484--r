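# condition helpers: distinct classes so the CLI can map them to exit codes
config_error <- function(msg) {
  stop(structure(class = c("gamblesim_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

io_error <- function(msg) {
  stop(structure(class = c("gamblesim_io_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# format a column for CSV output; doubles get 17 significant digits
# (round-trip exact)
fmt17 <- function(x) {
  if (is.character(x)) return(x)
  if (is.logical(x) || is.integer(x)) return(as.character(x))
  vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (is.infinite(v)) { if (v > 0) "Inf" else "-Inf" }
    else formatC(v, digits = 17, format = "g")
  }, character(1L))
}

# atomic write: build in a temp file next to `path`, then rename
write_atomically <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    io_error(sprintf("output directory does not exist: %s", dir))
  }
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- tryCatch({ writer(tmp); TRUE },
                 error = function(e) { unlink(tmp); stop(e) })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    io_error(sprintf("could not write output file: %s", path))
  }
  invisible(path)
}

# CSV dialect: comma separator, '.' decimal, header, LF endings, UTF-8,
# 17 significant digits on numeric columns
write_model_csv <- function(df, path) {
  cols <- lapply(df, fmt17)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  write_atomically(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  })
}

#' Export a trajectory as CSV
#'
#' Writes the per-period records with the fixed column order `t`, `S`,
#' `A_star`, `A`, `U_decision`, `U_experienced`, `craving_loss`, `status`.
#' Comma-separated, `.` decimal, header row, LF line endings, UTF-8,
#' numbers at 17 significant digits. The file is written atomically (no
#' partial output on failure).
#'
#' @param trajectory a `gambling_trajectory`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "gambling_trajectory"))
  write_model_csv(
    trajectory$periods[, c("t", "S", "A_star", "A", "U_decision",
                           "U_experienced", "craving_loss", "status")],
    path)
}

# JSON-safe copy: infinities become string markers
json_safe <- function(x) {
  rapply(x, function(v) {
    if (is.numeric(v)) {
      v2 <- as.list(v)
      v2 <- lapply(v2, function(e) {
        if (is.infinite(e)) { if (e > 0) "Inf" else "-Inf" } else e
      })
      if (length(v2) == 1L) v2[[1L]] else v2
    } else v
  }, how = "replace")
}

#' Export a regime classification as JSON
#'
#' @param classification a `regime_classification` from [classify_agent()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_classification_json <- function(classification, path) {
  stopifnot(inherits(classification, "regime_classification"))
  payload <- json_safe(unclass(classification))
  write_atomically(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  })
}

#' Export a cohort result
#'
#' Writes `summary.json` (prevalences, regime counts, lifetime-utility
#' summary) and `agents.csv` (per-agent parameters, regime, flags and
#' lifetime utilities) into `dir`.
#'
#' @param result a `cohort_result` from [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort_result <- function(result, dir) {
  stopifnot(inherits(result, "cohort_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary <- json_safe(list(
    n_agents = result$n_agents,
    T_horizon = result$T_horizon,
    participation_prevalence = result$participation_prevalence,
    harm_prevalence = result$harm_prevalence,
    harm_prevalence_among_participants =
      result$harm_prevalence_among_participants,
    regime_counts = as.list(result$regime_counts),
    lifetime_experienced_utility_summary =
      as.list(result$lifetime_experienced_utility_summary)
  ))
  write_atomically(file.path(dir, "summary.json"), function(tmp) {
    jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  })
  write_model_csv(result$agents, file.path(dir, "agents.csv"))
  invisible(dir)
}

## ---- run configuration -----------------------------------------------

known_config_keys <- c("mode", "seed", "horizon", "S0", "cap", "log_level",
                       "agent", "cohort", "interventions", "sweep", "out")

agent_config_keys <- c("subjective", "objective", "alpha_C", "d", "delta",
                       "income")
frame_config_keys <- c("alpha_P", "alpha_PP", "alpha_M", "alpha_MM")

check_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    config_error(sprintf("unknown key%s in %s: %s",
                         if (length(unknown) > 1L) "s" else "",
                         where, paste(unknown, collapse = ", ")))
  }
}

need_number <- function(x, name, where) {
  if (is.null(x)) config_error(sprintf("missing `%s` in %s", name, where))
  if (!is.numeric(x)) {
    config_error(sprintf("`%s` in %s must be numeric", name, where))
  }
  x
}

frame_from_config <- function(x, frame, where) {
  if (is.null(x)) config_error(sprintf("missing `%s` block", where))
  check_keys(x, frame_config_keys, where)
  tryCatch(
    coefficient_set(
      need_number(x$alpha_P, "alpha_P", where),
      need_number(x$alpha_PP, "alpha_PP", where),
      need_number(x$alpha_M, "alpha_M", where),
      need_number(x$alpha_MM, "alpha_MM", where),
      frame = frame),
    error = function(e) config_error(
      sprintf("invalid %s coefficients: %s", frame, conditionMessage(e))))
}

agent_from_config <- function(x) {
  if (is.null(x)) config_error("missing `agent` block")
  check_keys(x, agent_config_keys, "agent")
  subjective <- frame_from_config(x$subjective, "subjective",
                                  "agent.subjective")
  objective <- if (is.null(x$objective)) {
    tryCatch(
      coefficient_set(subjective$alpha_P, subjective$alpha_PP,
                      subjective$alpha_M, subjective$alpha_MM,
                      frame = "objective"),
      error = function(e) config_error(
        paste("`agent.objective` omitted but subjective coefficients are",
              "not valid objective ones:", conditionMessage(e))))
  } else {
    frame_from_config(x$objective, "objective", "agent.objective")
  }
  tryCatch(
    agent_parameters(
      subjective = subjective, objective = objective,
      alpha_C = need_number(x$alpha_C, "alpha_C", "agent"),
      d = need_number(x$d, "d", "agent"),
      delta = if (is.null(x$delta)) 0 else x$delta,
      income = if (is.null(x$income)) Inf else unlist(x$income)),
    error = function(e) config_error(
      sprintf("invalid agent parameters: %s", conditionMessage(e))))
}

dist_from_config <- function(x, name) {
  if (!is.list(x) || is.null(x$dist)) {
    config_error(sprintf(
      "distribution for `%s` must be a mapping with a `dist` key", name))
  }
  where <- sprintf("distribution `%s`", name)
  out <- tryCatch(switch(x$dist,
    point = { check_keys(x, c("dist", "value"), where)
              dist_point(need_number(x$value, "value", where)) },
    uniform = { check_keys(x, c("dist", "min", "max"), where)
                dist_uniform(need_number(x$min, "min", where),
                             need_number(x$max, "max", where)) },
    normal = { check_keys(x, c("dist", "mean", "sd"), where)
               dist_normal(need_number(x$mean, "mean", where),
                           need_number(x$sd, "sd", where)) },
    lognormal = { check_keys(x, c("dist", "meanlog", "sdlog"), where)
                  dist_lognormal(need_number(x$meanlog, "meanlog", where),
                                 need_number(x$sdlog, "sdlog", where)) },
    config_error(sprintf("unknown distribution type `%s` for `%s`",
                         x$dist, name))),
    error = function(e) {
      if (inherits(e, "gamblesim_config_error")) stop(e)
      config_error(sprintf("invalid %s: %s", where, conditionMessage(e)))
    })
  out
}

cohort_from_config <- function(x) {
  if (is.null(x)) config_error("missing `cohort` block")
  check_keys(x, c("n_agents", "distributions", "bias_link"), "cohort")
  if (is.null(x$distributions)) {
    config_error("missing `cohort.distributions`")
  }
  dists <- stats::setNames(
    lapply(names(x$distributions),
           function(nm) dist_from_config(x$distributions[[nm]], nm)),
    names(x$distributions))
  link <- if (is.null(x$bias_link)) NULL else stats::setNames(
    lapply(names(x$bias_link),
           function(nm) dist_from_config(x$bias_link[[nm]],
                                         paste0("bias_link.", nm))),
    names(x$bias_link))
  tryCatch(
    cohort_spec(need_number(x$n_agents, "n_agents", "cohort"),
                distributions = dists, bias_link = link, seed = 1L),
    error = function(e) config_error(
      sprintf("invalid cohort spec: %s", conditionMessage(e))))
}

intervention_from_config <- function(x, i) {
  where <- sprintf("interventions[%d]", i)
  if (!is.list(x) || is.null(x$type)) {
    config_error(sprintf("%s must be a mapping with a `type` key", where))
  }
  tryCatch(switch(x$type,
    scale_alpha_C = { check_keys(x, c("type", "factor"), where)
      intervention_scale_alpha_C(need_number(x$factor, "factor", where)) },
    shift_alpha_PP = { check_keys(x, c("type", "shift"), where)
      intervention_shift_alpha_PP(need_number(x$shift, "shift", where)) },
    amount_cap = { check_keys(x, c("type", "cap"), where)
      intervention_amount_cap(need_number(unlist(x$cap), "cap", where)) },
    income_limit = { check_keys(x, c("type", "limit"), where)
      intervention_income_limit(need_number(unlist(x$limit), "limit",
                                            where)) },
    config_error(sprintf("unknown intervention type `%s` in %s",
                         x$type, where))),
    error = function(e) {
      if (inherits(e, "gamblesim_config_error")) stop(e)
      config_error(sprintf("invalid %s: %s", where, conditionMessage(e)))
    })
}

sweep_axis_from_config <- function(x, name) {
  where <- sprintf("sweep.%s", name)
  if (!is.list(x) || is.null(x$name)) {
    config_error(sprintf("%s must be a mapping with `name` and `values` or `from`/`to`/`by`", where))
  }
  check_keys(x, c("name", "values", "from", "to", "by"), where)
  sweepable <- c("alpha_P_S", "alpha_PP_S", "alpha_M_S", "alpha_MM_S",
                 "alpha_P_O", "alpha_PP_O", "alpha_M_O", "alpha_MM_O",
                 "alpha_C", "d", "delta", "income")
  if (!x$name %in% sweepable) {
    config_error(sprintf("%s.name must be one of: %s",
                         where, paste(sweepable, collapse = ", ")))
  }
  values <- if (!is.null(x$values)) unlist(x$values)
            else seq(need_number(x$from, "from", where),
                     need_number(x$to, "to", where),
                     by = need_number(x$by, "by", where))
  list(name = x$name, values = as.numeric(values))
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration describing a run (mode, agent or
#' cohort specification, horizon, initial stock, caps, interventions and
#' seed), validates it against the schema — unknown keys are rejected with
#' the offending key named, and every parameter invariant is checked with a
#' message naming the field — and returns a `run_config` with all defaults
#' made explicit.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    config_error(sprintf("config file not found: %s", path))
  }
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) config_error(
    sprintf("could not parse config %s: %s", path, conditionMessage(e))))
  if (!is.list(raw)) config_error("config must be a mapping at top level")
  check_keys(raw, known_config_keys, "config")

  mode <- raw$mode
  if (is.null(mode) ||
      !mode %in% c("simulate", "classify", "cohort", "sweep")) {
    config_error(
      "`mode` must be one of: simulate, classify, cohort, sweep")
  }

  cfg <- list(
    mode = mode,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    horizon = if (is.null(raw$horizon)) 200L else as.integer(raw$horizon),
    S0 = if (is.null(raw$S0)) 0 else as.numeric(raw$S0),
    cap = if (is.null(raw$cap)) NULL else as.numeric(unlist(raw$cap)),
    log_level = if (is.null(raw$log_level)) "info" else raw$log_level,
    agent = NULL, cohort = NULL, interventions = list(), sweep = NULL
  )
  if (!cfg$log_level %in% c("info", "quiet")) {
    config_error("`log_level` must be \"info\" or \"quiet\"")
  }
  if (cfg$horizon < 1L) config_error("`horizon` must be at least 1")
  if (cfg$S0 < 0) config_error("`S0` must be non-negative")
  if (!is.null(cfg$cap) && any(cfg$cap < 0)) {
    config_error("`cap` must be non-negative")
  }

  if (mode %in% c("simulate", "classify", "sweep")) {
    cfg$agent <- agent_from_config(raw$agent)
  }
  if (mode == "cohort") {
    cfg$cohort <- cohort_from_config(raw$cohort)
    cfg$cohort$seed <- cfg$seed
  }
  if (mode == "sweep") {
    if (is.null(raw$sweep) || is.null(raw$sweep$param1)) {
      config_error("sweep mode requires a `sweep` block with `param1`")
    }
    check_keys(raw$sweep, c("param1", "param2"), "sweep")
    cfg$sweep <- list(
      param1 = sweep_axis_from_config(raw$sweep$param1, "param1"),
      param2 = if (is.null(raw$sweep$param2)) NULL
               else sweep_axis_from_config(raw$sweep$param2, "param2"))
  }
  if (!is.null(raw$interventions)) {
    cfg$interventions <- lapply(seq_along(raw$interventions), function(i)
      intervention_from_config(raw$interventions[[i]], i))
  }
  structure(cfg, class = "run_config")
}

# inverse of the *_from_config readers, for round-tripping a run_config
config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  frame_to_list <- function(cs) list(
    alpha_P = cs$alpha_P, alpha_PP = cs$alpha_PP,
    alpha_M = cs$alpha_M, alpha_MM = cs$alpha_MM)
  dist_to_list <- function(ds) unclass(ds)
  out <- list(mode = cfg$mode, seed = cfg$seed, horizon = cfg$horizon,
              S0 = cfg$S0, log_level = cfg$log_level)
  if (!is.null(cfg$cap)) out$cap <- cfg$cap
  if (!is.null(cfg$agent)) {
    a <- cfg$agent
    out$agent <- list(
      subjective = frame_to_list(a$subjective),
      objective = frame_to_list(a$objective),
      alpha_C = a$alpha_C, d = a$d, delta = a$delta, income = a$income)
  }
  if (!is.null(cfg$cohort)) {
    cs <- cfg$cohort
    out$cohort <- list(
      n_agents = cs$n_agents,
      distributions = lapply(cs$distributions, dist_to_list))
    if (!is.null(cs$bias_link)) {
      out$cohort$bias_link <- lapply(cs$bias_link, dist_to_list)
    }
  }
  if (length(cfg$interventions) > 0L) {
    out$interventions <- lapply(cfg$interventions, unclass)
  }
  if (!is.null(cfg$sweep)) {
    out$sweep <- list(param1 = cfg$sweep$param1)
    if (!is.null(cfg$sweep$param2)) out$sweep$param2 <- cfg$sweep$param2
  }
  out
}

#' Serialize a run configuration back to YAML
#'
#' Writes a [load_config()] result (with all defaults made explicit) to a
#' YAML file; loading that file again reproduces the configuration.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  payload <- config_to_list(cfg)
  write_atomically(path, function(tmp) yaml::write_yaml(payload, tmp))
}
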