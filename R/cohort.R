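#' Distribution specifications for cohort sampling
#'
#' Small helpers describing how one scalar agent parameter is drawn:
#' a point mass, a uniform, a normal truncated to the parameter's legal
#' range, or a lognormal (for strictly positive parameters). Negative-only
#' parameters such as the quadratic coefficients can use `dist_uniform()`
#' over a negative interval or a truncated `dist_normal()`.
#'
#' @param value,min,max,mean,sd,meanlog,sdlog distribution parameters.
#' @return A distribution specification (class `dist_spec`).
#' @examples
#' dist_point(0.5)
#' dist_uniform(-1.5, -0.5)
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  structure(list(dist = "point", value = value), class = "dist_spec")
}

#' @rdname dist_point
#' @export
dist_uniform <- function(min, max) {
  stopifnot(is.numeric(min), is.numeric(max), min <= max)
  structure(list(dist = "uniform", min = min, max = max), class = "dist_spec")
}

#' @rdname dist_point
#' @export
dist_normal <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  structure(list(dist = "normal", mean = mean, sd = sd), class = "dist_spec")
}

#' @rdname dist_point
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  stopifnot(is.numeric(meanlog), is.numeric(sdlog), sdlog >= 0)
  structure(list(dist = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "dist_spec")
}

draw_dist <- function(spec) {
  switch(spec$dist,
    point     = spec$value,
    uniform   = stats::runif(1L, spec$min, spec$max),
    normal    = stats::rnorm(1L, spec$mean, spec$sd),
    lognormal = stats::rlnorm(1L, spec$meanlog, spec$sdlog),
    stop(sprintf("unknown distribution `%s`", spec$dist), call. = FALSE)
  )
}

# legal open/closed ranges per sampled parameter
param_range <- function(name) {
  switch(name,
    alpha_PP_S = , alpha_PP_O = , alpha_MM_S = , alpha_MM_O = ,
    alpha_M_O  = list(lo = -Inf, hi = 0, hi_open = TRUE, lo_open = TRUE),
    alpha_C    = list(lo = 0, hi = Inf, lo_open = TRUE, hi_open = TRUE),
    d          = list(lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE),
    delta      = list(lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE),
    income     = list(lo = 0, hi = Inf, lo_open = FALSE, hi_open = TRUE),
    list(lo = -Inf, hi = Inf, lo_open = TRUE, hi_open = TRUE)
  )
}

in_range <- function(x, r) {
  lo_ok <- if (r$lo_open) x > r$lo else x >= r$lo
  hi_ok <- if (r$hi_open) x < r$hi else x <= r$hi
  lo_ok && hi_ok
}

# rejection-sample one parameter into its legal range; cap at 1000 draws
draw_param <- function(name, spec, max_reject = 1000L) {
  for (k in seq_len(max_reject)) {
    x <- draw_dist(spec)
    if (in_range(x, param_range(name))) return(x)
  }
  stop(sprintf(
    "could not sample `%s` inside its legal range after %d rejections",
    name, max_reject), call. = FALSE)
}

#' Specification of a heterogeneous synthetic cohort
#'
#' Describes how a cohort of agents is sampled: one distribution per scalar
#' parameter, an optional bias link generating subjective coefficients from
#' objective ones, and a root seed. Objective coefficients are always
#' sampled first; when `bias_link` supplies a wedge distribution for a
#' coefficient, the subjective value is the objective value plus a
#' non-negative sampled wedge (so decision utility weakly exceeds
#' experienced utility), and any subjective distribution given for that
#' coefficient is ignored.
#'
#' @param n_agents number of agents to sample.
#' @param distributions named list of [dist_point()]-style specifications.
#'   Recognised names: `alpha_P_O`, `alpha_PP_O`, `alpha_M_O`, `alpha_MM_O`,
#'   `alpha_P_S`, `alpha_PP_S`, `alpha_M_S`, `alpha_MM_S`, `alpha_C`, `d`,
#'   `delta`, `income`. Subjective coefficients default to the sampled
#'   objective values (no bias) when neither a subjective distribution nor
#'   a bias link is given.
#' @param bias_link optional named list of wedge distributions for any of
#'   `alpha_P`, `alpha_PP`, `alpha_M`, `alpha_MM`; wedges are truncated to
#'   be non-negative.
#' @param seed integer root seed; per-agent seeds are derived from it so
#'   cohorts are reproducible agent-by-agent.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_agents, distributions, bias_link = NULL,
                        seed = 1L) {
  if (!is.numeric(n_agents) || length(n_agents) != 1L || n_agents < 1) {
    stop("`n_agents` must be a positive count", call. = FALSE)
  }
  known <- c("alpha_P_O", "alpha_PP_O", "alpha_M_O", "alpha_MM_O",
             "alpha_P_S", "alpha_PP_S", "alpha_M_S", "alpha_MM_S",
             "alpha_C", "d", "delta", "income")
  required <- c("alpha_P_O", "alpha_PP_O", "alpha_M_O", "alpha_MM_O",
                "alpha_C", "d")
  if (!is.list(distributions) || is.null(names(distributions))) {
    stop("`distributions` must be a named list of dist_spec objects",
         call. = FALSE)
  }
  unknown <- setdiff(names(distributions), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown parameter(s) in `distributions`: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(required, names(distributions))
  if (length(missing) > 0L) {
    stop(sprintf("missing distribution(s) for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!all(vapply(distributions, inherits, logical(1L), "dist_spec"))) {
    stop("every entry of `distributions` must be a dist_spec", call. = FALSE)
  }
  if (!is.null(bias_link)) {
    bad <- setdiff(names(bias_link), c("alpha_P", "alpha_PP",
                                       "alpha_M", "alpha_MM"))
    if (length(bad) > 0L) {
      stop(sprintf("unknown coefficient(s) in `bias_link`: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (!all(vapply(bias_link, inherits, logical(1L), "dist_spec"))) {
      stop("every entry of `bias_link` must be a dist_spec", call. = FALSE)
    }
  }
  structure(
    list(n_agents = as.integer(n_agents), distributions = distributions,
         bias_link = bias_link, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default cohort distributions
#'
#' A moderate, heterogeneous reference population: objective net pleasure
#' centred slightly positive with substantial spread (so a minority are
#' non-participants), risk-averse monetary coefficients, lognormal craving
#' propensity, broad depreciation, light discounting, a finite per-period
#' budget, and modest non-negative belief wedges on the linear
#' coefficients (optimism about pleasure and monetary outcome).
#'
#' @param n_agents cohort size.
#' @param seed root seed.
#' @param biased include the non-negative belief wedges (default `TRUE`);
#'   with `FALSE` agents are unbiased.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_agents = 200L, seed = 1L, biased = TRUE) {
  cohort_spec(
    n_agents = n_agents,
    distributions = list(
      alpha_P_O  = dist_normal(0.75, 0.5),
      alpha_PP_O = dist_uniform(-1.5, -0.5),
      alpha_M_O  = dist_uniform(-1.0, -0.1),
      alpha_MM_O = dist_uniform(-1.5, -0.5),
      alpha_C    = dist_lognormal(log(0.08), 0.8),
      d          = dist_uniform(0.2, 0.8),
      delta      = dist_uniform(0, 0.2),
      income     = dist_point(10)
    ),
    bias_link = if (biased) list(
      alpha_P = dist_normal(0.08, 0.08),
      alpha_M = dist_normal(0.08, 0.08)
    ) else NULL,
    seed = seed
  )
}

sample_one_agent <- function(spec, max_reject = 1000L) {
  ds <- spec$distributions
  obj <- list(
    alpha_P  = draw_param("alpha_P_O",  ds$alpha_P_O,  max_reject),
    alpha_PP = draw_param("alpha_PP_O", ds$alpha_PP_O, max_reject),
    alpha_M  = draw_param("alpha_M_O",  ds$alpha_M_O,  max_reject),
    alpha_MM = draw_param("alpha_MM_O", ds$alpha_MM_O, max_reject)
  )
  subj <- obj
  for (coefn in c("alpha_P", "alpha_PP", "alpha_M", "alpha_MM")) {
    link <- spec$bias_link[[coefn]]
    if (!is.null(link)) {
      sname <- paste0(coefn, "_S")
      ok <- FALSE
      for (k in seq_len(max_reject)) {
        w <- draw_dist(link)
        if (w < 0) next  # wedges are non-negative by construction
        cand <- obj[[coefn]] + w
        if (in_range(cand, param_range(sname))) {
          subj[[coefn]] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) {
        stop(sprintf(
          "could not sample a valid subjective `%s` via bias_link", coefn),
          call. = FALSE)
      }
    } else {
      sname <- paste0(coefn, "_S")
      if (!is.null(ds[[sname]])) {
        subj[[coefn]] <- draw_param(sname, ds[[sname]], max_reject)
      }
    }
  }
  agent_parameters(
    subjective = coefficient_set(subj$alpha_P, subj$alpha_PP,
                                 subj$alpha_M, subj$alpha_MM,
                                 frame = "subjective"),
    objective  = coefficient_set(obj$alpha_P, obj$alpha_PP,
                                 obj$alpha_M, obj$alpha_MM,
                                 frame = "objective"),
    alpha_C = draw_param("alpha_C", ds$alpha_C, max_reject),
    d       = draw_param("d", ds$d, max_reject),
    delta   = if (is.null(ds$delta)) 0 else
              draw_param("delta", ds$delta, max_reject),
    income  = if (is.null(ds$income)) Inf else
              draw_param("income", ds$income, max_reject)
  )
}

#' Sample a cohort of agents
#'
#' Draws `n_agents` valid agents from a [cohort_spec()]. A per-agent seed
#' stream is derived from the root seed, so the i-th agent is identical
#' across runs regardless of how the others are processed. Draws landing
#' outside a parameter's legal range are rejected and redrawn, up to 1000
#' attempts per parameter before an error naming the parameter.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `agent_cohort`: a list of
#'   [agent_parameters()] objects with the cohort specification attached as
#'   an attribute.
#' @examples
#' coh <- sample_cohort(default_cohort_spec(n_agents = 10, seed = 42))
#' length(coh)
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_agents)
  agents <- vector("list", spec$n_agents)
  for (i in seq_len(spec$n_agents)) {
    set.seed(agent_seeds[i])
    agents[[i]] <- sample_one_agent(spec)
  }
  structure(agents, class = "agent_cohort", spec = spec)
}

#' @export
print.agent_cohort <- function(x, ...) {
  cat(sprintf("<agent_cohort> %d agents\n", length(x)))
  invisible(x)
}

#' Simulate and summarise a cohort
#'
#' Classifies every agent analytically (participation, convergence, harm
#' regime) and simulates every agent's trajectory over `T_horizon` periods
#' for the lifetime-utility summaries. Prevalence figures come from the
#' analytic classification, so they do not depend on the horizon; the
#' simulation serves as a consistency check and supplies discounted
#' lifetime utilities.
#'
#' @param cohort an `agent_cohort` from [sample_cohort()], or a plain list
#'   of [agent_parameters()].
#' @param T_horizon simulation horizon in periods.
#' @param cap optional per-period amount cap applied to every agent; an
#'   `amount_cap` intervention already attached to the cohort is combined
#'   with this by taking the minimum.
#' @return An object of class `cohort_result` with prevalence fields, a
#'   regime count table, lifetime experienced-utility summaries, and a
#'   per-agent data frame `agents`.
#' @export
simulate_cohort <- function(cohort, T_horizon = 200L, cap = NULL) {
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  attached_cap <- attr(cohort, "amount_cap")
  eff_cap <- if (is.null(attached_cap)) cap
             else if (is.null(cap)) attached_cap
             else pmin(cap, attached_cap)

  n <- length(cohort)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- cohort[[i]]
    cls <- classify_agent(p)
    tr <- simulate_trajectory(p, T_horizon = T_horizon, cap = eff_cap)
    rows[[i]] <- data.frame(
      agent_id = i,
      b_S = net_slope(p$subjective), c_S = net_curvature(p$subjective),
      b_O = net_slope(p$objective), c_O = net_curvature(p$objective),
      alpha_C = p$alpha_C, d = p$d, delta = p$delta,
      income = income_at(p, 0L),
      participates = cls$participates,
      converges = cls$converges,
      develops_negative_utility = cls$develops_negative_utility,
      regime = cls$regime,
      equilibrium_amount = cls$equilibrium_amount,
      long_run_experienced_utility = cls$long_run_experienced_utility,
      lifetime_decision_utility = tr$lifetime_decision_utility,
      lifetime_experienced_utility = tr$lifetime_experienced_utility,
      stringsAsFactors = FALSE
    )
  }
  agents <- do.call(rbind, rows)

  regimes <- c("non_participant", "benign_equilibrium",
               "harmful_equilibrium", "divergent_harmful")
  regime_counts <- vapply(regimes, function(r) sum(agents$regime == r),
                          integer(1L))
  n_part <- sum(agents$participates)
  q <- stats::quantile(agents$lifetime_experienced_utility,
                       probs = c(0.1, 0.25, 0.5, 0.75, 0.9), names = TRUE)
  structure(
    list(
      n_agents = n,
      participation_prevalence = n_part / n,
      harm_prevalence = sum(agents$develops_negative_utility) / n,
      harm_prevalence_among_participants =
        if (n_part > 0L) sum(agents$develops_negative_utility) / n_part
        else NA_real_,
      regime_counts = regime_counts,
      lifetime_experienced_utility_summary = c(
        mean = mean(agents$lifetime_experienced_utility), q),
      T_horizon = as.integer(T_horizon),
      agents = agents
    ),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d agents, horizon %d\n",
              x$n_agents, x$T_horizon))
  cat(sprintf("  participation prevalence: %.3f\n",
              x$participation_prevalence))
  cat(sprintf("  harm prevalence         : %.3f (among participants %.3f)\n",
              x$harm_prevalence, x$harm_prevalence_among_participants))
  cat("  regimes: ",
      paste(names(x$regime_counts), x$regime_counts,
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}
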