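#' System state of the two-consumer / one-resource model
#'
#' @param n_a,n_b population densities (individuals/L). Non-negative;
#'   integer-valued in stochastic mode, real in deterministic mode.
#' @param resource resource concentration (umol/L), non-negative.
#' @param t time step, non-negative integer.
#' @return list of class `"system_state"`.
#' @export
system_state <- function(n_a, n_b, resource, t = 0L) {
  stopifnot(length(n_a) == 1L, length(n_b) == 1L, length(resource) == 1L,
            is.numeric(n_a), is.numeric(n_b), is.numeric(resource),
            n_a >= 0, n_b >= 0, resource >= 0, t >= 0)
  structure(list(n_a = as.numeric(n_a), n_b = as.numeric(n_b),
                 resource = as.numeric(resource), t = as.integer(t)),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state t=%d> N_a=%g N_b=%g R=%g umol/L\n",
              x$t, x$n_a, x$n_b, x$resource))
  invisible(x)
}

#' Per-capita Monod growth rate
#'
#' \eqn{\mu R / (K + R)}: zero at zero resource, saturating at `mu` as the
#' resource becomes abundant. Evaluated at R = R* (for parameters derived
#' from that R*) it equals the dilution rate exactly.
#'
#' @param mu maximum growth rate (1/day).
#' @param k half-saturation constant (umol/L), positive.
#' @param r resource concentration (umol/L), non-negative.
#' @return per-capita growth rate (1/day). Vectorized.
#' @examples
#' monod_term(0.4, 4.32, 1.44) # = 0.1, the dilution rate that gave R* = 1.44
#' @export
monod_term <- function(mu, k, r) {
  stopifnot(is.numeric(mu), is.numeric(k), is.numeric(r))
  if (any(k <= 0)) stop("'k' must be positive")
  if (any(r < 0)) stop("resource concentration 'r' must be non-negative")
  mu * r / (k + r)
}

check_params <- function(params) {
  stopifnot(inherits(params, "regime_params") || is.list(params))
  needed <- c("mu_a", "mu_b", "k_a", "k_b", "dilution", "inflow",
              "quota_a", "quota_b")
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0)
    stop("params lacks fields: ", paste(missing, collapse = ", "))
  invisible(params)
}

#' One synchronous deterministic step
#'
#' Updates both populations and the resource from their time-t values:
#' \deqn{N_i(t+1) = N_i(t) + \mu_i N_i \frac{R}{K_i + R} - D N_i}
#' \deqn{R(t+1) = R(t) + D(I - R) - \sum_i Q_i \mu_i N_i \frac{R}{K_i + R}}
#' After the update any population below 1 individual is set to 0
#' (extinction threshold, applied every step so extinction is absorbing) and
#' the resource is clamped at 0.
#'
#' @param state a [system_state()].
#' @param params per-species parameters, e.g. from [point_params()].
#' @return the next [system_state()].
#' @export
deterministic_step <- function(state, params) {
  stopifnot(inherits(state, "system_state"))
  check_params(params)
  r <- state$resource
  g_a <- monod_term(params$mu_a, params$k_a, r) * state$n_a
  g_b <- monod_term(params$mu_b, params$k_b, r) * state$n_b
  uptake <- params$quota_a * g_a + params$quota_b * g_b
  n_a <- state$n_a + g_a - params$dilution * state$n_a
  n_b <- state$n_b + g_b - params$dilution * state$n_b
  if (n_a < 1) n_a <- 0
  if (n_b < 1) n_b <- 0
  r_new <- max(0, r + params$dilution * (params$inflow - r) - uptake)
  system_state(n_a, n_b, r_new, state$t + 1L)
}

# Largest-remainder reduction of drawn births when the required uptake
# exceeds the available resource. Mirrors cap_births() in src/trajectory.cpp
# draw-for-draw (one uniform consumed only on an exact remainder tie).
cap_births_r <- function(b_a, b_b, quota_a, quota_b, avail) {
  need <- quota_a * b_a + quota_b * b_b
  if (need <= avail || need <= 0) return(c(b_a, b_b))
  s <- if (avail > 0) avail / need else 0
  ta <- b_a * s
  tb <- b_b * s
  fa <- floor(ta)
  fb <- floor(tb)
  rema <- ta - fa
  remb <- tb - fb
  leftover <- avail - quota_a * fa - quota_b * fb
  a_first <- if (rema > remb) TRUE else if (remb > rema) FALSE else
    stats::runif(1) < 0.5
  if (a_first) {
    if (quota_a <= leftover) { fa <- fa + 1; leftover <- leftover - quota_a }
    if (quota_b <= leftover) { fb <- fb + 1; leftover <- leftover - quota_b }
  } else {
    if (quota_b <= leftover) { fb <- fb + 1; leftover <- leftover - quota_b }
    if (quota_a <= leftover) { fa <- fa + 1; leftover <- leftover - quota_a }
  }
  c(fa, fb)
}

#' One stochastic (Poisson birth-death) step
#'
#' Births are drawn as Poisson with mean equal to the deterministic growth
#' term \eqn{G_i = \mu_i N_i R / (K_i + R)}, deaths as Poisson with mean
#' \eqn{M_i = D N_i} truncated at the current population size, all from
#' time-t values. Resource uptake equals the quota times the births each
#' species actually achieved; if the drawn births would require more
#' resource than is available, total births are reduced to fit (largest
#' remainder allocation, see the package vignette) so uptake never exceeds
#' R(t). The resource itself receives no direct noise:
#' \eqn{R(t+1) = R(t) + D(I - R) - \sum_i Q_i b_i}, clamped at 0.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param state a [system_state()] with integer-valued populations.
#' @param params per-species parameters, e.g. from [point_params()].
#' @return list with `state` (the next [system_state()]) and `increments`
#'   (expected and realized births/deaths and the realized uptake).
#' @export
stochastic_step <- function(state, params) {
  stopifnot(inherits(state, "system_state"))
  check_params(params)
  if (state$n_a != floor(state$n_a) || state$n_b != floor(state$n_b))
    stop("stochastic mode requires integer-valued populations")
  r <- state$resource
  g_a <- monod_term(params$mu_a, params$k_a, r) * state$n_a
  g_b <- monod_term(params$mu_b, params$k_b, r) * state$n_b
  m_a <- params$dilution * state$n_a
  m_b <- params$dilution * state$n_b
  b_a <- stats::rpois(1, g_a)
  b_b <- stats::rpois(1, g_b)
  d_a <- min(stats::rpois(1, m_a), state$n_a)
  d_b <- min(stats::rpois(1, m_b), state$n_b)
  capped <- cap_births_r(b_a, b_b, params$quota_a, params$quota_b, r)
  b_a <- capped[1]
  b_b <- capped[2]
  uptake <- params$quota_a * b_a + params$quota_b * b_b
  n_a <- state$n_a + b_a - d_a
  n_b <- state$n_b + b_b - d_b
  if (n_a < 1) n_a <- 0
  if (n_b < 1) n_b <- 0
  r_new <- max(0, r + params$dilution * (params$inflow - r) - uptake)
  list(
    state = system_state(n_a, n_b, r_new, state$t + 1L),
    increments = list(
      growth_a = g_a, growth_b = g_b,
      mortality_a = m_a, mortality_b = m_b,
      realized_births_a = b_a, realized_births_b = b_b,
      realized_deaths_a = d_a, realized_deaths_b = d_b,
      uptake = uptake
    )
  )
}

#' Run a competition trajectory
#'
#' Iterates the deterministic or stochastic stepper for `horizon` steps from
#' the given initial state, recording the first step at which each
#' population hits zero. When both populations are extinct the run may exit
#' early (the remaining resource dynamics cannot affect the outcome
#' classification); the final state is then reported as at the horizon.
#'
#' Two engines are available: `"cpp"` (compiled, the default) and `"R"`
#' (the reference steppers [deterministic_step()] / [stochastic_step()]).
#' Both consume the global RNG stream identically and produce bit-identical
#' trajectories under the same seed.
#'
#' @param initial a [system_state()]; in stochastic mode populations must be
#'   integers.
#' @param params per-species parameters, e.g. from [point_params()].
#' @param horizon number of steps to simulate (>= 1).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param record if `TRUE`, keep the thinned trajectory (disables early
#'   exit).
#' @param stride thinning stride for the recorded trajectory.
#' @param engine `"cpp"` or `"R"`.
#' @param early_exit allow stopping once both populations are extinct.
#' @return list with `final` ([system_state()] at the horizon),
#'   `extinction_time_a`, `extinction_time_b` (first step at 0, or `NA` if
#'   the species survived) and `trajectory` (data frame `t`, `n_a`, `n_b`,
#'   `resource`, or `NULL`).
#' @examples
#' ps <- build_parameter_space(regime = "high_growth")
#' set.seed(1)
#' run_trajectory(system_state(512, 512, 10), point_params(ps, 1),
#'                horizon = 100)$final
#' @export
run_trajectory <- function(initial, params, horizon = 20000L,
                           mode = c("stochastic", "deterministic"),
                           record = FALSE, stride = 1L,
                           engine = c("cpp", "R"), early_exit = TRUE) {
  stopifnot(inherits(initial, "system_state"), horizon >= 1)
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  check_params(params)
  horizon <- as.integer(horizon)
  stride <- as.integer(stride)
  stochastic <- mode == "stochastic"
  if (stochastic &&
      (initial$n_a != floor(initial$n_a) || initial$n_b != floor(initial$n_b)))
    stop("stochastic mode requires integer-valued initial populations")

  if (engine == "cpp") {
    res <- run_traj_cpp(initial$n_a, initial$n_b, initial$resource,
                        initial$t, params$mu_a, params$mu_b,
                        params$k_a, params$k_b, params$dilution,
                        params$inflow, params$quota_a, params$quota_b,
                        horizon, stochastic, record, stride, early_exit)
    traj <- if (record) as.data.frame(res$trajectory) else NULL
    return(list(
      final = system_state(res$n_a, res$n_b, res$resource, res$t),
      extinction_time_a = res$ext_a,
      extinction_time_b = res$ext_b,
      trajectory = traj
    ))
  }

  state <- initial
  ext_a <- if (state$n_a < 1) state$t else NA_integer_
  ext_b <- if (state$n_b < 1) state$t else NA_integer_
  if (state$n_a < 1) state$n_a <- 0
  if (state$n_b < 1) state$n_b <- 0
  traj <- if (record) list(c(state$t, state$n_a, state$n_b, state$resource))
  for (step in seq_len(horizon)) {
    state <- if (stochastic) stochastic_step(state, params)$state
             else deterministic_step(state, params)
    if (is.na(ext_a) && state$n_a == 0) ext_a <- state$t
    if (is.na(ext_b) && state$n_b == 0) ext_b <- state$t
    if (record && (step %% stride == 0L || step == horizon))
      traj[[length(traj) + 1L]] <- c(state$t, state$n_a, state$n_b,
                                     state$resource)
    if (early_exit && !record && state$n_a == 0 && state$n_b == 0) {
      state$t <- initial$t + horizon
      break
    }
  }
  if (record) {
    traj <- as.data.frame(do.call(rbind, traj))
    names(traj) <- c("t", "n_a", "n_b", "resource")
  } else traj <- NULL
  list(final = state, extinction_time_a = ext_a, extinction_time_b = ext_b,
       trajectory = traj)
}
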