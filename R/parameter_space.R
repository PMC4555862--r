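#' Convert Monod growth parameters to R*
#'
#' The break-even resource concentration of a consumer in an open system is
#' the concentration at which per-capita Monod growth exactly balances
#' dilution losses: solving \eqn{\mu R / (K + R) = D} for \eqn{R} gives
#' \deqn{R^* = \frac{D K}{\mu - D}.}
#' The species with the lower R* is predicted to exclude its competitor when
#' both are limited by the same single resource.
#'
#' @param mu maximum growth rate (1/day). Must exceed `d`.
#' @param k half-saturation constant (umol/L), positive.
#' @param d dilution rate (1/day), positive.
#' @return R* (umol/L). Vectorized over all arguments.
#' @examples
#' rstar_from_params(0.105, 0.072, 0.1) # 1.44
#' @export
rstar_from_params <- function(mu, k, d) {
  stopifnot(is.numeric(mu), is.numeric(k), is.numeric(d))
  if (any(d <= 0)) stop("dilution rate 'd' must be positive")
  if (any(k <= 0)) stop("half-saturation constant 'k' must be positive")
  if (any(mu <= d)) {
    stop("'mu' must exceed 'd': a species with mu <= D cannot persist at ",
         "any resource concentration, so R* is undefined")
  }
  d * k / (mu - d)
}

#' Maximum growth rate realizing a target R*
#'
#' Inverse of [rstar_from_params()] in `mu`: \eqn{\mu = D + D K / R^*}.
#' Used to lay growth rates along an R* gradient while holding the
#' half-saturation constant fixed.
#'
#' @param rstar target break-even resource concentration (umol/L), positive.
#' @param k half-saturation constant (umol/L), positive.
#' @param d dilution rate (1/day), positive.
#' @return maximum growth rate (1/day). Vectorized.
#' @examples
#' mu_from_rstar(1.44, 0.072, 0.1) # 0.105
#' @export
mu_from_rstar <- function(rstar, k, d) {
  stopifnot(is.numeric(rstar), is.numeric(k), is.numeric(d))
  if (any(rstar <= 0)) stop("'rstar' must be positive")
  if (any(k <= 0)) stop("'k' must be positive")
  if (any(d <= 0)) stop("'d' must be positive")
  d + d * k / rstar
}

#' Half-saturation constant realizing a target R*
#'
#' Inverse of [rstar_from_params()] in `K`: \eqn{K = R^* (\mu - D) / D}.
#' Used to lay half-saturation constants along an R* gradient while holding
#' the maximum growth rate fixed.
#'
#' @inheritParams mu_from_rstar
#' @param mu maximum growth rate (1/day). Must exceed `d`.
#' @return half-saturation constant (umol/L). Vectorized.
#' @examples
#' k_from_rstar(1.44, 0.105, 0.1) # 0.072
#' @export
k_from_rstar <- function(rstar, mu, d) {
  stopifnot(is.numeric(rstar), is.numeric(mu), is.numeric(d))
  if (any(rstar <= 0)) stop("'rstar' must be positive")
  if (any(d <= 0)) stop("'d' must be positive")
  if (any(mu <= d)) stop("'mu' must exceed 'd' (R* undefined otherwise)")
  rstar * (mu - d) / d
}

#' Build the mirrored linear R* grid
#'
#' Constructs the fitness-inequality gradient: species A's R* ascends
#' linearly from `r_min` to `r_max` over `n_points` grid points while
#' species B's descends over the same values in reverse, so the two species
#' swap roles across the central point, where their R* values are exactly
#' equal and fitness inequality is zero. `n_points` must be odd so that the
#' central equality point exists.
#'
#' @param r_min,r_max R* range endpoints (umol/L), `r_min < r_max`.
#' @param n_points odd integer >= 3; number of grid points.
#' @return data frame with columns `point_index`, `rstar_a`, `rstar_b`.
#' @examples
#' g <- build_rstar_grid(1.10, 1.78, 35)
#' g[18, ] # central equality point: both R* = 1.44
#' @export
build_rstar_grid <- function(r_min = 1.10, r_max = 1.78, n_points = 35L) {
  stopifnot(is.numeric(r_min), is.numeric(r_max), length(r_min) == 1L,
            length(r_max) == 1L, length(n_points) == 1L)
  n_points <- as.integer(n_points)
  if (!is.finite(r_min) || !is.finite(r_max) || r_min >= r_max)
    stop("'r_min' must be strictly less than 'r_max'")
  if (r_min <= 0) stop("R* values must be positive")
  if (is.na(n_points) || n_points < 3L)
    stop("'n_points' must be an integer >= 3")
  if (n_points %% 2L == 0L)
    stop("'n_points' must be odd: an even grid has no central point where ",
         "the two species' R* values are equal")
  step <- (r_max - r_min) / (n_points - 1L)
  ra <- r_min + step * (seq_len(n_points) - 1L)
  # mirror by reversal so the central pair is equal to the last bit and the
  # two species traverse the exact same set of values
  data.frame(point_index = seq_len(n_points), rstar_a = ra, rstar_b = rev(ra))
}

#' Relative fitness and fitness inequality of an R* pair
#'
#' Relative fitness of a competitor is the other competitor's R* divided by
#' its own (so the more fit, lower-R* species has relative fitness > 1), and
#' fitness inequality is the absolute difference between the two relative
#' fitnesses, \eqn{|R^*_a/R^*_b - R^*_b/R^*_a|}. Inequality is zero exactly
#' when the two R* values are equal, and the metric is symmetric under
#' swapping the species labels.
#'
#' @param rstar_a,rstar_b the two break-even concentrations (umol/L),
#'   positive. Vectorized; alternatively pass a grid data frame from
#'   [build_rstar_grid()] as `rstar_a`.
#' @return data frame with columns `rel_fitness_a`, `rel_fitness_b`,
#'   `inequality`, `more_fit_id` (`"a"`, `"b"` or `"tie"`).
#' @examples
#' fitness_metrics(1.46, 1.42)$inequality # 0.0556 -> the first step off equality
#' @export
fitness_metrics <- function(rstar_a, rstar_b = NULL) {
  if (is.data.frame(rstar_a)) {
    df <- rstar_a
    stopifnot(all(c("rstar_a", "rstar_b") %in% names(df)))
    rstar_b <- df$rstar_b
    rstar_a <- df$rstar_a
  }
  stopifnot(is.numeric(rstar_a), is.numeric(rstar_b),
            length(rstar_a) == length(rstar_b))
  if (any(rstar_a <= 0) || any(rstar_b <= 0))
    stop("R* values must be positive")
  rel_a <- rstar_b / rstar_a
  rel_b <- rstar_a / rstar_b
  data.frame(
    rel_fitness_a = rel_a,
    rel_fitness_b = rel_b,
    inequality = abs(rel_a - rel_b),
    more_fit_id = ifelse(rstar_a == rstar_b, "tie",
                         ifelse(rstar_a < rstar_b, "a", "b"))
  )
}

regime_constants <- list(
  low_growth  = list(mu = 0.105, k = 0.072),
  high_growth = list(mu = 0.4,   k = 4.32)
)

#' Build the full fitness-inequality parameter space
#'
#' For each point of the mirrored R* grid, derives the per-species Monod
#' parameters that realize the grid R* values at the configured dilution
#' rate. One parameter is held at its regime value and the other is
#' recomputed from R*:
#' * `varying = "mu"`: K fixed (0.072 umol/L low growth, 4.32 high growth),
#'   growth rates from [mu_from_rstar()];
#' * `varying = "K"`: mu fixed (0.105 1/day low growth, 0.4 high growth),
#'   half-saturation constants from [k_from_rstar()].
#'
#' @param config a simulation configuration from [sim_config()], or `NULL`
#'   to use the arguments below.
#' @param regime `"low_growth"` or `"high_growth"`.
#' @param varying which Monod parameter tracks the R* gradient, `"mu"` or
#'   `"K"`.
#' @param dilution dilution rate D (1/day).
#' @param r_min,r_max,n_points grid as in [build_rstar_grid()].
#' @param inflow resource inflow concentration I (umol/L).
#' @param quota resource quota Q per new individual (umol/individual), used
#'   downstream by the dynamics.
#' @return data frame (one row per grid point) with columns `point_index`,
#'   `rstar_a`, `rstar_b`, `mu_a`, `mu_b`, `k_a`, `k_b`, `dilution`,
#'   `inflow`, `quota_a`, `quota_b`, `rel_fitness_a`, `rel_fitness_b`,
#'   `inequality`, `more_fit_id`, `regime_label`, `varying`; class
#'   `"param_space"`.
#' @examples
#' ps <- build_parameter_space(regime = "high_growth")
#' round(ps$mu_a[c(1, 18, 35)], 3) # 0.493 0.400 0.343
#' @export
build_parameter_space <- function(config = NULL,
                                  regime = c("low_growth", "high_growth"),
                                  varying = c("mu", "K"),
                                  dilution = 0.1,
                                  r_min = 1.10, r_max = 1.78, n_points = 35L,
                                  inflow = 10, quota = 1e-6) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    regime <- config$regime
    varying <- config$varying
    dilution <- config$dilution
    r_min <- config$r_min
    r_max <- config$r_max
    n_points <- config$n_points
    inflow <- config$inflow
    quota <- config$quota
  }
  regime <- match.arg(regime, c("low_growth", "high_growth"))
  varying <- match.arg(varying, c("mu", "K"))
  if (dilution <= 0) stop("'dilution' must be positive")
  grid <- build_rstar_grid(r_min, r_max, n_points)
  const <- regime_constants[[regime]]
  if (varying == "mu") {
    k_a <- rep(const$k, nrow(grid))
    k_b <- k_a
    mu_a <- mu_from_rstar(grid$rstar_a, k_a, dilution)
    mu_b <- mu_from_rstar(grid$rstar_b, k_b, dilution)
  } else {
    if (const$mu <= dilution) {
      stop(sprintf(
        "regime '%s' holds mu = %g, which does not exceed dilution %g; ",
        regime, const$mu, dilution),
        "no half-saturation constant can realize the R* grid")
    }
    mu_a <- rep(const$mu, nrow(grid))
    mu_b <- mu_a
    k_a <- k_from_rstar(grid$rstar_a, mu_a, dilution)
    k_b <- k_from_rstar(grid$rstar_b, mu_b, dilution)
  }
  bad <- which(mu_a <= dilution | mu_b <= dilution)
  if (length(bad) > 0) {
    stop("mu <= dilution at point(s) ", paste(bad, collapse = ", "),
         "; R* undefined there")
  }
  fm <- fitness_metrics(grid$rstar_a, grid$rstar_b)
  out <- cbind(
    grid,
    data.frame(mu_a = mu_a, mu_b = mu_b, k_a = k_a, k_b = k_b,
               dilution = dilution, inflow = inflow,
               quota_a = quota, quota_b = quota),
    fm,
    data.frame(regime_label = regime, varying = varying)
  )
  class(out) <- c("param_space", "data.frame")
  out
}

#' Extract per-species simulation parameters for one grid point
#'
#' @param space a parameter space from [build_parameter_space()].
#' @param point_index grid point (1-based).
#' @return list with fields `mu_a`, `mu_b`, `k_a`, `k_b`, `dilution`,
#'   `inflow`, `quota_a`, `quota_b`, `rstar_a`, `rstar_b`, `inequality`,
#'   `more_fit_id`, `point_index`; class `"regime_params"`.
#' @export
point_params <- function(space, point_index) {
  stopifnot(inherits(space, "param_space"),
            length(point_index) == 1L,
            point_index %in% space$point_index)
  row <- space[space$point_index == point_index, ]
  p <- list(
    mu_a = row$mu_a, mu_b = row$mu_b, k_a = row$k_a, k_b = row$k_b,
    dilution = row$dilution, inflow = row$inflow,
    quota_a = row$quota_a, quota_b = row$quota_b,
    rstar_a = row$rstar_a, rstar_b = row$rstar_b,
    inequality = row$inequality, more_fit_id = row$more_fit_id,
    point_index = row$point_index,
    regime_label = row$regime_label, varying = row$varying
  )
  class(p) <- "regime_params"
  p
}
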