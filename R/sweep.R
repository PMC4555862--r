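#' Simulation configuration
#'
#' Bundles every knob of the replicated experiment. Defaults reproduce the
#' canonical design: a 35-point R* grid from 1.10 to 1.78 umol/L, dilution
#' 0.1 1/day, inflow and initial resource 10 umol/L, quota 1e-6
#' umol/individual, initial population sizes 1, 2, 4, ..., 512, 100
#' replicates of 20 000 steps each.
#'
#' @param regime `"low_growth"` (mu around 0.105 1/day, K = 0.072 umol/L) or
#'   `"high_growth"` (mu around 0.4 1/day, K = 4.32 umol/L).
#' @param varying which Monod parameter follows the R* gradient (`"mu"` or
#'   `"K"`); the other is held at its regime value.
#' @param dilution dilution rate D (1/day).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param horizon steps per trajectory.
#' @param initial_sizes integer vector of initial population sizes (applied
#'   to both species).
#' @param n_replicates replicates per (point, initial size) treatment.
#' @param base_seed integer master seed; per-replicate streams are derived
#'   from it (see [replicate_seed()]).
#' @param r_min,r_max,n_points R* grid, see [build_rstar_grid()].
#' @param inflow resource inflow concentration I (umol/L).
#' @param initial_resource resource concentration at t = 0 (umol/L).
#' @param quota resource bound in each new individual, Q (umol/individual).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(regime = c("low_growth", "high_growth"),
                       varying = c("mu", "K"),
                       dilution = 0.1,
                       mode = c("stochastic", "deterministic"),
                       horizon = 20000L,
                       initial_sizes = 2L^(0:9),
                       n_replicates = 100L,
                       base_seed = 1L,
                       r_min = 1.10, r_max = 1.78, n_points = 35L,
                       inflow = 10, initial_resource = 10, quota = 1e-6) {
  regime <- match.arg(regime, c("low_growth", "high_growth"))
  varying <- match.arg(varying, c("mu", "K"))
  mode <- match.arg(mode, c("stochastic", "deterministic"))
  horizon <- as.integer(horizon)
  initial_sizes <- as.integer(initial_sizes)
  n_replicates <- as.integer(n_replicates)
  base_seed <- as.integer(base_seed)
  stopifnot(dilution > 0, horizon >= 1, length(initial_sizes) >= 1,
            all(initial_sizes >= 1), n_replicates >= 1,
            r_min > 0, r_min < r_max, n_points >= 3,
            inflow > 0, initial_resource >= 0, quota > 0,
            !is.na(base_seed))
  if (initial_resource > inflow)
    warning("initial_resource exceeds inflow concentration; the resource ",
            "ceiling R(t) <= I no longer holds from t = 0")
  cfg <- list(regime = regime, varying = varying, dilution = dilution,
              mode = mode, horizon = horizon, initial_sizes = initial_sizes,
              n_replicates = n_replicates, base_seed = base_seed,
              r_min = r_min, r_max = r_max, n_points = as.integer(n_points),
              inflow = inflow, initial_resource = initial_resource,
              quota = quota)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  regime: %s (varying %s), dilution %g /day, mode %s\n",
              x$regime, x$varying, x$dilution, x$mode))
  cat(sprintf("  grid: %d points, R* %g-%g umol/L\n",
              x$n_points, x$r_min, x$r_max))
  cat(sprintf("  horizon %d steps, N0 {%s}, %d replicates, base seed %d\n",
              x$horizon, paste(x$initial_sizes, collapse = ","),
              x$n_replicates, x$base_seed))
  invisible(x)
}

#' Derive the RNG seed of one replicate
#'
#' Each replicate runs on its own reproducible stream: a 31-bit seed is
#' derived from the base seed and the full treatment coordinates (regime,
#' varying parameter, mode, dilution, grid point, initial size, replicate
#' number) by hashing their string encoding with 32-bit FNV-1a, so any
#' single replicate can be re-run in isolation and results are independent
#' of execution order.
#'
#' @param config a [sim_config()].
#' @param point_index grid point (1-based).
#' @param n0 initial population size of the treatment.
#' @param replicate replicate number (1-based).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
replicate_seed <- function(config, point_index, n0, replicate) {
  stopifnot(inherits(config, "sim_config"))
  key <- sprintf("%d|%s|%s|%s|%.9g|%d|%d|%d",
                 config$base_seed, config$regime, config$varying,
                 config$mode, config$dilution, as.integer(point_index),
                 as.integer(n0), as.integer(replicate))
  # 32-bit FNV-1a; the multiply is split into 16-bit halves so every
  # intermediate stays below 2^53 and the arithmetic is exact in doubles
  mul32 <- function(a, b) {
    (((a %/% 65536 * b) %% 65536) * 65536 + (a %% 65536) * b) %% 4294967296
  }
  h <- 2166136261
  for (byte in utf8ToInt(key)) {
    h <- mul32(bitwXor(as.integer(h %% 2147483648), as.integer(byte)) +
                 (h %/% 2147483648) * 2147483648, 16777619)
  }
  as.integer(h %% 2147483645 + 1)
}

outcome_categories <- c("more_fit_dominant", "less_fit_dominant",
                        "co_persistence", "dual_extinction",
                        "dominance_at_equality")

#' Classify the outcome of a finished run
#'
#' Exactly one of five mutually exclusive categories, judged at the horizon:
#' both populations extant is `co_persistence`; both extinct is
#' `dual_extinction`; a single survivor is dominance, labelled
#' `more_fit_dominant` or `less_fit_dominant` by whether the survivor has
#' the lower R* of the pair, or `dominance_at_equality` when the point has
#' zero fitness inequality (where neither competitor is more or less fit).
#'
#' @param final_state the [system_state()] at the horizon.
#' @param point per-species parameters of the grid point
#'   ([point_params()]), or any list carrying `more_fit_id`.
#' @param extinction_time_a,extinction_time_b first step at which each
#'   population hit zero (`NA` if surviving); passed through to the result.
#' @return list with `category`, `winner_id` (`"a"`, `"b"` or `NA`),
#'   `extinction_time_a`, `extinction_time_b`.
#' @export
classify_outcome <- function(final_state, point,
                             extinction_time_a = NA_integer_,
                             extinction_time_b = NA_integer_) {
  stopifnot(inherits(final_state, "system_state"),
            !is.null(point$more_fit_id))
  alive_a <- final_state$n_a > 0
  alive_b <- final_state$n_b > 0
  if (alive_a && alive_b) {
    category <- "co_persistence"
    winner <- NA_character_
  } else if (!alive_a && !alive_b) {
    category <- "dual_extinction"
    winner <- NA_character_
  } else {
    winner <- if (alive_a) "a" else "b"
    category <- if (point$more_fit_id == "tie") "dominance_at_equality"
                else if (winner == point$more_fit_id) "more_fit_dominant"
                else "less_fit_dominant"
  }
  list(category = category, winner_id = winner,
       extinction_time_a = extinction_time_a,
       extinction_time_b = extinction_time_b)
}

#' Run all replicates of one treatment
#'
#' Simulates `config$n_replicates` independent trajectories of the treatment
#' (grid point, initial size), each started from equal populations
#' `(n0, n0)` and resource `config$initial_resource`, on its own seed from
#' [replicate_seed()], and classifies each. In deterministic mode the
#' replicates are identical, so a single trajectory is run and broadcast.
#'
#' @param point per-species parameters from [point_params()].
#' @param n0 initial population size for both species.
#' @param config a [sim_config()].
#' @return data frame with one row per replicate: `replicate`, `seed`,
#'   `category`, `winner_id`, `extinction_time_a`, `extinction_time_b`.
#' @export
run_replicates <- function(point, n0, config) {
  stopifnot(inherits(config, "sim_config"))
  n_eff <- if (config$mode == "deterministic") 1L else config$n_replicates
  rows <- vector("list", n_eff)
  for (rep_i in seq_len(n_eff)) {
    seed <- replicate_seed(config, point$point_index, n0, rep_i)
    set.seed(seed)
    tr <- run_trajectory(
      system_state(n0, n0, config$initial_resource),
      point, horizon = config$horizon, mode = config$mode
    )
    oc <- classify_outcome(tr$final, point,
                           tr$extinction_time_a, tr$extinction_time_b)
    rows[[rep_i]] <- data.frame(
      replicate = rep_i, seed = seed,
      category = oc$category,
      winner_id = if (is.na(oc$winner_id)) NA_character_ else oc$winner_id,
      extinction_time_a = oc$extinction_time_a,
      extinction_time_b = oc$extinction_time_b,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (config$mode == "deterministic" && config$n_replicates > 1L) {
    out <- out[rep(1L, config$n_replicates), ]
    out$replicate <- seq_len(config$n_replicates)
    rownames(out) <- NULL
  }
  out
}

#' Run the full replicated sweep
#'
#' Iterates every (grid point, initial size) treatment of the configuration,
#' running and classifying all replicates. Emits one long-format record per
#' replicate.
#'
#' @param config a [sim_config()].
#' @param progress print a progress tick per treatment to stderr.
#' @return list of class `"sweep_result"` with elements `records` (long
#'   data frame: regime, varying, dilution, mode, point_index, inequality,
#'   n0, replicate, seed, category, winner_id, extinction times), `space`
#'   (the parameter space) and `config`.
#' @export
run_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  space <- build_parameter_space(config)
  blocks <- vector("list", nrow(space) * length(config$initial_sizes))
  bi <- 0L
  for (pi in space$point_index) {
    point <- point_params(space, pi)
    for (n0 in config$initial_sizes) {
      reps <- run_replicates(point, n0, config)
      bi <- bi + 1L
      blocks[[bi]] <- cbind(
        data.frame(regime = config$regime, varying = config$varying,
                   dilution = config$dilution, mode = config$mode,
                   point_index = pi, inequality = point$inequality,
                   n0 = n0, stringsAsFactors = FALSE),
        reps
      )
      if (progress)
        message(sprintf("point %d/%d n0=%d done", pi, nrow(space), n0))
    }
  }
  res <- list(records = do.call(rbind, blocks), space = space,
              config = config)
  class(res) <- "sweep_result"
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d records (%s, varying %s, D=%g, %s)\n",
              nrow(x$records), x$config$regime, x$config$varying,
              x$config$dilution, x$config$mode))
  print(round(100 * prop.table(table(x$records$category)), 1))
  invisible(x)
}

#' Outcome frequencies per treatment cell
#'
#' Percentage of replicates in each of the five outcome categories for every
#' (grid point, initial size) cell. Percentages sum to 100 within each cell;
#' the more/less-fit dominance categories are structurally 0 at the
#' equality point.
#'
#' @param result a `"sweep_result"` from [run_sweep()], or its long-format
#'   records data frame (e.g. re-read from CSV).
#' @param expected_treatments optional data frame of `point_index` x `n0`
#'   combinations that must be present; missing treatments raise an error.
#'   Defaults to all combinations found in the configuration when `result`
#'   is a sweep_result.
#' @return data frame in long form: `point_index`, `inequality`, `n0`,
#'   `category`, `pct`, `n_replicates`.
#' @export
summarize_frequencies <- function(result, expected_treatments = NULL) {
  if (inherits(result, "sweep_result")) {
    records <- result$records
    if (is.null(expected_treatments))
      expected_treatments <- expand.grid(
        point_index = result$space$point_index,
        n0 = result$config$initial_sizes
      )
  } else {
    records <- result
  }
  stopifnot(is.data.frame(records),
            all(c("point_index", "n0", "category") %in% names(records)))
  if (!is.null(expected_treatments)) {
    have <- unique(records[c("point_index", "n0")])
    key <- function(d) paste(d$point_index, d$n0)
    miss <- setdiff(key(expected_treatments), key(have))
    if (length(miss) > 0)
      stop("sweep is incomplete; missing treatments (point n0): ",
           paste(miss, collapse = "; "))
  }
  records$category <- factor(records$category, levels = outcome_categories)
  counts <- as.data.frame(table(point_index = records$point_index,
                                n0 = records$n0,
                                category = records$category))
  counts$point_index <- as.integer(as.character(counts$point_index))
  counts$n0 <- as.integer(as.character(counts$n0))
  totals <- stats::aggregate(Freq ~ point_index + n0, counts, sum)
  names(totals)[3] <- "n_replicates"
  out <- merge(counts, totals, by = c("point_index", "n0"))
  out$pct <- 100 * out$Freq / out$n_replicates
  ineq <- unique(records[c("point_index", "inequality")])
  out <- merge(ineq, out, by = "point_index")
  out <- out[order(out$point_index, out$n0, out$category),
             c("point_index", "inequality", "n0", "category", "pct",
               "n_replicates")]
  rownames(out) <- NULL
  out
}

#' Pivot one outcome category to a point-by-size percentage grid
#'
#' @param summary long summary from [summarize_frequencies()].
#' @param category one of `"more_fit_dominant"`, `"less_fit_dominant"`,
#'   `"co_persistence"`, `"dual_extinction"`, `"dominance_at_equality"`.
#' @return numeric matrix, rows = grid points (named by index), columns =
#'   initial sizes.
#' @export
frequency_grid <- function(summary, category) {
  category <- match.arg(category, outcome_categories)
  sub <- summary[summary$category == category, ]
  pts <- sort(unique(sub$point_index))
  sizes <- sort(unique(sub$n0))
  m <- matrix(NA_real_, length(pts), length(sizes),
              dimnames = list(point_index = pts, n0 = sizes))
  m[cbind(match(sub$point_index, pts), match(sub$n0, sizes))] <- sub$pct
  m
}
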