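config_keys <- c("regime", "varying", "dilution", "mode", "horizon",
                 "initial_sizes", "n_replicates", "base_seed",
                 "r_min", "r_max", "n_points",
                 "inflow", "initial_resource", "quota")

#' Load a simulation configuration from a flat key = value file
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored. `initial_sizes` takes a comma-separated list. Absent keys fall
#' back to the canonical defaults of [sim_config()]; unknown keys are an
#' error (typo protection). The resulting configuration is validated,
#' including that mu > D holds across the whole grid.
#'
#' @param path path to the config file.
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("cannot parse config line: '", ln, "' (expected key = value)")
    kv[[m[2]]] <- trimws(m[3])
  }
  unknown <- setdiff(names(kv), config_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(config_keys, collapse = ", "))
  args <- list()
  for (key in names(kv)) {
    val <- kv[[key]]
    args[[key]] <- switch(
      key,
      regime = , varying = , mode = val,
      initial_sizes = {
        v <- suppressWarnings(as.integer(strsplit(val, ",")[[1]]))
        if (anyNA(v)) stop("invalid value for 'initial_sizes': ", val)
        v
      },
      horizon = , n_replicates = , base_seed = , n_points = {
        v <- suppressWarnings(as.integer(val))
        if (is.na(v)) stop("invalid value for '", key, "': ", val)
        v
      },
      {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v)) stop("invalid value for '", key, "': ", val)
        v
      }
    )
  }
  cfg <- do.call(sim_config, args)
  # surface grid-level validation errors (mu <= D, etc.) at load time
  invisible(build_parameter_space(cfg))
  cfg
}

#' Write the parameter space as CSV
#'
#' @param space a parameter space from [build_parameter_space()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parameter_space <- function(space, path) {
  stopifnot(inherits(space, "param_space"))
  utils::write.csv(as.data.frame(space), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write sweep results, summary grids and a run manifest
#'
#' Produces `results.csv` (one row per replicate, full float precision),
#' `summary_<category>.csv` (a point-by-size percentage grid per outcome
#' category), and `manifest.json` (the complete configuration, base seed
#' and package version: enough to re-run any replicate in isolation via
#' [replicate_seed()]).
#'
#' @param result a `"sweep_result"` from [run_sweep()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_sweep_results <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$records, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- summarize_frequencies(result)
  for (cat in outcome_categories) {
    g <- frequency_grid(summ, cat)
    df <- data.frame(point_index = as.integer(rownames(g)), g,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0("summary_", cat, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    config = unclass(result$config),
    package = "rstarcomp",
    version = as.character(utils::packageVersion("rstarcomp")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeding = "replicate_seed(config, point_index, n0, replicate)"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read long-format sweep results back from CSV
#'
#' @param path `results.csv` written by [write_sweep_results()].
#' @return data frame accepted by [summarize_frequencies()].
#' @export
read_sweep_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Heat-map of one outcome-frequency grid
#'
#' A data-faithful image of the percentage grid (grid points on the x axis
#' in fitness-inequality order, initial sizes on the y axis), not a
#' reproduction of any particular published figure's styling.
#'
#' @param summary long summary from [summarize_frequencies()].
#' @param category outcome category to draw.
#' @param ... passed to [graphics::image()].
#' @return the matrix drawn, invisibly.
#' @export
plot_outcome_grid <- function(summary, category, ...) {
  g <- frequency_grid(summary, category)
  graphics::image(
    x = seq_len(nrow(g)), y = seq_len(ncol(g)), z = g,
    zlim = c(0, 100), xlab = "parameter-space point",
    ylab = "initial population size (log2 index)",
    main = gsub("_", " ", category),
    col = grDevices::hcl.colors(64, "viridis"), ...
  )
  invisible(g)
}

cli_usage <- paste(
  "usage: rstarcomp <command> [options]",
  "",
  "commands:",
  "  space      write the parameter-space CSV",
  "  simulate   run a single trajectory, write its (thinned) CSV",
  "  sweep      run the replicated experiment, write results + manifest",
  "  summarize  recompute summary grids from a results CSV",
  "",
  "options:",
  "  --config PATH     key = value config file",
  "  --regime NAME     low_growth | high_growth",
  "  --vary PARAM      mu | K",
  "  --dilution D      dilution rate (1/day)",
  "  --mode MODE       stochastic | deterministic",
  "  --reps N          replicates per treatment",
  "  --horizon N       steps per trajectory",
  "  --seed N          base seed",
  "  --point I         grid point (simulate)",
  "  --n0 N            initial size (simulate)",
  "  --stride N        trajectory thinning stride (simulate, default 10)",
  "  --results PATH    input results.csv (summarize)",
  "  --out-dir DIR     output directory (default '.')",
  sep = "\n")

parse_cli_args <- function(args) {
  opts <- list()
  positional <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      if (i == length(args)) stop("missing value for option ", a)
      opts[[substring(a, 3)]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(command = if (length(positional) > 0) positional[[1]] else NA,
       opts = opts)
}

cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) load_config(opts$config) else sim_config()
  args <- unclass(cfg)
  if (!is.null(opts$regime)) args$regime <- opts$regime
  if (!is.null(opts$vary)) args$varying <- opts$vary
  if (!is.null(opts$dilution)) args$dilution <- as.numeric(opts$dilution)
  if (!is.null(opts$mode)) args$mode <- opts$mode
  if (!is.null(opts$reps)) args$n_replicates <- as.integer(opts$reps)
  if (!is.null(opts$horizon)) args$horizon <- as.integer(opts$horizon)
  if (!is.null(opts$seed)) args$base_seed <- as.integer(opts$seed)
  do.call(sim_config, args)
}

#' Command-line interface
#'
#' Entry point for `Rscript -e 'rstarcomp::rstarcomp_cli()'` or the
#' `inst/cli/rstarcomp` wrapper script. See the `space`, `simulate`,
#' `sweep` and `summarize` subcommands in the usage text.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   actual command line).
#' @return exit status (0 on success), invisibly. Errors in argument
#'   validation print a message and return 2 rather than throwing, so shell
#'   callers get a clean nonzero exit.
#' @export
rstarcomp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parsed <- parse_cli_args(args)
    out_dir <- if (!is.null(parsed$opts[["out-dir"]]))
      parsed$opts[["out-dir"]] else "."
    if (is.na(parsed$command)) {
      message(cli_usage)
      return(invisible(2L))
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- cli_config(parsed$opts)
    switch(
      parsed$command,
      space = {
        path <- file.path(out_dir, "parameter_space.csv")
        write_parameter_space(build_parameter_space(cfg), path)
        message("wrote ", path)
      },
      simulate = {
        pi <- as.integer(if (is.null(parsed$opts$point)) 18 else
          parsed$opts$point)
        n0 <- as.integer(if (is.null(parsed$opts$n0)) 512 else
          parsed$opts$n0)
        stride <- as.integer(if (is.null(parsed$opts$stride)) 10 else
          parsed$opts$stride)
        space <- build_parameter_space(cfg)
        set.seed(replicate_seed(cfg, pi, n0, 1L))
        tr <- run_trajectory(system_state(n0, n0, cfg$initial_resource),
                             point_params(space, pi),
                             horizon = cfg$horizon, mode = cfg$mode,
                             record = TRUE, stride = stride)
        path <- file.path(out_dir, "trajectory.csv")
        utils::write.csv(tr$trajectory, path, row.names = FALSE,
                         quote = FALSE)
        message("wrote ", path)
        print(tr$final)
      },
      sweep = {
        res <- run_sweep(cfg, progress = TRUE)
        write_sweep_results(res, out_dir)
        message("wrote results + manifest under ", out_dir)
      },
      summarize = {
        if (is.null(parsed$opts$results))
          stop("summarize needs --results PATH")
        summ <- summarize_frequencies(read_sweep_results(
          parsed$opts$results))
        for (cat in outcome_categories) {
          g <- frequency_grid(summ, cat)
          df <- data.frame(point_index = as.integer(rownames(g)), g,
                           check.names = FALSE)
          path <- file.path(out_dir, paste0("summary_", cat, ".csv"))
          utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
        }
        message("wrote summary grids under ", out_dir)
      },
      stop("unknown command '", parsed$command, "'\n", cli_usage)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
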