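# Simulated measurement protocols: ascending (staircase) searches for the
# critical ignition current and the breakdown voltage, run against a
# caller-supplied stochastic oracle so the protocol logic is testable without
# hardware. Oracles are functions level -> logical(1) whose success
# probability must be non-decreasing in level.

#' Configure a staircase protocol
#'
#' @param start_level First level tested (kA or kV).
#' @param max_level Largest level the generator can deliver; replicates that
#'   reach it without success are censored.
#' @param step_ratio Geometric increment between consecutive levels (> 1).
#'   Geometric steps keep the relative resolution constant across the range.
#' @param replicates Number of independent replicate searches.
#' @param consecutive_successes_required Trials that must all succeed at a
#'   level for the breakdown protocol to accept it.
#' @param rng_seed Integer seed; each replicate draws from its own stream
#'   derived from this seed, so adding replicates never perturbs earlier ones.
#'
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(start_level, max_level, step_ratio = 1.05,
                            replicates = 5, consecutive_successes_required = 5,
                            rng_seed = NULL) {
  stopifnot(is.numeric(start_level), is.numeric(max_level), is.numeric(step_ratio))
  if (start_level <= 0 || max_level <= start_level)
    stop("need 0 < start_level < max_level", call. = FALSE)
  if (step_ratio <= 1) stop("`step_ratio` must exceed 1", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be at least 1", call. = FALSE)
  if (consecutive_successes_required < 1)
    stop("`consecutive_successes_required` must be at least 1", call. = FALSE)
  structure(list(start_level = start_level, max_level = max_level,
                 step_ratio = step_ratio, replicates = as.integer(replicates),
                 consecutive_successes_required = as.integer(consecutive_successes_required),
                 rng_seed = rng_seed),
            class = "protocol_config")
}

protocol_levels <- function(config) {
  n <- floor(log(config$max_level / config$start_level) / log(config$step_ratio))
  config$start_level * config$step_ratio^(0:n)
}

# One sub-seed per replicate, drawn sequentially so the first k are identical
# for any number of replicates >= k.
replicate_seeds <- function(config) {
  if (is.null(config$rng_seed)) return(rep(list(NULL), config$replicates))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(config$rng_seed)
  as.list(sample.int(2147483646L, config$replicates))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

run_staircase <- function(oracle, config, accept_level) {
  levels <- protocol_levels(config)
  if (!is.null(config$rng_seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
  }
  seeds <- replicate_seeds(config)
  reps <- purrr::map_dfr(seq_len(config$replicates), function(i) {
    if (!is.null(seeds[[i]])) set.seed(seeds[[i]])
    hit <- NA_real_
    for (lv in levels) {
      if (accept_level(oracle, lv)) { hit <- lv; break }
    }
    tibble::tibble(replicate = i, level = hit, censored = is.na(hit))
  })
  ok <- reps$level[!reps$censored]
  if (any(reps$censored))
    warning(sum(reps$censored), " replicate(s) censored at max_level; ",
            "excluded from the summary", call. = FALSE)
  summary <- if (length(ok) >= 2) summarize_replicates(ok) else
    tibble::tibble(mean = if (length(ok)) ok else NA_real_, sd = NA_real_,
                   n = length(ok))
  structure(list(replicates = reps, summary = summary, config = config),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result> ", nrow(x$replicates), " replicates; mean = ",
      signif(x$summary$mean, 5), ", sd = ", signif(x$summary$sd, 4), "\n",
      sep = "")
  if (any(x$replicates$censored))
    cat("  (", sum(x$replicates$censored), " censored)\n", sep = "")
  invisible(x)
}

#' Ascending search for the critical ignition current
#'
#' Emulates the laboratory protocol: for each replicate, raise the current
#' from `start_level` by `step_ratio` until the bed first ignites, record that
#' level, and summarize the replicate levels by mean and sample SD.
#' Replicates that never ignite by `max_level` are flagged censored and
#' excluded from the summary with a warning.
#'
#' @param oracle Function `level -> logical(1)`: does a discharge at this
#'   level ignite the bed? Its success probability must be non-decreasing in
#'   level.
#' @param config A [protocol_config()].
#' @return A `protocol_result`: `$replicates` (tibble of per-replicate levels
#'   and censoring flags), `$summary` (mean, sd, n over uncensored levels).
#' @examples
#' cfg <- protocol_config(20, 120, replicates = 5, rng_seed = 1)
#' critical_current_search(function(level) level >= 33, cfg)
#' @export
critical_current_search <- function(oracle, config) {
  stopifnot(is.function(oracle), inherits(config, "protocol_config"))
  run_staircase(oracle, config, function(orc, lv) isTRUE(orc(lv)))
}

#' Ascending search for the breakdown voltage
#'
#' At each level the oracle is tried `consecutive_successes_required` times
#' (five in the laboratory protocol); the first level where every trial
#' breaks the bed down is that replicate's breakdown voltage. Six replicates
#' (the laboratory convention) give the reported mean and SD.
#'
#' @inheritParams critical_current_search
#' @return A `protocol_result`, as for [critical_current_search()].
#' @export
breakdown_voltage_protocol <- function(oracle, config) {
  stopifnot(is.function(oracle), inherits(config, "protocol_config"))
  m <- config$consecutive_successes_required
  run_staircase(oracle, config, function(orc, lv) {
    all(vapply(seq_len(m), function(k) isTRUE(orc(lv)), logical(1)))
  })
}

#' Full factorial design grid
#'
#' Cartesian product of factor levels in deterministic lexicographic order
#' (first factor varies slowest, like nested loops).
#'
#' @param ... Either named vectors of factor levels, or a single named list of
#'   them.
#' @return A tibble with one row per combination.
#' @examples
#' design_grid(peak_ka = c(20, 50), moisture = c(0, 0.107, 0.4))
#' @export
design_grid <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]]) &&
      is.null(names(args)))
    args <- args[[1]]
  if (length(args) == 0 || is.null(names(args)) || any(names(args) == ""))
    stop("factors must be named", call. = FALSE)
  empty <- names(args)[lengths(args) == 0]
  if (length(empty)) stop("factor(s) with no levels: ",
                          paste(empty, collapse = ", "), call. = FALSE)
  do.call(tidyr::expand_grid, args)
}

#' The study's 5 x 5 x 5 factorial design
#'
#' Peak current (20, 50, 60, 80, 100 kA), bed bulk density (0.0318, 0.0637,
#' 0.1062, 0.1274, 0.1699 g/cm^3) and dry-basis moisture (0, 10.7, 40, 80,
#' 120 %) -- 125 combinations covering most natural impulse currents and
#' needle-bed packings.
#'
#' @return A 125-row tibble with columns `peak_ka`, `bulk_gcm3`, `moisture`.
#' @export
study_design_grid <- function() {
  design_grid(peak_ka = c(20, 50, 60, 80, 100),
              bulk_gcm3 = c(0.0318, 0.0637, 0.1062, 0.1274, 0.1699),
              moisture = c(0, 0.107, 0.40, 0.80, 1.20))
}
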