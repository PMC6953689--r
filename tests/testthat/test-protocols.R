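# Staircase protocol simulations.

test_that("deterministic threshold oracle stops at the first level above it", {
  cfg <- protocol_config(20, 120, step_ratio = 1.05, replicates = 5)
  res <- critical_current_search(function(level) level >= 33, cfg)
  levels <- 20 * 1.05^(0:38)
  expected <- min(levels[levels >= 33])
  expect_equal(res$replicates$level, rep(expected, 5))
  expect_equal(res$summary$sd, 0)
})

test_that("an always-igniting oracle returns the start level", {
  cfg <- protocol_config(20, 120, replicates = 3)
  res <- critical_current_search(function(level) TRUE, cfg)
  expect_equal(res$replicates$level, rep(20, 3))
})

test_that("replicates that never succeed are censored, not dropped", {
  cfg <- protocol_config(20, 120, replicates = 3, rng_seed = 1)
  expect_warning(res <- critical_current_search(function(level) FALSE, cfg),
                 "censored")
  expect_true(all(res$replicates$censored))
  expect_true(is.na(res$summary$mean))
  expect_identical(res$summary$n, 0L)
})

test_that("seeded protocol runs are bit-for-bit reproducible", {
  cfg <- protocol_config(20, 120, replicates = 5, rng_seed = 42)
  orc <- logistic_oracle(33.67, 100)
  r1 <- critical_current_search(orc, cfg)
  r2 <- critical_current_search(orc, cfg)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$summary, r2$summary)
  r3 <- critical_current_search(orc, protocol_config(20, 120, replicates = 5,
                                                     rng_seed = 43))
  expect_false(identical(r1$replicates$level, r3$replicates$level))
})

test_that("extending a seeded run does not perturb the earlier replicates", {
  orc <- logistic_oracle(33.67, 100)
  r5 <- critical_current_search(orc, protocol_config(20, 120, replicates = 5,
                                                     rng_seed = 7))
  r8 <- critical_current_search(orc, protocol_config(20, 120, replicates = 8,
                                                     rng_seed = 7))
  expect_identical(r8$replicates$level[1:5], r5$replicates$level)
})

test_that("the returned level always exceeds every failing level in its replicate", {
  log_env <- new.env()
  log_env$tested <- list()
  orc <- function(level) {
    out <- stats::runif(1) < stats::plogis(20 * log(level / 40))
    log_env$tested[[length(log_env$tested) + 1]] <- c(level, out)
    out
  }
  cfg <- protocol_config(20, 120, replicates = 4, rng_seed = 5)
  res <- critical_current_search(orc, cfg)
  hist <- do.call(rbind, log_env$tested)
  # split the trial log at each return to the start level
  starts <- which(abs(hist[, 1] - 20) < 1e-12)
  bounds <- c(starts, nrow(hist) + 1)
  for (k in seq_len(length(bounds) - 1)) {
    rep_hist <- hist[bounds[k]:(bounds[k + 1] - 1), , drop = FALSE]
    fails <- rep_hist[rep_hist[, 2] == 0, 1]
    if (length(fails) && !res$replicates$censored[k])
      expect_gte(res$replicates$level[k], max(fails))
  }
})

test_that("breakdown protocol requires five successes out of five at a level", {
  cfg <- protocol_config(5, 12, step_ratio = 1.05, replicates = 6)
  res <- breakdown_voltage_protocol(function(level) level >= 7.5, cfg)
  levels <- 5 * 1.05^(0:17)
  expected <- min(levels[levels >= 7.5])
  expect_equal(res$replicates$level, rep(expected, 6))
  expect_equal(res$summary$sd, 0)

  # with per-trial success 0.9 the per-level pass rate is 0.9^5 ~ 0.59, so
  # the accepted level drifts above an always-pass oracle's start level
  cfg2 <- protocol_config(5, 12, replicates = 6, rng_seed = 1)
  flat <- breakdown_voltage_protocol(function(level) stats::runif(1) < 0.9, cfg2)
  expect_gt(flat$summary$mean, 5)
  expect_gt(flat$summary$sd, 0)
})

test_that("a seeded breakdown search around 7.52 kV is reproducible", {
  orc <- logistic_oracle(7.52, 100)
  cfg <- protocol_config(5, 12, replicates = 6, rng_seed = 99)
  r1 <- breakdown_voltage_protocol(orc, cfg)
  r2 <- breakdown_voltage_protocol(orc, cfg)
  expect_identical(r1$replicates, r2$replicates)
  expect_equal(r1$summary$n, 6L)
  expect_lt(abs(r1$summary$mean - 7.52) / 7.52, 0.25)
})

test_that("design grids enumerate the full factorial in nested-loop order", {
  g <- study_design_grid()
  expect_equal(nrow(g), 125)
  expect_equal(nrow(dplyr::distinct(g)), 125)
  # first factor varies slowest
  expect_equal(g$peak_ka[1:25], rep(20, 25))
  g2 <- design_grid(a = 1:2, b = c(10, 20, 30))
  expect_equal(nrow(g2), 6)
  expect_equal(g2$a, rep(1:2, each = 3))
  expect_equal(g2$b, rep(c(10, 20, 30), 2))
  expect_equal(nrow(design_grid(only = 1:3)), 3)
  expect_error(design_grid(a = 1:2, b = numeric(0)), "no levels")
  expect_error(design_grid(1:3), "named")
})

test_that("design grid size is the product of level counts", {
  withr::with_seed(3, {
    for (k in 1:5) {
      sizes <- sample(1:4, sample(2:4, 1), replace = TRUE)
      fac <- lapply(sizes, function(n) sort(runif(n)))
      names(fac) <- paste0("f", seq_along(fac))
      expect_equal(nrow(design_grid(fac)), prod(sizes))
    }
  })
})

test_that("protocol configuration is validated", {
  expect_error(protocol_config(10, 5), "start_level < max_level")
  expect_error(protocol_config(10, 50, step_ratio = 1), "exceed 1")
  expect_error(protocol_config(10, 50, replicates = 0), "at least 1")
})
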