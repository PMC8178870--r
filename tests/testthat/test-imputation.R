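test_that("bounds encode observed, partial and missing cells", {
  d <- tiny_trial(n = 6)
  d <- set_cell(d, "p01", 1, 2, "partial", count = 2999, wear = 300)
  d <- set_cell(d, "p02", 1, 3, "missing")
  spec <- imputation_spec(M = 2, cycles = 1)
  b <- build_bounds(d, spec)
  U <- log(1.5 * max(d$days$step_count) + 1)
  expect_equal(b$U, U)
  # partial: [log(count + 1), U]
  expect_equal(b$lower["p01", "y1_d2"], log(3000))
  expect_equal(b$upper["p01", "y1_d2"], U)
  # missing: unbounded below
  expect_equal(b$lower["p02", "y1_d3"], -Inf)
  expect_equal(b$upper["p02", "y1_d3"], U)
  # observed: degenerate at the recorded value
  expect_equal(b$lower["p03", "y0_d1"], log(7001))
  expect_equal(b$upper["p03", "y0_d1"], log(7001))
  # dismissive treatment: partial demoted to missing
  b2 <- build_bounds(d, spec, impute_partial_as_censored = FALSE)
  expect_equal(b2$lower["p01", "y1_d2"], -Inf)
  expect_equal(b2$status["p01", "y1_d2"], "missing")
  expect_equal(b2$orig_status["p01", "y1_d2"], "partial")
  # zero-count partial carries no information
  d0 <- set_cell(d, "p03", 2, 1, "partial", count = 0, wear = 100)
  expect_warning(b3 <- build_bounds(d0, spec), "zero recorded steps")
  expect_equal(b3$status["p03", "y2_d1"], "missing")
})

test_that("a complete dataset yields M identical copies", {
  sim <- simulate_trial(sim_config(n_participants = 20, miss_rate = 0,
                                   force_full_wear = TRUE,
                                   extra_week_prob = 0, seed = 2))
  imp <- chained_impute(sim$dataset, imputation_spec(M = 3, cycles = 2))
  expect_equal(imp$log_steps[, , 1], imp$log_steps[, , 2])
  expect_equal(imp$log_steps[, , 1], imp$log_steps[, , 3])
  m <- accelmi:::day_matrices(sim$dataset)
  expect_equal(imp$log_steps[, , 1], log(m$count + 1))
})

test_that("imputation is deterministic given the seed and respects bounds", {
  sim <- simulate_trial(sim_config(n_participants = 120, miss_rate = 0.25,
                                   extra_week_prob = 0, seed = 14))
  spec <- imputation_spec(M = 2, cycles = 2, seed = 99, pool_arms = TRUE)
  imp1 <- chained_impute(sim$dataset, spec, use_auxiliaries = FALSE)
  imp2 <- chained_impute(sim$dataset, spec, use_auxiliaries = FALSE)
  expect_identical(imp1$log_steps, imp2$log_steps)
  # different seed gives different draws for incomplete cells
  imp3 <- chained_impute(sim$dataset,
                         imputation_spec(M = 2, cycles = 2, seed = 100,
                                         pool_arms = TRUE),
                         use_auxiliaries = FALSE)
  inc <- imp1$status != "observed"
  expect_gt(mean(imp1$log_steps[, , 1][inc] != imp3$log_steps[, , 1][inc]),
            0.99)
  # bound respect, all cells, all imputations
  for (mm in 1:2) {
    v <- imp1$log_steps[, , mm]
    expect_true(all(v >= imp1$lower - 1e-10 & v <= imp1$upper + 1e-10))
    # observed cells untouched
    obs <- imp1$status == "observed"
    expect_equal(v[obs], imp1$observed_log[obs])
  }
})

test_that("MCAR imputation means track the complete-data truth", {
  # truth known: compare imputed cell means against the same participants'
  # true full-day counts from the generator
  sim <- simulate_trial(sim_config(n_participants = 150, miss_rate = 0.2,
                                   mechanism = "MCAR", extra_week_prob = 0,
                                   seed = 31))
  spec <- imputation_spec(M = 4, cycles = 3, seed = 8, pool_arms = TRUE)
  imp <- chained_impute(sim$dataset, spec, use_auxiliaries = FALSE)
  truth <- sim$truth$full_day_counts
  truth <- truth[truth$week == 1, ]
  ids <- rownames(imp$log_steps)
  idx <- cbind(match(truth$participant_id, ids),
               accelmi:::yd_col(truth$year, truth$day_of_week))
  true_log <- matrix(NA_real_, length(ids), 21)
  true_log[idx] <- log(truth$y_full + 1)
  mis <- imp$status == "missing"
  imp_mean <- apply(imp$log_steps, c(1, 2), mean)
  err <- imp_mean[mis] - true_log[mis]
  # unbiased on average: mean error within 3 MC SEs of zero
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
})

test_that("more observed information reduces between-imputation variance", {
  # same world, but in the second dataset half the year-2 days are removed:
  # baseline imputations should become more variable across imputations
  base_cfg <- sim_config(n_participants = 150, miss_rate = 0.15,
                         extra_week_prob = 0, seed = 77)
  sim <- simulate_trial(base_cfg)
  d_rich <- sim$dataset
  d_poor <- d_rich
  set.seed(55)
  w1 <- d_poor$days$week == 1 & d_poor$days$year == 2 &
    d_poor$days$status == "observed"
  drop_idx <- sample(which(w1), floor(sum(w1) * 0.6))
  d_poor$days$status[drop_idx] <- "missing"
  d_poor$days$step_count[drop_idx] <- 0
  d_poor$days$wear_minutes[drop_idx] <- 0
  spec <- imputation_spec(M = 8, cycles = 3, seed = 5, pool_arms = TRUE)
  imp_rich <- chained_impute(d_rich, spec, use_auxiliaries = FALSE)
  imp_poor <- chained_impute(d_poor, spec, use_auxiliaries = FALSE)
  mis0 <- imp_rich$status[, 1:7] != "observed"   # baseline incomplete cells
  bvar <- function(imp) {
    v <- apply(imp$log_steps[, 1:7, , drop = FALSE], c(1, 2), var)
    mean(v[mis0])
  }
  expect_lt(bvar(imp_rich), bvar(imp_poor))
})

test_that("small arms fail with a pooling hint and pool_arms works", {
  sim <- simulate_trial(sim_config(n_participants = 60, miss_rate = 0.2,
                                   extra_week_prob = 0, seed = 6))
  expect_error(chained_impute(sim$dataset,
                              imputation_spec(M = 2, cycles = 1),
                              use_auxiliaries = FALSE),
               "pool_arms")
  imp <- chained_impute(sim$dataset,
                        imputation_spec(M = 2, cycles = 1,
                                        pool_arms = TRUE),
                        use_auxiliaries = FALSE)
  expect_s3_class(imp, "imputed_set")
  df <- as.data.frame(imp)
  expect_equal(nrow(df), 60 * 21 * 2)
  expect_true(all(df$steps >= 0))
})
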