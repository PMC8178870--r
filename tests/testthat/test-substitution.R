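test_that("substitution follows the status-ordering rules", {
  d <- tiny_trial(n = 3, extra_week = TRUE)
  # missing Tuesday, observed following Tuesday -> substituted
  d1 <- set_cell(d, "p01", 1, 2, "missing")
  d1 <- set_cell(d1, "p01", 1, 2, "observed", count = 8000, wear = 900,
                 wk = 2)
  out <- day_substitute(d1)
  cell <- out$days[out$days$participant_id == "p01" & out$days$year == 1 &
                     out$days$day_of_week == 2, ]
  expect_equal(cell$status, "observed")
  expect_equal(cell$step_count, 8000)
  expect_equal(cell$substituted_from, 2L)

  # missing with only a partial candidate -> partial retained (with bound)
  d2 <- set_cell(d, "p01", 1, 2, "missing")
  d2 <- set_cell(d2, "p01", 1, 2, "partial", count = 2500, wear = 300,
                 wk = 2)
  cell <- inwindow_cell(day_substitute(d2), "p01", 1, 2)
  expect_equal(cell$status, "partial")
  expect_equal(cell$step_count, 2500)

  # partial is only upgraded by an observed candidate
  d3 <- set_cell(d, "p01", 1, 2, "partial", count = 3000, wear = 300)
  d3 <- set_cell(d3, "p01", 1, 2, "partial", count = 4000, wear = 400,
                 wk = 2)
  cell <- inwindow_cell(day_substitute(d3), "p01", 1, 2)
  expect_equal(cell$status, "partial")
  expect_equal(cell$step_count, 3000)
  expect_true(is.na(cell$substituted_from))

  # observed in-window days are never altered
  d4 <- set_cell(d, "p01", 1, 2, "observed", count = 1234, wear = 700,
                 wk = 2)
  cell <- inwindow_cell(day_substitute(d4), "p01", 1, 2)
  expect_equal(cell$step_count, 7000)
  expect_true(is.na(cell$substituted_from))

  # observed beats partial when both candidates exist
  d5 <- set_cell(d, "p02", 2, 5, "missing")
  d5 <- set_cell(d5, "p02", 2, 5, "observed", count = 9000, wear = 800,
                 wk = 2)
  # (the week-2 grid has all 7 days; make another day partial to tempt)
  cell <- inwindow_cell(day_substitute(d5), "p02", 2, 5)
  expect_equal(cell$step_count, 9000)
})

test_that("substitution is idempotent and monotone in status counts", {
  set.seed(5)
  sim <- simulate_trial(sim_config(n_participants = 40, miss_rate = 0.3,
                                   extra_week_prob = 1, seed = 5))
  once <- day_substitute(sim$dataset)
  n_obs <- function(d) sum(d$days$status[d$days$week == 1] == "observed")
  n_mis <- function(d) sum(d$days$status[d$days$week == 1] == "missing")
  expect_gte(n_obs(once), n_obs(sim$dataset))
  expect_lte(n_mis(once), n_mis(sim$dataset))
  # idempotence: week-2 records are consumed, a second pass is a no-op
  twice <- day_substitute(once)
  expect_identical(once$days, twice$days)
})

test_that("the report matches a brute-force recount", {
  set.seed(9)
  sim <- simulate_trial(sim_config(n_participants = 30, miss_rate = 0.3,
                                   extra_week_prob = 1, seed = 9))
  after <- day_substitute(sim$dataset)
  rep_tab <- substitution_report(sim$dataset, after)
  overall <- attr(rep_tab, "overall")
  # brute force: align the two day tables cell by cell
  b <- sim$dataset$days[sim$dataset$days$week == 1, ]
  a <- after$days
  key <- function(d) paste(d$participant_id, d$year, d$day_of_week)
  a <- a[match(key(b), key(a)), ]
  brute <- table(factor(b$status, c("observed", "partial", "missing")),
                 factor(a$status, c("observed", "partial", "missing")))
  expect_equal(as.vector(overall), as.vector(brute))
  expect_equal(sum(rep_tab$n), nrow(b))
  # identity run: diagonal only
  same <- substitution_report(sim$dataset, sim$dataset)
  expect_true(all(same$status_before == same$status_after))
})

test_that("substituted cells look exchangeable when weeks share one law", {
  set.seed(21)
  sim <- simulate_trial(sim_config(n_participants = 150, miss_rate = 0.3,
                                   extra_week_prob = 1, seed = 21))
  after <- day_substitute(sim$dataset)
  sub <- after$days[!is.na(after$days$substituted_from) &
                      after$days$status == "observed", ]
  ref <- sim$dataset$days[sim$dataset$days$week == 1 &
                            sim$dataset$days$status == "observed", ]
  ls <- log(sub$step_count + 1)
  lr <- log(ref$step_count + 1)
  se <- sqrt(var(ls) / length(ls) + var(lr) / length(lr))
  expect_lt(abs(mean(ls) - mean(lr)), 3 * se)
})

test_that("sunshine matching picks the closest week-2 day", {
  d <- tiny_trial(n = 3, extra_week = TRUE)
  d <- set_cell(d, "p01", 0, 3, "missing")
  # make week-2 sunshine values known: target day sunshine = 5
  a <- d$aux
  sel1 <- a$participant_id == "p01" & a$year == 0 & a$week == 1 &
    a$day_of_week == 3
  a$sunshine[sel1] <- 5
  sel2 <- a$participant_id == "p01" & a$year == 0 & a$week == 2
  a$sunshine[sel2] <- c(9, 8, 7, 6, 5.4, 3, 1)  # day 5 is nearest
  d <- trial_dataset(d$days, d$participants, a)
  out <- day_substitute(d, strategy = "sunshine")
  cell <- inwindow_cell(out, "p01", 0, 3)
  w2 <- d$days[d$days$week == 2 & d$days$participant_id == "p01" &
                 d$days$year == 0 & d$days$day_of_week == 5, ]
  expect_equal(cell$step_count, w2$step_count)
  expect_equal(cell$substituted_from, 2L)
  # without week-2 auxiliaries the strategy refuses
  d_noaux <- tiny_trial(n = 3, extra_week = TRUE)
  d_noaux$aux <- d_noaux$aux[d_noaux$aux$week == 1, ]
  d_noaux <- set_cell(d_noaux, "p01", 0, 3, "missing")
  expect_error(day_substitute(d_noaux, strategy = "sunshine"),
               "week-2 auxiliaries")
})
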