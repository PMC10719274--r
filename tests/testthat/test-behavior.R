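test_that("subjective value follows the hyperbolic form", {
  expect_equal(subjective_value(10000, 0, 0.0164), 10000)
  expect_equal(subjective_value(20000, 100, 0.01), 10000)
  expect_lt(abs(subjective_value(48000, 180, 0.0164) - 12145.75), 0.01)
  expect_error(subjective_value(-1, 10, 0.1), "positive")
  expect_error(subjective_value(100, -1, 0.1), "nonnegative")
  expect_error(subjective_value(100, 1, -0.1), "nonnegative")
})

test_that("subjective value is strictly monotone in delay and amount", {
  set.seed(101)
  for (i in 1:50) {
    A <- runif(1, 1000, 50000)
    k <- runif(1, 1e-4, 1)
    d1 <- runif(1, 0, 150)
    d2 <- d1 + runif(1, 0.5, 30)
    expect_lt(subjective_value(A, d2, k), subjective_value(A, d1, k))
    expect_gt(subjective_value(A * 1.2, d1, k), subjective_value(A, d1, k))
  }
})

test_that("choice probability is a logistic in the value difference", {
  # zero sensitivity means indifference whatever the options
  expect_equal(choice_probability(10000, 30000, 50, 0.01, 0), 0.5)
  # equal subjective values give 0.5 at any beta (kD = 1 halves 20000)
  expect_equal(choice_probability(10000, 20000, 100, 0.01, 0.001), 0.5)
  expect_equal(choice_probability(10000, 20000, 100, 0.01, 2), 0.5)
  p1 <- choice_probability(10000, 20000, 50, 0.01, 0.001)
  p2 <- choice_probability(10000, 30000, 50, 0.01, 0.001)
  expect_gt(p1, 0.5)
  expect_gt(p2, p1)
  expect_true(p2 < 1)
  expect_error(choice_probability(10000, 20000, 50, 0.01, -1), "beta")
})

test_that("single-option responders are flagged with the right reason", {
  all_del <- data.frame(choice = rep(1, 120))
  all_imm <- data.frame(choice = rep(0, 120))
  mixed <- data.frame(choice = c(rep(1, 119), 0))
  expect_true(detect_degenerate(all_del)$excluded)
  expect_identical(detect_degenerate(all_del)$reason, "always-delayed")
  expect_true(detect_degenerate(all_imm)$excluded)
  expect_identical(detect_degenerate(all_imm)$reason, "always-immediate")
  expect_false(detect_degenerate(mixed)$excluded)
  expect_error(detect_degenerate(data.frame(choice = numeric(0))), "empty")
})

test_that("the optimizer attains the likelihood-surface maximum (grid oracle)", {
  for (s in 1:3) {
    set.seed(700 + s)
    k_true <- 10^runif(1, -2.5, -1.2)
    tr <- simulate_choices(k_true, 0.005, task_design(n_trials = 20),
                           seed = 7000 + s)
    if (detect_degenerate(tr)$excluded) next
    fit <- fit_discounting(tr)
    oracle_nll <- dd_grid_scan(tr)
    expect_lte(-fit$log_likelihood, oracle_nll + 1e-6)
  }
})

test_that("the discount rate is recovered from simulated choices", {
  tr <- simulate_choices(0.0164, 0.005, seed = 42)
  fit <- fit_discounting(tr)
  expect_true(fit$converged)
  # factor-2 band around the true rate
  expect_gte(fit$k, 0.008)
  expect_lte(fit$k, 0.033)
  expect_equal(fit$log_k, log10(fit$k))
  expect_lte(fit$log_likelihood, 0)
})

test_that("a deterministic responder drives beta up and k to its threshold", {
  set.seed(77)
  k0 <- 0.02
  design <- task_design()
  amounts <- seq(11000, 48000, by = 1000)
  tr <- data.frame(immediate_amount = 10000,
                   delayed_amount = sample(amounts, 120, replace = TRUE),
                   delay_days = sample(2:180, 120, replace = TRUE))
  sv <- subjective_value(tr$delayed_amount, tr$delay_days, k0)
  tr$choice <- as.integer(sv > 10000)
  fit <- fit_discounting(tr)
  # perfectly separable data: likelihood approaches 0 from below and the
  # recovered k sits at the preference threshold
  expect_gt(fit$log_likelihood, -0.5)
  expect_lt(abs(fit$log_k - log10(k0)), 0.2)
})

test_that("degenerate choice data are refused by the fitter", {
  tr <- simulate_choices(0.0164, 0.005, seed = 1)
  tr$choice <- 1
  expect_error(fit_discounting(tr), "degenerate preference")
})

test_that("BIS-11 scoring spans 30..120 and partitions into subscales", {
  key <- bis11_key()
  expect_setequal(key$item, 1:30)
  expect_equal(sum(key$subscale == "attentional"), 8)
  expect_equal(sum(key$subscale == "motor"), 11)
  expect_equal(sum(key$subscale == "non_planning"), 11)

  # responses that score 1 on every item after reversal
  lo <- ifelse(key[order(key$item), ]$reverse, 4L, 1L)
  hi <- ifelse(key[order(key$item), ]$reverse, 1L, 4L)
  expect_equal(score_bis(lo)$total, 30)
  expect_equal(score_bis(hi)$total, 120)

  set.seed(5)
  for (i in 1:10) {
    s <- score_bis(sample(1:4, 30, replace = TRUE))
    expect_equal(s$total, s$attentional + s$motor + s$non_planning)
    expect_gte(s$total, 30)
    expect_lte(s$total, 120)
  }
})

test_that("BIS scoring rejects malformed responses naming the item", {
  items <- sample(1:4, 30, replace = TRUE)
  bad <- items
  bad[17] <- 5L
  expect_error(score_bis(bad), "item 17")
  expect_error(score_bis(items[-1]), "30 items")
  nas <- items
  nas[3] <- NA
  expect_error(score_bis(nas), "item 3")
})

test_that("BIS scoring is invariant to item permutation with a relabeled key", {
  set.seed(9)
  key <- bis11_key()
  items <- sample(1:4, 30, replace = TRUE)
  ref <- score_bis(items, key)
  perm <- sample(30)
  key_perm <- key[match(perm, key$item), ]
  key_perm$item <- 1:30
  got <- score_bis(items[perm], key_perm)
  expect_equal(got$total, ref$total)
  expect_equal(got$attentional, ref$attentional)
  expect_equal(got$motor, ref$motor)
  expect_equal(got$non_planning, ref$non_planning)
})

test_that("cohort-level fitting flags excluded subjects and fits the rest", {
  spec <- cohort_spec(n_subjects = 6, n_nodes = 30, seed = 3)
  sim <- simulate_cohort(spec)
  choices <- sim$choices
  # force one degenerate subject
  choices$choice[choices$subject_id == "sub002"] <- 1
  fits <- fit_dd_cohort(choices)
  expect_equal(nrow(fits), 6)
  expect_true(fits$excluded[fits$subject_id == "sub002"])
  expect_identical(fits$reason[fits$subject_id == "sub002"], "always-delayed")
  expect_true(all(!fits$excluded[fits$subject_id != "sub002"]))
  expect_true(all(is.finite(fits$k[!fits$excluded])))
})
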