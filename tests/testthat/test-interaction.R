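# Abundance-weighted expected CUE and the sequential one-sided classifier.

test_that("expected CUE is the abundance-weighted monoculture mixture", {
  a <- c(0.8, 0.8, 0.8); b <- c(0.2, 0.2, 0.2)
  # degenerate weight: all of species A
  e1 <- expected_cue(c(0.7, 0.8, 0.9), b, p_a = 1)
  expect_equal(e1$mu2, 0.8)
  expect_equal(e1$sd2, sd(c(0.7, 0.8, 0.9)))
  # midpoint
  expect_equal(expected_cue(a, b, p_a = 0.5)$mu2, 0.5)
  # the fraction at the study's median final ratio
  e3 <- expected_cue(a, b, p_a = 0.0347)
  expect_equal(e3$mu2, 0.0347 * 0.8 + 0.9653 * 0.2, tolerance = 1e-12)
  expect_equal(e3$mu2, 0.2208, tolerance = 1e-4)
  expect_equal(e3$sd2, 0)
  expect_equal(e3$n_effective, 3)
  # domain errors
  expect_error(expected_cue(a, b, p_a = 1.2), "\\[0, 1\\]")
  expect_error(expected_cue(a, b, p_a = 0.4, p_b = 0.7), "equal 1")
  expect_error(expected_cue(0.8, b, p_a = 0.5), ">= 2")
})

test_that("expected CUE is label-symmetric and bounded by the monoculture means", {
  set.seed(31)
  for (i in 1:100) {
    a <- rnorm(3, runif(1), 0.05)
    b <- rnorm(sample(2:5, 1), runif(1), 0.05)
    p <- runif(1)
    e_ab <- expected_cue(a, b, p_a = p)
    e_ba <- expected_cue(b, a, p_a = 1 - p)
    expect_equal(e_ab$mu2, e_ba$mu2)
    expect_equal(e_ab$sd2, e_ba$sd2)
    expect_gte(e_ab$mu2, min(mean(a), mean(b)) - 1e-12)
    expect_lte(e_ab$mu2, max(mean(a), mean(b)) + 1e-12)
  }
})

test_that("variance propagation modes behave as documented", {
  a <- c(0.7, 0.8, 0.9); b <- c(0.1, 0.2, 0.3)
  e <- expected_cue(a, b, p_a = 0.3)
  expect_equal(e$sd2^2, 0.3^2 * var(a) + 0.7^2 * var(b))
  ep <- expected_cue(a, b, p_a = 0.3, variance_mode = "pooled")
  expect_equal(ep$sd2^2, (2 * var(a) + 2 * var(b)) / 4)
  expect_equal(ep$mu2, e$mu2)
})

test_that("the sequential classifier reproduces the decision tree on toy inputs", {
  # summary with mu2 = 0.5, sd2 = 0.01, n_eff = 3 via a degenerate weight
  exp_mid <- expected_cue(exact_moment_sample(0.5, 0.01, 3),
                          exact_moment_sample(0, 1, 3), p_a = 1)
  # measured far above mu2: positive
  up <- classify_interaction(c(0.90, 0.91, 0.92), exp_mid)
  expect_equal(up$mode, "positive")
  expect_lt(up$p_pos, 1e-4)
  expect_true(is.na(up$p_neg))
  # mirrored far below: negative
  dn <- classify_interaction(c(0.10, 0.11, 0.12), exp_mid)
  expect_equal(dn$mode, "negative")
  expect_lt(dn$p_neg, 1e-4)
  expect_gte(dn$p_pos, 0.05)
  # measured equal to expected replicate-for-replicate: unresolved
  same <- classify_interaction(exact_moment_sample(0.5, 0.01, 3), exp_mid)
  expect_equal(same$mode, "unresolved")
  # degenerate: all dispersion zero with equal means
  e0 <- expected_cue(c(0.5, 0.5), c(0.5, 0.5), p_a = 0.5)
  z <- classify_interaction(c(0.5, 0.5), e0)
  expect_equal(z$mode, "unresolved")
  expect_equal(z$p_pos, 1)
  expect_error(classify_interaction(0.9, exp_mid), "2 measured")
})

test_that("the classifier agrees with a brute-force Welch t-test oracle", {
  # oracle: rebuild the expected-CUE summary as an explicit sample with the
  # exact mean/sd and run stats::t.test one-sided in both directions
  set.seed(77)
  alpha <- 0.05
  for (i in 1:400) {
    measured <- rnorm(3, runif(1, 0, 1), runif(1, 0.005, 0.1))
    mu2 <- runif(1, 0, 1); sd2 <- runif(1, 0.005, 0.1); n2 <- sample(2:5, 1)
    exp_obj <- expected_cue(exact_moment_sample(mu2, sd2, n2),
                            exact_moment_sample(0, 1, n2), p_a = 1)
    stopifnot(abs(exp_obj$mu2 - mu2) < 1e-9)
    got <- classify_interaction(measured, exp_obj, alpha = alpha)

    x2 <- exact_moment_sample(mu2, sd2, n2)
    p_greater <- t.test(measured, x2, alternative = "greater")$p.value
    p_less <- t.test(measured, x2, alternative = "less")$p.value
    want <- if (p_greater < alpha) "positive"
            else if (p_less < alpha) "negative" else "unresolved"
    expect_equal(got$mode, want)
    expect_equal(got$p_pos, p_greater, tolerance = 1e-9)
  }
})

test_that("raising every measured replicate never moves a call toward negative", {
  rank_of <- c(negative = 1, unresolved = 2, positive = 3)
  e <- expected_cue(c(0.45, 0.5, 0.55), c(0.1, 0.15, 0.2), p_a = 0.5)
  measured <- c(0.18, 0.22, 0.26)
  shifts <- seq(0, 0.4, by = 0.02)
  modes <- vapply(shifts, function(s) {
    classify_interaction(measured + s, e)$mode
  }, character(1))
  expect_true(all(diff(rank_of[modes]) >= 0))
})

test_that("bounds precheck implements the simple comparison rules", {
  expect_equal(bounds_precheck(0.95, 0.8, 0.2), "positive")
  expect_equal(bounds_precheck(0.1, 0.8, 0.2), "negative")
  expect_equal(bounds_precheck(0.5, 0.8, 0.2), "unresolved")
  # ordering of the monoculture means is internal
  expect_equal(bounds_precheck(0.95, 0.2, 0.8), "positive")
})

test_that("t-test call agrees with a decisive bounds precheck as dispersion vanishes", {
  set.seed(55)
  for (i in 1:100) {
    ma <- runif(1, 0.5, 0.9); mb <- runif(1, 0.05, 0.4)
    a <- exact_moment_sample(ma, 1e-6, 3)
    b <- exact_moment_sample(mb, 1e-6, 3)
    m_mean <- runif(1, -0.2, 1.2)
    measured <- exact_moment_sample(m_mean, 1e-6, 3)
    pre <- bounds_precheck(m_mean, ma, mb)
    call <- classify_interaction(measured,
                                 expected_cue(a, b, p_a = runif(1)))$mode
    if (pre != "unresolved") expect_equal(call, pre)
  }
})

test_that("null and planted-effect calibration of the sequential procedure", {
  # Under the null the two disjoint one-sided 5% rejection tails give a
  # combined positive+negative call rate near 2 * alpha.
  set.seed(101)
  n_sim <- 1000
  sigma <- 0.05
  null_calls <- replicate(n_sim, {
    a <- rnorm(3, 0.6, sigma); b <- rnorm(3, 0.2, sigma); p <- runif(1)
    e <- expected_cue(a, b, p_a = p)
    truth_mu <- p * 0.6 + (1 - p) * 0.2
    classify_interaction(rnorm(3, truth_mu, sigma), e)$mode
  })
  rate <- mean(null_calls != "unresolved")
  half <- 2.576 * sqrt(0.1 * 0.9 / n_sim)
  expect_gt(rate, 0.10 - half)
  expect_lt(rate, 0.10 + half)

  # with a 5 sigma planted shift the mode is recovered nearly always
  set.seed(102)
  rec <- replicate(400, {
    a <- rnorm(3, 0.6, sigma); b <- rnorm(3, 0.2, sigma); p <- runif(1)
    e <- expected_cue(a, b, p_a = p)
    truth_mu <- p * 0.6 + (1 - p) * 0.2
    sgn <- sample(c(-1, 1), 1)
    got <- classify_interaction(rnorm(3, truth_mu + sgn * 5 * sigma, sigma),
                                e)$mode
    got == ifelse(sgn > 0, "positive", "negative")
  })
  expect_gte(mean(rec), 0.95)
})

test_that("experiment-level classification recovers planted modes and summaries partition", {
  n <- 12
  ispec <- rbind(
    data.frame(culture = "1:1", carbon_id = sprintf("C%02d", 1:4),
               mode = "positive", delta = 0.15),
    data.frame(culture = "1:1", carbon_id = sprintf("C%02d", 5:8),
               mode = "negative", delta = 0.15))
  cfg <- small_config(n_carbons = n, cue_noise_sd = 0.01, seed = 13,
                      interaction_spec = ispec)
  ex <- generate_experiment(cfg)
  cue <- pipeline_cue(ex)
  sc <- fit_standard_curve(ex$standards$concentration, ex$standards$ct)
  fr <- final_ratios(ex$qpcr, sc)
  calls <- classify_interactions(cue, fr)
  expect_s3_class(calls, "interaction_calls")
  expect_equal(nrow(calls), 3 * n)
  truth <- ex$truth$interactions
  key <- paste(truth$culture, truth$carbon_id)
  planted <- truth$mode[match(paste(calls$culture, calls$carbon_id), key)]
  planted[planted == "neutral"] <- "unresolved"
  sel <- calls$culture == "1:1"
  expect_gte(mean(calls$mode[sel] == planted[sel]), 0.9)

  smry <- summarize_interactions(calls)
  expect_equal(smry$positive + smry$negative + smry$unresolved,
               rep(1, nrow(smry)))
  # stratified proportions partition the unstratified calls
  ann <- data.frame(carbon_id = sprintf("C%02d", 1:n),
                    usage_group = rep(c("U1", "U2"), each = n / 2))
  strat <- summarize_interactions(calls, ann, by = "usage_group")
  for (cc in unique(smry$culture)) {
    sub <- strat[strat$culture == cc, ]
    tot <- smry[smry$culture == cc, ]
    expect_equal(sum(sub$n), tot$n)
    expect_equal(sum(sub$n * sub$positive), tot$n * tot$positive)
  }
})
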