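# Independent dense-grid quadrature oracle for the JZS two-sample Bayes
# factor: trapezoidal integration over log(g), written without reference to
# the package's integrate()-based implementation.
jzs_bf_oracle <- function(x, y, rscale = sqrt(2) / 2) {
  n1 <- length(x); n2 <- length(y)
  nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / nu
  neff <- n1 * n2 / (n1 + n2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 / neff)
  lg <- seq(-12, 12, length.out = 20001)
  g <- exp(lg)
  dens <- (rscale^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-rscale^2 / (2 * g))
  like <- (1 + neff * g)^(-0.5) * (1 + t^2 / ((1 + neff * g) * nu))^(-(nu + 1) / 2)
  num <- sum(like * dens * g) * (lg[2] - lg[1]) # d g = g d(log g)
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  log(num / den)
}

test_that("JZS Bayes factor matches a dense-grid quadrature oracle", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(25 + i, 0, 1)
    y <- rnorm(30, i / 10, 1.2)
    got <- bayes_t_test(x, y, auto_rank = FALSE)
    expect_equal(as.numeric(got), jzs_bf_oracle(x, y), tolerance = 1e-4)
  }
})

test_that("Bayes factor favours the null for one common distribution and a big effect otherwise", {
  set.seed(32)
  x <- rnorm(150); y <- rnorm(150)
  expect_lt(as.numeric(bayes_t_test(x, y, auto_rank = FALSE)), 0)
  x2 <- rnorm(30, 0, 1); y2 <- rnorm(30, 2, 1) # d = 2
  expect_gt(as.numeric(bayes_t_test(x2, y2, auto_rank = FALSE)), 3)
})

test_that("Bayes factor is invariant to affine transforms and symmetric in magnitude", {
  set.seed(33)
  x <- rnorm(20, 5, 2); y <- rnorm(25, 6, 2)
  a <- bayes_t_test(x, y, auto_rank = FALSE)
  b <- bayes_t_test(3 * x - 7, 3 * y - 7, auto_rank = FALSE)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-8)
  swapped <- bayes_t_test(y, x, auto_rank = FALSE)
  expect_equal(as.numeric(a), as.numeric(swapped), tolerance = 1e-8)
  expect_equal(attr(a, "t"), -attr(swapped, "t"))
})

test_that("non-normal samples are rank-transformed when auto_rank is set", {
  set.seed(34)
  x <- rexp(40); y <- rexp(40, 0.5)
  r <- bayes_t_test(x, y)
  expect_true(attr(r, "rank_transformed"))
  rn <- bayes_t_test(rnorm(40), rnorm(40))
  expect_false(attr(rn, "rank_transformed"))
  expect_error(bayes_t_test(rep(1, 10), rep(1, 12), auto_rank = FALSE), "variance")
  expect_error(bayes_t_test(1, rnorm(5)), "n >= 2")
})

test_that("directed and undirected hypothesis decisions follow the draws", {
  fake <- structure(list(draws = cbind(b_x = c(rep(1, 900), rep(0.5, 100)))),
                    class = "fit_result")
  h <- test_hypothesis(fake, "b_x", directed = TRUE)
  expect_equal(h$posterior_probability, 1)
  expect_true(h$supported)
  sym <- structure(list(draws = cbind(b_x = c(seq(-1, 1, length.out = 2000)))),
                   class = "fit_result")
  h2 <- test_hypothesis(sym, "b_x", directed = TRUE)
  expect_equal(h2$posterior_probability, 0.5, tolerance = 0.01)
  expect_false(h2$supported)
  h3 <- test_hypothesis(sym, "b_x", directed = FALSE)
  expect_false(h3$supported)
  expect_equal(h3$lower, quantile(sym$draws[, "b_x"], 0.025, names = FALSE))
  # weighted contrasts and unknown parameters
  two <- structure(list(draws = cbind(b_a = rnorm(500, 2, 0.1),
                                      b_b = rnorm(500, 1, 0.1))),
                   class = "fit_result")
  hw <- test_hypothesis(two, c(b_a = 1, b_b = -2), directed = TRUE, direction = "<")
  expect_equal(hw$estimate, 0, tolerance = 0.05)
  expect_error(test_hypothesis(two, "b_missing"), "unknown parameter")
})

test_that("the ratings model recovers its generative coefficients", {
  # generative truth: dyad type -3.87, synchrony 0.83 on +/-1 codes
  des <- study_design(n_observers_per_group = c(30, 30), seed = 41)
  agg <- prepare_behavioural_table(gen_ratings(des))
  fit <- fit_mixed_model(agg, model_spec(
    "rating", ~ group_c * dyad_type_c * ips_c,
    list(participant_id = "1", dyad_id = "1"),
    chains = 3, draws = 1500, warmup = 1000, seed = 42))
  ps <- posterior_summary(fit)
  dt <- ps[ps$parameter == "b_dyad_type_c", ]
  expect_gt(-3.87, dt$lower); expect_lt(-3.87, dt$upper)
  ip <- ps[ps$parameter == "b_ips_c", ]
  expect_gt(0.83, ip$lower); expect_lt(0.83, ip$upper)
  # +/-1 coding: the marginal condition difference is twice the coefficient
  md <- marginal_difference(fit, "dyad_type_c")
  expect_equal(mean(md), 2 * dt$mean, tolerance = 1e-6)
  # row order does not matter beyond MCMC noise (fixed seed, same design)
  shuffled <- agg[sample(nrow(agg)), ]
  fit2 <- fit_mixed_model(shuffled, fit$spec)
  ps2 <- posterior_summary(fit2)
  expect_equal(ps2$mean[ps2$parameter == "b_dyad_type_c"], dt$mean, tolerance = 0.2)
})

test_that("null effects are covered by the 95% intervals at close to nominal rate", {
  covered <- 0; total <- 0
  for (s in 1:10) {
    des <- study_design(n_observers_per_group = c(8, 8), effects = c(),
                        sd_participant = 4, sd_dyad = 2, sigma = 8,
                        miss_prob = 0, seed = 500 + s)
    agg <- prepare_behavioural_table(gen_ratings(des))
    fit <- fit_mixed_model(agg, model_spec(
      "rating", ~ group_c * dyad_type_c * ips_c,
      list(participant_id = "1", dyad_id = "1"),
      chains = 2, draws = 600, warmup = 600, seed = s),
      rhat_max = 1.05)
    ps <- posterior_summary(fit, level = 0.95)
    eff <- ps[grepl("^b_", ps$parameter) & ps$parameter != "b_(Intercept)", ]
    covered <- covered + sum(eff$lower <= 0 & eff$upper >= 0)
    total <- total + nrow(eff)
  }
  expect_gte(covered / total, 0.9)
})

test_that("the Poisson model recovers the group saccade rates", {
  set.seed(51)
  tab <- expand.grid(participant_id = sprintf("s%02d", 1:24),
                     dyad_id = sprintf("d%d", 1:8),
                     condition = c("high", "low"), segment = 1:4,
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(as.integer(sub("s", "", tab$participant_id)) <= 12, "ASD", "COMP")
  tab$dyad_type <- ifelse(tab$dyad_id %in% sprintf("d%d", 1:4), "mixed", "non-autistic")
  tab$n_saccades <- rpois(nrow(tab), ifelse(tab$group == "ASD", 17.7, 20.2))
  fit <- fit_mixed_model(tab, model_spec(
    "n_saccades", ~ group_c * dyad_type_c * ips_c,
    list(participant_id = "1", dyad_id = "1"), likelihood = "poisson",
    chains = 2, draws = 1500, warmup = 1000, seed = 52))
  md <- marginal_difference(fit, "group_c")
  asd <- attr(md, "rate_plus"); comp <- attr(md, "rate_minus")
  expect_gt(17.7, quantile(asd, 0.025)); expect_lt(17.7, quantile(asd, 0.975))
  expect_gt(20.2, quantile(comp, 0.025)); expect_lt(20.2, quantile(comp, 0.975))
  # log group difference covered too
  lg <- log(fit$draws[, "b_group_c"] * 0 + attr(md, "rate_plus")) -
    log(attr(md, "rate_minus"))
  expect_gt(log(17.7 / 20.2), quantile(lg, 0.025))
  expect_lt(log(17.7 / 20.2), quantile(lg, 0.975))
})

test_that("posterior predictive quantiles are calibrated on self-generated data", {
  des <- study_design(n_observers_per_group = c(6, 6), seed = 61, miss_prob = 0)
  agg <- prepare_behavioural_table(gen_ratings(des))
  fit <- fit_mixed_model(agg, model_spec(
    "rating", ~ group_c * dyad_type_c * ips_c,
    list(participant_id = "1", dyad_id = "1"),
    chains = 2, draws = 800, warmup = 600, seed = 62), rhat_max = 1.05)
  pc <- predictive_check(fit, statistic = "mean", type = "posterior", nrep = 200)
  expect_true(all(pc$quantile > 0.01 & pc$quantile < 0.99))
  # prior predictive spans the outcome scale generously
  pp <- predictive_check(fit, statistic = "sd", type = "prior", nrep = 100)
  expect_true(all(is.finite(pp$quantile)))
})

test_that("degenerate model inputs are rejected", {
  des <- study_design(n_observers_per_group = c(4, 4), seed = 71)
  agg <- contrast_codes(prepare_behavioural_table(gen_ratings(des)))
  agg$clone <- agg$group_c
  expect_error(fit_mixed_model(agg, model_spec(
    "rating", ~ group_c + clone, list())), "rank-deficient")
  one <- agg[agg$group == "ASD", ]
  expect_error(fit_mixed_model(one, model_spec(
    "rating", ~ group_c, list())), "2 observed levels|rank-deficient")
})
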