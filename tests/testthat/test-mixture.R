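# Latent-class machinery: membership, unconditional likelihood, estimation,
# posteriors and shares.

test_that("membership probabilities: uniform, logistic hand value, S = 1", {
  p <- tiny_panel()
  spec <- model_spec(list(segment_spec("RUM", "a1"), segment_spec("RRM", "a1")),
                     membership = "female")
  params <- parameter_set(spec)
  P <- membership_probabilities(p$z, params$gamma, spec)
  expect_equal(P, matrix(0.5, 3, 2))

  # non-base constant 0.892 and female coefficient 0.869:
  # a male respondent's non-base probability is logistic(0.892)
  params$gamma[[2]][] <- c(0.892, 0.869)
  P <- membership_probabilities(p$z, params$gamma, spec)
  expect_equal(P[1, 2], exp(0.892) / (1 + exp(0.892)), tolerance = 1e-12)
  expect_equal(P[1, 2], 0.709, tolerance = 1e-3)
  expect_equal(P[2, 2], plogis(0.892 + 0.869), tolerance = 1e-12)
  expect_equal(rowSums(P), rep(1, 3))

  s1 <- model_spec(list(segment_spec("RUM", "a1")))
  expect_equal(membership_probabilities(p$z, parameter_set(s1)$gamma, s1),
               matrix(1, 3, 1))
})

test_that("unconditional log-likelihood: closed form, collapse, oracle", {
  spec <- model_spec(list(segment_spec("RUM", c("mean_exposure", "travel_time"))))
  tp <- parameter_set(spec)
  tp$beta[[1]][] <- c(-0.1, -0.1)
  d <- generate_design(20, seed = 31)
  pan <- simulate_choices(d, spec, tp, seed = 32)
  # all-zero coefficients: LL = -K * C * ln 3 with K = 5 occasions
  expect_equal(unconditional_loglik(pan, spec, parameter_set(spec)),
               -5 * 20 * log(3), tolerance = 1e-12)

  # S = 2 with identical segment parameters collapses to the S = 1 value
  spec2 <- model_spec(list(segment_spec("RUM", c("mean_exposure", "travel_time")),
                           segment_spec("RUM", c("mean_exposure", "travel_time"))),
                      membership = "female")
  z <- generate_covariates(20, seed = 33)
  pan$z <- z
  tp2 <- parameter_set(spec2)
  tp2$beta[[1]][] <- c(-0.1, -0.1)
  tp2$beta[[2]][] <- c(-0.1, -0.1)
  tp2$gamma[[2]][] <- c(1.3, -0.4)
  ll1 <- unconditional_loglik(pan, spec, tp)
  expect_equal(unconditional_loglik(pan, spec2, tp2), ll1, tolerance = 1e-12)

  # brute-force enumeration oracle on the tiny fixture
  p <- tiny_panel()
  spec_m <- model_spec(list(segment_spec("RRM", c("a1", "time")),
                            segment_spec("RUM", c("a1", "a2", "time"))),
                       membership = "female")
  pm <- parameter_set(spec_m)
  pm$beta[[1]][] <- c(-1.2, -0.07)
  pm$beta[[2]][] <- c(0.9, -0.5, -0.04)
  pm$gamma[[2]][] <- c(0.4, -0.8)
  expect_equal(unconditional_loglik(p, spec_m, pm),
               oracle_loglik(p, spec_m, pm), tolerance = 1e-10)
})

test_that("analytic score matches central finite differences", {
  pan <- tiny_panel()
  spec <- model_spec(list(segment_spec("RRM", c("a1", "time")),
                          segment_spec("RUM", c("a1", "a2", "time"))),
                     membership = "female")
  n <- length(flatten_params(parameter_set(spec), spec))
  set.seed(3)
  for (rep in 1:5) {
    theta <- rnorm(n, sd = 0.7)
    ag <- lcchoice:::.loglik_and_grad(pan, spec,
                                      unflatten_params(theta, spec))
    fd <- vapply(seq_len(n), function(i) {
      h <- 1e-6
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (unconditional_loglik(pan, spec, unflatten_params(tp, spec)) -
         unconditional_loglik(pan, spec, unflatten_params(tm, spec))) / (2 * h)
    }, 0)
    expect_equal(ag$grad, fd, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(ag$loglik,
                 unconditional_loglik(pan, spec,
                                      unflatten_params(theta, spec)))
  }
})

test_that("posteriors follow Bayes rule and shares average memberships", {
  # equal priors, conditional likelihoods (0.008, 0.002) -> posterior (0.8, 0.2)
  P <- matrix(0.5, 1, 2)
  lcs <- log(matrix(c(0.008, 0.002), 1))
  post <- lcchoice:::.posterior_from(P, lcs)
  expect_equal(post[1, ], c(0.8, 0.2))

  expect_equal(population_shares(matrix(c(0.2, 0.6, 0.8, 0.4), 2)),
               c(0.4, 0.6))
  expect_equal(population_shares(matrix(1 / 4, 6, 4)), rep(0.25, 4))
})

test_that("single-segment RUM estimates match glm's conditional-logit fit", {
  # with I = 2 alternatives the MNL is a binary logit on attribute
  # differences, so glm() is an independent oracle for the estimates
  set.seed(61)
  n <- 400
  x <- array(rnorm(n * 2 * 2), dim = c(n, 2, 2),
             dimnames = list(NULL, NULL, c("a", "b")))
  spec <- model_spec(list(segment_spec("RUM", c("a", "b"))))
  tp <- parameter_set(spec)
  tp$beta[[1]][] <- c(1.0, -0.7)
  skel <- choice_panel(x, rep(NA_integer_, n), resp = seq_len(n))
  pan <- simulate_choices(skel, spec, tp, seed = 62)
  fit <- lc_choice(pan, spec, n_starts = 1, tol = 1e-13, hessian = TRUE)
  da <- x[, 1, "a"] - x[, 2, "a"]
  db <- x[, 1, "b"] - x[, 2, "b"]
  y <- as.integer(pan$chosen == 1L)
  gfit <- glm(y ~ da + db - 1, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(gfit)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(gfit)), tolerance = 1e-10)
})

test_that("simulation from a known single-segment RUM model is recovered", {
  spec <- model_spec(list(segment_spec(
    "RUM", c("grade_steep", "mean_exposure", "travel_time"))))
  tp <- parameter_set(spec)
  truth <- c(-1.5, -0.07, -0.09)
  tp$beta[[1]][] <- truth
  d <- generate_design(600, seed = 71)
  pan <- simulate_choices(d, spec, tp, seed = 72)
  fit <- lc_choice(pan, spec, n_starts = 1)
  expect_true(fit$converged)
  expect_true(fit$inference_available)
  z <- abs(coef(fit) - truth) / fit$std_errors
  expect_true(all(z < 2))
  # MLE property: fitted LL is at least the LL at the generating parameters
  expect_gte(fit$loglik, unconditional_loglik(pan, spec, tp))
  # logLik method wires into stats::AIC / BIC with Q = choice observations
  expect_equal(AIC(fit), fit$fit$aic)
  expect_equal(BIC(fit), fit$fit$bic)
})

test_that("likelihood is label-permutation invariant and reporting canonical", {
  sim <- sim_two_class_panel(150, seed = 81)
  spec <- sim$spec
  tp <- sim$truth
  # swap the two segments with matching parameter swap: same likelihood
  spec_sw <- model_spec(list(spec$segments[[2]], spec$segments[[1]]),
                        membership = "female")
  tp_sw <- parameter_set(spec_sw)
  tp_sw$beta[[1]][] <- tp$beta[[2]]
  tp_sw$beta[[2]][] <- tp$beta[[1]]
  tp_sw$gamma[[2]][] <- -tp$gamma[[2]]
  expect_equal(unconditional_loglik(sim$panel, spec_sw, tp_sw),
               unconditional_loglik(sim$panel, spec, tp), tolerance = 1e-10)

  # canonical report: RRM segment first regardless of spec order
  fit <- lc_choice(sim$panel, spec_sw, n_starts = 1, hessian = FALSE)
  rules <- vapply(fit$spec$segments, `[[`, "", "rule")
  expect_equal(rules, c("RRM", "RUM"))
  expect_equal(fit$spec$base, 1L)
  expect_equal(sum(fit$shares), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$posteriors), rep(1, 150), tolerance = 1e-9)
})

test_that("an added zero-coefficient segment never decreases the fitted LL", {
  sim <- sim_two_class_panel(100, seed = 91)
  fit1 <- lc_choice(sim$panel,
                    model_spec(list(segment_spec("RUM", sim$attrs))),
                    n_starts = 1, hessian = FALSE)
  spec2 <- model_spec(list(segment_spec("RUM", sim$attrs),
                           segment_spec("RRM", sim$attrs)),
                      membership = "female")
  start <- parameter_set(spec2)
  start$beta[[1]][] <- fit1$params$beta[[1]]
  fit2 <- lc_choice(sim$panel, spec2, n_starts = 1, start = start,
                    hessian = FALSE)
  expect_gte(fit2$loglik, fit1$loglik - 1e-6)
})

test_that("posterior_segments rows sum to one and S = 1 posteriors are 1", {
  spec <- model_spec(list(segment_spec("RUM", c("mean_exposure", "travel_time"))))
  tp <- parameter_set(spec)
  tp$beta[[1]][] <- c(-0.1, -0.1)
  d <- generate_design(15, seed = 101)
  pan <- simulate_choices(d, spec, tp, seed = 102)
  fit <- lc_choice(pan, spec, n_starts = 1, hessian = FALSE)
  post <- posterior_segments(fit)
  expect_equal(post, matrix(1, 15, 1))
})
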