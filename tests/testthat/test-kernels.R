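# RUM and RRM choice-probability kernels, mixing, and their invariants.

test_that("RUM utilities: closed forms, masking and alignment errors", {
  p <- tiny_panel()
  expect_equal(rum_utilities(p, c(0, 0, 0), p$attributes),
               matrix(0, p$n_obs, p$n_alt))
  # single attribute, x = (1, 0, 0): utility is the coefficient itself
  u <- rum_utilities(p, -1.795, "a1")
  expect_equal(u[1, ], c(-1.795, 0, 0))
  # masked attribute contributes nothing: scenario 3 does not show a2
  u2 <- rum_utilities(p, c(1, 5), c("a1", "a2"))
  expect_equal(u2[3, ], rum_utilities(p, c(1, 0), c("a1", "a2"))[3, ])
  expect_error(rum_utilities(p, c(1, 2), p$attributes), "does not match")
})

test_that("MNL probabilities: softmax closed forms and overflow stability", {
  expect_equal(mnl_probabilities(matrix(0, 2, 3)),
               matrix(1 / 3, 2, 3))
  expect_equal(mnl_probabilities(matrix(c(log(2), 0, 0), 1)),
               matrix(c(0.5, 0.25, 0.25), 1))
  big <- mnl_probabilities(matrix(c(1000, 0, 0), 1))
  expect_true(all(is.finite(big)))
  expect_equal(big[1, 1], 1, tolerance = 1e-12)
})

test_that("RRM regret: zero-coefficient and identical-alternative closed forms", {
  p <- tiny_panel()
  M <- length(p$attributes)
  # delta = 0: every pairwise softplus is ln 2, two competitors each
  R0 <- rrm_regret(p, rep(0, M), p$attributes)
  expect_equal(R0[1, ], rep(2 * 2 * log(2) + 2 * log(2), 3))  # careful below
  # scenario 3 shows only 2 attributes, so its regret is 2*2*ln2
  expect_equal(R0[3, ], rep(2 * 2 * log(2), 3))
  # identical alternatives: differences vanish regardless of delta
  xi <- array(1, dim = c(1, 3, 2), dimnames = list(NULL, NULL, c("u", "v")))
  pid <- choice_panel(xi, 1L, 1L)
  expect_equal(rrm_regret(pid, c(3.7, -1.2), c("u", "v"))[1, ],
               rep(2 * 2 * log(2), 3))
})

test_that("RRM regret matches a hand evaluation with a dummy attribute", {
  # alternative 1 has the dummy, competitors lack it, delta = -2.131
  xi <- array(0, dim = c(1, 3, 1), dimnames = list(NULL, NULL, "steep"))
  xi[1, 1, 1] <- 1
  p1 <- choice_panel(xi, 1L, 1L)
  R <- rrm_regret(p1, -2.131, "steep")
  expect_equal(R[1, 1], 2 * log1p(exp(2.131)), tolerance = 1e-12)
  # competitors: one term against i=1 (difference -1), one ln 2 term
  expect_equal(R[1, 2], log1p(exp(-2.131)) + log(2), tolerance = 1e-12)
  expect_equal(R[1, 2], R[1, 3])
  expect_equal(R[1, 1], 4.486, tolerance = 1e-3)
})

test_that("rrm_probabilities: closed forms and normalization", {
  expect_equal(rrm_probabilities(matrix(1, 1, 3)), matrix(1 / 3, 1, 3))
  pr <- rrm_probabilities(matrix(c(0, log(4), log(4)), 1))
  expect_equal(pr, matrix(c(2 / 3, 1 / 6, 1 / 6), 1))
  set.seed(1)
  R <- matrix(rnorm(60, sd = 3), 20, 3)
  expect_equal(rowSums(rrm_probabilities(R)), rep(1, 20))
})

test_that("kernel probabilities match the brute-force loop oracle", {
  p <- tiny_panel()
  set.seed(11)
  for (rep in 1:5) {
    beta <- rnorm(3)
    expect_equal(mnl_probabilities(rum_utilities(p, beta, p$attributes)),
                 oracle_rum_probs(p, beta, p$attributes), tolerance = 1e-10)
    expect_equal(rrm_probabilities(rrm_regret(p, beta, p$attributes)),
                 oracle_rrm_probs(p, beta, p$attributes), tolerance = 1e-10)
  }
})

test_that("RUM is translation invariant; RRM is attribute-shift invariant", {
  p <- tiny_panel()
  beta <- c(0.8, -1.3, -0.05)
  U <- rum_utilities(p, beta, p$attributes)
  expect_equal(mnl_probabilities(U + 7.5), mnl_probabilities(U),
               tolerance = 1e-12)
  # shifting an attribute equally across alternatives leaves regret unchanged
  p2 <- p
  p2$x[, , "a2"] <- p2$x[, , "a2"] + 3
  expect_equal(rrm_regret(p2, beta, p$attributes),
               rrm_regret(p, beta, p$attributes), tolerance = 1e-12)
})

test_that("binary single-attribute RRM equals binary RUM logit", {
  set.seed(5)
  x <- array(rnorm(40), dim = c(20, 2, 1), dimnames = list(NULL, NULL, "a"))
  p <- choice_panel(x, chosen = rep(1L, 20), resp = 1:20)
  for (delta in c(-2.131, -0.5, 0.7)) {
    prum <- mnl_probabilities(rum_utilities(p, delta, "a"))
    prrm <- rrm_probabilities(rrm_regret(p, delta, "a"))
    expect_equal(prrm, prum, tolerance = 1e-12)
  }
})

test_that("panel likelihood: uniform closed form and mixing behavior", {
  p <- tiny_panel()  # K = 2 occasions
  seg <- segment_spec("RUM", p$attributes)
  L <- segment_panel_likelihood(p, seg, c(0, 0, 0))
  expect_equal(L, rep((1 / 3)^2, 3))
  expect_true(all(L > 0 & L <= 1))

  # missing draws for a mixed segment is an error
  segm <- segment_spec("RUM", p$attributes, random = "time")
  expect_error(segment_panel_likelihood(p, segm, c(0, 0, -0.1),
                                        log_spread = c(time = log(0.5))),
               "draws")

  # spread -> 0 recovers the unmixed likelihood
  dr <- draw_set(3, 64, 1, seed = 9)
  beta <- c(a1 = 0.5, a2 = -0.4, time = -0.08)
  L0 <- segment_panel_likelihood(p, seg, beta)
  Lm <- segment_panel_likelihood(p, segm, beta,
                                 log_spread = c(time = log(1e-10)), draws = dr)
  expect_equal(Lm, L0, tolerance = 1e-8)
})

test_that("Halton and pseudo-random simulated likelihoods agree within MC error", {
  spec1 <- model_spec(list(segment_spec("RUM",
                                        c("mean_exposure", "travel_time"),
                                        random = "travel_time")))
  tp <- parameter_set(spec1)
  tp$beta[[1]][] <- c(-0.08, -0.12)
  tp$log_spread[[1]][] <- log(0.06)
  d <- generate_design(60, seed = 21)
  pan <- simulate_choices(d, spec1, tp, seed = 22)
  seg <- spec1$segments[[1]]
  ll_h <- sum(segment_panel_likelihood(
    pan, seg, tp$beta[[1]], tp$log_spread[[1]],
    draw_set(60, 200, 1, seed = 1, type = "halton"), log = TRUE))
  ll_p <- sum(segment_panel_likelihood(
    pan, seg, tp$beta[[1]], tp$log_spread[[1]],
    draw_set(60, 2000, 1, seed = 2, type = "pseudo"), log = TRUE))
  expect_equal(ll_h, ll_p, tolerance = 5e-3)
})

test_that("draw sets are deterministic given seed and respondent-specific", {
  d1 <- draw_set(5, 20, 2, seed = 3)
  d2 <- draw_set(5, 20, 2, seed = 3)
  expect_identical(d1, d2)
  d3 <- draw_set(5, 20, 2, seed = 4)
  expect_false(identical(unclass(d1), unclass(d3)))
  expect_false(any(duplicated(matrix(d1, nrow = 5))))
})
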