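# Shared fixtures and independent brute-force oracles. The oracles compute
# choice probabilities and likelihoods with plain per-observation loops,
# deliberately avoiding the package's vectorized kernels.

# A small deterministic panel: 3 respondents x 2 scenarios x 3 alternatives,
# 3 attribute columns, with one attribute masked out in one scenario.
tiny_panel <- function() {
  C <- 3L; K <- 2L; I <- 3L
  attrs <- c("a1", "a2", "time")
  n_obs <- C * K
  x <- array(0, dim = c(n_obs, I, 3L), dimnames = list(NULL, NULL, attrs))
  # fixed, hand-chosen values
  x[, , "a1"]   <- matrix(c(1, 0, 0,
                            0, 1, 0,
                            1, 1, 0,
                            0, 0, 1,
                            1, 0, 1,
                            0, 1, 1), n_obs, I, byrow = TRUE)
  x[, , "a2"]   <- matrix(c(0.5, -0.5, 0.0,
                            1.0,  0.0, -1.0,
                            0.2,  0.4,  0.6,
                            -0.3, 0.3,  0.0,
                            0.0,  0.0,  0.0,
                            2.0,  1.0,  0.5), n_obs, I, byrow = TRUE)
  x[, , "time"] <- matrix(c(20, 30, 40,
                            25, 25, 35,
                            40, 20, 30,
                            35, 30, 25,
                            20, 40, 20,
                            30, 35, 25), n_obs, I, byrow = TRUE)
  avail <- matrix(TRUE, n_obs, 3L, dimnames = list(NULL, attrs))
  avail[3L, "a2"] <- FALSE  # scenario 3 did not show a2
  x[3L, , "a2"] <- 0
  z <- cbind(`(Intercept)` = 1, female = c(0, 1, 1))
  chosen <- c(1L, 2L, 3L, 1L, 2L, 1L)
  choice_panel(x, chosen, resp = rep(1:3, each = K), z = z, avail = avail)
}

softplus_ref <- function(u) log1p(exp(u))  # fine for moderate u

# Naive per-observation RUM probabilities.
oracle_rum_probs <- function(panel, beta, attrs) {
  P <- matrix(0, panel$n_obs, panel$n_alt)
  for (o in seq_len(panel$n_obs)) {
    u <- numeric(panel$n_alt)
    for (i in seq_len(panel$n_alt)) {
      for (m in seq_along(attrs)) {
        if (panel$avail[o, attrs[m]]) {
          u[i] <- u[i] + beta[m] * panel$x[o, i, attrs[m]]
        }
      }
    }
    P[o, ] <- exp(u) / sum(exp(u))
  }
  P
}

# Naive per-observation RRM regrets and probabilities.
oracle_rrm_regret <- function(panel, delta, attrs) {
  R <- matrix(0, panel$n_obs, panel$n_alt)
  for (o in seq_len(panel$n_obs)) {
    for (i in seq_len(panel$n_alt)) {
      for (j in seq_len(panel$n_alt)) {
        if (j == i) next
        for (m in seq_along(attrs)) {
          if (panel$avail[o, attrs[m]]) {
            R[o, i] <- R[o, i] +
              softplus_ref(delta[m] * (panel$x[o, j, attrs[m]] -
                                         panel$x[o, i, attrs[m]]))
          }
        }
      }
    }
  }
  R
}

oracle_rrm_probs <- function(panel, delta, attrs) {
  R <- oracle_rrm_regret(panel, delta, attrs)
  t(apply(R, 1L, function(r) exp(-r) / sum(exp(-r))))
}

# Naive latent-class log-likelihood: explicit loops over respondents,
# segments and occasions, no log-scale tricks (fixture values are benign).
oracle_loglik <- function(panel, spec, params) {
  S <- length(spec$segments)
  zc <- panel$z[, spec$membership, drop = FALSE]
  ll <- 0
  for (c in seq_len(panel$n_resp)) {
    v <- numeric(S)
    for (s in seq_len(S)) {
      g <- params$gamma[[s]]
      if (!is.null(g) && length(g)) v[s] <- sum(g * zc[c, ])
    }
    pcs <- if (S == 1L) 1 else exp(v) / sum(exp(v))
    pc <- 0
    for (s in seq_len(S)) {
      seg <- spec$segments[[s]]
      beta <- params$beta[[s]][seg$attributes]
      P <- if (seg$rule == "RUM") {
        oracle_rum_probs(panel, beta, seg$attributes)
      } else {
        oracle_rrm_probs(panel, beta, seg$attributes)
      }
      lcs <- 1
      for (o in which(panel$resp == c)) {
        lcs <- lcs * P[o, panel$chosen[o]]
      }
      pc <- pc + pcs[s] * lcs
    }
    ll <- ll + log(pc)
  }
  ll
}

# Convenience: simulated two-rule panel used by several estimation tests.
sim_two_class_panel <- function(C, seed = 20240101 %% 1000L,
                                gamma = c(-0.6, 1.4),
                                beta_rum = c(-1.8, -1.6, -0.06, -0.05),
                                beta_rrm = c(-2.1, -1.1, -0.07, -0.25)) {
  attrs <- c("grade_steep", "traffic_heavy", "mean_exposure", "travel_time")
  spec <- model_spec(list(segment_spec("RRM", attrs),
                          segment_spec("RUM", attrs)),
                     membership = "female")
  d <- generate_design(C, seed = seed)
  z <- generate_covariates(C, seed = seed + 1L)
  tp <- parameter_set(spec)
  tp$beta[[1]][] <- beta_rrm
  tp$beta[[2]][] <- beta_rum
  tp$gamma[[2]][] <- gamma
  panel <- simulate_choices(d, spec, tp, z = z, seed = seed + 2L)
  list(panel = panel, spec = spec, truth = tp, attrs = attrs)
}
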