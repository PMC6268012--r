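# Latent-class machinery: membership probabilities, the unconditional
# (simulated) log-likelihood, and the maximum-likelihood fitting function
# lc_choice() with its inference, posteriors and population shares.

#' Segment membership probabilities
#'
#' Logit membership model on respondent covariates:
#' `P_cs = exp(gamma_s' z_c) / sum_s' exp(gamma_s'' z_c)`, with the base
#' segment's coefficients fixed at zero for identification.
#'
#' @param z respondent covariate matrix `(C, P)` with named columns.
#' @param gamma list of named membership coefficient vectors, one per segment
#'   (`NULL`/empty for the base segment), as in a `parameter_set`.
#' @param spec the [model_spec].
#' @return matrix `(C, S)`; each row a probability simplex.
#' @export
membership_probabilities <- function(z, gamma, spec) {
  S <- length(spec$segments)
  C <- nrow(z)
  if (S == 1L) return(matrix(1, C, 1L))
  V <- matrix(0, C, S)
  zm <- z[, spec$membership, drop = FALSE]
  for (s in seq_len(S)) {
    g <- gamma[[s]]
    if (s == spec$base || is.null(g) || !length(g)) next
    if (length(g) != ncol(zm)) {
      stop("membership coefficients for segment ", s,
           " do not match the covariate list")
    }
    V[, s] <- zm %*% g
  }
  softmax_rows(V)
}

# Internal: (C x S) matrix of log conditional likelihoods log L_{c|s}.
.conditional_logL <- function(panel, spec, params, draws = NULL) {
  S <- length(spec$segments)
  out <- matrix(0, panel$n_resp, S)
  for (s in seq_len(S)) {
    seg <- spec$segments[[s]]
    dr <- if (length(seg$random)) draws[[s]] else NULL
    out[, s] <- .segment_logLc(panel, seg, params$beta[[s]],
                               params$log_spread[[s]], dr)
  }
  out
}

#' Unconditional latent-class log-likelihood
#'
#' `LL = sum_c log sum_s P_cs * L_{c|s}`, where `P_cs` is the logit membership
#' probability and `L_{c|s}` the segment-conditional panel likelihood
#' (simulated when the segment has random coefficients). The inner sum over
#' segments is evaluated on the log scale by log-sum-exp.
#'
#' @param panel a [choice_panel] with recorded choices.
#' @param spec a validated [model_spec].
#' @param params a `parameter_set` for `spec`.
#' @param draws optional per-segment list of [draw_set] arrays (required for
#'   segments with random attributes).
#' @return scalar log-likelihood.
#' @export
unconditional_loglik <- function(panel, spec, params, draws = NULL) {
  P <- membership_probabilities(panel$z, params$gamma, spec)
  lcs <- .conditional_logL(panel, spec, params, draws)
  llc <- logsumexp_rows(log(P) + lcs)
  if (any(!is.finite(llc))) {
    stop("non-finite likelihood contribution for respondent ",
         which(!is.finite(llc))[1L])
  }
  sum(llc)
}

#' Population shares
#'
#' The expected fraction of the population in each segment: the average over
#' respondents of the membership probabilities, `GS_s = sum_c P_cs / C`.
#'
#' @param P membership (or posterior) probability matrix `(C, S)`.
#' @return numeric vector of length `S` summing to one.
#' @export
population_shares <- function(P) {
  colMeans(as.matrix(P))
}

# Analytic score of the unconditional log-likelihood for specs without
# random coefficients. Returns list(loglik, grad) with grad in the flat
# parameter layout. Mixing falls back to finite differences in lc_choice.
.loglik_and_grad <- function(panel, spec, params) {
  S <- length(spec$segments)
  n_obs <- panel$n_obs
  I <- panel$n_alt
  P <- membership_probabilities(panel$z, params$gamma, spec)
  lcs <- matrix(0, panel$n_resp, S)
  probs <- vector("list", S)
  for (s in seq_len(S)) {
    seg <- spec$segments[[s]]
    beta <- params$beta[[s]][seg$attributes]
    Pm <- if (seg$rule == "RUM") {
      mnl_probabilities(rum_utilities(panel, beta, seg$attributes))
    } else {
      rrm_probabilities(rrm_regret(panel, beta, seg$attributes))
    }
    probs[[s]] <- Pm
    lcs[, s] <- as.vector(rowsum(log(Pm[cbind(seq_len(n_obs), panel$chosen)]),
                                 panel$resp))
  }
  lp <- log(P) + lcs
  llc <- logsumexp_rows(lp)
  W <- exp(lp - llc)  # posterior segment weights, C x S

  g_gamma <- vector("list", S)
  if (length(spec$membership)) {
    zm <- panel$z[, spec$membership, drop = FALSE]
    for (s in seq_len(S)) {
      if (s == spec$base) next
      g_gamma[[s]] <- colSums((W[, s] - P[, s]) * zm)
    }
  }
  g_beta <- vector("list", S)
  chosen_idx <- cbind(seq_len(n_obs), panel$chosen)
  for (s in seq_len(S)) {
    seg <- spec$segments[[s]]
    beta <- params$beta[[s]][seg$attributes]
    Pm <- probs[[s]]
    w_obs <- W[panel$resp, s]
    g <- numeric(length(seg$attributes))
    for (m in seq_along(seg$attributes)) {
      a <- seg$attributes[m]
      xm <- .attr_mat(panel, a)
      if (seg$rule == "RUM") {
        score <- xm[chosen_idx] - rowSums(Pm * xm)
      } else {
        av <- panel$avail[, a]
        dR <- matrix(0, n_obs, I)
        for (i in seq_len(I)) {
          for (j in seq_len(I)[-i]) {
            d <- xm[, j] - xm[, i]
            dR[, i] <- dR[, i] + av * stats::plogis(beta[m] * d) * d
          }
        }
        score <- rowSums(Pm * dR) - dR[chosen_idx]
      }
      g[m] <- sum(w_obs * score)
    }
    g_beta[[s]] <- g
  }
  gp <- parameter_set(spec)
  for (s in seq_len(S)) {
    if (!is.null(gp$gamma[[s]]) && length(gp$gamma[[s]])) {
      gp$gamma[[s]][] <- g_gamma[[s]]
    }
    gp$beta[[s]][] <- g_beta[[s]]
  }
  list(loglik = sum(llc), grad = flatten_params(gp, spec))
}

# Build the per-segment draw list for a spec (NULL entries for fixed-coefficient
# segments). One independent draw block per segment, seeded deterministically.
.build_draws <- function(panel, spec, n_draws, seed, type) {
  lapply(seq_along(spec$segments), function(s) {
    seg <- spec$segments[[s]]
    if (!length(seg$random)) return(NULL)
    draw_set(panel$n_resp, n_draws, length(seg$random),
             seed = seed + 1000L * s, type = type)
  })
}

# Starting values: each segment's coefficients from its own single-segment
# fit (memoized over identical rule+attribute sets), membership coefficients
# zero, log spreads log(0.5).
.warm_start <- function(panel, spec, n_draws, seed, type) {
  params <- parameter_set(spec)
  cache <- list()
  for (s in seq_along(spec$segments)) {
    seg <- spec$segments[[s]]
    key <- paste(seg$rule, paste(seg$attributes, collapse = ","), sep = "|")
    if (is.null(cache[[key]])) {
      sub <- model_spec(list(segment_spec(seg$rule, seg$attributes)))
      fit1 <- lc_choice(panel, sub, n_draws = n_draws, seed = seed,
                        n_starts = 1L, start = "zero", hessian = FALSE,
                        canonical = FALSE, draw_type = type)
      cache[[key]] <- fit1$params$beta[[1L]]
    }
    params$beta[[s]][] <- cache[[key]]
    if (length(seg$random)) params$log_spread[[s]][] <- log(0.5)
  }
  params
}

#' Fit a latent-class choice model by maximum (simulated) likelihood
#'
#' The main fitting function. Maximizes the unconditional latent-class
#' log-likelihood over the flattened parameter vector with quasi-Newton
#' (BFGS) iterations from one or more perturbed starting points, computes
#' standard errors from the inverse numerical Hessian at the optimum, and
#' reports population shares and posterior segment assignments. Segments are
#' relabeled to a canonical order (RRM segments before RUM, descending
#' population share within rule) so that reported results are deterministic
#' despite label-switching symmetry; membership coefficients are re-expressed
#' against the new base segment.
#'
#' @param panel a [choice_panel] with recorded choices.
#' @param spec a [model_spec].
#' @param n_draws draws per respondent for segments with random coefficients
#'   (default 200).
#' @param draw_type `"halton"` (randomized Halton, default) or `"pseudo"`.
#' @param seed integer seed controlling draws and start perturbations.
#' @param n_starts number of starting points (default 5); the first is the
#'   warm start, the rest are perturbed copies.
#' @param start optional starting `parameter_set`, flat numeric vector, or
#'   `"zero"` for an all-zero start (skips the warm-start pre-fits).
#' @param max_iter BFGS iteration cap per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param hessian compute standard errors (default `TRUE`).
#' @param canonical apply canonical segment reordering (default `TRUE`).
#' @return an object of class `lc_choice`; see [summary.lc_choice].
#' @seealso [posterior_segments], [population_shares], [search_compositions]
#' @export
lc_choice <- function(panel, spec, n_draws = 200L,
                      draw_type = c("halton", "pseudo"), seed = 1L,
                      n_starts = 5L, start = NULL, max_iter = 500L,
                      tol = 1e-8, hessian = TRUE, canonical = TRUE) {
  draw_type <- match.arg(draw_type)
  validate_spec(spec, panel)
  draws <- .build_draws(panel, spec, n_draws, seed, draw_type)

  mixed <- any(vapply(spec$segments, function(s) length(s$random) > 0L, TRUE))
  negll <- function(theta) {
    p <- unflatten_params(theta, spec)
    -tryCatch(unconditional_loglik(panel, spec, p, draws),
              error = function(e) -Inf)
  }
  # analytic score where available (no mixing); otherwise optim's own
  # finite-difference gradient
  neggr <- if (mixed) NULL else function(theta) {
    p <- unflatten_params(theta, spec)
    g <- tryCatch(.loglik_and_grad(panel, spec, p)$grad,
                  error = function(e) rep(0, length(theta)))
    -g
  }

  start_params <- if (is.null(start)) {
    if (length(spec$segments) > 1L) {
      .warm_start(panel, spec, n_draws, seed, draw_type)
    } else {
      parameter_set(spec)
    }
  } else if (identical(start, "zero")) {
    parameter_set(spec)
  } else if (inherits(start, "parameter_set")) {
    start
  } else {
    unflatten_params(as.numeric(start), spec)
  }
  theta0 <- flatten_params(start_params, spec)

  starts <- with_seed(seed + 7L, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1L) theta0
      else theta0 + stats::rnorm(length(theta0), 0, 0.25 * abs(theta0) + 0.1)
    })
  })

  best <- NULL
  trace <- data.frame(start = seq_len(n_starts), loglik = NA_real_,
                      converged = NA)
  for (i in seq_len(n_starts)) {
    opt <- tryCatch(
      stats::optim(starts[[i]], negll, gr = neggr, method = "BFGS",
                   control = list(maxit = max_iter, reltol = tol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    trace$loglik[i] <- -opt$value
    trace$converged[i] <- opt$convergence == 0L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("no starting point produced a finite optimum")

  params <- unflatten_params(best$par, spec)

  # ---- canonical segment ordering (resolves label switching) ----
  if (canonical && length(spec$segments) > 1L) {
    P <- membership_probabilities(panel$z, params$gamma, spec)
    gs <- population_shares(P)
    rules <- vapply(spec$segments, `[[`, "", "rule")
    ord <- order(rules != "RRM", -gs)  # RRM first, then descending share
    if (!identical(ord, seq_along(ord))) {
      co <- .reorder_segments(spec, params, ord)
      spec <- co$spec
      params <- co$params
      draws <- .build_draws(panel, spec, n_draws, seed, draw_type)
    }
  }
  theta <- flatten_params(params, spec)
  loglik <- unconditional_loglik(panel, spec, params, draws)

  # ---- inference: inverse numerical Hessian at the (canonical) optimum ----
  se <- rep(NA_real_, length(theta))
  vcov <- NULL
  inference <- FALSE
  if (hessian && length(theta)) {
    negll_c <- function(th) {
      p <- unflatten_params(th, spec)
      -tryCatch(unconditional_loglik(panel, spec, p, draws),
                error = function(e) -Inf)
    }
    neggr_c <- if (mixed) NULL else function(th) {
      -.loglik_and_grad(panel, spec, unflatten_params(th, spec))$grad
    }
    H <- tryCatch(stats::optimHess(theta, negll_c, gr = neggr_c),
                  error = function(e) NULL)
    if (!is.null(H)) {
      ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                     error = function(e) -1)
      if (all(ev > 0)) {
        vcov <- solve(H)
        dimnames(vcov) <- list(names(theta), names(theta))
        se <- sqrt(diag(vcov))
        inference <- TRUE
      }
    }
  }

  P <- membership_probabilities(panel$z, params$gamma, spec)
  lcs <- .conditional_logL(panel, spec, params, draws)
  post <- .posterior_from(P, lcs)
  shares <- population_shares(P)

  k <- length(theta)
  q <- panel$n_obs
  fit <- fit_statistics(loglik, k, q)

  res <- structure(list(
    spec = spec, params = params, coefficients = theta,
    loglik = loglik, fit = fit,
    std_errors = stats::setNames(se, names(theta)),
    t_stats = stats::setNames(theta / se, names(theta)),
    vcov = vcov, inference_available = inference,
    shares = shares, posteriors = post,
    converged = any(trace$converged, na.rm = TRUE),
    n_draws = if (any(vapply(spec$segments, function(s) length(s$random) > 0L,
                             TRUE))) n_draws else 0L,
    draw_type = draw_type, seed = as.integer(seed),
    start_trace = trace, panel = panel, call = match.call()),
    class = "lc_choice")
  res
}

# Permute segments of (spec, params) by `ord`, re-expressing membership
# coefficients against the new base (position 1 after reordering).
.reorder_segments <- function(spec, params, ord) {
  S <- length(spec$segments)
  memb <- spec$membership
  G <- matrix(0, max(1L, length(memb)), S)
  for (s in seq_len(S)) {
    if (!is.null(params$gamma[[s]]) && length(params$gamma[[s]])) {
      G[, s] <- params$gamma[[s]]
    }
  }
  G <- G[, ord, drop = FALSE]
  G <- G - G[, 1L]  # rebase on the new first segment
  new_spec <- model_spec(spec$segments[ord], membership = setdiff(memb, "(Intercept)"),
                         base = 1L)
  new_spec$membership <- memb  # preserve original covariate order
  new_params <- parameter_set(new_spec)
  for (s in seq_len(S)) {
    new_params$beta[[s]][] <- params$beta[[ord[s]]]
    if (length(new_params$log_spread[[s]])) {
      new_params$log_spread[[s]][] <- params$log_spread[[ord[s]]]
    }
    if (s != 1L && length(memb)) {
      new_params$gamma[[s]][] <- G[, s]
    }
  }
  # refresh default labels to reflect the new order
  for (s in seq_len(S)) {
    new_spec$segments[[s]]$label <-
      paste0("Segment-", s, " (", new_spec$segments[[s]]$rule, ")")
  }
  list(spec = new_spec, params = new_params)
}

# Bayes posterior over segments from prior P and log conditional likelihoods.
.posterior_from <- function(P, lcs) {
  lp <- log(P) + lcs
  post <- exp(lp - logsumexp_rows(lp))
  post / rowSums(post)
}

#' Posterior segment assignment probabilities
#'
#' Bayes rule: the prior membership probability of each segment times the
#' segment-conditional likelihood of the respondent's observed choice
#' sequence, normalized over segments.
#'
#' @param result a fitted [lc_choice] object.
#' @param panel optionally, a different [choice_panel] (defaults to the
#'   fitting panel).
#' @return matrix `(C, S)`; rows sum to one.
#' @export
posterior_segments <- function(result, panel = result$panel) {
  stopifnot(inherits(result, "lc_choice"))
  draws <- .build_draws(panel, result$spec, max(result$n_draws, 1L),
                        result$seed, result$draw_type)
  P <- membership_probabilities(panel$z, result$params$gamma, result$spec)
  lcs <- .conditional_logL(panel, result$spec, result$params, draws)
  .posterior_from(P, lcs)
}
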