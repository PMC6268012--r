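# S3 methods for fitted lc_choice objects.

#' Parameter table of a fitted latent-class choice model
#'
#' One row per estimated parameter: segment label, decision rule, block
#' (membership / choice / mixing spread), variable name, estimate, standard
#' error and t-statistic. The layout mirrors the conventional reporting of
#' latent-class choice models (segmentation component on top, segment-specific
#' choice components below).
#'
#' @param result a fitted [lc_choice].
#' @return a `data.frame`.
#' @export
parameter_table <- function(result) {
  stopifnot(inherits(result, "lc_choice"))
  spec <- result$spec
  nm <- names(result$coefficients)
  seg_idx <- as.integer(sub("^(gamma|beta|lsd)([0-9]+)\\..*$", "\\2", nm))
  block <- c(gamma = "membership", beta = "choice", lsd = "spread")[
    sub("^(gamma|beta|lsd)[0-9]+\\..*$", "\\1", nm)]
  variable <- sub("^(gamma|beta|lsd)[0-9]+\\.", "", nm)
  data.frame(
    segment = vapply(seg_idx, function(s) spec$segments[[s]]$label, ""),
    rule = vapply(seg_idx, function(s) spec$segments[[s]]$rule, ""),
    block = unname(block),
    variable = variable,
    estimate = unname(result$coefficients),
    std_error = unname(result$std_errors),
    t_stat = unname(result$t_stats),
    stringsAsFactors = FALSE)
}

#' @export
print.lc_choice <- function(x, ...) {
  S <- length(x$spec$segments)
  cat("Latent-class choice model (", S, " segment",
      if (S > 1) "s", ")\n", sep = "")
  rules <- vapply(x$spec$segments, `[[`, "", "rule")
  cat("Composition:", sum(rules == "RUM"), "RUM +", sum(rules == "RRM"),
      "RRM segment(s)\n")
  cat(sprintf("Log-likelihood: %.3f   parameters: %d   observations: %d\n",
              x$loglik, x$fit$n_params, x$fit$n_obs))
  cat(sprintf("AIC: %.3f   BIC: %.3f\n", x$fit$aic, x$fit$bic))
  cat("Population shares:",
      paste(sprintf("%s %.1f%%",
                    vapply(x$spec$segments, `[[`, "", "label"),
                    100 * x$shares), collapse = ", "), "\n")
  if (!x$converged) cat("Warning: no start reported clean convergence\n")
  invisible(x)
}

#' @export
summary.lc_choice <- function(object, ...) {
  out <- list(result = object, table = parameter_table(object))
  class(out) <- "summary.lc_choice"
  out
}

#' @export
print.summary.lc_choice <- function(x, ...) {
  print(x$result)
  cat("\nParameter estimates:\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, 4)
  tab$std_error <- round(tab$std_error, 4)
  tab$t_stat <- round(tab$t_stat, 3)
  print(tab, row.names = FALSE)
  if (!x$result$inference_available) {
    cat("\nStandard errors unavailable: Hessian not positive definite.\n")
  }
  invisible(x)
}

#' @export
coef.lc_choice <- function(object, ...) object$coefficients

#' @export
vcov.lc_choice <- function(object, ...) object$vcov

#' @export
logLik.lc_choice <- function(object, ...) {
  structure(object$loglik, df = object$fit$n_params,
            nobs = object$fit$n_obs, class = "logLik")
}

#' @export
nobs.lc_choice <- function(object, ...) object$fit$n_obs

#' Predicted choice probabilities
#'
#' Unconditional per-scenario choice probabilities:
#' `P_c(i) = sum_s P_cs * P_c(i)|s`, with segment-conditional probabilities
#' averaged over the draw set for mixed segments. `type = "posterior"` returns
#' the posterior segment probabilities instead; `type = "shares"` the
#' population shares.
#'
#' @param object a fitted [lc_choice].
#' @param newdata optionally a different [choice_panel].
#' @param type one of `"probabilities"`, `"posterior"`, `"shares"`.
#' @param ... unused.
#' @return matrix `(n_obs, n_alt)`, matrix `(C, S)`, or numeric vector.
#' @export
predict.lc_choice <- function(object, newdata = NULL,
                              type = c("probabilities", "posterior", "shares"),
                              ...) {
  type <- match.arg(type)
  panel <- if (is.null(newdata)) object$panel else newdata
  if (type == "shares") {
    P <- membership_probabilities(panel$z, object$params$gamma, object$spec)
    return(population_shares(P))
  }
  if (type == "posterior") return(posterior_segments(object, panel))
  spec <- object$spec
  draws <- .build_draws(panel, spec, max(object$n_draws, 1L), object$seed,
                        object$draw_type)
  Pm <- membership_probabilities(panel$z, object$params$gamma, spec)
  out <- matrix(0, panel$n_obs, panel$n_alt)
  for (s in seq_along(spec$segments)) {
    seg <- spec$segments[[s]]
    beta <- object$params$beta[[s]]
    if (!length(seg$random)) {
      Ps <- if (seg$rule == "RUM") {
        mnl_probabilities(rum_utilities(panel, beta[seg$attributes],
                                        seg$attributes))
      } else {
        rrm_probabilities(rrm_regret(panel, beta[seg$attributes],
                                     seg$attributes))
      }
    } else {
      dr <- draws[[s]]
      D <- dim(dr)[2L]
      sigma <- exp(object$params$log_spread[[s]][seg$random])
      ridx <- match(seg$random, seg$attributes)
      Ps <- matrix(0, panel$n_obs, panel$n_alt)
      for (d in seq_len(D)) {
        bmat <- matrix(beta[seg$attributes], panel$n_obs, length(seg$attributes),
                       byrow = TRUE)
        for (r in seq_along(seg$random)) {
          bmat[, ridx[r]] <- bmat[, ridx[r]] + sigma[r] * dr[panel$resp, d, r]
        }
        Ps <- Ps + (if (seg$rule == "RUM") {
          mnl_probabilities(rum_utilities(panel, bmat, seg$attributes))
        } else {
          rrm_probabilities(rrm_regret(panel, bmat, seg$attributes))
        }) / D
      }
    }
    out <- out + Pm[panel$resp, s] * Ps
  }
  out
}

#' @export
fitted.lc_choice <- function(object, ...) predict(object)

#' Response residuals
#'
#' Indicator of the chosen alternative minus its predicted unconditional
#' probability, per scenario and alternative.
#'
#' @param object a fitted [lc_choice].
#' @param ... unused.
#' @return matrix `(n_obs, n_alt)`.
#' @export
residuals.lc_choice <- function(object, ...) {
  p <- predict(object)
  y <- matrix(0, nrow(p), ncol(p))
  y[cbind(seq_len(nrow(p)), object$panel$chosen)] <- 1
  y - p
}

#' Simulate choice sequences from a fitted model
#'
#' Draws new chosen alternatives on the fitting panel's design from the
#' fitted latent-class model (segment per respondent from the membership
#' model, then choices from that segment's rule), the same generative scheme
#' as [simulate_choices].
#'
#' @param object a fitted [lc_choice].
#' @param nsim number of replicate panels.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` [choice_panel]s.
#' @export
simulate.lc_choice <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i) {
    simulate_choices(object$panel, object$spec, object$params,
                     z = object$panel$z, seed = seed + i - 1L)
  })
}

#' Plot population shares and posterior assignment
#'
#' Barplot of the estimated population shares with the distribution of
#' maximum-posterior assignments overlaid.
#'
#' @param x a fitted [lc_choice].
#' @param ... passed to [graphics::barplot].
#' @export
plot.lc_choice <- function(x, ...) {
  labels <- vapply(x$spec$segments, `[[`, "", "label")
  hard <- tabulate(max.col(x$posteriors), nbins = length(labels)) /
    nrow(x$posteriors)
  m <- rbind(`population share` = x$shares, `modal assignment` = hard)
  graphics::barplot(m, beside = TRUE, names.arg = labels,
                    legend.text = rownames(m),
                    ylab = "share of respondents", ...)
  invisible(x)
}
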