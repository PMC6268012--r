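# Per-segment choice-probability kernels.
#
# RUM: utility U_cik = sum_m beta_m x_cikm over the segment's available
# attributes; choice probabilities are the softmax of U over alternatives.
# RRM: regret R_cik = sum_{j != i} sum_m softplus(delta_m (x_cjkm - x_cikm));
# choice probabilities are the softmax of -R. Both kernels support
# respondent-specific coefficients (for random-coefficient mixing) through an
# observation-by-coefficient matrix.

# Internal: coefficient input as either a vector (shared) or a matrix with one
# row per observation (respondent-specific draws expanded to observations).
.coef_matrix <- function(beta, attrs, n_obs) {
  if (is.matrix(beta)) {
    if (ncol(beta) != length(attrs) || nrow(beta) != n_obs) {
      stop("coefficient matrix must be n_obs x ", length(attrs))
    }
    beta
  } else {
    if (length(beta) != length(attrs)) {
      stop("coefficient length ", length(beta), " does not match ",
           length(attrs), " segment attributes")
    }
    matrix(beta, n_obs, length(attrs), byrow = TRUE)
  }
}

#' Random-utility (linear) utilities for a segment
#'
#' Computes `U[obs, i] = sum_m beta_m * x[obs, i, m]` over the segment's
#' attributes, restricted to attributes available (shown) in each scenario;
#' unavailable attributes contribute zero.
#'
#' @param panel a [choice_panel].
#' @param beta coefficient vector aligned to `segment_attrs` (or an
#'   observation-by-coefficient matrix for respondent-specific draws).
#' @param segment_attrs attribute names entering this segment's model.
#' @return numeric matrix `(n_obs, n_alt)` of utilities.
#' @export
rum_utilities <- function(panel, beta, segment_attrs) {
  stopifnot(inherits(panel, "choice_panel"))
  b <- .coef_matrix(beta, segment_attrs, panel$n_obs)
  U <- matrix(0, panel$n_obs, panel$n_alt)
  for (m in seq_along(segment_attrs)) {
    a <- segment_attrs[m]
    w <- b[, m] * panel$avail[, a]
    U <- U + .attr_mat(panel, a) * w
  }
  U
}

#' Multinomial-logit probabilities from utilities
#'
#' Softmax over alternatives within each scenario row, computed with
#' max-subtraction so extreme utilities do not overflow.
#'
#' @param utilities numeric matrix `(n_obs, n_alt)`.
#' @return probability matrix of the same shape; rows sum to one.
#' @export
mnl_probabilities <- function(utilities) {
  stopifnot(is.matrix(utilities), all(is.finite(utilities)))
  softmax_rows(utilities)
}

#' Random-regret values for a segment
#'
#' Computes the pairwise regret
#' `R[obs, i] = sum_{j != i} sum_m log(1 + exp(delta_m (x[obs,j,m] - x[obs,i,m])))`
#' over the segment's available attributes, with the softplus evaluated stably
#' for large arguments. Unavailable attributes contribute zero.
#'
#' @param panel a [choice_panel].
#' @param delta regret coefficient vector aligned to `segment_attrs` (or an
#'   observation-by-coefficient matrix).
#' @param segment_attrs attribute names entering this segment's model.
#' @return numeric matrix `(n_obs, n_alt)` of regrets.
#' @export
rrm_regret <- function(panel, delta, segment_attrs) {
  stopifnot(inherits(panel, "choice_panel"))
  d <- .coef_matrix(delta, segment_attrs, panel$n_obs)
  I <- panel$n_alt
  R <- matrix(0, panel$n_obs, I)
  for (m in seq_along(segment_attrs)) {
    a <- segment_attrs[m]
    av <- panel$avail[, a]
    xm <- .attr_mat(panel, a)
    for (i in seq_len(I)) {
      for (j in seq_len(I)[-i]) {
        # masked attributes contribute zero regret, not softplus(0)
        R[, i] <- R[, i] + av * softplus(d[, m] * (xm[, j] - xm[, i]))
      }
    }
  }
  R
}

#' Choice probabilities from regrets
#'
#' Softmax of the negated regrets over alternatives: the minimum-regret
#' alternative is the most likely choice.
#'
#' @param R numeric regret matrix `(n_obs, n_alt)`.
#' @return probability matrix; rows sum to one.
#' @export
rrm_probabilities <- function(R) {
  stopifnot(is.matrix(R), all(is.finite(R)))
  softmax_rows(-R)
}

# Internal: per-observation probability of the chosen alternative for one
# segment, given a coefficient vector or per-observation coefficient matrix.
.segment_chosen_prob <- function(panel, seg, coefs) {
  P <- if (seg$rule == "RUM") {
    mnl_probabilities(rum_utilities(panel, coefs, seg$attributes))
  } else {
    rrm_probabilities(rrm_regret(panel, coefs, seg$attributes))
  }
  P[cbind(seq_len(panel$n_obs), panel$chosen)]
}

# Internal log conditional likelihood per respondent for one segment.
# Returns log L_{c|s}, length C. With random attributes, averages the panel
# product over the draw set (simulated likelihood); otherwise exact.
.segment_logLc <- function(panel, seg, beta, log_spread = NULL, draws = NULL) {
  if (anyNA(panel$chosen)) stop("panel has no recorded choices")
  if (!is.null(names(beta))) beta <- beta[seg$attributes]
  if (!length(seg$random)) {
    lp <- log(.segment_chosen_prob(panel, seg, beta))
    return(as.vector(rowsum(lp, panel$resp)))
  }
  if (is.null(draws)) {
    stop("segment '", seg$label, "' has random attributes but no draws were supplied")
  }
  stopifnot(length(dim(draws)) == 3L, dim(draws)[3L] >= length(seg$random))
  D <- dim(draws)[2L]
  if (D < 1L) stop("at least one draw is required for mixing")
  sigma <- exp(if (is.null(names(log_spread))) log_spread else
                 log_spread[seg$random])
  ll <- matrix(0, panel$n_resp, D)
  base_b <- beta
  ridx <- match(seg$random, seg$attributes)
  for (d in seq_len(D)) {
    bmat <- matrix(base_b, panel$n_obs, length(base_b), byrow = TRUE)
    for (r in seq_along(seg$random)) {
      # respondent-level draw reused across that respondent's occasions
      dev <- sigma[r] * draws[panel$resp, d, r]
      bmat[, ridx[r]] <- bmat[, ridx[r]] + dev
    }
    lp <- log(.segment_chosen_prob(panel, seg, bmat))
    ll[, d] <- as.vector(rowsum(lp, panel$resp))
  }
  logsumexp_rows(ll) - log(D)
}

#' Conditional panel likelihood of one segment
#'
#' For each respondent, the probability of their observed choice sequence
#' under the segment's decision rule: the product over the respondent's
#' occasions of the chosen alternative's probability. With random
#' coefficients, the product is averaged over the supplied draw set
#' (maximum-simulated-likelihood approximation of the mixing integral);
#' without, the exact product is returned.
#'
#' @param panel a [choice_panel] with recorded choices.
#' @param seg a [segment_spec].
#' @param beta named coefficient vector covering `seg$attributes` (the means
#'   of random coefficients).
#' @param log_spread named vector of log mixing standard deviations for
#'   `seg$random` (required iff the segment has random attributes).
#' @param draws a [draw_set] array (required iff the segment has random
#'   attributes).
#' @param log if `TRUE` return the log likelihoods.
#' @return numeric vector of length `C`, in `(0, 1]` on the probability scale.
#' @export
segment_panel_likelihood <- function(panel, seg, beta, log_spread = NULL,
                                     draws = NULL, log = FALSE) {
  ll <- .segment_logLc(panel, seg, beta, log_spread, draws)
  if (log) ll else exp(ll)
}
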