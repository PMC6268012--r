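# Shared numerical helpers. All choice-probability code funnels through these so
# that stability conventions (max-subtraction, softplus guards) live in one place.

#' Numerically stable softplus
#'
#' Computes `log(1 + exp(u))` as `max(u, 0) + log1p(exp(-|u|))`, which neither
#' overflows for large positive `u` nor underflows for large negative `u`.
#' This is the building block of the regret function, where arguments can be
#' products of coefficients and large attribute differences.
#'
#' @param u numeric vector, matrix or array.
#' @return object of the same shape as `u`.
#' @keywords internal
softplus <- function(u) {
  pmax(u, 0) + log1p(exp(-abs(u)))
}

# Row-wise log-sum-exp of a matrix, with max subtraction.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  # all -Inf rows stay -Inf rather than NaN
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# Row-wise softmax with max subtraction.
softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

# Attribute slice of a panel's x tensor as an (n_obs x n_alt) matrix,
# robust to the single-scenario case where `[` would drop dimensions.
.attr_mat <- function(panel, a) {
  matrix(panel$x[, , a], panel$n_obs, panel$n_alt)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Every stochastic entry point in the package
# goes through this so runs are reproducible and side-effect free.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# First n primes (enough dimensions for any realistic random-coefficient set).
.primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L, 43L,
             47L, 53L, 59L, 61L, 67L, 71L)

# Radical-inverse (van der Corput) sequence in the given base.
.vdc <- function(n, base, skip = 0L) {
  idx <- seq.int(skip + 1L, skip + n)
  out <- numeric(n)
  denom <- base
  while (any(idx > 0L)) {
    out <- out + (idx %% base) / denom
    idx <- idx %/% base
    denom <- denom * base
  }
  out
}

#' Respondent-level quasi-random standard-normal draws
#'
#' Builds the draw array used by the simulated (mixed-logit) likelihood:
#' one set of `n_draws` standard-normal deviates per respondent and random
#' coefficient, reused across all of that respondent's choice occasions
#' (panel mixing). The default generator is a randomized Halton sequence:
#' consecutive primes as bases, the first `skip` points dropped, and an
#' independent uniform shift applied modulo one per dimension before the
#' normal quantile transform. `type = "pseudo"` gives plain pseudo-random
#' normals for comparison.
#'
#' @param n_resp number of respondents.
#' @param n_draws draws per respondent (default 200).
#' @param n_dim number of random coefficients.
#' @param seed integer seed; the draw set is deterministic given
#'   `(type, seed, n_resp, n_draws, n_dim)`.
#' @param type `"halton"` (randomized Halton, default) or `"pseudo"`.
#' @param skip leading Halton points to discard (default 50).
#' @return array with dim `c(n_resp, n_draws, n_dim)` and attributes
#'   `type` and `seed`.
#' @export
#' @examples
#' d <- draw_set(3, 50, 1, seed = 7)
#' dim(d)
draw_set <- function(n_resp, n_draws = 200L, n_dim = 1L, seed = 1L,
                     type = c("halton", "pseudo"), skip = 50L) {
  type <- match.arg(type)
  stopifnot(n_resp >= 1L, n_draws >= 1L, n_dim >= 1L)
  if (n_dim > length(.primes)) {
    stop("at most ", length(.primes), " random coefficients supported")
  }
  n <- n_resp * n_draws
  out <- with_seed(seed, {
    if (type == "pseudo") {
      array(stats::rnorm(n * n_dim), dim = c(n_resp, n_draws, n_dim))
    } else {
      shifts <- stats::runif(n_dim)
      a <- array(0, dim = c(n_resp, n_draws, n_dim))
      for (r in seq_len(n_dim)) {
        u <- (.vdc(n, .primes[r], skip = skip) + shifts[r]) %% 1
        # clamp away from 0/1 so qnorm stays finite
        u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
        # contiguous blocks per respondent (leapfrogging a Halton sequence by
        # a step sharing factors with the base destroys its equidistribution)
        a[, , r] <- matrix(stats::qnorm(u), nrow = n_resp, ncol = n_draws,
                           byrow = TRUE)
      }
      a
    }
  })
  structure(out, type = type, seed = as.integer(seed))
}
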