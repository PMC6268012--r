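# Fit statistics and the greedy search over segment compositions.

#' Akaike information criterion from a log-likelihood
#'
#' `AIC = 2k - 2 ln(L)` with `ln(L)` the maximized log-likelihood and `k` the
#' number of estimated parameters.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (`k >= 0`).
#' @return numeric.
#' @export
model_aic <- function(loglik, k) {
  stopifnot(k >= 0)
  2 * k - 2 * loglik
}

#' Bayesian information criterion from a log-likelihood
#'
#' `BIC = -2 ln(L) + K ln(Q)` with `Q` the number of choice observations.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param q number of observations (`q >= 1`).
#' @return numeric.
#' @export
model_bic <- function(loglik, k, q) {
  stopifnot(k >= 0, q >= 1)
  -2 * loglik + k * log(q)
}

#' Bundle fit statistics
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of estimated parameters.
#' @param n_obs number of choice observations.
#' @return list with `loglik`, `n_params`, `n_obs`, `aic`, `bic`.
#' @export
fit_statistics <- function(loglik, n_params, n_obs) {
  list(loglik = loglik, n_params = as.integer(n_params),
       n_obs = as.integer(n_obs),
       aic = model_aic(loglik, n_params),
       bic = model_bic(loglik, n_params, n_obs))
}

#' Goodness-of-fit comparison table
#'
#' Builds a model-comparison table (label, log-likelihood, parameters,
#' observations, BIC, AIC) from fitted [lc_choice] objects or from a data
#' frame of `(loglik, n_params, n_obs)` triples (e.g. published values),
#' sorted by the chosen criterion ascending with ties broken by fewer
#' parameters.
#'
#' @param x list of fitted [lc_choice] objects, or a `data.frame` with
#'   columns `loglik`, `n_params`, `n_obs` and optionally `model`.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return a `data.frame` with columns `model`, `loglik`, `n_params`,
#'   `n_obs`, `bic`, `aic`.
#' @export
fit_table <- function(x, criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  if (is.data.frame(x)) {
    stopifnot(all(c("loglik", "n_params", "n_obs") %in% names(x)))
    df <- data.frame(
      model = if ("model" %in% names(x)) x$model else
        paste0("model-", seq_len(nrow(x))),
      loglik = x$loglik, n_params = x$n_params, n_obs = x$n_obs,
      stringsAsFactors = FALSE)
  } else {
    if (inherits(x, "lc_choice")) x <- list(x)
    stopifnot(length(x) >= 1L,
              all(vapply(x, inherits, TRUE, "lc_choice")))
    df <- data.frame(
      model = vapply(seq_along(x), function(i) {
        rules <- vapply(x[[i]]$spec$segments, `[[`, "", "rule")
        nm <- names(x)[i]
        if (!is.null(nm) && nzchar(nm)) nm
        else paste0(sum(rules == "RUM"), " RUM + ", sum(rules == "RRM"), " RRM")
      }, ""),
      loglik = vapply(x, `[[`, 0, "loglik"),
      n_params = vapply(x, function(r) r$fit$n_params, 0L),
      n_obs = vapply(x, function(r) r$fit$n_obs, 0L),
      stringsAsFactors = FALSE)
  }
  df$bic <- model_bic(df$loglik, df$n_params, df$n_obs)
  df$aic <- model_aic(df$loglik, df$n_params)
  key <- if (criterion == "BIC") df$bic else df$aic
  df <- df[order(key, df$n_params), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Greedy search over segment compositions
#'
#' Implements the sequential segment-addition strategy: first the two
#' single-segment models (one per decision rule) are estimated; then, at each
#' step, a new RUM or RRM segment is added to the incumbent composition and
#' both candidates are estimated; the search stops when neither addition
#' improves the selection criterion, when a candidate's smallest population
#' share falls below `min_share` (such models are recorded but inadmissible),
#' or when `max_segments` is reached. All segments use the same attribute
#' list; `exhaustive = TRUE` instead enumerates every composition up to
#' `max_segments`.
#'
#' @param panel a [choice_panel].
#' @param attributes attribute columns used by every segment.
#' @param membership membership covariate names (used when `S > 1`).
#' @param rules candidate decision rules (default both).
#' @param max_segments largest total number of segments explored.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param min_share smallest admissible population share (default 0.05).
#' @param exhaustive enumerate all compositions instead of greedy addition.
#' @param ... further arguments to [lc_choice] (e.g. `n_starts`, `seed`).
#' @return an object of class `lc_search`: list with `evaluated` (named list
#'   of fits or error messages), `table` (comparison data frame with an
#'   `admissible` column), `incumbent` (best admissible fit), `composition`
#'   (its `c(n_rum, n_rrm)`), `criterion`, `min_share`.
#' @export
search_compositions <- function(panel, attributes, membership = character(),
                                rules = c("RUM", "RRM"), max_segments = 4L,
                                criterion = c("BIC", "AIC"), min_share = 0.05,
                                exhaustive = FALSE, ...) {
  criterion <- match.arg(criterion)
  stopifnot(max_segments >= 1L)
  rules <- match.arg(rules, c("RUM", "RRM"), several.ok = TRUE)

  comp_label <- function(comp) paste0(comp[1L], "RUM+", comp[2L], "RRM")
  make_spec <- function(comp) {
    segs <- c(replicate(comp[1L], segment_spec("RUM", attributes),
                        simplify = FALSE),
              replicate(comp[2L], segment_spec("RRM", attributes),
                        simplify = FALSE))
    model_spec(segs, membership = if (sum(comp) > 1L) membership else character())
  }

  evaluated <- list()
  crit_of <- function(fit) if (criterion == "BIC") fit$fit$bic else fit$fit$aic
  eval_comp <- function(comp) {
    lab <- comp_label(comp)
    if (!is.null(evaluated[[lab]])) return(invisible(NULL))
    fit <- tryCatch(lc_choice(panel, make_spec(comp), ...),
                    error = function(e) conditionMessage(e))
    evaluated[[lab]] <<- fit
    invisible(NULL)
  }
  admissible <- function(fit) {
    inherits(fit, "lc_choice") && min(fit$shares) >= min_share
  }

  singles <- list()
  if ("RUM" %in% rules) singles <- c(singles, list(c(1L, 0L)))
  if ("RRM" %in% rules) singles <- c(singles, list(c(0L, 1L)))
  for (comp in singles) eval_comp(comp)

  if (exhaustive) {
    for (total in seq_len(max_segments)) {
      for (nr in 0:total) {
        comp <- c(nr, total - nr)
        if ((comp[1L] > 0L && !"RUM" %in% rules) ||
            (comp[2L] > 0L && !"RRM" %in% rules)) next
        eval_comp(comp)
      }
    }
  } else {
    pick_best <- function() {
      fits <- Filter(admissible, evaluated)
      if (!length(fits)) return(NULL)
      fits[[order(vapply(fits, crit_of, 0),
                  vapply(fits, function(f) f$fit$n_params, 0L))[1L]]]
    }
    repeat {
      incumbent <- pick_best()
      if (is.null(incumbent)) break
      rl <- vapply(incumbent$spec$segments, `[[`, "", "rule")
      comp <- c(sum(rl == "RUM"), sum(rl == "RRM"))
      if (sum(comp) >= max_segments) break
      cands <- list()
      if ("RUM" %in% rules) cands <- c(cands, list(comp + c(1L, 0L)))
      if ("RRM" %in% rules) cands <- c(cands, list(comp + c(0L, 1L)))
      for (cc in cands) eval_comp(cc)
      new_best <- pick_best()
      improved <- !is.null(new_best) && crit_of(new_best) < crit_of(incumbent)
      if (!improved) break
    }
  }

  fits <- Filter(function(f) inherits(f, "lc_choice"), evaluated)
  if (!length(fits)) stop("every candidate composition failed to estimate")
  tab <- fit_table(fits, criterion = criterion)
  tab$admissible <- vapply(tab$model, function(lab) admissible(fits[[lab]]),
                           TRUE)
  adm <- Filter(admissible, fits)
  best <- adm[[order(vapply(adm, crit_of, 0),
                     vapply(adm, function(f) f$fit$n_params, 0L))[1L]]]
  rl <- vapply(best$spec$segments, `[[`, "", "rule")
  structure(list(evaluated = evaluated, table = tab, incumbent = best,
                 composition = c(n_rum = sum(rl == "RUM"),
                                 n_rrm = sum(rl == "RRM")),
                 criterion = criterion, min_share = min_share),
            class = "lc_search")
}

#' @export
print.lc_search <- function(x, ...) {
  cat("Segment-composition search (criterion:", x$criterion,
      ", min share:", x$min_share, ")\n")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 3)
  tab$bic <- round(tab$bic, 3)
  tab$aic <- round(tab$aic, 3)
  print(tab, row.names = FALSE)
  cat("Selected composition:", x$composition["n_rum"], "RUM +",
      x$composition["n_rrm"], "RRM\n")
  invisible(x)
}
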