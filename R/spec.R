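# Model specification objects: segment definitions (decision rule + attribute
# set + random-coefficient flags), the full latent-class layout, and the
# structured <-> flat parameter-vector mapping used by the optimizer.

#' Define one latent segment
#'
#' A segment is characterized by its decision rule — `"RUM"` (random utility
#' maximization: linear-in-attributes utility, multinomial logit) or `"RRM"`
#' (random regret minimization: pairwise softplus regret, logit over negated
#' regrets) — the attribute columns entering its choice model, and the subset
#' of those attributes given a normally distributed random coefficient.
#'
#' @param rule `"RUM"` or `"RRM"`.
#' @param attributes character vector of attribute column names.
#' @param random subset of `attributes` receiving random (mixed) coefficients.
#' @param label optional display label.
#' @return object of class `segment_spec`.
#' @export
segment_spec <- function(rule = c("RUM", "RRM"), attributes,
                         random = character(), label = NULL) {
  rule <- match.arg(rule)
  attributes <- as.character(attributes)
  random <- as.character(random)
  if (!length(attributes)) stop("a segment needs at least one attribute")
  if (anyDuplicated(attributes)) stop("duplicate attributes in segment")
  extra <- setdiff(random, attributes)
  if (length(extra)) {
    stop("random attributes not in the segment's attribute list: ",
         paste(extra, collapse = ", "))
  }
  structure(list(rule = rule, attributes = attributes, random = random,
                 label = label),
            class = "segment_spec")
}

#' Define a latent-class model layout
#'
#' Combines an ordered list of [segment_spec]s with the respondent covariates
#' driving the logit membership model. The base segment's membership
#' coefficients are fixed to zero for identification.
#'
#' @param segments list of [segment_spec]; length `S >= 1`.
#' @param membership character vector of covariate column names (the intercept
#'   column `"(Intercept)"` is added if absent); must be empty when `S = 1`.
#' @param base index of the base segment (default 1).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(segments, membership = character(), base = 1L) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  if (!length(segments)) stop("at least one segment is required (S >= 1)")
  if (!all(vapply(segments, inherits, TRUE, "segment_spec"))) {
    stop("'segments' must be a list of segment_spec objects")
  }
  S <- length(segments)
  base <- as.integer(base)
  if (base < 1L || base > S) stop("base segment index out of range")
  membership <- as.character(membership)
  if (S == 1L) {
    membership <- character()
  } else if (!"(Intercept)" %in% membership) {
    membership <- c("(Intercept)", membership)
  }
  for (s in seq_len(S)) {
    if (is.null(segments[[s]]$label)) {
      segments[[s]]$label <- paste0("Segment-", s, " (", segments[[s]]$rule, ")")
    }
  }
  structure(list(segments = segments, membership = membership, base = base),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Latent-class model:", length(x$segments), "segment(s)\n")
  for (s in seq_along(x$segments)) {
    seg <- x$segments[[s]]
    cat(sprintf("  %d. %s [%s]%s: %s\n", s, seg$label, seg$rule,
                if (s == x$base) " (membership base)" else "",
                paste(seg$attributes, collapse = ", ")))
    if (length(seg$random)) {
      cat("     random coefficients:", paste(seg$random, collapse = ", "), "\n")
    }
  }
  if (length(x$membership)) {
    cat("Membership covariates:", paste(x$membership, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a model specification against a panel
#'
#' Checks that every attribute named by the segments exists among the panel's
#' attribute columns and every membership covariate among the panel's
#' respondent covariates. Returns the spec unchanged.
#'
#' @param spec a [model_spec].
#' @param panel a [choice_panel].
#' @return `spec`, invisibly validated.
#' @export
validate_spec <- function(spec, panel) {
  stopifnot(inherits(spec, "model_spec"), inherits(panel, "choice_panel"))
  for (s in seq_along(spec$segments)) {
    seg <- spec$segments[[s]]
    unknown <- setdiff(seg$attributes, panel$attributes)
    if (length(unknown)) {
      stop("segment ", s, " names unknown attribute(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  unknown <- setdiff(spec$membership, colnames(panel$z))
  if (length(unknown)) {
    stop("unknown membership covariate(s): ", paste(unknown, collapse = ", "))
  }
  spec
}

#' Create a zero-initialized parameter set for a model spec
#'
#' A parameter set holds membership coefficients `gamma` (one named vector per
#' non-base segment), per-segment choice coefficients `beta` (utility
#' coefficients for RUM segments, regret coefficients for RRM segments) and
#' `log_spread` — the log mixing standard deviation for each random
#' coefficient, so the spread is strictly positive by construction.
#'
#' @param spec a [model_spec].
#' @return object of class `parameter_set`: list with elements `gamma`,
#'   `beta`, `log_spread`.
#' @export
parameter_set <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  S <- length(spec$segments)
  gamma <- vector("list", S)
  for (s in seq_len(S)) {
    if (s != spec$base && length(spec$membership)) {
      gamma[[s]] <- stats::setNames(numeric(length(spec$membership)),
                                    spec$membership)
    }
  }
  beta <- lapply(spec$segments, function(seg) {
    stats::setNames(numeric(length(seg$attributes)), seg$attributes)
  })
  log_spread <- lapply(spec$segments, function(seg) {
    stats::setNames(numeric(length(seg$random)), seg$random)
  })
  structure(list(gamma = gamma, beta = beta, log_spread = log_spread),
            class = "parameter_set")
}

#' Flatten a parameter set to the optimizer's real vector
#'
#' Deterministic layout: membership coefficients of each non-base segment (in
#' segment order), then each segment's choice coefficients, then each
#' segment's log mixing spreads. [unflatten_params] is the exact inverse.
#'
#' @param params a `parameter_set`.
#' @param spec the [model_spec] it belongs to.
#' @return named numeric vector.
#' @export
flatten_params <- function(params, spec) {
  S <- length(spec$segments)
  out <- numeric(0)
  for (s in seq_len(S)) {
    g <- params$gamma[[s]]
    if (!is.null(g) && length(g)) {
      out <- c(out, stats::setNames(g, paste0("gamma", s, ".", names(g))))
    }
  }
  for (s in seq_len(S)) {
    b <- params$beta[[s]]
    out <- c(out, stats::setNames(b, paste0("beta", s, ".", names(b))))
  }
  for (s in seq_len(S)) {
    v <- params$log_spread[[s]]
    if (length(v)) {
      out <- c(out, stats::setNames(v, paste0("lsd", s, ".", names(v))))
    }
  }
  out
}

#' Rebuild a structured parameter set from a flat vector
#'
#' @param theta numeric vector in the layout produced by [flatten_params].
#' @param spec the [model_spec].
#' @return a `parameter_set`.
#' @export
unflatten_params <- function(theta, spec) {
  params <- parameter_set(spec)
  pos <- 0L
  take <- function(n) {
    if (pos + n > length(theta)) stop("parameter vector too short for spec")
    v <- theta[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  S <- length(spec$segments)
  for (s in seq_len(S)) {
    g <- params$gamma[[s]]
    if (!is.null(g) && length(g)) {
      params$gamma[[s]][] <- take(length(g))
    }
  }
  for (s in seq_len(S)) {
    params$beta[[s]][] <- take(length(params$beta[[s]]))
  }
  for (s in seq_len(S)) {
    if (length(params$log_spread[[s]])) {
      params$log_spread[[s]][] <- take(length(params$log_spread[[s]]))
    }
  }
  if (pos != length(theta)) stop("parameter vector too long for spec")
  params
}

# number of free parameters implied by a spec
n_params <- function(spec) {
  length(flatten_params(parameter_set(spec), spec))
}
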