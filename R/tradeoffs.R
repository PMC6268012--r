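# Time-based trade-offs (willingness-to-travel) for RUM and RRM segments,
# including the "Value of Clean Ride" for pollution-exposure attributes.

#' Willingness-to-travel for a utility-based segment
#'
#' For a RUM segment the trade-off between an attribute and travel time is
#' the ratio of their coefficients: minutes of extra travel a respondent will
#' accept per `scale` units of the attribute. By default the value is
#' reported as positive minutes (the magnitude of the ratio), the convention
#' for willingness-to-travel tables; set `magnitude = FALSE` for the raw
#' signed ratio.
#'
#' @param beta_attr coefficient of the attribute.
#' @param beta_time coefficient of travel time (per minute); must be nonzero.
#' @param scale attribute units to evaluate (e.g. 15 for a 15-ppb exposure
#'   level); default 1.
#' @param magnitude report positive minutes (default `TRUE`).
#' @return minutes.
#' @export
#' @examples
#' tradeoff_rum(-1.795, -0.050)        # 35.9 minutes
#' tradeoff_rum(-0.058, -0.050, 15)    # 17.4 minutes per 15 ppb
tradeoff_rum <- function(beta_attr, beta_time, scale = 1, magnitude = TRUE) {
  if (any(beta_time == 0)) stop("travel-time coefficient must be nonzero")
  r <- (beta_attr * scale) / beta_time
  if (magnitude) abs(r) else r
}

#' Willingness-to-travel for a regret-based segment
#'
#' For an RRM segment the trade-off is choice-set dependent. With attribute
#' differences `delta_attr[j] = t_j - t_i` and travel-time differences
#' `delta_time[j] = r_j - r_i` to each competitor `j`, the value is
#'
#' `sum_j -beta_attr * logistic(beta_attr * delta_attr_j) /
#'  sum_j -beta_time * logistic(beta_time * delta_time_j)`
#'
#' where `logistic(u) = 1 / (1 + exp(-u))`. When every difference is zero
#' each logistic term equals 1/2 and the value reduces to the coefficient
#' ratio `beta_attr / beta_time`.
#'
#' @param beta_attr regret coefficient of the attribute.
#' @param beta_time regret coefficient of travel time.
#' @param delta_attr numeric vector of attribute differences, one per
#'   competitor (length >= 1).
#' @param delta_time numeric vector of travel-time differences (minutes),
#'   same length as `delta_attr`.
#' @return minutes (raw ratio; sign follows the formula).
#' @export
#' @examples
#' tradeoff_rrm(-2.131, -0.248, delta_attr = -1, delta_time = -10)
tradeoff_rrm <- function(beta_attr, beta_time, delta_attr, delta_time) {
  stopifnot(length(delta_attr) >= 1L,
            length(delta_attr) == length(delta_time))
  num <- sum(-beta_attr * stats::plogis(beta_attr * delta_attr))
  den <- sum(-beta_time * stats::plogis(beta_time * delta_time))
  if (abs(den) < .Machine$double.eps * 100) {
    stop("travel-time denominator is numerically zero")
  }
  num / den
}

# Extract the (named) choice coefficient vector and rule for one segment from
# a fitted object, or pass a named numeric vector straight through.
.segment_coefs <- function(object, segment = NULL) {
  if (inherits(object, "lc_choice")) {
    if (is.null(segment)) stop("a segment index is required for a fitted model")
    S <- length(object$spec$segments)
    if (segment < 1L || segment > S) stop("segment index out of range")
    list(beta = object$params$beta[[segment]],
         rule = object$spec$segments[[segment]]$rule)
  } else if (is.numeric(object) && !is.null(names(object))) {
    list(beta = object, rule = NA_character_)
  } else {
    stop("'object' must be a fitted lc_choice model or a named numeric vector")
  }
}

#' Value of Clean Ride
#'
#' Minutes of extra travel accepted per ppb reduction in pollution exposure,
#' for the mean- and maximum-exposure attributes of a utility-based segment:
#' the magnitude of each exposure coefficient divided by the travel-time
#' coefficient.
#'
#' @param object a fitted [lc_choice] or a named coefficient vector.
#' @param segment segment index (required for a fitted model); must be a RUM
#'   segment.
#' @param mean_name,max_name,time_name coefficient names of mean exposure,
#'   maximum exposure and travel time.
#' @return named vector `c(mean = ..., max = ...)` in min/ppb.
#' @export
#' @examples
#' value_of_clean_ride(c(mean_exposure = -0.058, max_exposure = -0.034,
#'                       travel_time = -0.050))
value_of_clean_ride <- function(object, segment = NULL,
                                mean_name = "mean_exposure",
                                max_name = "max_exposure",
                                time_name = "travel_time") {
  sc <- .segment_coefs(object, segment)
  if (!is.na(sc$rule) && sc$rule != "RUM") {
    stop("Value of Clean Ride is defined for RUM segments")
  }
  need <- c(mean_name, max_name, time_name)
  miss <- setdiff(need, names(sc$beta))
  if (length(miss)) {
    stop("coefficient(s) absent from segment: ", paste(miss, collapse = ", "))
  }
  c(mean = tradeoff_rum(sc$beta[[mean_name]], sc$beta[[time_name]]),
    max = tradeoff_rum(sc$beta[[max_name]], sc$beta[[time_name]]))
}

#' Time-based trade-off table
#'
#' Builds a willingness-to-travel table over a grid of travel times. For RUM
#' segments the trade-off is constant in travel time (a single column,
#' repeated); for RRM segments one column per grid value is computed with
#' [tradeoff_rrm] under an explicit difference configuration. Because
#' regret-based trade-offs are choice-set dependent, the configuration
#' (number of competitors and the functions generating attribute and time
#' differences) must be supplied or defaulted *explicitly*; it is echoed in
#' the CSV header when `file` is given.
#'
#' @param object a fitted [lc_choice], or a named list of named coefficient
#'   vectors with a `rule` attribute each.
#' @param rows `data.frame` with columns `label`, `variable` (coefficient
#'   name) and `scale` (units multiplier); defaults to every coefficient
#'   except travel time at scale 1.
#' @param time_grid travel-time grid in minutes (default 20, 25, 30, 35, 40).
#' @param time_name travel-time coefficient name.
#' @param config list with `delta_attr(scale)` and `delta_time(t, grid)`
#'   returning one difference per competitor. Default: a single competitor
#'   that has the attribute advantage (`delta_attr = -scale`) and the
#'   travel-time advantage of the fastest grid option
#'   (`delta_time = min(grid) - t`).
#' @param file optional CSV output path.
#' @return `data.frame` of class `tradeoff_table`: one row per attribute,
#'   one column per segment (RUM) or per segment x grid value (RRM).
#' @export
tradeoff_table <- function(object, rows = NULL,
                           time_grid = c(20, 25, 30, 35, 40),
                           time_name = "travel_time",
                           config = list(
                             delta_attr = function(scale) -scale,
                             delta_time = function(t, grid) min(grid) - t),
                           file = NULL) {
  stopifnot(inherits(object, "lc_choice"))
  spec <- object$spec
  segs <- seq_along(spec$segments)
  has_time <- vapply(segs, function(s) {
    time_name %in% names(object$params$beta[[s]])
  }, TRUE)
  if (any(!has_time)) {
    warning("segment(s) without a travel-time coefficient skipped: ",
            paste(which(!has_time), collapse = ", "))
    segs <- segs[has_time]
  }
  if (is.null(rows)) {
    vars <- unique(unlist(lapply(segs, function(s) {
      setdiff(names(object$params$beta[[s]]), time_name)
    })))
    rows <- data.frame(label = vars, variable = vars, scale = 1)
  }
  out <- data.frame(attribute = rows$label, stringsAsFactors = FALSE)
  for (s in segs) {
    seg <- spec$segments[[s]]
    beta <- object$params$beta[[s]]
    bt <- beta[[time_name]]
    if (seg$rule == "RUM") {
      col <- vapply(seq_len(nrow(rows)), function(r) {
        v <- rows$variable[r]
        if (!v %in% names(beta)) return(NA_real_)
        tradeoff_rum(beta[[v]], bt, scale = rows$scale[r])
      }, 0)
      out[[seg$label]] <- col
    } else {
      for (t in time_grid) {
        col <- vapply(seq_len(nrow(rows)), function(r) {
          v <- rows$variable[r]
          if (!v %in% names(beta)) return(NA_real_)
          abs(tradeoff_rrm(beta[[v]], bt,
                           delta_attr = config$delta_attr(rows$scale[r]),
                           delta_time = config$delta_time(t, time_grid)))
        }, 0)
        out[[paste0(seg$label, " @", t, "min")]] <- col
      }
    }
  }
  class(out) <- c("tradeoff_table", "data.frame")
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(
      "# Time-based trade-offs (willingness-to-travel, minutes)",
      "# RRM columns are choice-set dependent; difference configuration:",
      paste0("#   competitors: ", length(config$delta_attr(1))),
      paste0("#   delta_attr: ",
             paste(deparse(config$delta_attr), collapse = " ")),
      paste0("#   delta_time: ",
             paste(deparse(config$delta_time), collapse = " ")),
      paste0("#   travel-time grid: ", paste(time_grid, collapse = ", "))),
      con)
    utils::write.csv(out, con, row.names = FALSE)
  }
  out
}
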