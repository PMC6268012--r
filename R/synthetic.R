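# Synthetic stated-preference generator: partitioned route-choice experiment
# designs (three generic route alternatives, five scenarios per respondent,
# five attributes shown per scenario) and choice simulation from arbitrary
# latent-class RUM/RRM parameter sets. This is the fixture source for every
# estimation test and for parameter-recovery studies.

#' Attribute catalog for the route-choice experiment
#'
#' The default attribute levels: three roadway characteristics (grade,
#' traffic volume, roadway type — three levels each), two cycling
#' infrastructure characteristics (continuity, segregation — two levels
#' each), NO2 exposure in ppb (mean 5/10/15, maximum 20/40/60) and travel
#' time in minutes (20 to 40 in steps of 5). Categorical base levels (flat
#' grade, light traffic, residential road, discontinuous, shared) are listed
#' first and omitted from the dummy coding.
#'
#' @return a list with elements `categorical` (named list of level vectors,
#'   base first), `numeric` (named list of level sets), `core` (attributes
#'   shown in every scenario), `roadway` and `bike` (the rotating blocks).
#' @export
sp_attribute_catalog <- function() {
  list(
    categorical = list(
      grade = c("flat", "moderate", "steep"),
      traffic = c("light", "moderate", "heavy"),
      road_type = c("residential", "minor_arterial", "major_arterial"),
      continuity = c("discontinuous", "continuous"),
      segregation = c("shared", "exclusive")),
    numeric = list(
      mean_exposure = c(5, 10, 15),
      max_exposure = c(20, 40, 60),
      travel_time = c(20, 25, 30, 35, 40)),
    core = c("mean_exposure", "max_exposure", "travel_time"),
    roadway = c("grade", "traffic", "road_type"),
    bike = c("continuity", "segregation"))
}

# dummy column names for one conceptual attribute
.cat_cols <- function(name, levels) paste(name, levels[-1L], sep = "_")

#' Generate a partitioned stated-preference design
#'
#' Builds the attribute side of a choice panel (no choices yet): each
#' respondent faces `scenarios_per_respondent` scenarios of `n_alternatives`
#' generic routes. Every scenario shows the three core attributes (mean
#' exposure, maximum exposure, travel time) plus one roadway and one bike
#' attribute; the rotating blocks are assigned per respondent round-robin, so
#' pooling respondents covers all attributes. Levels are drawn uniformly at
#' random per alternative from the catalog; categorical attributes are
#' dummy-coded with the base level omitted. Deterministic given `seed`.
#'
#' @param n_respondents number of respondents.
#' @param scenarios_per_respondent choice occasions per respondent (default 5).
#' @param n_alternatives routes per scenario (default 3).
#' @param seed integer seed.
#' @param catalog attribute catalog, see [sp_attribute_catalog].
#' @return a [choice_panel] skeleton with `chosen = NA` and an
#'   intercept-only covariate matrix.
#' @export
generate_design <- function(n_respondents, scenarios_per_respondent = 5L,
                            n_alternatives = 3L, seed = 1L,
                            catalog = sp_attribute_catalog()) {
  stopifnot(n_respondents >= 1L, scenarios_per_respondent >= 1L,
            n_alternatives >= 2L)
  K <- scenarios_per_respondent
  I <- n_alternatives
  n_obs <- n_respondents * K
  cat_cols <- unlist(lapply(names(catalog$categorical), function(a) {
    .cat_cols(a, catalog$categorical[[a]])
  }))
  attrs <- c(cat_cols, names(catalog$numeric))
  groups <- c(lapply(stats::setNames(names(catalog$categorical),
                                     names(catalog$categorical)),
                     function(a) .cat_cols(a, catalog$categorical[[a]])),
              lapply(stats::setNames(names(catalog$numeric),
                                     names(catalog$numeric)), identity))

  # round-robin rotating-block assignment per respondent
  road_attr <- catalog$roadway[(seq_len(n_respondents) - 1L) %%
                                 length(catalog$roadway) + 1L]
  bike_attr <- catalog$bike[(seq_len(n_respondents) - 1L) %%
                              length(catalog$bike) + 1L]

  x <- array(0, dim = c(n_obs, I, length(attrs)),
             dimnames = list(NULL, NULL, attrs))
  avail <- matrix(FALSE, n_obs, length(attrs), dimnames = list(NULL, attrs))
  resp <- rep(seq_len(n_respondents), each = K)

  with_seed(seed, {
    for (a in names(catalog$numeric)) {
      lv <- catalog$numeric[[a]]
      x[, , a] <- matrix(sample(lv, n_obs * I, replace = TRUE), n_obs, I)
      avail[, a] <- TRUE
    }
    for (a in names(catalog$categorical)) {
      lv <- catalog$categorical[[a]]
      shown <- (road_attr == a | bike_attr == a)[resp]
      if (!any(shown)) next
      cols <- .cat_cols(a, lv)
      lev_draw <- matrix(sample(seq_along(lv), n_obs * I, replace = TRUE),
                         n_obs, I)
      for (j in seq_along(cols)) {
        x[, , cols[j]][shown, ] <- (lev_draw == j + 1L)[shown, ] * 1
      }
      avail[shown, cols] <- TRUE
    }
  })

  choice_panel(x, chosen = rep(NA_integer_, n_obs), resp = resp,
               avail = avail, groups = groups)
}

#' Generate respondent covariates
#'
#' Simulates a respondent covariate matrix with an intercept column,
#' independent binary dummies with the given proportions, and optional
#' mutually exclusive categorical dummies. Defaults loosely emulate a
#' commuter-cyclist sample: 42% female, 40% aged 35+, 58% from a
#' car-owning household, 35% daily riders, and commute length split
#' short / moderate-to-long / long as 45/35/20%.
#'
#' @param n_respondents number of respondents.
#' @param proportions named vector of Bernoulli proportions, one dummy each.
#' @param exclusive named list of named probability vectors; each generates a
#'   mutually exclusive dummy block, the *first* (base) category omitted.
#' @param seed integer seed.
#' @return numeric matrix `(n_respondents, P)` with an `"(Intercept)"` column.
#' @export
generate_covariates <- function(n_respondents,
                                proportions = c(female = 0.42,
                                                age_35plus = 0.40,
                                                auto_owner = 0.58,
                                                biking_daily = 0.35),
                                exclusive = list(
                                  commute = c(short = 0.45,
                                              moderate_long = 0.35,
                                              long = 0.20)),
                                seed = 1L) {
  stopifnot(n_respondents >= 1L,
            all(proportions >= 0 & proportions <= 1))
  with_seed(seed, {
    z <- matrix(1, n_respondents, 1L, dimnames = list(NULL, "(Intercept)"))
    for (nm in names(proportions)) {
      z <- cbind(z, stats::rbinom(n_respondents, 1L, proportions[nm]))
      colnames(z)[ncol(z)] <- nm
    }
    for (nm in names(exclusive)) {
      p <- exclusive[[nm]]
      stopifnot(abs(sum(p) - 1) < 1e-8)
      draw <- sample(seq_along(p), n_respondents, replace = TRUE, prob = p)
      for (j in seq_along(p)[-1L]) {
        z <- cbind(z, as.numeric(draw == j))
        colnames(z)[ncol(z)] <- paste(nm, names(p)[j], sep = "_")
      }
    }
    z
  })
}

#' Simulate choices from a latent-class truth
#'
#' Turns a design skeleton into a full choice panel by simulating from a
#' generating latent-class model: each respondent's segment is drawn from the
#' logit membership model on `z`; if the segment has random coefficients, a
#' respondent-level coefficient vector is drawn from the mixing normal; each
#' scenario's chosen alternative is then drawn from the segment's RUM or RRM
#' choice probabilities. The true segment labels are attached as attribute
#' `"true_segment"` for diagnostics only — estimation code never reads them.
#' Deterministic given `seed`.
#'
#' @param design a [choice_panel] skeleton (e.g. from [generate_design]).
#' @param spec the generating [model_spec].
#' @param params the generating `parameter_set`.
#' @param z respondent covariate matrix (default: the design's own `z`).
#' @param seed integer seed.
#' @return a [choice_panel] with simulated `chosen` and covariates `z`.
#' @export
simulate_choices <- function(design, spec, params, z = NULL, seed = 1L) {
  stopifnot(inherits(design, "choice_panel"))
  panel <- design
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (!"(Intercept)" %in% colnames(z)) z <- cbind(`(Intercept)` = 1, z)
    stopifnot(nrow(z) == panel$n_resp)
    panel$z <- z
  }
  validate_spec(spec, panel)
  S <- length(spec$segments)
  Pm <- membership_probabilities(panel$z, params$gamma, spec)

  chosen <- integer(panel$n_obs)
  with_seed(seed, {
    seg_of <- vapply(seq_len(panel$n_resp), function(c) {
      sample.int(S, 1L, prob = Pm[c, ])
    }, 0L)
    for (s in seq_len(S)) {
      seg <- spec$segments[[s]]
      members <- which(seg_of == s)
      if (!length(members)) next
      rows <- which(panel$resp %in% members)
      beta <- params$beta[[s]][seg$attributes]
      bmat <- matrix(beta, panel$n_obs, length(beta), byrow = TRUE)
      if (length(seg$random)) {
        sigma <- exp(params$log_spread[[s]][seg$random])
        ridx <- match(seg$random, seg$attributes)
        for (r in seq_along(seg$random)) {
          dev <- stats::setNames(rep(0, panel$n_resp), NULL)
          dev[members] <- stats::rnorm(length(members), 0, sigma[r])
          bmat[, ridx[r]] <- bmat[, ridx[r]] + dev[panel$resp]
        }
      }
      P <- if (seg$rule == "RUM") {
        mnl_probabilities(rum_utilities(panel, bmat, seg$attributes))
      } else {
        rrm_probabilities(rrm_regret(panel, bmat, seg$attributes))
      }
      for (i in rows) {
        chosen[i] <- sample.int(panel$n_alt, 1L, prob = P[i, ])
      }
    }
    panel$chosen <- chosen
    attr(panel, "true_segment") <- seg_of
  })
  panel
}
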