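# Choice-panel container: respondents x occasions x alternatives attribute data
# with a chosen-alternative index, respondent covariates and an
# attribute-availability mask for partitioned stated-preference designs.

#' Construct a choice panel
#'
#' The central data container: a stated-preference (or any repeated-choice)
#' panel with `C` respondents, a fixed number of choice occasions per
#' respondent, `I` unlabeled alternatives per occasion and `M` real-valued
#' attribute columns (categorical attributes are expected dummy-coded).
#' Scenarios are stored as rows of a three-way array `x[obs, alternative,
#' attribute]`; `avail[obs, attribute]` marks which attributes were actually
#' shown in that scenario. Attributes that were not shown contribute zero to
#' utility and regret in every kernel.
#'
#' @param x numeric array `(n_obs, n_alt, n_attr)`; third dimension must carry
#'   attribute names.
#' @param chosen integer vector of chosen alternative indices in `1..n_alt`
#'   (may be `NA` for a design skeleton awaiting simulated choices).
#' @param resp integer vector mapping each observation (scenario) to its
#'   respondent `1..C`; must be non-decreasing blocks.
#' @param z numeric respondent covariate matrix `(C, P)` with column names;
#'   if it lacks an `"(Intercept)"` column one is prepended.
#' @param avail logical availability matrix `(n_obs, n_attr)`; default all
#'   `TRUE`.
#' @param resp_ids optional vector of original respondent identifiers.
#' @param groups optional named list mapping conceptual attributes (e.g.
#'   `grade`) to their dummy-column names; used by design generators.
#' @return an object of class `choice_panel`.
#' @export
choice_panel <- function(x, chosen, resp, z = NULL, avail = NULL,
                         resp_ids = NULL, groups = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  n_obs <- dim(x)[1L]
  n_alt <- dim(x)[2L]
  attrs <- dimnames(x)[[3L]]
  if (is.null(attrs)) stop("attribute dimension of 'x' must be named")
  resp <- as.integer(resp)
  chosen <- as.integer(chosen)
  if (length(chosen) != n_obs) stop("'chosen' must have one entry per scenario")
  if (length(resp) != n_obs) stop("'resp' must have one entry per scenario")
  if (any(diff(resp) < 0L)) stop("'resp' must be grouped and non-decreasing")
  n_resp <- max(resp)
  if (!setequal(unique(resp), seq_len(n_resp))) {
    stop("'resp' must cover 1..C without gaps")
  }
  if (is.null(avail)) {
    avail <- matrix(TRUE, n_obs, length(attrs))
  }
  avail <- matrix(as.logical(avail), n_obs, length(attrs),
                  dimnames = list(NULL, attrs))
  ok <- is.na(chosen) | (chosen >= 1L & chosen <= n_alt)
  if (!all(ok)) stop("'chosen' indices must lie in 1..", n_alt)
  xa <- x
  for (m in seq_along(attrs)) {
    xm <- matrix(x[, , m], n_obs, n_alt)
    bad <- avail[, m] & rowSums(!is.finite(xm)) > 0L
    if (any(bad)) {
      stop("non-finite attribute values where '", attrs[m],
           "' is marked available (scenario ", which(bad)[1L], ")")
    }
    # unavailable cells are normalized to 0 so kernels can skip masking checks
    xm[!avail[, m], ] <- 0
    xa[, , m] <- xm
  }
  if (is.null(z)) {
    z <- matrix(1, n_resp, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    z <- as.matrix(z)
    if (is.null(colnames(z))) stop("'z' must have column names")
    if (!"(Intercept)" %in% colnames(z)) {
      z <- cbind(`(Intercept)` = 1, z)
    }
    if (nrow(z) != n_resp) stop("'z' must have one row per respondent")
  }
  if (is.null(resp_ids)) resp_ids <- seq_len(n_resp)
  structure(
    list(x = xa, chosen = chosen, resp = resp, z = z, avail = avail,
         n_resp = n_resp, n_alt = n_alt, n_obs = n_obs,
         attributes = attrs, resp_ids = resp_ids, groups = groups),
    class = "choice_panel")
}

#' @export
print.choice_panel <- function(x, ...) {
  cat("Choice panel: ", x$n_resp, " respondents, ", x$n_obs, " scenarios, ",
      x$n_alt, " alternatives, ", length(x$attributes), " attribute columns\n",
      sep = "")
  cat("Attributes:", paste(x$attributes, collapse = ", "), "\n")
  cat("Covariates:", paste(colnames(x$z), collapse = ", "), "\n")
  shown <- mean(rowSums(x$avail))
  cat(sprintf("Mean attribute columns shown per scenario: %.1f\n", shown))
  invisible(x)
}

# Expand one character/factor column into base-omitted dummy columns.
# `levels` is the full level vector with the base level first.
.dummy_code <- function(values, name, levels) {
  values[!is.na(values) & !nzchar(values)] <- NA  # empty CSV cells
  known <- !is.na(values) & !(values %in% levels)
  if (any(known)) {
    stop("attribute '", name, "' has level '", values[known][1L],
         "' not in its declared levels")
  }
  non_base <- levels[-1L]
  out <- matrix(NA_real_, length(values), length(non_base),
                dimnames = list(NULL, paste(name, non_base, sep = "_")))
  for (j in seq_along(non_base)) {
    out[, j] <- as.numeric(values == non_base[j])
  }
  out
}

#' Read a choice panel from long-format CSV files
#'
#' Reads a long-format alternatives table (one row per respondent x scenario x
#' alternative) and a respondent covariates table, validates them and returns a
#' [choice_panel]. Categorical attributes named in `factors` are dummy-coded
#' with the first declared level as the omitted base. In partitioned designs,
#' attributes not shown in a scenario must be left empty (`NA`) for *all* of
#' that scenario's alternatives; such cells become unavailable and contribute
#' zero to utility and regret.
#'
#' @param alternatives_file path to the long-format alternatives CSV.
#' @param covariates_file path to the respondent covariates CSV (keyed by the
#'   respondent id column).
#' @param schema named list mapping roles to column names:
#'   `respondent`, `scenario`, `alternative`, `chosen`; optional `attributes`
#'   (defaults to every remaining column).
#' @param factors named list of level vectors (base level first) for
#'   categorical attribute columns; remaining attribute columns are taken as
#'   numeric and passed through unscaled.
#' @return a [choice_panel].
#' @export
read_choice_panel <- function(alternatives_file, covariates_file,
                              schema = list(respondent = "resp_id",
                                            scenario = "scenario",
                                            alternative = "alt",
                                            chosen = "chosen"),
                              factors = NULL) {
  alt <- utils::read.csv(alternatives_file, check.names = FALSE)
  cov <- utils::read.csv(covariates_file, check.names = FALSE)
  need <- c("respondent", "scenario", "alternative", "chosen")
  miss <- setdiff(need, names(schema))
  if (length(miss)) stop("schema missing roles: ", paste(miss, collapse = ", "))
  for (role in need) {
    if (!schema[[role]] %in% names(alt)) {
      stop("alternatives table lacks column '", schema[[role]], "' (", role, ")")
    }
  }
  rid <- alt[[schema$respondent]]
  sid <- alt[[schema$scenario]]
  aid <- alt[[schema$alternative]]
  key <- paste(rid, sid, aid, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (respondent, scenario, alternative) rows in alternatives table")
  }
  attr_cols <- schema$attributes
  if (is.null(attr_cols)) {
    attr_cols <- setdiff(names(alt), unlist(schema[need]))
  }
  if (!length(attr_cols)) stop("no attribute columns found")

  # canonical ordering: respondent blocks, scenarios within, alternatives within
  o <- order(match(rid, unique(rid)), sid, aid)
  alt <- alt[o, , drop = FALSE]
  rid <- rid[o]; sid <- sid[o]; aid <- aid[o]

  resp_ids <- unique(rid)
  cov_key <- cov[[schema$respondent]]
  if (is.null(cov_key)) {
    stop("covariates table lacks respondent id column '", schema$respondent, "'")
  }
  absent <- setdiff(resp_ids, cov_key)
  if (length(absent)) {
    stop("respondents absent from covariates table: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  }

  scen_key <- paste(match(rid, resp_ids), sid, sep = "\r")
  scen <- match(scen_key, unique(scen_key))
  n_obs <- max(scen)
  n_alt <- unique(tabulate(scen))
  if (length(n_alt) != 1L) {
    stop("all scenarios must present the same number of alternatives")
  }

  chosen_flag <- alt[[schema$chosen]]
  n_chosen <- tapply(chosen_flag, scen, sum)
  if (any(n_chosen != 1)) {
    bad <- which(n_chosen != 1)[1L]
    stop("scenario ", bad, " has ", n_chosen[bad], " chosen rows (expected 1)")
  }

  # dummy-code categoricals, pass numerics through
  blocks <- list()
  for (a in attr_cols) {
    if (!is.null(factors) && a %in% names(factors)) {
      blocks[[a]] <- .dummy_code(as.character(alt[[a]]), a, factors[[a]])
    } else {
      v <- alt[[a]]
      if (is.character(v) || is.factor(v)) {
        stop("attribute '", a, "' is non-numeric; declare its levels in 'factors'")
      }
      blocks[[a]] <- matrix(as.numeric(v), ncol = 1L,
                            dimnames = list(NULL, a))
    }
  }
  xm <- do.call(cbind, blocks)
  attrs <- colnames(xm)

  # availability: per scenario x attribute column, all-NA -> not shown
  x <- array(NA_real_, dim = c(n_obs, n_alt, length(attrs)),
             dimnames = list(NULL, NULL, attrs))
  within_alt <- stats::ave(scen, scen, FUN = seq_along)
  for (m in seq_along(attrs)) {
    x[cbind(scen, within_alt, m)] <- xm[, m]
  }
  avail <- matrix(TRUE, n_obs, length(attrs), dimnames = list(NULL, attrs))
  for (m in seq_along(attrs)) {
    na_count <- rowSums(is.na(x[, , m, drop = FALSE]), dims = 1L)
    avail[, m] <- na_count == 0L
    partial <- na_count > 0L & na_count < n_alt
    if (any(partial)) {
      stop("attribute '", attrs[m], "' is empty for some but not all ",
           "alternatives of scenario ", which(partial)[1L],
           "; unshown attributes must be empty for the whole scenario")
    }
    x[, , m][!avail[, m], ] <- 0
  }

  dummy_cols <- unlist(lapply(names(blocks), function(a) {
    if (!is.null(factors) && a %in% names(factors)) colnames(blocks[[a]]) else NULL
  }))
  for (dcol in dummy_cols) {
    vals <- x[, , dcol][avail[, dcol], ]
    if (length(vals) && !all(vals %in% c(0, 1))) {
      stop("dummy column '", dcol, "' has values outside {0, 1}")
    }
  }

  chosen <- integer(n_obs)
  chosen[scen[chosen_flag == 1]] <- within_alt[chosen_flag == 1]
  resp <- match(rid[!duplicated(scen)], resp_ids)

  zc <- cov[match(resp_ids, cov_key), setdiff(names(cov), schema$respondent),
            drop = FALSE]
  z <- as.matrix(zc)
  storage.mode(z) <- "double"
  groups <- if (is.null(factors)) NULL else {
    g <- lapply(attr_cols, function(a) {
      if (a %in% names(factors)) colnames(blocks[[a]]) else a
    })
    names(g) <- attr_cols
    g
  }
  choice_panel(x, chosen, resp, z = z, resp_ids = resp_ids, avail = avail,
               groups = groups)
}

#' Write a choice panel to long-format CSV files
#'
#' Inverse of [read_choice_panel] for an already dummy-coded panel: writes the
#' alternatives table (unavailable attribute cells as empty fields) and the
#' covariates table. Reading the pair back with the default schema and no
#' `factors` reproduces `x`, `chosen`, `z` and the availability mask exactly.
#'
#' @param panel a [choice_panel].
#' @param alternatives_file,covariates_file output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_choice_panel <- function(panel, alternatives_file, covariates_file) {
  stopifnot(inherits(panel, "choice_panel"))
  n_obs <- panel$n_obs; n_alt <- panel$n_alt
  scen_within <- stats::ave(panel$resp, panel$resp, FUN = seq_along)
  long <- data.frame(
    resp_id = rep(panel$resp_ids[panel$resp], each = n_alt),
    scenario = rep(scen_within, each = n_alt),
    alt = rep(seq_len(n_alt), times = n_obs),
    chosen = as.integer(rep(seq_len(n_alt), times = n_obs) ==
                          rep(panel$chosen, each = n_alt)),
    check.names = FALSE)
  for (m in seq_along(panel$attributes)) {
    v <- as.vector(t(.attr_mat(panel, panel$attributes[m])))
    v[rep(!panel$avail[, m], each = n_alt)] <- NA
    long[[panel$attributes[m]]] <- v
  }
  utils::write.csv(long, alternatives_file, row.names = FALSE, na = "")
  covs <- data.frame(resp_id = panel$resp_ids, check.names = FALSE)
  zz <- panel$z
  for (j in colnames(zz)) covs[[j]] <- zz[, j]
  utils::write.csv(covs, covariates_file, row.names = FALSE, na = "")
  invisible(c(alternatives_file, covariates_file))
}
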