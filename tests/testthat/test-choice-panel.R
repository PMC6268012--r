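# Reading, validation and round-tripping of choice-panel data.

make_long_files <- function(dir, n_resp = 2L, K = 5L, I = 3L,
                            drop_attr = NULL, double_chosen = FALSE,
                            drop_cov_resp = FALSE) {
  rows <- expand.grid(alt = seq_len(I), scenario = seq_len(K),
                      resp_id = seq_len(n_resp))
  set.seed(42)
  rows$grade <- sample(c("flat", "moderate", "steep"), nrow(rows), TRUE)
  rows$continuity <- sample(c("discontinuous", "continuous"), nrow(rows), TRUE)
  rows$segregation <- sample(c("shared", "exclusive"), nrow(rows), TRUE)
  rows$mean_exposure <- sample(c(5, 10, 15), nrow(rows), TRUE)
  rows$travel_time <- sample(seq(20, 40, 5), nrow(rows), TRUE)
  rows$chosen <- as.integer(rows$alt == 1L)
  if (double_chosen) rows$chosen[rows$scenario == 2 & rows$resp_id == 1] <- 1L
  if (!is.null(drop_attr)) {
    rows[[drop_attr]][rows$scenario == 1] <- NA
  }
  alt_file <- file.path(dir, "alts.csv")
  cov_file <- file.path(dir, "covs.csv")
  write.csv(rows, alt_file, row.names = FALSE, na = "")
  covs <- data.frame(resp_id = seq_len(n_resp),
                     female = rep_len(c(0, 1), n_resp))
  if (drop_cov_resp) covs <- covs[-1, ]
  write.csv(covs, cov_file, row.names = FALSE)
  list(alts = alt_file, covs = cov_file)
}

schema <- list(respondent = "resp_id", scenario = "scenario",
               alternative = "alt", chosen = "chosen")
factors <- list(grade = c("flat", "moderate", "steep"),
                continuity = c("discontinuous", "continuous"),
                segregation = c("shared", "exclusive"))

test_that("reader recovers panel shape, dummy coding and full availability", {
  f <- make_long_files(withr::local_tempdir())
  p <- read_choice_panel(f$alts, f$covs, schema, factors)
  expect_s3_class(p, "choice_panel")
  expect_equal(p$n_resp, 2L)
  expect_equal(p$n_obs, 10L)
  expect_equal(p$n_alt, 3L)
  expect_true(all(p$avail))
  # base levels omitted: 3-level grade -> 2 dummies, 2-level factors -> 1 each
  expect_setequal(p$attributes,
                  c("grade_moderate", "grade_steep", "continuity_continuous",
                    "segregation_exclusive", "mean_exposure", "travel_time"))
  expect_true(all(p$x[, , "grade_moderate"] %in% c(0, 1)))
  expect_true(all(p$x[, , "grade_moderate"] + p$x[, , "grade_steep"] <= 1))
  expect_true(all(p$chosen == 1L))
  expect_equal(colnames(p$z), c("(Intercept)", "female"))
})

test_that("scenario-wide empty attribute becomes unavailable, partial is an error", {
  f <- make_long_files(withr::local_tempdir(), drop_attr = "segregation")
  p <- read_choice_panel(f$alts, f$covs, schema, factors)
  first <- p$resp == 1 | p$resp == 2
  scen1 <- rep(c(TRUE, rep(FALSE, 4)), 2)  # first scenario of each respondent
  expect_true(all(!p$avail[scen1, "segregation_exclusive"]))
  expect_true(all(p$avail[!scen1, "segregation_exclusive"]))
  # unavailable cells are zero so they contribute nothing downstream
  expect_true(all(p$x[scen1, , "segregation_exclusive"] == 0))

  # partially empty attribute within a scenario is rejected
  alt <- read.csv(f$alts)
  alt$travel_time[1] <- NA
  write.csv(alt, f$alts, row.names = FALSE, na = "")
  expect_error(read_choice_panel(f$alts, f$covs, schema, factors),
               "some but not all")
})

test_that("reader rejects malformed input", {
  dir <- withr::local_tempdir()
  f <- make_long_files(dir, double_chosen = TRUE)
  expect_error(read_choice_panel(f$alts, f$covs, schema, factors), "chosen")

  f <- make_long_files(dir)
  alt <- read.csv(f$alts)
  write.csv(rbind(alt, alt[1, ]), f$alts, row.names = FALSE)
  expect_error(read_choice_panel(f$alts, f$covs, schema, factors), "duplicate")

  f <- make_long_files(dir, drop_cov_resp = TRUE)
  expect_error(read_choice_panel(f$alts, f$covs, schema, factors),
               "absent from covariates")
})

test_that("write/read round-trip reproduces the panel bit-exactly", {
  spec <- model_spec(list(segment_spec("RUM", c("mean_exposure", "travel_time"))))
  tp <- parameter_set(spec)
  tp$beta[[1]][] <- c(-0.1, -0.1)
  d <- generate_design(8, seed = 2)
  z <- generate_covariates(8, seed = 3)
  p <- simulate_choices(d, spec, tp, z = z, seed = 4)
  dir <- withr::local_tempdir()
  write_choice_panel(p, file.path(dir, "a.csv"), file.path(dir, "c.csv"))
  p2 <- read_choice_panel(file.path(dir, "a.csv"), file.path(dir, "c.csv"))
  expect_identical(p2$x, p$x)
  expect_identical(p2$chosen, p$chosen)
  expect_identical(p2$avail, p$avail)
  expect_identical(unname(p2$z), unname(p$z))
  expect_identical(colnames(p2$z), colnames(p$z))
})

test_that("constructor enforces chosen-index and finiteness invariants", {
  x <- array(1, dim = c(2, 3, 1), dimnames = list(NULL, NULL, "a"))
  expect_error(choice_panel(x, chosen = c(1L, 4L), resp = c(1L, 2L)),
               "1..3")
  x[1, 2, 1] <- NA
  expect_error(choice_panel(x, chosen = c(1L, 1L), resp = c(1L, 2L)),
               "non-finite")
})
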