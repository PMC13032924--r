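make_recordings <- function(n, turbine_year = "ty1", site = "s1", month = 7,
                            group = "Nyctaloid", valid = TRUE, offset = 0) {
  data.frame(recording_id = paste0(turbine_year, "_", month, "_", group, "_",
                                   offset + seq_len(n)),
             site_id = site, turbine_year_id = turbine_year, month = month,
             group = group, valid = valid, stringsAsFactors = FALSE)
}

test_that("activity aggregation counts per cell and drops zero-recording cells", {
  rec <- rbind(make_recordings(100, month = 7),
               make_recordings(40, month = 8, group = "Pipistrelloid"))
  buzz <- rec$recording_id[1:2]
  soc <- rec$recording_id[101:104]
  cells <- aggregate_activity(rec, buzz, soc)
  c7 <- cells[cells$month == 7 & cells$group == "Nyctaloid", ]
  expect_equal(c7$n_recordings, 100)
  expect_equal(c7$n_feeding / c7$n_recordings, 0.02)
  expect_equal(sum(cells$n_recordings), nrow(rec))
  expect_equal(sum(cells$n_feeding), 2)
  expect_equal(sum(cells$n_social), 4)
  # the empty cross cells are reported, not silently lost
  excl <- attr(cells, "excluded")
  expect_equal(nrow(cells) + nrow(excl), 2 * 2)  # 2 months x 2 groups
  expect_true(all(excl$n_recordings == 0))
  # invalid recordings are not counted
  rec$valid[1:50] <- FALSE
  cells2 <- aggregate_activity(rec, buzz, soc)
  expect_equal(cells2$n_recordings[cells2$month == 7 &
                                     cells2$group == "Nyctaloid"], 50)
  # unknown recording ids in the buzz table are an error
  expect_error(aggregate_activity(rec, c("nope"), soc), "nope")
})

test_that("month contrasts are orthonormal polynomials matching a Gram-Schmidt oracle", {
  for (n in c(3, 5, 7)) {
    deg <- min(5, n - 1)
    ctr <- suppressWarnings(orthogonal_month_contrasts(n, 5))
    expect_equal(ncol(ctr), deg)
    g <- crossprod(ctr)
    expect_equal(g, diag(deg), tolerance = 1e-12, ignore_attr = TRUE)
    oracle <- gram_schmidt_poly_oracle(n, deg)
    expect_equal(abs(ctr), abs(oracle), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(suppressWarnings(orthogonal_month_contrasts(3, 5))[, 1] *
                 sqrt(2),
               c(-1, 0, 1), tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(orthogonal_month_contrasts(4, 5), "truncated")
  expect_error(orthogonal_month_contrasts(1), "2 ordered levels")
})

test_that("the activity GLMM has the published fixed-effect structure", {
  cells <- simulate_activity_dataset(seed = 21, response = "feeding")
  m <- suppressMessages(fit_activity_glmm(cells, "feeding"))
  expect_s3_class(m, "activity_glmm")
  expect_equal(nrow(m$fixed), 12)
  expect_equal(m$fixed$term[1:3],
               c("(Intercept)", "Species Group (Pip)", "Month (Linear)"))
  expect_true(any(grepl("x Month \\(Quintic\\)", m$fixed$term)))
  expect_setequal(names(m$varcomp), c("site_id", "obs_id"))
  expect_true(m$converged)
})

test_that("the GLMM reduces to plain logistic regression without random-effect variance", {
  cells <- simulate_activity_dataset(seed = 22, response = "feeding",
                                     site_sd = 0, olre_sd = 0,
                                     mean_recordings = 2000, dispersion = 5)
  glmm <- suppressMessages(fit_activity_glmm(cells, "feeding"))
  glm0 <- fit_activity_glmm(cells, "feeding", random_effects = FALSE)
  expect_true(glmm$singular)   # variances estimated at the boundary
  expect_equal(glmm$fixed$estimate, glm0$fixed$estimate, tolerance = 1e-4)
})

test_that("estimates are invariant to the row order of the cells", {
  cells <- simulate_activity_dataset(seed = 23, response = "feeding")
  m1 <- suppressMessages(fit_activity_glmm(cells, "feeding"))
  set.seed(1)
  m2 <- suppressMessages(
    fit_activity_glmm(cells[sample(nrow(cells)), ], "feeding"))
  expect_equal(m1$fixed$estimate, m2$fixed$estimate, tolerance = 1e-3)
})

test_that("marginal means and Tukey contrasts behave at the degenerate and null limits", {
  # identical groups: contrasts ~ 0 with p ~ 1
  base <- expand.grid(turbine_year_id = paste0("ty", 1:8), month = 5:9,
                      stringsAsFactors = FALSE)
  base$site_id <- rep(paste0("s", 1:4), each = 2)[
    as.integer(sub("ty", "", base$turbine_year_id))]
  base$n_recordings <- 200
  base$n_feeding <- rep(c(3, 5, 8, 6, 4), each = 8) +
    rep(c(0, 1, 2, 1), length.out = nrow(base))
  cells <- rbind(transform(base, group = "Nyctaloid"),
                 transform(base, group = "Pipistrelloid"))
  m <- suppressWarnings(suppressMessages(fit_activity_glmm(cells, "feeding")))
  mm <- suppressWarnings(marginal_means_and_contrasts(m))
  expect_true(all(abs(mm$contrasts$estimate) < 1e-4))
  expect_true(all(mm$contrasts$p.value > 0.99))
  # Tukey adjustment never reduces a p-value
  mm_all <- suppressWarnings(marginal_means_and_contrasts(m, by_month = FALSE))
  ctr_raw <- emmeans::contrast(
    emmeans::emmeans(m$fit, ~ group * month), method = "pairwise",
    adjust = "none")
  expect_true(all(mm_all$contrasts$p.value >=
                    summary(ctr_raw)$p.value - 1e-12))
})

test_that("Spearman activity correlations match direct rank computation", {
  counts <- data.frame(bat_files = c(10, 50, 200, 500, 1000),
                       buzz_files = c(1, 4, 10, 30, 80),
                       social_files = c(80, 30, 12, 4, 1))
  out <- activity_correlation(counts)
  expect_equal(out$rho, c(1, -1))
  # tied data: rho equals the average-rank (Pearson-on-ranks) oracle
  set.seed(30)
  tied <- data.frame(bat_files = sample(1:5, 20, replace = TRUE),
                     buzz_files = sample(1:4, 20, replace = TRUE))
  got <- activity_correlation(tied, responses = "buzz_files")
  oracle <- cor(rank(tied$bat_files), rank(tied$buzz_files))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_error(activity_correlation(
    data.frame(bat_files = rep(1, 5), buzz_files = 1:5)), "constant")
  expect_error(activity_correlation(counts[1:3, ]), "n >= 4")
})
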