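#' Aggregate monthly activity cells from recording-level tables
#'
#' Builds the turbine-year x month x species-group table feeding the
#' binomial mixed model: per cell, the number of valid bat recordings and
#' how many of them contained feeding buzzes or social vocalisations.
#' Cells of the full turbine-year x month x group grid with zero valid
#' recordings are dropped and reported in the `excluded` attribute.
#'
#' @param recordings Data.frame with one row per bat recording: columns
#'   `recording_id`, `site_id`, `turbine_year_id`, `month`, `group`,
#'   `valid` (logical; microphone sensitivity within calibration bounds).
#' @param buzzes Data.frame (or vector) of `recording_id`s containing
#'   feeding buzzes.
#' @param social Data.frame (or vector) of `recording_id`s containing
#'   social vocalisations.
#' @return Data.frame of activity cells: `site_id`, `turbine_year_id`,
#'   `month`, `group`, `n_recordings`, `n_feeding`, `n_social`, with the
#'   dropped zero-recording cells in `attr(, "excluded")`.
#' @export
aggregate_activity <- function(recordings, buzzes, social) {
  req <- c("recording_id", "site_id", "turbine_year_id", "month", "group",
           "valid")
  missing <- setdiff(req, names(recordings))
  if (length(missing) > 0)
    stop("recordings table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  buzz_ids <- if (is.data.frame(buzzes)) buzzes$recording_id else buzzes
  social_ids <- if (is.data.frame(social)) social$recording_id else social
  orphans <- setdiff(c(buzz_ids, social_ids), recordings$recording_id)
  if (length(orphans) > 0)
    stop("recording ids absent from the recordings table: ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)

  rec <- recordings[recordings$valid, , drop = FALSE]
  rec$has_buzz <- rec$recording_id %in% buzz_ids
  rec$has_social <- rec$recording_id %in% social_ids

  grid <- expand.grid(
    turbine_year_id = unique(recordings$turbine_year_id),
    month = sort(unique(recordings$month)),
    group = unique(recordings$group),
    stringsAsFactors = FALSE)
  key <- function(d) paste(d$turbine_year_id, d$month, d$group, sep = "\r")
  agg_n <- tapply(rep(1L, nrow(rec)), key(rec), sum)
  agg_f <- tapply(as.integer(rec$has_buzz), key(rec), sum)
  agg_s <- tapply(as.integer(rec$has_social), key(rec), sum)
  k <- key(grid)
  grid$n_recordings <- ifelse(is.na(agg_n[k]), 0L, agg_n[k])
  grid$n_feeding <- ifelse(is.na(agg_f[k]), 0L, agg_f[k])
  grid$n_social <- ifelse(is.na(agg_s[k]), 0L, agg_s[k])
  site_of <- recordings$site_id[match(grid$turbine_year_id,
                                      recordings$turbine_year_id)]
  grid$site_id <- site_of
  grid <- grid[, c("site_id", "turbine_year_id", "month", "group",
                   "n_recordings", "n_feeding", "n_social")]
  excluded <- grid[grid$n_recordings == 0, , drop = FALSE]
  cells <- grid[grid$n_recordings > 0, , drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "excluded") <- excluded
  cells
}

#' Orthogonal polynomial contrasts for ordered month levels
#'
#' Orthonormal polynomial contrast matrix for an ordered factor; column
#' `k` is a degree-`k` polynomial in the level index. When fewer levels
#' than `degree + 1` are available the degree is truncated with a
#' warning.
#'
#' @param levels Vector of ordered levels (or an integer count).
#' @param degree Highest polynomial degree requested (default 5).
#' @return Matrix with `length(levels)` rows and `degree` columns.
#' @examples
#' orthogonal_month_contrasts(4:10)
#' @export
orthogonal_month_contrasts <- function(levels, degree = 5) {
  n <- if (length(levels) == 1 && is.numeric(levels)) levels
       else length(levels)
  if (n < 2) stop("need at least 2 ordered levels", call. = FALSE)
  if (degree > n - 1) {
    warning(sprintf("degree %d truncated to %d (only %d levels)",
                    degree, n - 1, n))
    degree <- n - 1
  }
  cp <- stats::contr.poly(n)
  cp[, seq_len(degree), drop = FALSE]
}

.poly_label <- function(k) {
  c("Linear", "Quadratic", "Cubic", "Quartic", "Quintic", "Sextic",
    "Septic")[k]
}

# pretty Table-style term names for the group*month fixed effects
.pretty_terms <- function(terms) {
  out <- terms
  out[out == "(Intercept)"] <- "(Intercept)"
  out <- gsub("^groupPipistrelloid", "Species Group (Pip)", out)
  suffixes <- c(".L", ".Q", ".C", "^4", "^5", "^6", "^7")
  for (k in seq_along(suffixes)) {
    out <- gsub(paste0("month", suffixes[k]),
                paste0("Month (", .poly_label(k), ")"), out, fixed = TRUE)
  }
  gsub(":", " x ", out)
}

#' Fit the binomial activity GLMM
#'
#' Binomial-logit mixed model for the proportion of bat recordings
#' containing feeding buzzes (or social vocalisations), with fixed effects
#' for species group, ordered-month polynomial contrasts (degree 5 by
#' default) and their interaction, and random intercepts for site and an
#' observation-level unit (one level per cell, absorbing
#' overdispersion). Fitted by Laplace-approximated maximum likelihood
#' with the bobyqa optimiser (iteration cap 1e5).
#'
#' @param cells Activity-cell table (see [aggregate_activity()] or
#'   [simulate_activity_dataset()]).
#' @param response `"feeding"` (column `n_feeding`) or `"social"`
#'   (column `n_social`).
#' @param degree Polynomial degree for the month contrasts.
#' @param include_year Also add a year random intercept (needs a `year`
#'   column). Off by default: in the motivating analysis the year effect
#'   explained no variability and was removed.
#' @param random_effects `FALSE` fits the fixed-effects-only logistic
#'   regression (the model the GLMM reduces to when both random-effect
#'   variances are zero).
#' @return An object of class `activity_glmm`: list with the fitted model
#'   (`fit`), a Table-style fixed-effects data.frame (`fixed`: term,
#'   estimate, std_error, z, p), random-effect standard deviations
#'   (`varcomp`), `converged` and `singular` flags, and the model
#'   metadata.
#' @export
fit_activity_glmm <- function(cells, response = c("feeding", "social"),
                              degree = 5, include_year = FALSE,
                              random_effects = TRUE) {
  response <- match.arg(response)
  ycol <- paste0("n_", response)
  stopifnot(ycol %in% names(cells), "n_recordings" %in% names(cells))
  if (length(unique(cells$site_id)) < 2 && random_effects)
    stop("need >= 2 sites for the site random intercept", call. = FALSE)
  d <- cells
  d$k <- d[[ycol]]
  if (any(d$k > d$n_recordings))
    stop("event counts exceed recording counts", call. = FALSE)
  mlev <- sort(unique(d$month))
  d$month <- factor(d$month, levels = mlev, ordered = TRUE)
  ctr <- orthogonal_month_contrasts(length(mlev), degree)
  # how.many stops R from padding the contrast matrix back to nlevels - 1
  stats::contrasts(d$month, how.many = ncol(ctr)) <- ctr
  d$group <- factor(d$group, levels = c("Nyctaloid", "Pipistrelloid"))
  d$obs_id <- factor(seq_len(nrow(d)))

  rhs <- "group * month"
  if (random_effects) {
    rhs <- paste(rhs, "+ (1 | site_id) + (1 | obs_id)")
    if (include_year) rhs <- paste(rhs, "+ (1 | year)")
    fit <- lme4::glmer(
      stats::as.formula(paste("cbind(k, n_recordings - k) ~", rhs)),
      data = d, family = stats::binomial(link = "logit"),
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   optCtrl = list(maxfun = 1e5),
                                   calc.derivs = FALSE))
    cf <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    varcomp <- vapply(vc, function(v) attr(v, "stddev"), numeric(1))
    singular <- lme4::isSingular(fit)
    converged <- length(fit@optinfo$conv$lme4) == 0
  } else {
    fit <- stats::glm(
      stats::as.formula(paste("cbind(k, n_recordings - k) ~", rhs)),
      data = d, family = stats::binomial(link = "logit"))
    cf <- summary(fit)$coefficients
    varcomp <- numeric(0)
    singular <- FALSE
    converged <- fit$converged
  }
  fixed <- data.frame(term = .pretty_terms(rownames(cf)),
                      estimate = cf[, 1], std_error = cf[, 2],
                      z = cf[, 3], p = cf[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(fit = fit, fixed = fixed, varcomp = varcomp,
                 converged = converged, singular = singular,
                 response = response, degree = degree,
                 month_levels = mlev, data = d),
            class = "activity_glmm")
}

#' @export
print.activity_glmm <- function(x, ...) {
  cat(sprintf("<activity_glmm> response: %s; %d cells; converged: %s%s\n",
              x$response, nrow(x$data), x$converged,
              if (x$singular) " (singular random effects)" else ""))
  print(x$fixed, digits = 3)
  if (length(x$varcomp) > 0) {
    cat("Random-effect SDs:\n")
    print(round(x$varcomp, 3))
  }
  invisible(x)
}

#' Marginal means and Tukey-adjusted pairwise contrasts
#'
#' Estimated marginal means for the group x month interaction on the
#' log-odds scale with 95% confidence intervals, and Tukey-adjusted
#' pairwise comparisons over the requested contrast family.
#'
#' @param model An [fit_activity_glmm()] result.
#' @param by_month If `TRUE` (default) pairwise group contrasts are formed
#'   within each month; if `FALSE` one Tukey family over all group x month
#'   cells.
#' @return List with `emmeans` and `contrasts` data.frames.
#' @export
marginal_means_and_contrasts <- function(model, by_month = TRUE) {
  if (!model$converged)
    warning("model had convergence warnings; marginal means may be unstable")
  if (by_month) {
    emm <- emmeans::emmeans(model$fit, ~ group | month)
    ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  } else {
    emm <- emmeans::emmeans(model$fit, ~ group * month)
    ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  }
  list(emmeans = as.data.frame(summary(emm, infer = c(TRUE, FALSE))),
       contrasts = as.data.frame(summary(ctr)))
}

#' Spearman correlations between overall and behavioural activity
#'
#' Tie-corrected Spearman rank correlation between per-turbine-year bat
#' recording counts and the counts of buzz- and social-containing
#' recordings.
#'
#' @param counts Data.frame with a `bat_files` column and one column per
#'   response (e.g. `buzz_files`, `social_files`).
#' @param responses Names of the response columns.
#' @return Data.frame with `response`, `rho`, `p`, `n`.
#' @export
activity_correlation <- function(counts,
                                 responses = c("buzz_files", "social_files")) {
  if (nrow(counts) < 4) stop("need n >= 4 turbine-years", call. = FALSE)
  if (length(unique(counts$bat_files)) == 1)
    stop("`bat_files` is constant; correlation undefined", call. = FALSE)
  rows <- lapply(responses, function(rsp) {
    y <- counts[[rsp]]
    if (length(unique(y)) == 1)
      stop(sprintf("`%s` is constant; correlation undefined", rsp),
           call. = FALSE)
    ct <- suppressWarnings(
      stats::cor.test(counts$bat_files, y, method = "spearman"))
    data.frame(response = rsp, rho = unname(ct$estimate), p = ct$p.value,
               n = nrow(counts), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
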