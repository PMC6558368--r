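# The analysis ladder: ordinary least-squares fits with standardized
# coefficients, AIC-guided backward single-term elimination, nested-model F
# comparisons, interaction models on centred products, and simple-slopes
# points for plotting moderation effects.

#' Fit a linear model with standardized coefficients
#'
#' Ordinary least squares of `outcome` on `predictors` over complete cases.
#' Coefficients are reported standardized (all variables z-scored), so a
#' beta is the expected SD change in the outcome per SD of the predictor;
#' R-squared, the overall F against the intercept-only model, and the
#' Gaussian maximum-likelihood AIC (constants included, as `stats::AIC`
#' computes it) are taken from the fit on the raw scale.
#'
#' @param data A data frame.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `ladder_fit`.
#' @export
fit_lm <- function(data, outcome, predictors) {
  stopifnot(is.data.frame(data), length(predictors) >= 1L)
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  d <- tibble::as_tibble(data)[cols]
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  k <- length(predictors)
  if (n < k + 2L) rlang::abort("too few complete cases for the model")
  fml <- stats::reformulate(predictors, response = outcome)
  fit_raw <- stats::lm(fml, data = d)
  if (fit_raw$rank < k + 1L) {
    rlang::abort("rank-deficient design matrix", class = "minimuse_rank_deficient")
  }
  dz <- tibble::as_tibble(lapply(d, function(v) as.numeric(scale(v))))
  fit_std <- stats::lm(fml, data = dz)
  new_ladder_fit(fit_raw, fit_std, outcome, predictors, d)
}

new_ladder_fit <- function(fit_raw, fit_std, outcome, predictors, data,
                           meta = NULL) {
  structure(list(fit_raw = fit_raw, fit_std = fit_std, outcome = outcome,
                 terms = predictors, data = data, n = nrow(data),
                 meta = meta),
            class = "ladder_fit")
}

#' @export
print.ladder_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ladder_fit> %s ~ %s\n", x$outcome,
              paste(x$terms, collapse = " + ")))
  cat(sprintf("  n = %d, R2 = %.3f, AIC = %.2f, F(%d,%d) = %.2f, p = %.3g\n",
              g$n, g$r2, g$aic, g$df1, g$df2, g$f_overall, g$p_overall))
  print(tidy(x))
  invisible(x)
}

#' Tidy a ladder fit: one row per term
#'
#' @param x A `ladder_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `beta_std`, `estimate` (unstandardized),
#'   `t`, `p`.
#' @export
tidy.ladder_fit <- function(x, ...) {
  cs <- stats::coef(summary(x$fit_std))
  cr <- stats::coef(x$fit_raw)
  terms <- setdiff(rownames(cs), "(Intercept)")
  tibble::tibble(term = terms,
                 beta_std = unname(cs[terms, "Estimate"]),
                 estimate = unname(cr[terms]),
                 t = unname(cs[terms, "t value"]),
                 p = unname(cs[terms, "Pr(>|t|)"]))
}

#' Model-level summary of a ladder fit
#'
#' @param x A `ladder_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `r2`, `adj_r2`, `aic`, `f_overall`, `df1`,
#'   `df2`, `p_overall`.
#' @export
glance.ladder_fit <- function(x, ...) {
  s <- summary(x$fit_raw)
  fs <- s$fstatistic
  tibble::tibble(n = x$n, r2 = s$r.squared, adj_r2 = s$adj.r.squared,
                 aic = stats::AIC(x$fit_raw),
                 f_overall = unname(fs[1]), df1 = as.integer(fs[2]),
                 df2 = as.integer(fs[3]),
                 p_overall = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
}

refit <- function(fit, terms) {
  fit_lm(fit$data, fit$outcome, terms)
}

#' Backward single-term elimination
#'
#' Starting from the full model, repeatedly deletes the single term whose
#' removal most improves (lowers) the AIC, until no single-term deletion
#' improves it — the reduced model is the most parsimonious member of the
#' ladder. A p-value mode (`criterion = "p"`) instead drops the largest
#' non-significant p (> `alpha`) each round.
#'
#' @param fit A `ladder_fit` from [fit_lm()].
#' @param criterion `"aic"` (default) or `"p"`.
#' @param alpha Significance threshold for the p-value mode.
#' @return The reduced `ladder_fit`, with the elimination trace (a tibble of
#'   `step`, `dropped`, `aic`) as attribute `"trace"`.
#' @export
backward_eliminate <- function(fit, criterion = c("aic", "p"), alpha = 0.05) {
  criterion <- rlang::arg_match(criterion)
  stopifnot(inherits(fit, "ladder_fit"))
  current <- fit
  trace <- tibble::tibble(step = 0L, dropped = NA_character_,
                          aic = glance(fit)$aic)
  step <- 0L
  repeat {
    terms <- current$terms
    if (length(terms) <= 1L) break
    if (criterion == "aic") {
      cand <- purrr::map_dfr(terms, function(tm) {
        f2 <- refit(current, setdiff(terms, tm))
        tibble::tibble(dropped = tm, aic = glance(f2)$aic)
      })
      best <- cand[which.min(cand$aic), ]
      if (best$aic >= glance(current)$aic) break
      current <- refit(current, setdiff(terms, best$dropped))
      step <- step + 1L
      trace <- dplyr::bind_rows(trace,
                                tibble::tibble(step = step,
                                               dropped = best$dropped,
                                               aic = best$aic))
    } else {
      td <- tidy(current)
      worst <- td[which.max(td$p), ]
      if (worst$p <= alpha) break
      current <- refit(current, setdiff(terms, worst$term))
      step <- step + 1L
      trace <- dplyr::bind_rows(trace,
                                tibble::tibble(step = step,
                                               dropped = worst$term,
                                               aic = glance(current)$aic))
    }
  }
  attr(current, "trace") <- trace
  current
}

#' Compare nested models by the extra-sum-of-squares F test
#'
#' @param reduced,full `ladder_fit` objects on the same rows, the reduced
#'   model's terms a strict subset of the full model's.
#' @return One-row tibble: `f_stat`, `df1`, `df2`, `p`.
#' @export
compare_nested <- function(reduced, full) {
  stopifnot(inherits(reduced, "ladder_fit"), inherits(full, "ladder_fit"))
  if (!all(reduced$terms %in% full$terms)) {
    rlang::abort("models are not nested", class = "minimuse_not_nested")
  }
  if (reduced$n != full$n) {
    rlang::abort("models were fitted on different numbers of rows",
                 class = "minimuse_not_nested")
  }
  rss_r <- sum(stats::resid(reduced$fit_raw)^2)
  rss_f <- sum(stats::resid(full$fit_raw)^2)
  df1 <- length(full$terms) - length(reduced$terms)
  df2 <- full$n - length(full$terms) - 1L
  if (df1 == 0L) {
    return(tibble::tibble(f_stat = 0, df1 = 0L, df2 = df2, p = 1))
  }
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  f <- max(f, 0)
  tibble::tibble(f_stat = f, df1 = as.integer(df1), df2 = as.integer(df2),
                 p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Fit an interaction (moderation) model
#'
#' Builds product terms between a moderator and one or more skill variables
#' from centred copies (so each product has mean approximately zero) and
#' fits them alongside any extra covariates. By default the products enter
#' without their constituent main effects — mirroring the structure this
#' battery's analyses tabulate — which is non-standard, so a warning is
#' raised; set `main_effects = TRUE` for the conventional specification, or
#' `center = FALSE` for raw products.
#'
#' @param data A data frame.
#' @param outcome Outcome column name.
#' @param moderator Moderator column name (e.g., a home-musical-engagement
#'   score).
#' @param skill_terms Character vector of skill columns to interact with
#'   the moderator.
#' @param covariates Additional main-effect columns.
#' @param main_effects Include the moderator and skills as main effects?
#' @param center Centre variables before forming products?
#' @return A `ladder_fit` whose `meta` records the product construction
#'   (variable means and SDs) for [simple_slopes_points()].
#' @export
interaction_fit <- function(data, outcome, moderator, skill_terms,
                            covariates = character(), main_effects = FALSE,
                            center = TRUE) {
  stopifnot(is.data.frame(data), length(skill_terms) >= 1L)
  d <- tibble::as_tibble(data)[c(outcome, moderator, skill_terms, covariates)]
  d <- d[stats::complete.cases(d), ]
  centers <- purrr::map_dbl(d[c(moderator, skill_terms)], mean)
  sds <- purrr::map_dbl(d[c(moderator, skill_terms)], stats::sd)
  if (!center) centers[] <- 0
  prods <- character()
  for (sk in skill_terms) {
    nm <- paste0(moderator, "_x_", sk)
    d[[nm]] <- (d[[moderator]] - centers[[moderator]]) *
      (d[[sk]] - centers[[sk]])
    prods <- c(prods, nm)
  }
  terms <- c(if (main_effects) c(moderator, skill_terms), covariates, prods)
  if (!main_effects) {
    rlang::warn(
      "interaction terms entered without their main effects (non-standard)",
      class = "minimuse_no_main_effects")
  }
  out <- fit_lm(d, outcome, terms)
  out$meta <- list(moderator = moderator, skill_terms = skill_terms,
                   centers = centers, sds = sds, center = center,
                   products = prods)
  out
}

#' Simple-slopes points for plotting an interaction
#'
#' Predicted outcomes, from the model's unstandardized coefficients, at the
#' four combinations of predictor and moderator one SD below/above their
#' means — the points the moderation figures are drawn through.
#'
#' @param fit A `ladder_fit` from [interaction_fit()].
#' @param skill Which skill term to plot (defaults to the first).
#' @return A tibble of four rows: `skill_level`, `moderator_level`, `skill`,
#'   `moderator`, `predicted`.
#' @export
simple_slopes_points <- function(fit, skill = NULL) {
  stopifnot(inherits(fit, "ladder_fit"))
  meta <- fit$meta
  if (is.null(meta)) rlang::abort("fit was not produced by interaction_fit()")
  skill <- skill %||% meta$skill_terms[1L]
  if (!skill %in% meta$skill_terms) rlang::abort("unknown skill term")
  mod <- meta$moderator
  grid <- tidyr::expand_grid(skill_level = c("low", "high"),
                             moderator_level = c("low", "high"))
  co <- stats::coef(fit$fit_raw)
  mean_row <- fit$data |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean))
  purrr::pmap_dfr(grid, function(skill_level, moderator_level) {
    xs <- mean_row[[skill]] + ifelse(skill_level == "high", 1, -1) * meta$sds[[skill]]
    xm <- mean_row[[mod]] + ifelse(moderator_level == "high", 1, -1) * meta$sds[[mod]]
    row <- mean_row
    row[[skill]] <- xs
    row[[mod]] <- xm
    for (sk in meta$skill_terms) {
      nm <- paste0(mod, "_x_", sk)
      row[[nm]] <- (row[[mod]] - meta$centers[[mod]]) *
        (row[[sk]] - meta$centers[[sk]])
    }
    pred <- co[["(Intercept)"]] +
      sum(purrr::map_dbl(fit$terms, ~ co[[.x]] * row[[.x]]))
    tibble::tibble(skill_level = skill_level,
                   moderator_level = moderator_level,
                   skill = xs, moderator = xm, predicted = pred)
  })
}

#' Plot simple slopes of an interaction model
#'
#' @param fit A `ladder_fit` from [interaction_fit()].
#' @param skill Skill term to plot.
#' @return A ggplot with one line per moderator level.
#' @export
plot_simple_slopes <- function(fit, skill = NULL) {
  pts <- simple_slopes_points(fit, skill)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$skill, y = .data$predicted,
                                    colour = .data$moderator_level,
                                    group = .data$moderator_level)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = skill %||% fit$meta$skill_terms[1L],
                  y = fit$outcome, colour = fit$meta$moderator) +
    ggplot2::theme_minimal()
}
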