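# Task scoring: percent correct for the oddity tasks, the two-rater song
# composite, and the phonological-awareness principal-component composite
# with sampling-adequacy diagnostics.

#' Score an oddity task as percent correct
#'
#' @param responses Logical vector of per-trial correctness (non-empty), or
#'   a data frame with a logical `correct` column.
#' @param task Optional task label carried into the result.
#' @return A one-row tibble: `task`, `n_correct`, `n_trials`, `percent`.
#' @examples
#' percent_correct(c(TRUE, TRUE, FALSE), task = "pitch")
#' @export
percent_correct <- function(responses, task = NA_character_) {
  if (is.data.frame(responses)) responses <- responses$correct
  responses <- as.logical(responses)
  if (!length(responses) || anyNA(responses)) {
    rlang::abort("responses must be a non-empty logical vector without NAs")
  }
  tibble::tibble(task = task, n_correct = sum(responses),
                 n_trials = length(responses),
                 percent = 100 * sum(responses) / length(responses))
}

#' Two-rater song-production composite
#'
#' Singing is scored 0--10 by two independent raters; the child's score is
#' the mean of the two ratings.
#'
#' @param rater1,rater2 Numeric ratings in \[0, 10\] (vectorised).
#' @return A tibble with `rater1`, `rater2`, `composite`.
#' @export
song_composite <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) rlang::abort("rating vectors differ in length")
  if (any(rater1 < 0 | rater1 > 10 | rater2 < 0 | rater2 > 10, na.rm = TRUE)) {
    rlang::abort("ratings must lie in [0, 10]")
  }
  tibble::tibble(rater1 = rater1, rater2 = rater2,
                 composite = (rater1 + rater2) / 2)
}

#' Inter-rater agreement (Pearson correlation)
#'
#' @param vec1,vec2 Equal-length rating vectors, length >= 3.
#' @return Pearson r.
#' @export
inter_rater <- function(vec1, vec2) {
  if (length(vec1) != length(vec2) || length(vec1) < 3L) {
    rlang::abort("need equal-length vectors of at least 3 ratings")
  }
  if (stats::sd(vec1) == 0 || stats::sd(vec2) == 0) {
    rlang::abort("zero-variance rating vector", class = "minimuse_degenerate")
  }
  stats::cor(vec1, vec2)
}

#' Phonological-awareness principal-component composite
#'
#' Runs a principal component analysis on the (standardized) phonological
#' awareness subtests, retains components by the Kaiser criterion
#' (eigenvalue > 1), and returns factor scores by the regression method
#' together with sampling-adequacy diagnostics: the Kaiser-Meyer-Olkin
#' measure (zero-order vs partial correlations) and Bartlett's test of
#' sphericity, chi^2 = -(n - 1 - (2p + 5)/6) log det R on p(p-1)/2 df.
#'
#' @param subtests A data frame or matrix, children in rows and subtests in
#'   columns (at least two subtests, more children than subtests after
#'   listwise deletion of incomplete rows).
#' @return An object of class `phono_composite` with fields `eigenvalues`,
#'   `n_retained`, `loadings`, `variance_explained_pct`, `kmo`,
#'   `bartlett_chi2`, `bartlett_df`, `bartlett_p`, `factor_scores`, `n`,
#'   `p`, `dropped_rows`.
#' @export
phonological_composite <- function(subtests) {
  x <- as.matrix(as.data.frame(subtests))
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  if (p < 2L) rlang::abort("need at least two subtests")
  if (n <= p) rlang::abort("need more complete rows than subtests")
  z <- scale(x)
  r <- stats::cor(x)
  detr <- det(r)
  if (!is.finite(detr) || detr < 1e-12) {
    rlang::abort("correlation matrix is (near-)singular",
                 class = "minimuse_singular")
  }
  eig <- eigen(r, symmetric = TRUE)
  vals <- eig$values
  retained <- which(vals > 1)
  if (!length(retained)) {
    rlang::warn("no eigenvalue exceeds the Kaiser criterion; retaining the largest")
    retained <- 1L
  }
  loadings <- eig$vectors[, retained, drop = FALSE] %*%
    diag(sqrt(vals[retained]), length(retained))
  # fix sign so each component correlates positively with the subtest mean
  for (j in seq_len(ncol(loadings))) {
    if (sum(loadings[, j]) < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_along(retained)))
  # regression-method factor scores: Z R^{-1} L, unit variance for PCA
  scores <- z %*% solve(r, loadings)
  bart_chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detr)
  bart_df <- p * (p - 1) / 2
  structure(
    list(eigenvalues = vals,
         n_retained = length(retained),
         loadings = loadings,
         variance_explained_pct = 100 * sum(vals[retained]) / p,
         kmo = kmo_statistic(r),
         bartlett_chi2 = bart_chi2,
         bartlett_df = bart_df,
         bartlett_p = stats::pchisq(bart_chi2, bart_df, lower.tail = FALSE),
         factor_scores = scores,
         n = n, p = p,
         dropped_rows = sum(!complete)),
    class = "phono_composite")
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO compares squared zero-order correlations with squared partial
#' correlations (computed from the inverse correlation matrix): values near
#' 1 indicate compact correlation structure suited to PCA.
#'
#' @param r A correlation matrix.
#' @return The overall KMO statistic in (0, 1\].
#' @export
kmo_statistic <- function(r) {
  q <- solve(r)
  d <- diag(1 / sqrt(diag(q)))
  partial <- -d %*% q %*% d
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

#' @export
print.phono_composite <- function(x, ...) {
  cat(sprintf("<phono_composite> %d children x %d subtests (%d dropped)\n",
              x$n, x$p, x$dropped_rows))
  cat(sprintf("  %d component(s) retained (Kaiser), %.2f%% variance\n",
              x$n_retained, x$variance_explained_pct))
  cat(sprintf("  KMO = %.2f; Bartlett chi2(%d) = %.1f, p = %.3g\n",
              x$kmo, x$bartlett_df, x$bartlett_chi2, x$bartlett_p))
  invisible(x)
}

#' Tidy the loadings of a phonological composite
#'
#' @param x A `phono_composite`.
#' @param ... Unused.
#' @return Tibble with `subtest`, `component`, `loading`.
#' @export
tidy.phono_composite <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "subtest") |>
    tidyr::pivot_longer(-"subtest", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.phono_composite <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, n_retained = x$n_retained,
                 variance_explained_pct = x$variance_explained_pct,
                 kmo = x$kmo, bartlett_chi2 = x$bartlett_chi2,
                 bartlett_df = x$bartlett_df, bartlett_p = x$bartlett_p)
}

#' Scree plot of a phonological composite
#'
#' @param object A `phono_composite`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phono_composite <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "component", y = "eigenvalue") +
    ggplot2::theme_minimal()
}
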