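# Shared statistical primitives.
#
# All group comparisons in the pipeline go through ranksum(); all multiple
# testing through bh_fdr(); all correlations through pearson_cor(). Keeping
# them in one place pins down small-sample behaviour (exact vs approximate
# rank-sum path) and the direction convention (higher mean rank) used by the
# enrichment and burden analyses.

#' Unpaired two-sided Wilcoxon rank-sum test with direction
#'
#' Two-sided rank-sum (Mann-Whitney) test. For small tie-free samples
#' (both groups at most `exact_max` observations) the exact null distribution
#' is enumerated; otherwise a tie-corrected normal approximation with
#' continuity correction is used. The reported direction is the sample with
#' the higher mean rank in the pooled ranking (not the higher mean value),
#' which is robust to outliers.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max switchover: exact enumeration is used when
#'   `length(x) <= exact_max`, `length(y) <= exact_max` and there are no ties.
#' @return object of class `"ranksum_test"`: list with `statistic` (W, number
#'   of (x, y) pairs with x > y plus half the ties), `p`, `direction`
#'   (`"x"`, `"y"` or `"none"`) and `method_note` (`"exact"` or
#'   `"normal-approximation"`).
#' @examples
#' r <- ranksum(c(1, 2, 3), c(4, 5, 6))
#' r$p          # exact: 2 * 1/choose(6, 3) = 0.1
#' r$direction  # "y"
#' @export
ranksum <- function(x, y, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  stop_if_not(length(x) >= 1 && length(y) >= 1,
              "ranksum: both samples must be non-empty")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)),
              "ranksum: samples must be finite")
  pooled <- c(x, y)
  tied <- anyDuplicated(pooled) > 0
  use_exact <- !tied && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  r <- rank(pooled)
  mrx <- mean(r[seq_along(x)])
  mry <- mean(r[length(x) + seq_along(y)])
  direction <- if (mrx > mry) "x" else if (mry > mrx) "y" else "none"
  p <- min(1, unname(wt$p.value))
  structure(
    list(statistic = unname(wt$statistic), p = p, direction = direction,
         mean_rank_x = mrx, mean_rank_y = mry,
         method_note = if (use_exact) "exact" else "normal-approximation"),
    class = "ranksum_test"
  )
}

#' @export
print.ranksum_test <- function(x, ...) {
  cat("Unpaired Wilcoxon rank-sum test (", x$method_note, ")\n", sep = "")
  cat(sprintf("  W = %g, p = %.4g, higher mean rank: %s\n",
              x$statistic, x$p, x$direction))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values with enforced monotonicity; `q >= p` elementwise.
#' `NA` p-values propagate to `NA` q-values and do not count toward the
#' number of tests.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  stop_if_not(all(p[ok] > 0 & p[ok] <= 1), "bh_fdr: p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation; p from the t transform with n - 2 degrees of
#' freedom. Constant input is flagged rather than an error: `cc` and `p` are
#' `NA` and `flag = "constant-input"`.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list with `cc`, `p`, `n`, `flag` (`NA` or `"constant-input"`).
#' @export
pearson_cor <- function(x, y) {
  stop_if_not(length(x) == length(y), "pearson_cor: length mismatch")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  stop_if_not(length(x) >= 3, "pearson_cor: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(cc = NA_real_, p = NA_real_, n = length(x),
                flag = "constant-input"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(cc = unname(ct$estimate), p = unname(ct$p.value), n = length(x),
       flag = NA_character_)
}

#' Per-factor and combined linear-model fit
#'
#' For a response and a set of candidate predictors, returns the per-factor
#' Pearson correlation and R squared, and an ordinary least-squares fit on
#' all (non-constant) predictors jointly with its R squared and overall-F
#' p-value. Constant predictors are flagged and excluded from the joint fit.
#'
#' @param response numeric vector.
#' @param predictors named list (or data.frame) of numeric vectors aligned
#'   with `response`.
#' @return list with `per_factor` (data.frame: factor, cc, r_squared, p,
#'   excluded) and `combined` (list: r_squared, p, n_predictors).
#' @export
ols_correlates <- function(response, predictors) {
  predictors <- as.data.frame(predictors, check.names = FALSE)
  stop_if_not(nrow(predictors) == length(response),
              "ols_correlates: predictor length mismatch")
  stop_if_not(length(response) >= 3, "ols_correlates: need n >= 3")
  per <- lapply(names(predictors), function(nm) {
    v <- predictors[[nm]]
    if (stats::sd(v) == 0) {
      data.frame(factor = nm, cc = NA_real_, r_squared = NA_real_,
                 p = NA_real_, excluded = TRUE)
    } else {
      pc <- pearson_cor(v, response)
      data.frame(factor = nm, cc = pc$cc, r_squared = pc$cc^2, p = pc$p,
                 excluded = FALSE)
    }
  })
  per <- do.call(rbind, per)
  keep <- names(predictors)[!per$excluded]
  combined <- list(r_squared = NA_real_, p = NA_real_,
                   n_predictors = length(keep))
  if (length(keep) >= 1) {
    df <- data.frame(.y = response, predictors[keep], check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = df)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    combined$r_squared <- sm$r.squared
    combined$p <- unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                   lower.tail = FALSE))
  }
  list(per_factor = per, combined = combined)
}
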