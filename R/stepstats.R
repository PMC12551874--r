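# Stepwise statistics: when do gaze and gait deviations start changing before
# a transition? Wilcoxon signed-rank tests on consecutive step pairs from six
# steps before to three steps after the transition, Bonferroni-corrected per
# variable x category family, with paired Cohen's d and bootstrap CIs.

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are discarded (the classic zero-discard convention); `W`
#' is the smaller of the positive and negative rank sums (the two-sided
#' convention under which a fully one-sided sample gives W = 0). The p-value
#' uses the normal approximation with continuity correction; with all
#' differences zero the result is degenerate (W = 0, p = 1).
#'
#' @param x,y paired samples.
#' @return list with `W`, `p`, `n_eff` (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (length(d) == 0) return(list(W = 0, p = 1, n_eff = 0L))
  r <- rank(abs(d))
  W <- min(sum(r[d > 0]), sum(r[d < 0]))
  p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                           correct = TRUE)$p.value)
  list(W = W, p = p, n_eff = length(d))
}

#' Paired Cohen's d
#'
#' `mean(x - y) / sd(x - y)`; 0 when all differences are zero.
#'
#' @param x,y paired samples.
#' @return effect size d.
#' @export
cohens_d_paired <- function(x, y) {
  d <- (x - y)[!is.na(x - y)]
  s <- stats::sd(d)
  m <- mean(d)
  if (is.na(s) || s == 0) {
    if (isTRUE(all.equal(m, 0)) || is.na(m)) return(0)
    return(sign(m) * Inf)
  }
  m / s
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values numeric sample (>= 2 values).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed optional seed for reproducibility.
#' @return numeric length-2 vector (lower, upper).
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.95, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values for a bootstrap CI")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(values)
  means <- colMeans(matrix(values[sample.int(n, n * n_boot, replace = TRUE)],
                           nrow = n))
  a <- (1 - level) / 2
  stats::quantile(means, c(a, 1 - a), type = 7, names = FALSE)
}

.step_pair_sequence <- function() {
  # consecutive step pairs from -6 to +3 (no step 0): i -> next step
  i <- c(-6:-1, 1, 2)
  j <- c(-5:-1, 1, 2, 3)
  data.frame(step_a = i, step_b = j)
}

#' Stepwise pairwise tests for one variable
#'
#' For each transition category and each pair of consecutive steps from six
#' steps before to three steps after the transition, runs a paired Wilcoxon
#' signed-rank test on the per-instance values of the two steps. P-values are
#' Bonferroni-corrected within the variable-by-category family (eight pairs).
#' Paired Cohen's d and percentile bootstrap CIs of the per-step means are
#' reported alongside.
#'
#' @param transitions long instance table from [extract_transitions()].
#' @param variable feature column to test (e.g. "dalpha", "dl_norm").
#' @param n_boot bootstrap resamples for the per-step CIs.
#' @param seed seed for the bootstrap.
#' @return data.frame with one row per (category, step pair): `category`,
#'   `variable`, `step_a`, `step_b`, `n`, `W`, `p_raw`, `p_bonferroni`, `d`,
#'   and CI bounds of the mean at both steps.
#' @export
pairwise_stepwise_tests <- function(transitions, variable, n_boot = 1000,
                                    seed = 1L) {
  pairs <- .step_pair_sequence()
  out <- list()
  for (cat in unique(transitions$category)) {
    sub <- transitions[transitions$category == cat, ]
    sub$.id <- as.character(interaction(sub$participant, sub$lap,
                                        sub$instance, drop = TRUE))
    wide <- stats::reshape(sub[, c(".id", "rel_index", variable)],
                           idvar = ".id", timevar = "rel_index",
                           direction = "wide")
    if (nrow(wide) < 6) {
      warning(sprintf("category '%s' has %d instance(s) (< 6); skipped",
                      cat, nrow(wide)))
      next
    }
    col_of <- function(s) wide[[paste(variable, s, sep = ".")]]
    res <- lapply(seq_len(nrow(pairs)), function(k) {
      a <- col_of(pairs$step_a[k]); b <- col_of(pairs$step_b[k])
      wt <- wilcoxon_signed_rank(b, a)
      ci_a <- bootstrap_ci(a, n_boot = n_boot, seed = seed + k)
      ci_b <- bootstrap_ci(b, n_boot = n_boot, seed = seed + 1000L + k)
      data.frame(category = cat, variable = variable,
                 step_a = pairs$step_a[k], step_b = pairs$step_b[k],
                 n = sum(!is.na(a - b)), W = wt$W, p_raw = wt$p,
                 d = cohens_d_paired(b, a),
                 ci_a_lower = ci_a[1], ci_a_upper = ci_a[2],
                 ci_b_lower = ci_b[1], ci_b_upper = ci_b[2])
    })
    res <- do.call(rbind, res)
    res$p_bonferroni <- pmin(1, res$p_raw * nrow(res))
    out[[cat]] <- res
  }
  if (length(out) == 0)
    stop("no category with at least 6 instances")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Earliest significant pre-transition change
#'
#' Scans the consecutive-step comparisons from -6 forward and returns the most
#' negative step `i` whose (i, i+1) comparison is significant after Bonferroni
#' correction; NA when no pair is significant.
#'
#' @param results result table from [pairwise_stepwise_tests()] (one
#'   category/variable family).
#' @param alpha significance level applied to `p_bonferroni`.
#' @return step index (integer) or NA.
#' @export
earliest_significant_step <- function(results, alpha = 0.05) {
  ord <- order(results$step_a)
  sig <- results$p_bonferroni[ord] <= alpha
  if (!any(sig)) return(NA_integer_)
  as.integer(results$step_a[ord][which(sig)[1]])
}
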