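# Group comparison of barrier samples, error propagation, and the
# barrier summary table.

#' Two-sample t-test on barrier samples
#'
#' Welch's unequal-variance t-test (two-sided) by default; set
#' \code{pooled = TRUE} for the classical pooled-variance variant. When both
#' groups have zero variance, equal means give p = 1 (by convention) and
#' unequal means p = 0.
#'
#' @param groupA,groupB numeric samples, each n >= 2.
#' @param alpha significance level for the flag (default 0.05).
#' @param pooled use pooled variance instead of Welch.
#' @return A list of class \code{ComparisonResult}: \code{means}, \code{sds},
#'   \code{t}, \code{df}, \code{p}, \code{significant}, \code{alpha}.
#' @export
welchTest <- function(groupA, groupB, alpha = 0.05, pooled = FALSE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group must have n >= 2")
  sds <- c(stats::sd(groupA), stats::sd(groupB))
  means <- c(mean(groupA), mean(groupB))
  if (all(sds == 0)) {
    if (means[1] == means[2]) {
      tt <- list(statistic = 0, parameter = length(groupA) + length(groupB) - 2,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(means[1] - means[2]) * Inf,
                 parameter = length(groupA) + length(groupB) - 2, p.value = 0)
    }
  } else {
    ht <- stats::t.test(groupA, groupB, var.equal = pooled)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(means = means, sds = sds, t = tt$statistic,
                 df = tt$parameter, p = tt$p.value,
                 significant = tt$p.value < alpha, alpha = alpha),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult: %.3f +/- %.3f vs %.3f +/- %.3f\n",
              x$means[1], x$sds[1], x$means[2], x$sds[2]))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.4g (%s at %.2g)\n", x$t, x$df,
              x$p, if (x$significant) "significant" else "ns", x$alpha))
  invisible(x)
}

#' Propagate standard deviations
#'
#' Default: root-sum-of-squares, the standard propagation for a difference of
#' independent estimates (so \code{propagateSd(c(3, 4)) == 5}). The literal
#' root-of-summed-values reading is available as \code{method = "literal"}.
#'
#' @param sds non-negative standard deviations.
#' @param method "rss" (default) or "literal".
#' @return Combined sd; always >= max(sds) for "rss".
#' @export
propagateSd <- function(sds, method = c("rss", "literal")) {
  method <- match.arg(method)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (method == "rss") sqrt(sum(sds^2)) else sqrt(sum(sds))
}

#' Barrier summary table
#'
#' For each (group, form) cell: mean and sd of the absolute (vacuum-
#' referenced) barriers; the bulk-referenced relative barrier
#' \code{mean - bulk meanG} with the bulk sd propagated in quadrature; the
#' Welch p-value against the paired group in the same form; and a one-sample
#' t-test of the relative barriers against zero.
#'
#' @param samples data.frame with columns \code{value} (kcal/mol),
#'   \code{group} (e.g. genotype), \code{form} (e.g. apo/holo), and
#'   optionally \code{replica}, \code{monomer}.
#' @param bulkReference a \code{BulkReference} (or list with \code{meanG},
#'   \code{sd}).
#' @param alpha significance level.
#' @return data.frame, one row per (group, form): \code{group}, \code{form},
#'   \code{n}, \code{barrier_abs_mean}, \code{barrier_abs_sd},
#'   \code{barrier_rel_mean}, \code{barrier_rel_sd}, \code{p_vs_other},
#'   \code{flag_vs_other}, \code{p_vs_zero}.
#' @export
summarizeBarriers <- function(samples, bulkReference, alpha = 0.05) {
  if (is.null(bulkReference$meanG)) stop("missing bulk reference")
  if (is.null(samples$form)) samples$form <- "all"
  cells <- unique(samples[, c("group", "form")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$group[i]; f <- cells$form[i]
    v <- samples$value[samples$group == g & samples$form == f]
    other <- samples$value[samples$group != g & samples$form == f]
    pOther <- NA_real_
    if (length(other) >= 2 && length(v) >= 2 &&
        length(unique(samples$group[samples$form == f])) == 2)
      pOther <- welchTest(v, other, alpha)$p
    rel <- v - bulkReference$meanG
    pZero <- if (length(v) >= 2 && stats::sd(v) > 0)
      stats::t.test(rel, mu = 0)$p.value else NA_real_
    data.frame(group = g, form = f, n = length(v),
               barrier_abs_mean = mean(v), barrier_abs_sd = stats::sd(v),
               barrier_rel_mean = mean(v) - bulkReference$meanG,
               barrier_rel_sd = propagateSd(c(stats::sd(v), bulkReference$sd)),
               p_vs_other = pOther,
               flag_vs_other = ifelse(is.na(pOther), "",
                                      ifelse(pOther < alpha, "*", "ns")),
               p_vs_zero = pZero, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
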