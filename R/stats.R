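#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: each p-value is multiplied by
#' `m / rank`, a running minimum is taken from the largest rank downwards,
#' and results are capped at 1. Output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Chi-squared association between region status and a clinical factor
#'
#' Pearson chi-squared test (no continuity correction) on the cross-table
#' of per-sample imprinting-status labels at one DMR against a clinical or
#' genomic factor. Samples missing either label are dropped; status or
#' factor levels unobserved after dropping do not enter the table.
#'
#' @param status Character/factor vector of per-sample region status
#'   labels at one DMR.
#' @param factor_labels Character/factor vector of per-sample clinical
#'   labels, same length/order.
#' @return A list of class `"dmr_assoc"`: `contingency` (status x factor
#'   counts), `chi2`, `df`, `p`, `n`, `expected_below_5` (logical). A
#'   degenerate table (fewer than 2 rows or columns) returns `NULL` with a
#'   message. A warning is raised when any expected count is below 5.
#' @export
crosstab_test <- function(status, factor_labels) {
  stopifnot(length(status) == length(factor_labels))
  keep <- !is.na(status) & !is.na(factor_labels)
  tab <- table(status = as.character(status[keep]),
               factor = as.character(factor_labels[keep]))
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    message("degenerate contingency table (single row or column): ",
            "no test performed")
    return(NULL)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  low <- any(ct$expected < 5)
  if (low) {
    warning("expected cell count(s) below 5: chi-squared approximation ",
            "may be poor")
  }
  structure(list(contingency = tab,
                 chi2 = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 n = sum(tab),
                 expected_below_5 = low),
            class = "dmr_assoc")
}

#' Association tests across the most-altered DMRs
#'
#' For each DMR (by default those flagged `most_altered` in the cohort
#' summary), tests the association between region status and one clinical
#' factor, then BH-adjusts across the tested DMRs as one family.
#'
#' @param region_calls Region calls from [call_regions()].
#' @param clinical `data.frame` with `sample_id` and the factor column.
#' @param factor_name Name of the clinical column to test.
#' @param cohort_summary Optional output of [summarize_cohort()]; when
#'   supplied, tests are restricted to its `most_altered` DMRs unless
#'   `all_dmrs = TRUE`.
#' @param all_dmrs Test every DMR regardless of the most-altered flag.
#' @return `data.frame` with `dmr_name`, `factor`, `chi2`, `df`, `p`,
#'   `p_bh`, `n`; DMRs with degenerate tables are omitted.
#' @export
test_associations <- function(region_calls, clinical, factor_name,
                              cohort_summary = NULL, all_dmrs = FALSE) {
  stopifnot(factor_name %in% names(clinical),
            "sample_id" %in% names(clinical))
  dmrs <- unique(region_calls$dmr_name)
  if (!is.null(cohort_summary) && !all_dmrs) {
    dmrs <- intersect(dmrs,
                      cohort_summary$dmr_name[cohort_summary$most_altered])
  }
  fac <- clinical[[factor_name]][match(region_calls$sample_id,
                                       clinical$sample_id)]
  rows <- lapply(dmrs, function(d) {
    sel <- region_calls$dmr_name == d
    res <- crosstab_test(region_calls$call[sel], fac[sel])
    if (is.null(res)) return(NULL)
    data.frame(dmr_name = d, factor = factor_name, chi2 = res$chi2,
               df = res$df, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(dmr_name = character(), factor = character(),
                      chi2 = numeric(), df = integer(), p = numeric(),
                      n = integer(), p_bh = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$p_bh <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Pairwise group comparisons of altered-DMR burden
#'
#' Compares per-sample counts of altered DMRs between every pair of
#' groups with a two-sided Wilcoxon rank-sum test (burden counts are
#' non-normal; a Welch t-test is available via `test`), BH-adjusting
#' across the pairs as one family.
#'
#' @param burden Numeric vector of per-sample altered-DMR counts.
#' @param groups Character/factor vector of group labels, same length.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return `data.frame` with `group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic`, `p`, `p_bh`.
#' @export
compare_burden <- function(burden, groups, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(length(burden) == length(groups))
  keep <- !is.na(burden) & !is.na(groups)
  burden <- burden[keep]
  groups <- as.character(groups[keep])
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need at least 2 nonempty groups")
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- burden[groups == pairs[1L, k]]
    b <- burden[groups == pairs[2L, k]]
    if (!length(a) || !length(b)) {
      warning("empty group in pair ", pairs[1L, k], " vs ", pairs[2L, k],
              ": skipped")
      return(NULL)
    }
    ht <- if (test == "wilcoxon") {
      suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    } else {
      stats::t.test(a, b, alternative = "two.sided")
    }
    data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k],
               n_a = length(a), n_b = length(b),
               statistic = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
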