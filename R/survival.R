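#' Kaplan-Meier curves and log-rank test across status groups
#'
#' Fits product-limit survival curves for each imprinting-status group at
#' one DMR and tests group equality with the multi-group log-rank test.
#'
#' @param status Character vector of per-sample region status labels.
#' @param time,event Follow-up time (years from diagnosis) and death
#'   indicator (0/1), aligned with `status`. Samples missing any of the
#'   three are dropped.
#' @return A list of class `"dmr_logrank"`: `chi2`, `df` (nonempty groups
#'   minus one), `p`, `group_sizes`, and `curves` — a `data.frame` of
#'   per-group step-function points (`group`, `time`, `n_risk`,
#'   `n_event`, `survival`). `NULL` with a message when fewer than two
#'   nonempty groups remain.
#' @export
km_logrank <- function(status, time, event) {
  stopifnot(length(status) == length(time), length(time) == length(event))
  keep <- !is.na(status) & !is.na(time) & !is.na(event)
  status <- as.character(status[keep])
  time <- time[keep]
  event <- event[keep]
  if (any(time < 0)) stop("negative follow-up time")
  if (length(unique(status)) < 2L) {
    message("log-rank skipped: fewer than 2 nonempty groups")
    return(NULL)
  }
  grp <- factor(status)
  sd1 <- survival::survdiff(survival::Surv(time, event) ~ grp)
  df <- length(sd1$n) - 1L
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  sm <- summary(fit, censored = TRUE)
  curves <- data.frame(
    group = sub("^grp=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    survival = sm$surv, stringsAsFactors = FALSE)
  origin <- data.frame(group = levels(grp), time = 0,
                       n_risk = as.integer(table(grp)), n_event = 0L,
                       survival = 1, stringsAsFactors = FALSE)
  curves <- rbind(origin, curves)
  curves <- curves[order(curves$group, curves$time), , drop = FALSE]
  rownames(curves) <- NULL
  structure(list(chi2 = sd1$chisq, df = df,
                 p = pchisq(sd1$chisq, df = df, lower.tail = FALSE),
                 group_sizes = setNames(as.integer(table(grp)),
                                        levels(grp)),
                 curves = curves),
            class = "dmr_logrank")
}

#' @export
print.dmr_logrank <- function(x, ...) {
  cat("Log-rank test:", "chi2 =", format(x$chi2, digits = 4),
      "df =", x$df, "p =", format.pval(x$p, digits = 3), "\n")
  cat("Groups:", paste(names(x$group_sizes), x$group_sizes,
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Cox proportional-hazards fit for one status contrast
#'
#' Contrasts one status category against the No-change group (samples in
#' neither group are excluded), optionally adjusting for the established
#' binary risk factors. Ties are handled with the Efron approximation.
#'
#' @param status Character vector of per-sample region status labels.
#' @param time,event Follow-up time and death indicator.
#' @param focal The status category to contrast (e.g. `"GOM"`).
#' @param reference Reference category (default `"NO_CHANGE"`).
#' @param adjusters Optional named list/data.frame of binary (0/1)
#'   covariates aligned with `status`, e.g. age >= 1.5 years at diagnosis,
#'   MYCN amplification, 11q deletion. Constant covariates (after
#'   restriction) are dropped with a warning.
#' @param all_levels If `TRUE`, dummy-codes every status category against
#'   the reference instead of restricting to the focal pair.
#' @return `data.frame` with one row per model term: `term`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `n`, `n_event`. `NULL` with a message on a
#'   degenerate contrast or non-convergence.
#' @export
cox_fit <- function(status, time, event, focal,
                    reference = "NO_CHANGE", adjusters = NULL,
                    all_levels = FALSE) {
  status <- as.character(status)
  dat <- data.frame(status = status, time = time, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(adjusters)) {
    adjusters <- as.data.frame(adjusters)
    stopifnot(nrow(adjusters) == length(status))
    dat <- cbind(dat, adjusters)
  }
  if (all_levels) {
    dat$focal_ind <- NULL
    dat <- dat[!is.na(dat$status), , drop = FALSE]
    dat$status <- stats::relevel(factor(dat$status), ref = reference)
    terms <- "status"
  } else {
    dat <- dat[!is.na(dat$status) & dat$status %in% c(focal, reference), ,
               drop = FALSE]
    dat$focal_ind <- as.integer(dat$status == focal)
    if (length(unique(dat$focal_ind)) < 2L) {
      message("degenerate contrast: focal and reference groups not both ",
              "represented")
      return(NULL)
    }
    terms <- "focal_ind"
  }
  dat <- dat[complete.cases(dat[setdiff(names(dat), "status")]), ,
             drop = FALSE]
  adj_names <- if (is.null(adjusters)) character() else names(adjusters)
  for (a in adj_names) {
    if (length(unique(dat[[a]])) < 2L) {
      warning("constant covariate dropped: ", a)
      dat[[a]] <- NULL
      adj_names <- setdiff(adj_names, a)
    }
  }
  fm <- stats::reformulate(c(terms, adj_names),
                           response = "survival::Surv(time, event)")
  fit <- tryCatch(
    survival::coxph(fm, data = dat, ties = "efron"),
    error = function(e) e, warning = function(w) w)
  if (inherits(fit, "condition")) {
    message("Cox fit failed: ", conditionMessage(fit))
    return(NULL)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  out <- data.frame(term = rownames(co),
                    hr = unname(co[, "exp(coef)"]),
                    ci_low = unname(ci[, "lower .95"]),
                    ci_high = unname(ci[, "upper .95"]),
                    p = unname(co[, "Pr(>|z|)"]),
                    n = sm$n, n_event = sm$nevent,
                    stringsAsFactors = FALSE)
  out$term[out$term == "focal_ind"] <- paste0(focal, "_vs_", reference)
  rownames(out) <- NULL
  out
}

#' Optimal expression cutoff by Kaplan scan
#'
#' Scans every distinct expression value that splits the cohort into low
#' and high groups each of at least `min_group` samples, computes the
#' two-group log-rank p at each cutoff, and returns the minimizing cutoff
#' with a Bonferroni correction equal to the number of cutoffs actually
#' tested. Samples with expression strictly above the cutoff form the
#' high group, so the scan is invariant to strictly monotone transforms
#' of the expression scale.
#'
#' @param expression Numeric per-sample expression values for one gene.
#' @param time,event Follow-up time and death indicator, aligned.
#' @param min_group Minimum size for both groups at a candidate cutoff
#'   (default 8).
#' @return A list of class `"kaplan_scan"`: `cutoff`, `n_cutoffs_tested`,
#'   `p_raw`, `p_bonferroni` (`min(1, p_raw * n_cutoffs_tested)`),
#'   `n_low`, `n_high`; `NULL` with a message if no cutoff is feasible.
#' @export
kaplan_scan <- function(expression, time, event, min_group = 8L) {
  stopifnot(length(expression) == length(time),
            length(time) == length(event))
  keep <- !is.na(expression) & !is.na(time) & !is.na(event)
  expression <- expression[keep]
  time <- time[keep]
  event <- event[keep]
  if (length(expression) < 2L * min_group) {
    message("kaplan scan skipped: fewer than 2 * min_group usable samples")
    return(NULL)
  }
  vals <- sort(unique(expression))
  cand <- vals[vapply(vals, function(v) {
    n_low <- sum(expression <= v)
    n_low >= min_group && (length(expression) - n_low) >= min_group
  }, logical(1L))]
  if (!length(cand)) {
    message("kaplan scan skipped: no cutoff satisfies min_group = ",
            min_group)
    return(NULL)
  }
  pvals <- vapply(cand, function(v) {
    grp <- expression > v
    sd1 <- survival::survdiff(survival::Surv(time, event) ~ grp)
    pchisq(sd1$chisq, df = 1L, lower.tail = FALSE)
  }, numeric(1L))
  best <- which.min(pvals)
  structure(list(cutoff = cand[best],
                 n_cutoffs_tested = length(cand),
                 p_raw = pvals[best],
                 p_bonferroni = min(1, pvals[best] * length(cand)),
                 n_low = sum(expression <= cand[best]),
                 n_high = sum(expression > cand[best])),
            class = "kaplan_scan")
}

#' @export
print.kaplan_scan <- function(x, ...) {
  cat("Kaplan scan: cutoff =", format(x$cutoff, digits = 4),
      "(", x$n_low, "low /", x$n_high, "high )\n")
  cat("  p_raw =", format.pval(x$p_raw, digits = 3),
      " p_bonferroni =", format.pval(x$p_bonferroni, digits = 3),
      " over", x$n_cutoffs_tested, "cutoffs\n")
  invisible(x)
}

#' Survival stratification within the low-risk stratum
#'
#' Restricts to MYCN non-amplified samples and runs the status-group
#' log-rank separately within the 11q-normal and the 11q-deleted strata —
#' the contrast that asks whether imprinting status further splits cases
#' that current markers call low-risk.
#'
#' @param status Per-sample region status labels at one DMR.
#' @param time,event Follow-up time and death indicator.
#' @param mycn Per-sample labels; `"amplified"` samples are excluded.
#' @param chr11 Per-sample labels among `"11q deleted"`, `"11q normal"`
#'   (other labels are ignored for stratification).
#' @return Named list with elements `q11_normal` and `q11_deleted`, each a
#'   `dmr_logrank` or `NULL` (empty or degenerate stratum, skipped with a
#'   warning).
#' @export
stratified_km_low_risk <- function(status, time, event, mycn, chr11) {
  stopifnot(length(status) == length(mycn), length(mycn) == length(chr11))
  non_amp <- !is.na(mycn) & mycn != "amplified"
  out <- list()
  for (stratum in c("11q normal", "11q deleted")) {
    key <- if (stratum == "11q normal") "q11_normal" else "q11_deleted"
    sel <- non_amp & !is.na(chr11) & chr11 == stratum
    if (!any(sel)) {
      warning("empty stratum skipped: MYCN non-amplified / ", stratum)
      out[[key]] <- NULL
      next
    }
    out[[key]] <- km_logrank(status[sel], time[sel], event[sel])
  }
  out
}
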