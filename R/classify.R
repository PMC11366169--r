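#' @name imprinting-status-labels
#' @title Imprinting status labels
#' @description Internal label set for probe- and region-level calls, in
#'   increasing order of methylation: `LOM < INT_LOM < NO_CHANGE < INT_GOM
#'   < GOM`. [status_labels()] returns the machine labels;
#'   [status_display()] maps them to report spellings ("Gain of
#'   methylation" style short forms "GOM", "LOM", "Intermediate GOM",
#'   "Intermediate LOM", "No change").
NULL

#' @rdname imprinting-status-labels
#' @export
status_labels <- function() c("LOM", "INT_LOM", "NO_CHANGE", "INT_GOM", "GOM")

#' @rdname imprinting-status-labels
#' @param call Character vector of machine labels.
#' @export
status_display <- function(call) {
  map <- c(LOM = "LOM", INT_LOM = "Intermediate LOM",
           NO_CHANGE = "No change", INT_GOM = "Intermediate GOM",
           GOM = "GOM")
  unname(map[call])
}

#' Build a per-probe control reference from control samples
#'
#' @param beta Numeric matrix of beta-values, probes in rows (rownames =
#'   probe ids), samples in columns.
#' @param control_ids Column names of the control (normal-tissue) samples;
#'   at least two are required so the SD is defined.
#' @return `data.frame` with `probe_id`, `mean`, `sd`, `n_controls`.
#' @export
build_control_reference <- function(beta, control_ids) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  missing_ids <- setdiff(control_ids, colnames(beta))
  if (length(missing_ids)) {
    stop("control sample(s) not in beta matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  if (length(control_ids) < 2L) {
    stop("need at least 2 control samples to estimate a control SD")
  }
  ctrl <- beta[, control_ids, drop = FALSE]
  data.frame(probe_id = rownames(beta),
             mean = rowMeans(ctrl, na.rm = TRUE),
             sd = apply(ctrl, 1L, sd, na.rm = TRUE),
             n_controls = length(control_ids),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a probe beta-value against imprinting thresholds
#'
#' Strong calls use absolute thresholds on the beta-value; intermediate
#' calls compare against the control band `mean +/- k_sd * sd`. All
#' inequalities are strict, and strong calls take precedence: in order,
#' GOM if `beta > gom_threshold`, LOM if `beta < lom_threshold`, then
#' Intermediate LOM / Intermediate GOM outside the control band, else No
#' change. A beta of exactly 0.8 is therefore not GOM.
#'
#' @param beta Numeric vector of beta-values in `[0, 1]`; `NA` yields `NA`
#'   (no call).
#' @param ctrl_mean,ctrl_sd Control reference mean and SD, recycled along
#'   `beta`.
#' @param gom_threshold,lom_threshold Absolute beta cutoffs for the strong
#'   calls (defaults 0.8 / 0.2).
#' @param k_sd Width of the control band in control SDs (default 2).
#' @return Character vector of calls in `status_labels()`, `NA` where
#'   `beta` is missing.
#' @export
classify_probe <- function(beta, ctrl_mean, ctrl_sd,
                           gom_threshold = 0.8, lom_threshold = 0.2,
                           k_sd = 2) {
  ctrl_mean <- rep_len(ctrl_mean, length(beta))
  ctrl_sd <- rep_len(ctrl_sd, length(beta))
  ok <- !is.na(beta)
  if (any(beta[ok] < 0 | beta[ok] > 1)) {
    stop("beta-values must lie in [0, 1]")
  }
  if (any(is.na(ctrl_mean[ok])) || any(is.na(ctrl_sd[ok]))) {
    stop("missing control reference for classified probe(s)")
  }
  if (any(ctrl_sd[ok] < 0)) stop("control sd must be nonnegative")
  lo <- ctrl_mean - k_sd * ctrl_sd
  hi <- ctrl_mean + k_sd * ctrl_sd
  call <- rep(NA_character_, length(beta))
  call[ok] <- "NO_CHANGE"
  call[ok & beta > hi] <- "INT_GOM"
  call[ok & beta < lo] <- "INT_LOM"
  call[ok & beta > gom_threshold] <- "GOM"
  call[ok & beta < lom_threshold] <- "LOM"
  call
}

#' Probe-wise classification of a beta matrix
#'
#' @param beta Numeric probes-by-samples matrix with dimnames.
#' @param ctrl Control reference from [build_control_reference()]; must
#'   cover every probe in `beta`.
#' @param probe_map Mapped probe manifest (the `probes` element of
#'   [map_probes_to_dmrs()]); only probes assigned to a DMR are classified.
#' @inheritParams classify_probe
#' @return Long-format `data.frame`: `sample_id`, `probe_id`, `dmr_name`,
#'   `beta`, `call`. Probes with missing beta are omitted (no call).
#' @export
classify_probes <- function(beta, ctrl, probe_map,
                            gom_threshold = 0.8, lom_threshold = 0.2,
                            k_sd = 2) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)),
            !is.null(colnames(beta)))
  mapped <- probe_map[!is.na(probe_map$dmr_name), , drop = FALSE]
  keep <- intersect(rownames(beta), mapped$probe_id)
  if (!length(keep)) stop("no probes in the beta matrix map to a DMR")
  idx <- match(keep, ctrl$probe_id)
  if (anyNA(idx)) {
    stop("missing control reference for probe(s): ",
         paste(keep[is.na(idx)], collapse = ", "))
  }
  if (any(ctrl$n_controls[idx] < 2L)) {
    stop("control reference must be built from at least 2 controls")
  }
  b <- beta[keep, , drop = FALSE]
  n_p <- length(keep)
  n_s <- ncol(b)
  long <- data.frame(
    sample_id = rep(colnames(b), each = n_p),
    probe_id = rep(keep, times = n_s),
    dmr_name = rep(mapped$dmr_name[match(keep, mapped$probe_id)],
                   times = n_s),
    beta = as.vector(b),
    stringsAsFactors = FALSE)
  long$call <- classify_probe(long$beta,
                              ctrl_mean = rep(ctrl$mean[idx], times = n_s),
                              ctrl_sd = rep(ctrl$sd[idx], times = n_s),
                              gom_threshold = gom_threshold,
                              lom_threshold = lom_threshold,
                              k_sd = k_sd)
  long[!is.na(long$call), , drop = FALSE]
}

#' Aggregate probe calls into a region call
#'
#' The region call is the status category backed by strictly more than
#' `majority` of the usable probes in the region. When no category clears
#' the majority, the call falls back to `NO_CHANGE` with `ambiguous =
#' TRUE`; the winning (modal) fraction is still reported as `support`.
#'
#' @param calls Character vector of probe calls for one (sample, DMR);
#'   `NA`s (missing betas) are dropped from the denominator.
#' @param majority Required probe fraction, strict (default 0.60, so
#'   exactly 60% is not enough).
#' @return One-row `data.frame`: `call`, `support`, `n_probes_used`,
#'   `ambiguous`; `NULL` when no usable probe remains.
#' @export
aggregate_region <- function(calls, majority = 0.60) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NULL)
  tab <- table(factor(calls, levels = status_labels()))
  frac <- as.numeric(tab) / length(calls)
  top <- which.max(frac)
  if (frac[top] > majority) {
    data.frame(call = status_labels()[top], support = frac[top],
               n_probes_used = length(calls), ambiguous = FALSE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(call = "NO_CHANGE", support = frac[top],
               n_probes_used = length(calls), ambiguous = TRUE,
               stringsAsFactors = FALSE)
  }
}

#' Region-level calls for every (sample, DMR)
#'
#' @param probe_calls Long-format probe calls from [classify_probes()].
#' @inheritParams aggregate_region
#' @return `data.frame` with `sample_id`, `dmr_name`, `call`, `support`,
#'   `n_probes_used`, `ambiguous`; (sample, DMR) pairs with zero usable
#'   probes are absent.
#' @export
call_regions <- function(probe_calls, majority = 0.60) {
  pieces <- split(probe_calls$call,
                  list(sample_id = probe_calls$sample_id,
                       dmr_name = probe_calls$dmr_name),
                  drop = TRUE, sep = "\r")
  keys <- strsplit(names(pieces), "\r", fixed = TRUE)
  rows <- lapply(seq_along(pieces), function(i) {
    rc <- aggregate_region(pieces[[i]], majority = majority)
    if (is.null(rc)) return(NULL)
    cbind(data.frame(sample_id = keys[[i]][1L], dmr_name = keys[[i]][2L],
                     stringsAsFactors = FALSE), rc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$dmr_name, out$sample_id), , drop = FALSE]
}

#' Cohort-level summary and most-altered detection
#'
#' Per DMR, the proportion of called samples in each of the five status
#' categories, and whether the region counts as "most altered": a strong
#' GOM or strong LOM proportion strictly above `altered_fraction`
#' (intermediate calls do not count towards the criterion). With two
#' cohorts (e.g. discovery and validation), the criterion must hold in
#' both.
#'
#' @param region_calls Region calls from [call_regions()].
#' @param altered_fraction Strict cohort-proportion cutoff (default 0.30).
#' @param region_calls2 Optional second cohort's region calls.
#' @return `data.frame` with one row per DMR: `dmr_name`, `n_called`,
#'   proportions `p_gom`, `p_lom`, `p_int_gom`, `p_int_lom`,
#'   `p_no_change`, plus `most_altered` and `dominant_event` (`"GOM"`,
#'   `"LOM"` or `NA`).
#' @export
summarize_cohort <- function(region_calls, altered_fraction = 0.30,
                             region_calls2 = NULL) {
  one <- function(rc) {
    tab <- table(rc$dmr_name, factor(rc$call, levels = status_labels()))
    n <- rowSums(tab)
    prop <- sweep(tab, 1L, n, "/")
    data.frame(dmr_name = rownames(tab),
               n_called = as.integer(n),
               p_gom = prop[, "GOM"],
               p_lom = prop[, "LOM"],
               p_int_gom = prop[, "INT_GOM"],
               p_int_lom = prop[, "INT_LOM"],
               p_no_change = prop[, "NO_CHANGE"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  s <- one(region_calls)
  hit <- s$p_gom > altered_fraction | s$p_lom > altered_fraction
  if (!is.null(region_calls2)) {
    s2 <- one(region_calls2)
    i <- match(s$dmr_name, s2$dmr_name)
    hit2 <- !is.na(i) &
      (s2$p_gom[i] > altered_fraction | s2$p_lom[i] > altered_fraction)
    hit <- hit & hit2
  }
  s$most_altered <- hit
  s$dominant_event <- ifelse(!hit, NA_character_,
                             ifelse(s$p_gom >= s$p_lom, "GOM", "LOM"))
  s[order(-pmax(s$p_gom, s$p_lom)), , drop = FALSE]
}

#' Per-sample altered-DMR burden
#'
#' Counts, for each sample, the number of DMRs with a strong GOM call and
#' with a strong LOM call; intermediate calls and No change are not
#' counted.
#'
#' @param region_calls Region calls from [call_regions()].
#' @return `data.frame` with `sample_id`, `n_gom`, `n_lom`.
#' @export
altered_dmr_burden <- function(region_calls) {
  samples <- unique(region_calls$sample_id)
  tab <- table(factor(region_calls$sample_id, levels = samples),
               factor(region_calls$call, levels = status_labels()))
  data.frame(sample_id = samples,
             n_gom = as.integer(tab[, "GOM"]),
             n_lom = as.integer(tab[, "LOM"]),
             row.names = NULL, stringsAsFactors = FALSE)
}
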