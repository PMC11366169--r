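#' Load allele-specific copy-number segments
#'
#' Reads ASCAT-style allele-specific segment profiles. `nMajor` and
#' `nMinor` are the copy numbers of the more and less abundant parental
#' haplotype; their sum is the total copy number at the locus, so by
#' convention `nMajor >= nMinor >= 0`.
#'
#' @param path TSV with columns `sample`, `chrom`, `startpos`, `endpos`,
#'   `nMajor`, `nMinor` (1-based inclusive coordinates).
#' @return `data.frame` with columns `sample_id`, `chrom`, `start`, `end`,
#'   `nMajor`, `nMinor`, `total`, sorted by sample, chromosome and start.
#'   An empty file yields a zero-row frame.
#' @export
load_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
  required <- c("sample", "chrom", "startpos", "endpos", "nMajor", "nMinor")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("segment file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  seg <- data.frame(sample_id = as.character(raw$sample),
                    chrom = as.character(raw$chrom),
                    start = as.integer(raw$startpos),
                    end = as.integer(raw$endpos),
                    nMajor = as.integer(raw$nMajor),
                    nMinor = as.integer(raw$nMinor),
                    stringsAsFactors = FALSE)
  validate_segments(seg)
}

validate_segments <- function(seg) {
  if (nrow(seg) == 0L) {
    seg$total <- integer()
    return(seg)
  }
  if (any(seg$nMinor < 0L | seg$nMajor < 0L)) {
    stop("negative allele counts in segment row(s) ",
         paste(which(seg$nMinor < 0L | seg$nMajor < 0L), collapse = ", "))
  }
  if (any(seg$nMinor > seg$nMajor)) {
    stop("nMinor > nMajor violates the major/minor convention in row(s) ",
         paste(which(seg$nMinor > seg$nMajor), collapse = ", "))
  }
  if (any(seg$start > seg$end)) {
    stop("start > end in segment row(s) ",
         paste(which(seg$start > seg$end), collapse = ", "))
  }
  seg$total <- seg$nMajor + seg$nMinor
  seg[order(seg$sample_id, seg$chrom, seg$start), , drop = FALSE]
}

#' Resolve the copy state of a DMR in each sample
#'
#' For every sample, picks among the segments overlapping a DMR the one
#' covering the largest fraction of the DMR, and reports that segment's
#' allele counts together with the covered fraction. (Sample, DMR) pairs
#' with no overlapping segment are absent from the result and thereby
#' excluded from downstream regression. Allele counts are never averaged
#' across segments, so they stay integers.
#'
#' @param segments Validated segments from [load_segments()].
#' @param catalog `dmr_catalog` of regions to resolve.
#' @return `data.frame` with `sample_id`, `dmr_name`, `nMajor`, `nMinor`,
#'   `total`, `coverage` (fraction of DMR length covered, in (0, 1]).
#' @export
resolve_copy_state <- function(segments, catalog) {
  if (nrow(segments) == 0L || nrow(catalog) == 0L) {
    return(data.frame(sample_id = character(), dmr_name = character(),
                      nMajor = integer(), nMinor = integer(),
                      total = integer(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  gr_seg <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start, end = segments$end))
  gr_dmr <- dmr_granges(catalog)
  hits <- GenomicRanges::findOverlaps(gr_seg, gr_dmr)
  if (length(hits) == 0L) {
    return(data.frame(sample_id = character(), dmr_name = character(),
                      nMajor = integer(), nMinor = integer(),
                      total = integer(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(gr_seg)[qh],
                            IRanges::ranges(gr_dmr)[sh])
  cov <- IRanges::width(ov) / IRanges::width(IRanges::ranges(gr_dmr)[sh])
  cand <- data.frame(sample_id = segments$sample_id[qh],
                     dmr_name = catalog$name[sh],
                     nMajor = segments$nMajor[qh],
                     nMinor = segments$nMinor[qh],
                     total = segments$total[qh],
                     coverage = cov,
                     stringsAsFactors = FALSE)
  # largest-coverage segment wins per (sample, DMR)
  ord <- order(cand$sample_id, cand$dmr_name, -cand$coverage)
  cand <- cand[ord, , drop = FALSE]
  keep <- !duplicated(cand[, c("sample_id", "dmr_name")])
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CNA-predicted methylation for one (sample, DMR)
#'
#' Under the null of no epimutation, the bulk methylation level at an
#' imprinted DMR is set by the allele counts and the parental origin of
#' the methylated copy. The minor methylation value is
#' `nMinor / (nMajor + nMinor)`. The methylated haplotype is assumed to be
#' the minor one when at least half of the observed probe betas are
#' `<= 0.5` (equality folds into the minor branch), in which case the
#' predicted methylation equals the minor methylation value; otherwise the
#' major haplotype is assumed methylated and the prediction is its
#' complement. A diploid 1+1 state predicts 0.5 either way; copy-neutral
#' LOH (`nMinor = 0`) predicts 0 or 1.
#'
#' @param nMajor,nMinor Allele counts for the (sample, DMR); their sum must
#'   be at least 1 (a homozygous deletion has no defined allele fraction
#'   and yields `NULL` with a warning).
#' @param observed_betas Non-missing probe beta-values for that sample in
#'   that DMR; the median is recorded as the observed region value.
#' @return One-row `data.frame`: `minor_meth_value`, `observed_beta`,
#'   `methylated_allele_side` (`"minor"`/`"major"`), `predicted`; or
#'   `NULL` when no prediction is possible.
#' @export
predict_methylation <- function(nMajor, nMinor, observed_betas) {
  observed_betas <- observed_betas[!is.na(observed_betas)]
  if (!length(observed_betas)) stop("no observed beta-values supplied")
  if (nMajor + nMinor == 0L) {
    warning("homozygous deletion (nMajor + nMinor = 0): no prediction")
    return(NULL)
  }
  minor_meth <- nMinor / (nMajor + nMinor)
  side <- if (mean(observed_betas <= 0.5) >= 0.5) "minor" else "major"
  predicted <- if (side == "minor") minor_meth else 1 - minor_meth
  data.frame(minor_meth_value = minor_meth,
             observed_beta = median(observed_betas),
             methylated_allele_side = side,
             predicted = predicted,
             stringsAsFactors = FALSE)
}

#' CNA-predicted methylation across a cohort
#'
#' Joins resolved copy states with observed probe betas and computes the
#' per-(sample, DMR) prediction of [predict_methylation()].
#'
#' @param copy_states Output of [resolve_copy_state()].
#' @param probe_calls Long-format probe table from [classify_probes()]
#'   (only `sample_id`, `dmr_name`, `beta` are used).
#' @param observed_summary Summary used for the observed region value:
#'   `"median"` (default) or `"mean"`.
#' @return `data.frame` with `sample_id`, `dmr_name`, `nMajor`, `nMinor`,
#'   `minor_meth_value`, `methylated_allele_side`, `observed_beta`,
#'   `predicted`.
#' @export
predict_methylation_cohort <- function(copy_states, probe_calls,
                                       observed_summary = c("median",
                                                            "mean")) {
  observed_summary <- match.arg(observed_summary)
  summarise <- if (observed_summary == "median") median else mean
  key_obs <- paste(probe_calls$sample_id, probe_calls$dmr_name, sep = "\r")
  betas <- split(probe_calls$beta, key_obs)
  rows <- vector("list", nrow(copy_states))
  for (i in seq_len(nrow(copy_states))) {
    key <- paste(copy_states$sample_id[i], copy_states$dmr_name[i],
                 sep = "\r")
    b <- betas[[key]]
    b <- b[!is.na(b)]
    if (!length(b)) next
    if (copy_states$nMajor[i] + copy_states$nMinor[i] == 0L) {
      warning("homozygous deletion at ", copy_states$dmr_name[i], " in ",
              copy_states$sample_id[i], ": pair excluded")
      next
    }
    p <- predict_methylation(copy_states$nMajor[i], copy_states$nMinor[i], b)
    p$observed_beta <- summarise(b)
    rows[[i]] <- cbind(copy_states[i, c("sample_id", "dmr_name",
                                        "nMajor", "nMinor")], p,
                       stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), dmr_name = character(),
                      nMajor = integer(), nMinor = integer(),
                      minor_meth_value = numeric(),
                      observed_beta = numeric(),
                      methylated_allele_side = character(),
                      predicted = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Regress observed on CNA-predicted methylation for one region
#'
#' Ordinary least squares of the observed region methylation on the
#' CNA-based prediction, across samples. The adjusted R-squared for the
#' single-predictor model is `1 - (1 - r2) * (n - 1) / (n - 2)`; it can be
#' negative, which flags a fit worse than the intercept-only model — the
#' signature of a region whose methylation changes are epimutations rather
#' than copy-number effects.
#'
#' @param observed,predicted Numeric vectors of equal length (one entry
#'   per sample).
#' @return One-row `data.frame`: `n`, `slope`, `intercept`, `r2`,
#'   `adj_r2`, `p_value` (slope t-test); `NULL` with a message when
#'   `n < 3` or the predictor is constant.
#' @export
regress_observed_on_predicted <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  observed <- observed[ok]
  predicted <- predicted[ok]
  n <- length(observed)
  if (n < 3L) {
    message("regression skipped: fewer than 3 complete pairs")
    return(NULL)
  }
  if (length(unique(predicted)) < 2L) {
    message("regression skipped: constant predictor")
    return(NULL)
  }
  fit <- lm(observed ~ predicted)
  sm <- summary(fit)
  data.frame(n = n,
             slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]),
             r2 = sm$r.squared,
             adj_r2 = sm$adj.r.squared,
             p_value = sm$coefficients["predicted", "Pr(>|t|)"],
             stringsAsFactors = FALSE)
}

#' Per-DMR concordance between observed and CNA-predicted methylation
#'
#' Runs [regress_observed_on_predicted()] for each DMR over samples,
#' producing one row per region sorted by decreasing adjusted R-squared —
#' the layout in which copy-number-driven regions rise to the top and
#' epimutation-driven regions sink to (negative) adjusted R-squared.
#'
#' @param predictions Output of [predict_methylation_cohort()].
#' @return `data.frame` with `dmr_name`, `n`, `slope`, `intercept`, `r2`,
#'   `adj_r2`, `p_value`; regions failing the preconditions are omitted.
#' @export
cna_concordance <- function(predictions) {
  rows <- lapply(split(predictions, predictions$dmr_name), function(d) {
    r <- regress_observed_on_predicted(d$observed_beta, d$predicted)
    if (is.null(r)) return(NULL)
    cbind(data.frame(dmr_name = d$dmr_name[1L], stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(dmr_name = character(), n = integer(),
                      slope = numeric(), intercept = numeric(),
                      r2 = numeric(), adj_r2 = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(-out$adj_r2), , drop = FALSE]
}
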