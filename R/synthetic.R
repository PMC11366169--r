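#' Simulation configuration for synthetic imprinting cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#' Defaults describe a mid-size neuroblastoma-like cohort: 300 tumours,
#' 11 normal controls, beta noise giving a control SD of about 0.03 at a
#' hemi-methylated locus, loss of methylation more prevalent than gain,
#' MYCN amplification in ~25% and 11q deletion in ~30% of tumours, a
#' stage distribution dominated by stage 4, and administrative censoring
#' at 15 years.
#'
#' @param seed Integer seed; it fully determines the generated bundle.
#' @param n_tumours,n_controls Cohort sizes (controls model normal
#'   biparental tissue centred at beta 0.5).
#' @param catalog `dmr_catalog` to simulate over (default: packaged
#'   49-region catalog).
#' @param probes_per_dmr Integer, or named integer vector keyed by DMR
#'   name, of CpG probes simulated per region.
#' @param prevalence Named numeric with entries `GOM`, `LOM`, `INT_GOM`,
#'   `INT_LOM`: baseline per-DMR event prevalences (remainder is No
#'   change). Must sum to at most 1.
#' @param prevalence_overrides Optional `data.frame` (`dmr_name`, `GOM`,
#'   `LOM`, `INT_GOM`, `INT_LOM`) overriding the baseline for named DMRs.
#' @param precision Beta-distribution precision `phi`; betas are drawn
#'   from `Beta(mu * phi, (1 - mu) * phi)`. The default 277 gives
#'   SD ~ 0.03 at `mu = 0.5`.
#' @param cna List with whole-chromosome event probabilities `p_gain`
#'   (2+1), `p_loss` (1+0), `p_cnloh` (2+0); the remainder stays diploid
#'   1+1. An optional `per_chrom` element — a named list of such lists —
#'   overrides the rates for individual chromosomes (e.g. to model the
#'   low segmental-alteration rate of chromosome 15 relative to 11q or
#'   17q in neuroblastoma).
#' @param cna_driven_dmrs Character vector of DMR names whose betas track
#'   the methylated-allele fraction implied by the sample's allele counts
#'   instead of an epigenetic status (those regions get truth status No
#'   change).
#' @param clinical List: `p_mycn`, `p_11q_del`, `p_11q_gain`,
#'   `p_11q_loss`, `p_age_ge18m`, `stage_probs` (named over
#'   `1,2,3,4,4s`).
#' @param enrichment Optional `data.frame` (`dmr_name`, `status`,
#'   `factor`, `level`, `log_or`) adding `log_or` to the log-odds of
#'   `status` at `dmr_name` for samples whose clinical `factor` equals
#'   `level`.
#' @param survival List: `baseline_hazard` (events per year),
#'   `censor_time` (years), `effects` — `data.frame` (`dmr_name`,
#'   `status`, `log_hr`) summed into each sample's log-hazard.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tumours = 300L,
                       n_controls = 11L,
                       catalog = load_dmr_catalog(),
                       probes_per_dmr = 4L,
                       prevalence = c(GOM = 0.05, LOM = 0.15,
                                      INT_GOM = 0.02, INT_LOM = 0.08),
                       prevalence_overrides = NULL,
                       precision = 277,
                       cna = list(p_gain = 0.20, p_loss = 0.10,
                                  p_cnloh = 0.05),
                       cna_driven_dmrs = character(),
                       clinical = list(p_mycn = 0.25, p_11q_del = 0.30,
                                       p_11q_gain = 0.01, p_11q_loss = 0.05,
                                       p_age_ge18m = 0.65,
                                       stage_probs = c(`1` = 0.08,
                                                       `2` = 0.04,
                                                       `3` = 0.07,
                                                       `4` = 0.68,
                                                       `4s` = 0.13)),
                       enrichment = NULL,
                       survival = list(baseline_hazard = 0.08,
                                       censor_time = 15,
                                       effects = NULL)) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_tumours >= 1L, n_controls >= 2L,
            inherits(catalog, "dmr_catalog"), nrow(catalog) >= 1L,
            precision > 0)
  events <- c("GOM", "LOM", "INT_GOM", "INT_LOM")
  if (!all(events %in% names(prevalence))) {
    stop("prevalence must name GOM, LOM, INT_GOM and INT_LOM")
  }
  prev <- build_prevalence(catalog$name, prevalence[events],
                           prevalence_overrides)
  bad <- rowSums(prev[, events]) > 1 + 1e-12 | apply(prev[, events] < 0,
                                                     1L, any)
  if (any(bad)) {
    stop("event prevalences must be nonnegative and sum to <= 1; ",
         "offending DMR(s): ", paste(prev$dmr_name[bad], collapse = ", "))
  }
  if (length(probes_per_dmr) == 1L && is.null(names(probes_per_dmr))) {
    probes_per_dmr <- setNames(rep(as.integer(probes_per_dmr),
                                   nrow(catalog)), catalog$name)
  }
  if (!all(catalog$name %in% names(probes_per_dmr))) {
    stop("probes_per_dmr must cover every DMR in the catalog")
  }
  stopifnot(all(probes_per_dmr[catalog$name] >= 1L))
  check_rates <- function(r) {
    p <- r$p_gain + r$p_loss + r$p_cnloh
    if (p > 1 || any(c(r$p_gain, r$p_loss, r$p_cnloh) < 0)) {
      stop("cna event probabilities must be nonnegative and sum to <= 1")
    }
  }
  check_rates(cna)
  for (r in cna$per_chrom) check_rates(r)
  unknown <- setdiff(cna_driven_dmrs, catalog$name)
  if (length(unknown)) {
    stop("cna_driven_dmrs not in catalog: ",
         paste(unknown, collapse = ", "))
  }
  sp <- clinical$stage_probs
  if (abs(sum(sp) - 1) > 1e-8) stop("stage_probs must sum to 1")
  structure(list(seed = as.integer(seed),
                 n_tumours = as.integer(n_tumours),
                 n_controls = as.integer(n_controls),
                 catalog = catalog,
                 probes_per_dmr = probes_per_dmr[catalog$name],
                 prevalence = prev,
                 precision = precision,
                 cna = cna,
                 cna_driven_dmrs = cna_driven_dmrs,
                 clinical = clinical,
                 enrichment = enrichment,
                 survival = survival),
            class = "sim_config")
}

build_prevalence <- function(dmr_names, base, overrides) {
  events <- c("GOM", "LOM", "INT_GOM", "INT_LOM")
  prev <- data.frame(dmr_name = dmr_names, stringsAsFactors = FALSE)
  for (e in events) prev[[e]] <- unname(base[[e]])
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "dmr_name" %in% names(overrides))
    unknown <- setdiff(overrides$dmr_name, dmr_names)
    if (length(unknown)) {
      stop("prevalence override for unknown DMR(s): ",
           paste(unknown, collapse = ", "))
    }
    i <- match(overrides$dmr_name, prev$dmr_name)
    for (e in intersect(events, names(overrides))) {
      prev[[e]][i] <- overrides[[e]]
    }
  }
  prev
}

draw_beta <- function(mu, phi) {
  mu <- pmin(pmax(mu, 0.03), 0.97)  # keep both beta shapes well-defined
  pmin(pmax(rbeta(length(mu), mu * phi, (1 - mu) * phi), 0), 1)
}

status_to_mu <- function(status, ctrl_sd) {
  centres <- c(NO_CHANGE = 0.5, GOM = 0.90, LOM = 0.10,
               INT_GOM = 0.5 + 3 * ctrl_sd, INT_LOM = 0.5 - 3 * ctrl_sd)
  unname(centres[status])
}

#' Generate a complete synthetic cohort with recorded truth
#'
#' Draws, in a seed-determined order: clinical covariates; per-chromosome
#' allele-specific copy-number events (whole-chromosome segments with
#' nMajor/nMinor counts and a methylated-haplotype side); per-(sample,
#' DMR) true imprinting status from the configured prevalences (with
#' optional clinical log-odds enrichments); probe-level betas from a
#' bounded Beta noise model centred at the status-implied mean (or at the
#' methylated-allele fraction for copy-number-driven regions); control
#' betas centred at 0.5; and exponential survival times whose log-hazard
#' sums the configured per-status effects, administratively censored.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, the bundle is also written
#'   as TSV files (`beta.tsv`, `probes.tsv`, `segments.tsv`,
#'   `clinical.tsv`, `truth_status.tsv`, `truth_alleles.tsv`).
#' @return A list of class `sim_cohort`: `beta` (probes x samples matrix,
#'   tumours then controls), `control_ids`, `probes` (manifest with
#'   `dmr_name`), `segments`, `clinical`, and `truth` (long status table,
#'   allele counts with methylated-copy count, per-sample log-hazard
#'   linear predictor).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  catalog <- config$catalog
  ctrl_sd <- sqrt(0.25 / (1 + config$precision))

  tumour_ids <- sprintf("T%04d", seq_len(config$n_tumours))
  control_ids <- sprintf("C%03d", seq_len(config$n_controls))

  probes <- make_probe_manifest(catalog, config$probes_per_dmr)
  clinical <- draw_clinical(tumour_ids, config$clinical)
  alle <- draw_cna(tumour_ids, catalog, config$cna)
  truth_status <- draw_truth_status(tumour_ids, catalog, config, clinical)

  # allele counts resolved per (sample, DMR) from the chromosome events
  key_chrom <- paste(alle$events$sample_id, alle$events$chrom, sep = "\r")
  idx <- match(paste(rep(tumour_ids, each = nrow(catalog)),
                     rep(catalog$chrom, times = length(tumour_ids)),
                     sep = "\r"), key_chrom)
  truth_alleles <- data.frame(
    sample_id = rep(tumour_ids, each = nrow(catalog)),
    dmr_name = rep(catalog$name, times = length(tumour_ids)),
    nMajor = alle$events$nMajor[idx],
    nMinor = alle$events$nMinor[idx],
    n_meth = ifelse(alle$events$meth_is_major[idx],
                    alle$events$nMajor[idx], alle$events$nMinor[idx]),
    stringsAsFactors = FALSE)
  truth_alleles$total <- truth_alleles$nMajor + truth_alleles$nMinor

  # probe betas: status-driven centre, or allele fraction for CNA-driven
  n_probes <- nrow(probes)
  beta <- matrix(NA_real_, nrow = n_probes,
                 ncol = length(tumour_ids) + length(control_ids),
                 dimnames = list(probes$probe_id,
                                 c(tumour_ids, control_ids)))
  status_key <- paste(truth_status$sample_id, truth_status$dmr_name,
                      sep = "\r")
  allele_key <- paste(truth_alleles$sample_id, truth_alleles$dmr_name,
                      sep = "\r")
  cna_driven <- probes$dmr_name %in% config$cna_driven_dmrs
  for (s in tumour_ids) {
    keys <- paste(s, probes$dmr_name, sep = "\r")
    st <- truth_status$status[match(keys, status_key)]
    mu <- status_to_mu(st, ctrl_sd)
    if (any(cna_driven)) {
      ai <- match(keys[cna_driven], allele_key)
      mu[cna_driven] <- truth_alleles$n_meth[ai] / truth_alleles$total[ai]
    }
    beta[, s] <- draw_beta(mu, config$precision)
  }
  for (s in control_ids) {
    beta[, s] <- draw_beta(rep(0.5, n_probes), config$precision)
  }

  surv <- draw_survival(tumour_ids, truth_status, config$survival)
  clinical$os_time_years <- surv$os_time_years
  clinical$os_event <- surv$os_event

  bundle <- structure(list(beta = beta,
                           control_ids = control_ids,
                           probes = probes,
                           segments = alle$segments,
                           clinical = clinical,
                           truth = list(status = truth_status,
                                        alleles = truth_alleles,
                                        linear_predictor = surv$lp)),
                      class = "sim_cohort")
  if (!is.null(dir)) write_cohort(bundle, dir)
  bundle
}

make_probe_manifest <- function(catalog, probes_per_dmr) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    k <- probes_per_dmr[[catalog$name[i]]]
    pos <- if (catalog$start[i] == catalog$end[i]) {
      rep(catalog$start[i], k)
    } else {
      as.integer(round(seq(catalog$start[i], catalog$end[i],
                           length.out = k)))
    }
    data.frame(chrom = catalog$chrom[i], pos = pos,
               dmr_name = catalog$name[i], stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, rows)
  probes$probe_id <- sprintf("cgSIM%05d", seq_len(nrow(probes)))
  probes[, c("probe_id", "chrom", "pos", "dmr_name")]
}

draw_clinical <- function(sample_ids, cl) {
  n <- length(sample_ids)
  mycn <- ifelse(runif(n) < cl$p_mycn, "amplified", "not amplified")
  u <- runif(n)
  chr11 <- rep("11q normal", n)
  chr11[u < cl$p_11q_del] <- "11q deleted"
  chr11[u >= cl$p_11q_del &
          u < cl$p_11q_del + cl$p_11q_gain] <- "whole gain"
  chr11[u >= cl$p_11q_del + cl$p_11q_gain &
          u < cl$p_11q_del + cl$p_11q_gain + cl$p_11q_loss] <- "whole loss"
  age_group <- ifelse(runif(n) < cl$p_age_ge18m, ">=1.5", "<1.5")
  stage <- sample(names(cl$stage_probs), n, replace = TRUE,
                  prob = cl$stage_probs)
  # telomere-maintenance subclass loosely tied to MYCN status
  subclass <- ifelse(mycn == "amplified",
                     ifelse(runif(n) < 0.8, "Mycn Type",
                            "Alt/Tert Tmm Positive"),
                     ifelse(runif(n) < 0.45, "Tmm Negative",
                            ifelse(runif(n) < 0.5, "Alt/Tert Tmm Positive",
                                   "Mycn Type")))
  data.frame(sample_id = sample_ids, age_group = age_group, stage = stage,
             mycn = mycn, chr11 = chr11, subclass = subclass,
             stringsAsFactors = FALSE)
}

draw_cna <- function(sample_ids, catalog, cna) {
  chroms <- unique(catalog$chrom)
  grid <- expand.grid(sample_id = sample_ids, chrom = chroms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, grid$chrom), , drop = FALSE]
  rate <- function(field) {
    vapply(grid$chrom, function(ch) {
      ov <- cna$per_chrom[[ch]]
      if (!is.null(ov) && !is.null(ov[[field]])) ov[[field]]
      else cna[[field]]
    }, numeric(1L))
  }
  p_gain <- rate("p_gain")
  p_loss <- rate("p_loss")
  p_cnloh <- rate("p_cnloh")
  u <- runif(nrow(grid))
  nMajor <- rep(1L, nrow(grid))
  nMinor <- rep(1L, nrow(grid))
  gain <- u < p_gain
  loss <- u >= p_gain & u < p_gain + p_loss
  cnloh <- u >= p_gain + p_loss & u < p_gain + p_loss + p_cnloh
  nMajor[gain] <- 2L
  nMinor[loss] <- 0L
  nMajor[cnloh] <- 2L
  nMinor[cnloh] <- 0L
  grid$nMajor <- nMajor
  grid$nMinor <- nMinor
  grid$meth_is_major <- runif(nrow(grid)) < 0.5
  segments <- data.frame(sample_id = grid$sample_id, chrom = grid$chrom,
                         start = 1L, end = 250000000L,
                         nMajor = grid$nMajor, nMinor = grid$nMinor,
                         stringsAsFactors = FALSE)
  segments$total <- segments$nMajor + segments$nMinor
  list(events = grid, segments = segments)
}

draw_truth_status <- function(sample_ids, catalog, config, clinical) {
  events <- c("GOM", "LOM", "INT_GOM", "INT_LOM")
  prev <- config$prevalence
  rows <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    d <- catalog$name[i]
    if (d %in% config$cna_driven_dmrs) {
      rows[[i]] <- data.frame(sample_id = sample_ids, dmr_name = d,
                              status = "NO_CHANGE",
                              stringsAsFactors = FALSE)
      next
    }
    p <- unlist(prev[prev$dmr_name == d, events])
    probs <- matrix(rep(c(p, 1 - sum(p)), each = length(sample_ids)),
                    nrow = length(sample_ids),
                    dimnames = list(NULL, c(events, "NO_CHANGE")))
    if (!is.null(config$enrichment)) {
      enr <- config$enrichment[config$enrichment$dmr_name == d, ,
                               drop = FALSE]
      for (j in seq_len(nrow(enr))) {
        hit <- clinical[[enr$factor[j]]] == enr$level[j]
        cat_j <- enr$status[j]
        # multiply the category's odds by exp(log_or), renormalize
        odds <- probs[hit, cat_j] / (1 - probs[hit, cat_j])
        odds <- odds * exp(enr$log_or[j])
        newp <- odds / (1 + odds)
        scale <- (1 - newp) / (1 - probs[hit, cat_j])
        probs[hit, ] <- probs[hit, , drop = FALSE] * scale
        probs[hit, cat_j] <- newp
      }
    }
    u <- runif(length(sample_ids))
    cum <- t(apply(probs, 1L, cumsum))
    pick <- max.col(u < cum, ties.method = "first")
    rows[[i]] <- data.frame(sample_id = sample_ids, dmr_name = d,
                            status = colnames(probs)[pick],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

draw_survival <- function(sample_ids, truth_status, sv) {
  lp <- setNames(numeric(length(sample_ids)), sample_ids)
  if (!is.null(sv$effects) && nrow(sv$effects)) {
    for (j in seq_len(nrow(sv$effects))) {
      hit <- truth_status$dmr_name == sv$effects$dmr_name[j] &
        truth_status$status == sv$effects$status[j]
      lp[truth_status$sample_id[hit]] <-
        lp[truth_status$sample_id[hit]] + sv$effects$log_hr[j]
    }
  }
  t_event <- rexp(length(sample_ids), rate = sv$baseline_hazard * exp(lp))
  os_event <- as.integer(t_event <= sv$censor_time)
  list(os_time_years = pmin(t_event, sv$censor_time),
       os_event = os_event, lp = lp)
}

#' Generate uniparental-diploidy reference samples
#'
#' Maternal UPD carries two maternal copies, so maternally methylated
#' DMRs sit near beta 1 and paternally methylated DMRs near 0; paternal
#' UPD is the mirror image. Centres are 0.97 / 0.03 with the configured
#' beta noise.
#'
#' @param config A [sim_config()] (its catalog, probe layout, precision
#'   and seed are used).
#' @param n_mupd,n_pupd Numbers of maternal- and paternal-UPD samples
#'   (defaults 1 and 2).
#' @return List: `beta` (probes x UPD samples matrix), `probes` manifest,
#'   `upd_type` (named vector, `"mUPD"`/`"pUPD"`).
#' @export
generate_upd_references <- function(config, n_mupd = 1L, n_pupd = 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)  # distinct stream from the main cohort
  probes <- make_probe_manifest(config$catalog, config$probes_per_dmr)
  ids <- c(sprintf("mUPD%02d", seq_len(n_mupd)),
           sprintf("pUPD%02d", seq_len(n_pupd)))
  type <- setNames(rep(c("mUPD", "pUPD"), c(n_mupd, n_pupd)), ids)
  meth_allele <- config$catalog$methylated_allele[
    match(probes$dmr_name, config$catalog$name)]
  beta <- matrix(NA_real_, nrow = nrow(probes), ncol = length(ids),
                 dimnames = list(probes$probe_id, ids))
  for (s in ids) {
    maternal_high <- type[[s]] == "mUPD"
    mu <- ifelse((meth_allele == "M") == maternal_high, 0.97, 0.03)
    beta[, s] <- draw_beta(mu, config$precision)
  }
  list(beta = beta, probes = probes, upd_type = type)
}

#' Write a synthetic cohort bundle as TSV files
#'
#' Emits exactly the formats the analysis functions consume: a beta
#' matrix (first column `probe_id`), a probe manifest, ASCAT-style
#' segments (`sample`, `chrom`, `startpos`, `endpos`, `nMajor`,
#' `nMinor`), the clinical table and the two truth tables.
#'
#' @param bundle A `sim_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  beta_df <- data.frame(probe_id = rownames(bundle$beta),
                        signif(bundle$beta, 6), check.names = FALSE,
                        stringsAsFactors = FALSE)
  paths <- c(paths, tsv(beta_df, "beta.tsv"))
  paths <- c(paths, tsv(bundle$probes, "probes.tsv"))
  seg <- bundle$segments
  seg_df <- data.frame(sample = seg$sample_id, chrom = seg$chrom,
                       startpos = seg$start, endpos = seg$end,
                       nMajor = seg$nMajor, nMinor = seg$nMinor,
                       stringsAsFactors = FALSE)
  paths <- c(paths, tsv(seg_df, "segments.tsv"))
  cl <- bundle$clinical
  cl$os_time_years <- signif(cl$os_time_years, 6)
  paths <- c(paths, tsv(cl, "clinical.tsv"))
  paths <- c(paths, tsv(bundle$truth$status, "truth_status.tsv"))
  paths <- c(paths, tsv(bundle$truth$alleles, "truth_alleles.tsv"))
  invisible(paths)
}
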