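#' Load an imprinted-DMR catalog
#'
#' Reads a tab-separated catalog of imprinted differentially methylated
#' regions (DMRs). Coordinates are 1-based and inclusive at both ends
#' (GRCh37); single-CpG regions are stored with `start == end`.
#'
#' @param path Path to a TSV with columns `name`, `display_name`, `chrom`,
#'   `start`, `end`, `methylated_allele` (`"M"` maternal / `"P"` paternal)
#'   and `genes` (semicolon-separated symbols, possibly empty). Defaults to
#'   the catalog of 49 imprinted DMRs shipped with the package.
#' @return A `data.frame` of class `dmr_catalog`, one row per DMR, with a
#'   list-column `genes` and an `n_probes` column initialised to `NA`
#'   (filled by [map_probes_to_dmrs()]).
#' @examples
#' catalog <- load_dmr_catalog()
#' nrow(catalog)  # 49
#' @export
load_dmr_catalog <- function(path = system.file("extdata",
                                                "imprinted_dmr_catalog.tsv",
                                                package = "imprintDMR")) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty DMR catalog: ", path)
    cat0 <- data.frame(name = character(), display_name = character(),
                       chrom = character(), start = integer(),
                       end = integer(), methylated_allele = character(),
                       stringsAsFactors = FALSE)
    cat0$genes <- list()
    cat0$n_probes <- integer()
    class(cat0) <- c("dmr_catalog", "data.frame")
    return(cat0)
  }
  required <- c("name", "display_name", "chrom", "start", "end",
                "methylated_allele", "genes")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  bad_coord <- which(is.na(start) | is.na(end))
  if (length(bad_coord)) {
    stop("non-numeric coordinates in catalog row(s) ",
         paste(bad_coord, collapse = ", "))
  }
  bad <- which(start > end)
  if (length(bad)) {
    stop("start > end in catalog row(s) ", paste(bad, collapse = ", "))
  }
  dup <- which(duplicated(raw$name))
  if (length(dup)) {
    stop("duplicate DMR name(s) in catalog row(s) ",
         paste(dup, collapse = ", "), ": ",
         paste(unique(raw$name[dup]), collapse = ", "))
  }
  bad_allele <- which(!raw$methylated_allele %in% c("M", "P"))
  if (length(bad_allele)) {
    stop("methylated_allele must be 'M' or 'P'; offending row(s) ",
         paste(bad_allele, collapse = ", "))
  }
  out <- data.frame(name = raw$name,
                    display_name = raw$display_name,
                    chrom = raw$chrom,
                    start = start,
                    end = end,
                    methylated_allele = raw$methylated_allele,
                    stringsAsFactors = FALSE)
  out$genes <- lapply(raw$genes, function(g) {
    g <- trimws(strsplit(g, ";", fixed = TRUE)[[1]])
    g[nzchar(g)]
  })
  out$n_probes <- NA_integer_
  class(out) <- c("dmr_catalog", "data.frame")
  message(nrow(out), " imprinted DMRs loaded from ", basename(path))
  out
}

#' @export
print.dmr_catalog <- function(x, ...) {
  cat("Imprinted-DMR catalog:", nrow(x), "regions on",
      length(unique(x$chrom)), "chromosomes\n")
  NextMethod()
}

dmr_granges <- function(catalog) {
  GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$start, end = catalog$end),
    name = catalog$name)
}

#' Assign array probes to imprinted DMRs
#'
#' A probe belongs to a DMR iff its position lies inside the DMR interval,
#' 1-based and inclusive at both ends. Catalog intervals must be pairwise
#' disjoint: a probe falling into two DMRs is an error, not a silent pick.
#'
#' @param probes `data.frame` with columns `probe_id`, `chrom`, `pos`
#'   (1-based positions on the catalog's assembly). `probe_id` must be
#'   unique.
#' @param catalog A `dmr_catalog` from [load_dmr_catalog()].
#' @return A list with `probes` (input plus a `dmr_name` column, `NA` for
#'   unmapped probes) and `catalog` (input with `n_probes` filled; DMRs
#'   with zero probes keep `n_probes = 0`).
#' @export
map_probes_to_dmrs <- function(probes, catalog) {
  stopifnot(is.data.frame(probes))
  required <- c("probe_id", "chrom", "pos")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols)) {
    stop("probe manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe_id in manifest: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]),
               collapse = ", "))
  }
  probes$dmr_name <- NA_character_
  if (nrow(probes) > 0L && nrow(catalog) > 0L) {
    gr_p <- GenomicRanges::GRanges(
      seqnames = probes$chrom,
      ranges = IRanges::IRanges(start = probes$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr_p, dmr_granges(catalog))
    qh <- S4Vectors::queryHits(hits)
    if (anyDuplicated(qh)) {
      bad <- probes$probe_id[unique(qh[duplicated(qh)])]
      stop("probe(s) overlap more than one DMR (catalog intervals must be ",
           "disjoint): ", paste(bad, collapse = ", "))
    }
    probes$dmr_name[qh] <- catalog$name[S4Vectors::subjectHits(hits)]
  }
  counts <- table(factor(probes$dmr_name, levels = catalog$name))
  catalog$n_probes <- as.integer(counts)
  zero <- catalog$name[catalog$n_probes == 0L]
  if (length(zero)) {
    message(length(zero), " DMR(s) with zero probes: ",
            paste(zero, collapse = ", "))
  }
  list(probes = probes, catalog = catalog)
}
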