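# Small in-code fixtures shared across test files.

# Build a dmr_catalog directly (bypassing the TSV loader) for unit tests.
make_catalog <- function(name, chrom, start, end,
                         methylated_allele = "M",
                         display_name = name, genes = NULL) {
  n <- length(name)
  out <- data.frame(name = name,
                    display_name = rep_len(display_name, n),
                    chrom = rep_len(chrom, n),
                    start = as.integer(rep_len(start, n)),
                    end = as.integer(rep_len(end, n)),
                    methylated_allele = rep_len(methylated_allele, n),
                    stringsAsFactors = FALSE)
  out$genes <- if (is.null(genes)) replicate(n, character(), FALSE) else genes
  out$n_probes <- NA_integer_
  class(out) <- c("dmr_catalog", "data.frame")
  out
}

subset_catalog <- function(catalog, names) {
  out <- catalog[catalog$name %in% names, , drop = FALSE]
  class(out) <- class(catalog)
  rownames(out) <- NULL
  out
}

# Write a catalog data.frame (plain columns) to a temp TSV for loader tests.
write_catalog_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_segments_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent brute-force probe-to-DMR assignment (interval scan).
brute_force_map <- function(probes, catalog) {
  vapply(seq_len(nrow(probes)), function(i) {
    hit <- which(catalog$chrom == probes$chrom[i] &
                   catalog$start <= probes$pos[i] &
                   catalog$end >= probes$pos[i])
    if (length(hit) == 1L) catalog$name[hit] else NA_character_
  }, character(1L))
}

# A 300-tumour default cohort reused by several test files (built once).
demo_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- suppressMessages(sim_config(seed = 42L))
      cache <<- generate_cohort(cfg)
      attr(cache, "config") <- cfg
    }
    cache
  }
})

classify_cohort <- function(bundle, catalog) {
  ctrl <- build_control_reference(bundle$beta, bundle$control_ids)
  mapped <- suppressMessages(
    map_probes_to_dmrs(bundle$probes[, c("probe_id", "chrom", "pos")],
                       catalog))
  tumours <- setdiff(colnames(bundle$beta), bundle$control_ids)
  pc <- classify_probes(bundle$beta[, tumours, drop = FALSE], ctrl,
                        mapped$probes)
  list(probe_calls = pc, region_calls = call_regions(pc),
       mapped = mapped)
}
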