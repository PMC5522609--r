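# Internal helpers shared across modules.

# Half-away-from-zero rounding (base round() is round-half-even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic sub-seed derivation; stays well inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000L) * 10007 + 101 * k) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a site-record data frame (chrom, pos, strand, context, counts).
check_records <- function(records) {
  needed <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("record table lacks columns: ", paste(missing, collapse = ", "))
  if (any(records$n_meth < 0) || any(records$n_unmeth < 0))
    stop("negative methylation counts are not valid")
  bad_ctx <- setdiff(unique(records$context), c("CG", "CHG", "CHH", "UNKNOWN"))
  if (length(bad_ctx))
    stop("invalid sequence context value(s): ", paste(bad_ctx, collapse = ", "))
  invisible(records)
}

# Sort records by chrom then pos then strand and drop duplicate site keys.
sort_dedup_records <- function(records) {
  ord <- order(records$chrom, records$pos, records$strand)
  records <- records[ord, , drop = FALSE]
  key <- paste(records$chrom, records$pos, records$strand)
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL
  records
}

methylation_ratio <- function(records) {
  cov <- records$n_meth + records$n_unmeth
  ifelse(cov > 0, records$n_meth / cov, NA_real_)
}

# DMRs as GRanges on 1-based closed coordinates (internal intervals are
# 0-based half-open, so start shifts by +1).
dmr_granges <- function(dmrs) {
  GenomicRanges::GRanges(
    seqnames = dmrs$chrom,
    ranges = IRanges::IRanges(start = dmrs$start + 1L, end = dmrs$end)
  )
}

empty_dmr_frame <- function() {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    n_sites = integer(), context_label = character(),
    direction = character(), mean_diff = numeric(), area_stat = numeric(),
    source = character(), dose_group = character(),
    stringsAsFactors = FALSE
  )
}

# Stamp a data frame to disk as TSV with a reproducible provenance header.
write_tsv_stamped <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- sprintf("# methyldose %s",
                    as.character(utils::packageVersion("methyldose")))
  if (!is.null(seed)) header <- paste0(header, "; seed=", seed)
  if (!is.null(config_hash)) header <- paste0(header, "; config=", config_hash)
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_stamped <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
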