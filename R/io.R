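#' Construct a sample's cytosine site table
#'
#' A `SampleSet` bundles one bisulfite-sequencing replicate: its per-cytosine
#' count table plus the experimental metadata (herbicide dose as percent of
#' the field application rate, and replicate number).
#'
#' @param records data frame with columns `chrom`, `pos` (1-based position of
#'   the cytosine), `strand` (`"+"`, `"-"`, or `"*"` when unknown), `context`
#'   (`"CG"`, `"CHG"`, `"CHH"`, or `"UNKNOWN"`), `n_meth`, `n_unmeth`.
#' @param sample_id character scalar.
#' @param dose numeric treatment dose (percent of field rate, e.g. 0, 5, 10).
#' @param replicate integer replicate index.
#' @return An object of class `SampleSet`: a list with elements `sample_id`,
#'   `dose`, `replicate` and `records` (sorted by chrom/pos, deduplicated).
#' @export
sample_set <- function(records, sample_id, dose = NA_real_,
                       replicate = NA_integer_) {
  check_records(records)
  records <- sort_dedup_records(records)
  structure(
    list(sample_id = as.character(sample_id), dose = as.numeric(dose),
         replicate = as.integer(replicate), records = records),
    class = "SampleSet"
  )
}

#' @export
print.SampleSet <- function(x, ...) {
  cov <- x$records$n_meth + x$records$n_unmeth
  cat(sprintf("SampleSet '%s' (dose %s%%, replicate %s): %d sites, median coverage %s\n",
              x$sample_id, x$dose, x$replicate, nrow(x$records),
              if (length(cov)) stats::median(cov[cov > 0]) else NA))
  invisible(x)
}

#' Read a Bismark-style per-cytosine count table
#'
#' Supports the two Bismark output dialects: the seven-column cytosine
#' (CX) report (`chrom pos strand count_meth count_unmeth context tri`)
#' and the six-column coverage file
#' (`chrom start end pct_meth count_meth count_unmeth`).  Coverage files
#' carry neither strand nor context; such records are read with strand `"*"`
#' and context `"UNKNOWN"` and must be completed with
#' [classify_contexts()] against the reference before use.
#'
#' @param path file path.
#' @param dialect `"cx_report"` or `"cov"`.
#' @param sample_id,dose,replicate metadata stored on the result
#'   (default `sample_id` is the file base name).
#' @return A [sample_set()].
#' @export
read_cytosine_table <- function(path, dialect = c("cx_report", "cov"),
                                sample_id = NULL, dose = NA_real_,
                                replicate = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("empty cytosine table: ", path)
    rec <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_unmeth = integer(),
                      stringsAsFactors = FALSE)
    return(sample_set(rec, sample_id, dose, replicate))
  }
  fields <- strsplit(lines, "[\t ]+")
  n_expected <- if (dialect == "cx_report") 7L else 6L
  nf <- lengths(fields)
  if (any(nf < n_expected - (dialect == "cx_report"))) {  # tri column optional
    bad <- which(nf < n_expected - (dialect == "cx_report"))[1]
    stop(sprintf("malformed %s line %d in %s: '%s'", dialect, bad, path,
                 lines[bad]))
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  if (dialect == "cx_report") {
    rec <- data.frame(
      chrom = get(1), pos = as.integer(get(2)), strand = get(3),
      context = get(6),
      n_meth = as.integer(get(4)), n_unmeth = as.integer(get(5)),
      stringsAsFactors = FALSE
    )
  } else {
    rec <- data.frame(
      chrom = get(1), pos = as.integer(get(2)), strand = "*",
      context = "UNKNOWN",
      n_meth = as.integer(get(5)), n_unmeth = as.integer(get(6)),
      stringsAsFactors = FALSE
    )
  }
  if (anyNA(rec$pos) || anyNA(rec$n_meth) || anyNA(rec$n_unmeth)) {
    bad <- which(is.na(rec$pos) | is.na(rec$n_meth) | is.na(rec$n_unmeth))[1]
    stop(sprintf("malformed %s line %d in %s (non-numeric field)",
                 dialect, bad, path))
  }
  if (any(rec$n_meth < 0) || any(rec$n_unmeth < 0))
    stop("negative counts in ", path)
  sample_set(rec, sample_id, dose, replicate)
}

#' Write a sample's records as a Bismark CX report
#'
#' @param samples a [sample_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cytosine_table <- function(samples, path) {
  r <- samples$records
  tri <- ifelse(r$context == "CG", "CG", r$context)  # trinucleotide surrogate
  utils::write.table(
    data.frame(r$chrom, r$pos, r$strand, r$n_meth, r$n_unmeth, r$context, tri),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Classify CG/CHG/CHH sequence contexts from a reference
#'
#' Annotates every record with its plant methylation context: `CG` when the
#' base 3' of the cytosine (on the cytosine's own strand) is G, `CHG` when it
#' is H (A, T or C) followed by G, and `CHH` otherwise.  Records whose
#' position does not carry a C (plus strand) or G (minus strand) in the
#' reference raise an error; strand `"*"` records (coverage-file dialect)
#' have their strand inferred from the reference base.  Sites too close to a
#' contig end for the context to be determined are dropped with a warning.
#'
#' @param samples a [sample_set()].
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return The annotated `SampleSet`.
#' @export
classify_contexts <- function(samples, reference) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  seqs <- lapply(as.character(reference), function(s) strsplit(s, "")[[1]])
  r <- samples$records
  if (!nrow(r)) return(samples)
  if (!all(r$chrom %in% names(seqs)))
    stop("contig(s) absent from reference: ",
         paste(setdiff(unique(r$chrom), names(seqs)), collapse = ", "))
  ctx <- character(nrow(r))
  strand <- r$strand
  keep <- rep(TRUE, nrow(r))
  for (chr in unique(r$chrom)) {
    idx <- which(r$chrom == chr)
    s <- seqs[[chr]]
    L <- length(s)
    pos <- r$pos[idx]
    if (any(pos < 1 | pos > L))
      stop("position outside contig ", chr)
    base <- s[pos]
    str_i <- strand[idx]
    infer <- str_i == "*"
    str_i[infer & base == "C"] <- "+"
    str_i[infer & base == "G"] <- "-"
    ok <- (str_i == "+" & base == "C") | (str_i == "-" & base == "G")
    if (!all(ok)) {
      bad <- idx[which(!ok)[1]]
      stop(sprintf("reference base mismatch at %s:%d (%s strand): found %s",
                   chr, r$pos[bad], strand[bad], base[which(!ok)[1]]))
    }
    strand[idx] <- str_i
    for (k in seq_along(idx)) {
      p <- pos[k]
      if (str_i[k] == "+") {
        b1 <- if (p + 1 <= L) s[p + 1] else NA
        b2 <- if (p + 2 <= L) s[p + 2] else NA
      } else {
        comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
        b1 <- if (p - 1 >= 1) comp[[s[p - 1]]] else NA
        b2 <- if (p - 2 >= 1) comp[[s[p - 2]]] else NA
      }
      if (!is.na(b1) && b1 == "G") {
        ctx[idx[k]] <- "CG"
      } else if (is.na(b1) || is.na(b2)) {
        keep[idx[k]] <- FALSE
      } else if (b2 == "G") {
        ctx[idx[k]] <- "CHG"
      } else {
        ctx[idx[k]] <- "CHH"
      }
    }
  }
  if (!all(keep))
    warning(sum(!keep), " site(s) dropped: context incomplete at contig end")
  r$context <- ctx
  r$strand <- strand
  r <- r[keep, , drop = FALSE]
  sample_set(r, samples$sample_id, samples$dose, samples$replicate)
}

#' Estimate bisulfite conversion efficiency from an unmethylated control
#'
#' Bisulfite treatment converts unmethylated cytosines to uracil; any
#' methylated call on a genuinely unmethylated genome (in the original study,
#' the chloroplast) reflects conversion failure.  The non-conversion rate is
#' the pooled fraction of methylated calls over all covered cytosines of the
#' control contig.
#'
#' @param samples a [sample_set()].
#' @param control_contig contig id of the unmethylated control.
#' @return A list of class `ConversionReport` with `control_contig`,
#'   `n_meth_calls`, `n_total_calls`, `non_conversion_rate`, `efficiency`.
#' @export
estimate_conversion <- function(samples, control_contig) {
  r <- samples$records[samples$records$chrom == control_contig, , drop = FALSE]
  total <- sum(r$n_meth) + sum(r$n_unmeth)
  if (!nrow(r) || total == 0)
    stop("no covered cytosines on control contig '", control_contig, "'")
  rate <- sum(r$n_meth) / total
  structure(
    list(control_contig = control_contig,
         n_meth_calls = sum(r$n_meth), n_total_calls = total,
         non_conversion_rate = rate, efficiency = 1 - rate),
    class = "ConversionReport"
  )
}

#' @export
print.ConversionReport <- function(x, ...) {
  cat(sprintf("Conversion efficiency %.4f (non-conversion %.4f; %d/%d methylated calls on '%s')\n",
              x$efficiency, x$non_conversion_rate, x$n_meth_calls,
              x$n_total_calls, x$control_contig))
  invisible(x)
}

#' Write and read DMR tables as BED6+
#'
#' DMR intervals are 0-based half-open internally, which is the BED
#' convention, so coordinates pass through unchanged.  Columns beyond BED6
#' carry `direction`, `n_sites`, `source`, `dose_group`, `mean_diff` and
#' `area_stat` so that `read_dmrs_bed(write_dmrs_bed(x))` restores the table.
#'
#' @param dmrs DMR data frame (`chrom`, `start`, `end`, `n_sites`,
#'   `context_label`, `direction`, `mean_diff`, `area_stat`, `source`,
#'   `dose_group`).
#' @param path output file.
#' @return `path` (write) or a DMR data frame (read).
#' @export
write_dmrs_bed <- function(dmrs, path) {
  if (nrow(dmrs) && any(dmrs$end <= dmrs$start))
    stop("invalid interval: end <= start")
  score <- round_half_up(ifelse(is.na(dmrs$area_stat), abs(dmrs$mean_diff),
                                abs(dmrs$area_stat)))
  bed <- data.frame(
    dmrs$chrom, dmrs$start, dmrs$end, dmrs$context_label, score, ".",
    dmrs$direction, dmrs$n_sites, dmrs$source, dmrs$dose_group,
    dmrs$mean_diff, dmrs$area_stat
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmrs_bed
#' @export
read_dmrs_bed <- function(path) {
  if (file.size(path) == 0) return(empty_dmr_frame())
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(
    chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]), n_sites = as.integer(bed[[8]]),
    context_label = as.character(bed[[4]]), direction = as.character(bed[[7]]),
    mean_diff = as.numeric(bed[[11]]), area_stat = as.numeric(bed[[12]]),
    source = as.character(bed[[9]]), dose_group = as.character(bed[[10]]),
    stringsAsFactors = FALSE
  )
}

#' Read gene / transposable-element features from GFF3
#'
#' Keeps `gene`, `transposable_element` and `transposable_element_gene`
#' records and converts 1-based inclusive GFF coordinates to the internal
#' 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return Data frame with `id`, `chrom`, `start`, `end`, `feature_type`
#'   (`gene`, `transposable_element`, `te_gene`, or `other`).
#' @export
read_features_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("gene", "transposable_element",
                      "transposable_element_gene")
  gr <- gr[keep]
  type <- type[keep]
  ftype <- c(gene = "gene", transposable_element = "transposable_element",
             transposable_element_gene = "te_gene")[type]
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  if (anyNA(id)) stop("GFF feature(s) without an ID attribute")
  if (anyDuplicated(id)) stop("duplicate feature ids in ", path)
  data.frame(
    id = id, chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    feature_type = unname(ftype), stringsAsFactors = FALSE
  )
}

#' Read a gene list (one id per line)
#'
#' @param path text file.
#' @return Character vector of unique ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
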