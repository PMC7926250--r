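# Internal helpers shared across modules.

abort_field <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

# Reverse complement of an ACGTN character vector (uppercase).
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonical representative of a k-mer / revcomp pair used throughout the
# sgRNA finder: prefer the orientation ending in "GG" (the protospacer+PAM
# form); if both or neither end in "GG", take the lexicographic minimum.
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  gg_x <- endsWith(x, "GG")
  gg_rc <- endsWith(rc, "GG")
  out <- pmin(x, rc)
  out[gg_x & !gg_rc] <- x[gg_x & !gg_rc]
  out[!gg_x & gg_rc] <- rc[!gg_x & gg_rc]
  out
}

# tibble(chrom, start, end) [0-based half-open] -> GRanges
df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

gr_to_df <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_field("%s is missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(df)
}
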