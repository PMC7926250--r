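#' Enumerate PAM-adjacent k-mer candidates for chromosome labelling
#'
#' Scans a genome for all 22- and 23-mers of the form `N{20,21}GG` (the
#' sgRNA protospacer plus "GG" PAM core) and counts their occurrences per
#' chromosome. Counting is strand-collapsed and per genomic interval: an
#' occurrence of the k-mer or of its reverse complement contributes one
#' count, overlapping occurrences are all counted, and a palindromic k-mer
#' is counted once per interval. A k-mer and its reverse complement form one
#' candidate, reported in the "GG"-ending orientation (lexicographic minimum
#' when both orientations end in "GG"). Only candidates reaching
#' `min_copies` on at least one chromosome are returned; k-mers containing
#' `N` never match.
#'
#' @param genome Named character vector of chromosome sequences
#'   (A/C/G/T/N), or a [Biostrings::DNAStringSet].
#' @param min_copies Minimum per-chromosome copy number (default 20, i.e.
#'   copy number > 19).
#' @param k Candidate lengths (default `c(22, 23)`).
#' @return Tibble of class `kmer_stats` in long form: `sequence`, `chrom`,
#'   `count`, plus `total` (genome-wide count) and `max_count` repeated per
#'   sequence. Includes zero-count rows for every (sequence, chromosome)
#'   pair so off-chromosome sums are explicit.
#' @export
enumerate_sgrna_candidates <- function(genome, min_copies = 20, k = c(22L, 23L)) {
  genome <- as_genome_charvec(genome)
  if (length(genome) == 0 || sum(nchar(genome)) == 0) {
    return(empty_kmer_stats(names(genome)))
  }
  bad <- vapply(genome, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    abort_field("enumerate_sgrna_candidates: sequence(s) %s contain non-ACGTN characters",
                paste(names(genome)[bad], collapse = ", "))
  }
  if (min_copies < 1) abort_field("enumerate_sgrna_candidates: min_copies must be >= 1")

  occ <- sgrna_occurrences(genome, k)
  kmer_stats_from_occ(occ, names(genome), min_copies)
}

kmer_stats_from_occ <- function(occ, chroms, min_copies) {
  if (nrow(occ) == 0) return(empty_kmer_stats(chroms))
  counts <- occ |>
    dplyr::count(.data$sequence, .data$chrom, name = "count") |>
    tidyr::complete(sequence = unique(occ$sequence),
                    chrom = chroms, fill = list(count = 0L)) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::mutate(total = sum(.data$count), max_count = max(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$max_count >= min_copies) |>
    dplyr::arrange(.data$sequence, .data$chrom)
  class(counts) <- c("kmer_stats", class(counts))
  counts
}

empty_kmer_stats <- function(chroms) {
  out <- tibble::tibble(sequence = character(), chrom = character(),
                        count = integer(), total = integer(),
                        max_count = integer())
  class(out) <- c("kmer_stats", class(out))
  out
}

as_genome_charvec <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (length(genome) == 0) return(stats::setNames(character(), character()))
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    abort_field("genome must have unique chromosome names")
  }
  toupper(genome)
}

# All candidate occurrences as (sequence [canonical], chrom, start [0-based]).
# PAM-anchored: plus-strand hits end in GG, minus-strand hits (revcomp ends
# in GG) start with CC. The same interval found through both anchors is
# deduplicated.
sgrna_occurrences <- function(genome, k = c(22L, 23L)) {
  res <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    n <- nchar(s)
    gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
    gg <- gg[gg > 0]
    cc <- gregexpr("(?=CC)", s, perl = TRUE)[[1]]
    cc <- cc[cc > 0]
    for (kk in k) {
      # k-mer ending at GG (positions q, q+1): start = q + 2 - k (1-based)
      st_plus <- gg + 2L - kk
      st_plus <- st_plus[st_plus >= 1]
      # k-mer starting at CC: start = q, needs q + k - 1 <= n
      st_minus <- cc[cc + kk - 1L <= n]
      starts <- c(st_plus, st_minus)
      if (length(starts) == 0) next
      words <- substring(s, starts, starts + kk - 1L)
      ok <- !grepl("N", words, fixed = TRUE)
      if (!any(ok)) next
      uw <- unique(words[ok])
      canon <- canonical_kmer(uw)
      res[[length(res) + 1]] <- tibble::tibble(
        chrom = chrom,
        start = starts[ok] - 1L,
        sequence = canon[match(words[ok], uw)],
        k = kk
      )
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          sequence = character(), k = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(res), .data$chrom, .data$start,
                  .data$sequence, .keep_all = TRUE)
}

#' Chromosome specificity of a candidate k-mer
#'
#' The specificity of sequence `s` in chromosome `c` is
#' `f_c(s) / (1 + sum_{i != c} f_i(s))` where `f_c(s)` is the
#' strand-collapsed occurrence count of `s` on `c`. Candidates are retained
#' for chromosome labelling when the value is strictly greater than 19.
#'
#' @param stats A `kmer_stats` tibble from [enumerate_sgrna_candidates()].
#' @param chrom Target chromosome.
#' @return Tibble with `sequence`, `count` (on `chrom`), `total_off`
#'   (occurrences elsewhere), `specificity`.
#' @export
sgrna_specificity <- function(stats, chrom) {
  check_cols(stats, c("sequence", "chrom", "count", "total"), "stats")
  if (!chrom %in% stats$chrom) {
    abort_field("sgrna_specificity: chromosome '%s' not present in stats", chrom)
  }
  stats |>
    dplyr::filter(.data$chrom == !!chrom) |>
    dplyr::transmute(
      sequence = .data$sequence,
      count = .data$count,
      total_off = .data$total - .data$count,
      specificity = .data$count / (1 + .data$total - .data$count)
    )
}

#' Locate sub-megabase focal regions of a chromosome-specific k-mer
#'
#' Searches the sorted occurrence positions of a candidate on its target
#' chromosome for maximal runs of consecutive occurrences whose enclosing
#' interval (including the k-mer footprint) spans less than `max_span`.
#' For each maximal window the number of copies left outside is
#' `nR = fc - in_region`, and the window is reported iff
#' `nR <= (fc - 20 * total_off - 20) / 21`, the rearrangement of the
#' requirement that the specificity restricted to the region,
#' `(fc - nR) / (1 + total_off + nR)`, is at least 20. A negative bound
#' yields no regions. Nested sub-windows of a qualifying window are
#' suppressed.
#'
#' @param occurrences Sorted 0-based start positions of the candidate on the
#'   target chromosome (both orientations).
#' @param total_off Total occurrences on all other chromosomes.
#' @param k K-mer length (footprint used for span computation).
#' @param max_span Maximum region span in bp (default 1e6).
#' @param min_region_specificity Region-specificity threshold (default 20).
#' @return Tibble with `start`, `end` (smallest enclosing interval of the
#'   in-region occurrences, 0-based half-open), `in_region`, `n_outside`,
#'   `specificity_in_region`.
#' @export
find_focal_regions <- function(occurrences, total_off, k = 23L,
                               max_span = 1e6, min_region_specificity = 20) {
  if (is.unsorted(occurrences)) {
    abort_field("find_focal_regions: occurrences must be sorted ascending")
  }
  fc <- length(occurrences)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          in_region = integer(), n_outside = integer(),
                          specificity_in_region = numeric())
  if (fc == 0) return(empty)
  m <- min_region_specificity
  # integer form of nR <= (fc - m*total_off - m) / (m + 1); exact at the
  # boundary, unlike the float division
  rhs <- fc - m * total_off - m
  if (rhs < 0) return(empty)

  # Two-pointer maximal windows: for each i the largest j with span < max_span.
  jmax <- integer(fc)
  j <- 1L
  for (i in seq_len(fc)) {
    if (j < i) j <- i
    while (j + 1L <= fc && (occurrences[j + 1L] + k - occurrences[i]) < max_span) {
      j <- j + 1L
    }
    jmax[i] <- j
  }
  out <- list()
  for (i in seq_len(fc)) {
    if (i > 1L && jmax[i - 1L] >= jmax[i]) next  # nested in previous window
    in_region <- jmax[i] - i + 1L
    nR <- fc - in_region
    if ((m + 1) * nR > rhs) next
    out[[length(out) + 1]] <- tibble::tibble(
      start = occurrences[i],
      end = occurrences[jmax[i]] + k,
      in_region = in_region,
      n_outside = nR,
      specificity_in_region = (fc - nR) / (1 + total_off + nR)
    )
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Search a genome for chromosome-specific repeat sgRNA targets
#'
#' End-to-end candidate search: enumerate PAM-adjacent 22/23-mers, keep
#' those with per-chromosome copy number >= `min_copies` and chromosome
#' specificity strictly greater than `min_specificity` on the target
#' chromosome, then locate their sub-megabase focal regions.
#'
#' @inheritParams enumerate_sgrna_candidates
#' @param target_chrom Chromosome to design against.
#' @param min_specificity Chromosome-specificity threshold (strict; default 19).
#' @param max_span Maximum focal-region span (default 1e6 bp).
#' @return List of class `sgrna_targets` with `report` (one row per
#'   candidate x region: `sequence`, `chrom`, `count`, `total_off`,
#'   `specificity`, `region_start`, `region_end`, `n_outside`,
#'   `specificity_in_region`) and `regions` (BED-like tibble).
#' @export
sgrna_find <- function(genome, target_chrom, min_copies = 20,
                       min_specificity = 19, max_span = 1e6) {
  genome <- as_genome_charvec(genome)
  if (!target_chrom %in% names(genome)) {
    abort_field("sgrna_find: target chromosome '%s' not in genome", target_chrom)
  }
  occ_all <- sgrna_occurrences(genome)
  stats <- kmer_stats_from_occ(occ_all, names(genome), min_copies)
  spec <- sgrna_specificity(stats, target_chrom) |>
    dplyr::filter(.data$count >= min_copies,
                  .data$specificity > min_specificity)
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    sq <- spec$sequence[i]
    occ <- sort(occ_all$start[occ_all$sequence == sq &
                              occ_all$chrom == target_chrom])
    reg <- find_focal_regions(occ, spec$total_off[i], k = nchar(sq),
                              max_span = max_span)
    if (nrow(reg) == 0) next
    rows[[length(rows) + 1]] <- dplyr::mutate(
      reg, sequence = sq, chrom = target_chrom, count = spec$count[i],
      total_off = spec$total_off[i], specificity = spec$specificity[i]
    )
  }
  report <- if (length(rows) == 0) {
    tibble::tibble(sequence = character(), chrom = character(),
                   count = integer(), total_off = integer(),
                   specificity = numeric(), region_start = integer(),
                   region_end = integer(), in_region = integer(),
                   n_outside = integer(), specificity_in_region = numeric())
  } else {
    dplyr::bind_rows(rows) |>
      dplyr::rename(region_start = "start", region_end = "end") |>
      dplyr::select("sequence", "chrom", "count", "total_off", "specificity",
                    "region_start", "region_end", "in_region", "n_outside",
                    "specificity_in_region") |>
      dplyr::arrange(.data$chrom, .data$region_start, .data$sequence)
  }
  structure(list(report = report,
                 regions = report_targets(report)$bed),
            class = "sgrna_targets")
}

#' @export
print.sgrna_targets <- function(x, ...) {
  cat("sgRNA repeat-target search:", nrow(x$report), "candidate/region pairs,",
      nrow(x$regions), "focal regions\n")
  invisible(x)
}

#' Assemble BED and TSV outputs for focal-region candidates
#'
#' @param report Report tibble as produced inside [sgrna_find()].
#' @param merge If TRUE, identical region intervals shared by several
#'   candidates collapse to one BED record.
#' @param bed_path,tsv_path Optional paths; when given the tables are
#'   written (BED is 0-based half-open; both files carry a header line in
#'   the TSV only).
#' @return List with `bed` and `tsv` tibbles, deterministically ordered by
#'   (chrom, start, sequence).
#' @export
report_targets <- function(report, merge = TRUE, bed_path = NULL,
                           tsv_path = NULL) {
  tsv <- dplyr::arrange(report, .data$chrom, .data$region_start, .data$sequence)
  bed <- tibble::tibble(chrom = tsv$chrom, start = tsv$region_start,
                        end = tsv$region_end, name = tsv$sequence)
  if (merge && nrow(bed) > 0) {
    bed <- bed |>
      dplyr::group_by(.data$chrom, .data$start, .data$end) |>
      dplyr::summarise(name = paste(.data$name, collapse = ","),
                       .groups = "drop") |>
      dplyr::arrange(.data$chrom, .data$start)
  }
  if (!is.null(bed_path)) {
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(bed = bed, tsv = tsv)
}
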