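#' Assign fragments to parental alleles from their SNP content
#'
#' Re-implements the SNPsplit assignment rule on tabular fragments: a
#' fragment whose observed SNP bases all match the first (B6) allele is
#' `B6`, all matching the second (Cast) allele is `Cast`, covering no
#' informative SNP is `unassigned`, and a mixture is `conflicting`.
#' An observed base matching neither allele is treated as a sequencing
#' error (uninformative), not an error condition.
#'
#' @param fragments Tibble with `chrom`, `start`, `end` (0-based
#'   half-open) and `snp_bases`, a string of semicolon-separated
#'   `pos:base` pairs (1-based positions; empty string for none).
#' @param snps SNP table: `chrom`, `pos` (1-based), `allele1` (B6 base),
#'   `allele2` (Cast base).
#' @return `fragments` with an `allele` factor column
#'   (`B6`/`Cast`/`unassigned`/`conflicting`).
#' @export
assign_alleles <- function(fragments, snps) {
  check_cols(fragments, c("chrom", "start", "end", "snp_bases"), "fragments")
  check_cols(snps, c("chrom", "pos", "allele1", "allele2"), "snps")
  n <- nrow(fragments)
  lev <- c("B6", "Cast", "unassigned", "conflicting")
  if (n == 0) {
    fragments$allele <- factor(character(), levels = lev)
    return(fragments)
  }

  obs <- strsplit(fragments$snp_bases, ";", fixed = TRUE)
  len <- lengths(obs)
  idx <- rep.int(seq_len(n), len)
  flat <- unlist(obs, use.names = FALSE)
  flat <- flat[nzchar(flat)]
  idx <- idx[nzchar(unlist(obs, use.names = FALSE))]

  n_b6 <- integer(n); n_cast <- integer(n)
  if (length(flat) > 0) {
    pos <- as.integer(sub(":.*", "", flat))
    base <- toupper(sub(".*:", "", flat))
    key <- paste(fragments$chrom[idx], pos)
    snp_key <- paste(snps$chrom, snps$pos)
    m <- match(key, snp_key)
    if (anyNA(m)) {
      abort_field("assign_alleles: fragment cites SNP position(s) absent from the SNP table (e.g. %s)",
                  key[which(is.na(m))[1]])
    }
    hit_b6 <- base == toupper(snps$allele1[m])
    hit_cast <- base == toupper(snps$allele2[m])
    t_b6 <- tapply(hit_b6, idx, sum)
    t_cast <- tapply(hit_cast, idx, sum)
    n_b6[as.integer(names(t_b6))] <- as.integer(t_b6)
    n_cast[as.integer(names(t_cast))] <- as.integer(t_cast)
  }
  call <- rep("unassigned", n)
  call[n_b6 > 0 & n_cast == 0] <- "B6"
  call[n_cast > 0 & n_b6 == 0] <- "Cast"
  call[n_b6 > 0 & n_cast > 0] <- "conflicting"
  fragments$allele <- factor(call, levels = lev)
  fragments
}

#' Count fragments per window, per sample, per allele
#'
#' Each fragment is counted once, in the single window with the largest
#' overlap (ties broken to the leftmost window); fragments overlapping no
#' window are dropped. This is the deterministic analogue of
#' featureCounts-style counting against a complete genome tiling.
#'
#' @param fragments Tibble with `chrom`, `start`, `end`, `sample_id` and
#'   `allele` (from [assign_alleles()] or simulation truth).
#' @param windows Tiling tibble with `chrom`, `start`, `end` and optionally
#'   `window` id (default `chrom:start-end`).
#' @return Tibble of class `allelic_counts`: `window`, `chrom`, `start`,
#'   `end`, `sample_id`, `allele`, `count`, complete over the allele
#'   levels for every (window, sample) pair that received any fragment.
#' @export
count_windows <- function(fragments, windows) {
  check_cols(fragments, c("chrom", "start", "end", "sample_id", "allele"),
             "fragments")
  check_cols(windows, c("chrom", "start", "end"), "windows")
  if (any(fragments$end <= fragments$start)) {
    abort_field("count_windows: zero- or negative-length fragments present")
  }
  if (!"window" %in% names(windows)) {
    windows$window <- paste0(windows$chrom, ":", windows$start, "-", windows$end)
  }
  frg <- df_to_gr(fragments)
  win <- df_to_gr(windows)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(frg, win))
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(frg)[S4Vectors::queryHits(hits)],
    IRanges::ranges(win)[S4Vectors::subjectHits(hits)]
  ))
  hdf <- tibble::tibble(
    frag = S4Vectors::queryHits(hits),
    win = S4Vectors::subjectHits(hits),
    overlap = ov,
    win_start = windows$start[S4Vectors::subjectHits(hits)]
  )
  best <- hdf |>
    dplyr::group_by(.data$frag) |>
    dplyr::arrange(dplyr::desc(.data$overlap), .data$win_start,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  assigned <- fragments[best$frag, c("sample_id", "allele")]
  assigned$window <- windows$window[best$win]
  counts <- assigned |>
    dplyr::count(.data$window, .data$sample_id, .data$allele,
                 name = "count") |>
    dplyr::mutate(allele = as.character(.data$allele)) |>
    tidyr::complete(
      tidyr::nesting(window, sample_id),
      allele = levels(fragments$allele),
      fill = list(count = 0L)
    ) |>
    dplyr::mutate(allele = factor(.data$allele,
                                  levels = levels(fragments$allele))) |>
    dplyr::left_join(windows[, c("window", "chrom", "start", "end")],
                     by = "window") |>
    dplyr::select("window", "chrom", "start", "end", "sample_id",
                  "allele", "count") |>
    dplyr::arrange(.data$chrom, .data$start, .data$sample_id, .data$allele)
  class(counts) <- c("allelic_counts", class(counts))
  counts
}

#' Per-scope B6 allelic fraction
#'
#' `B6 / (B6 + Cast)` per chromosome or per window; scopes with no
#' informative read are reported as `NA`.
#'
#' @param counts An `allelic_counts` tibble.
#' @param scope `"chrom"` or `"window"`.
#' @param by_sample Split by sample (default TRUE).
#' @return Tibble with the scope column(s), `b6`, `cast`, `fraction_b6`.
#' @export
allelic_fraction <- function(counts, scope = c("chrom", "window"),
                             by_sample = TRUE) {
  scope <- match.arg(scope)
  grp <- c(scope, if (by_sample) "sample_id")
  counts |>
    dplyr::filter(.data$allele %in% c("B6", "Cast")) |>
    tidyr::pivot_wider(names_from = "allele", values_from = "count",
                       values_fill = 0L) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(b6 = sum(.data$B6), cast = sum(.data$Cast),
                     .groups = "drop") |>
    dplyr::mutate(fraction_b6 = ifelse(.data$b6 + .data$cast > 0,
                                       .data$b6 / (.data$b6 + .data$cast),
                                       NA_real_))
}

#' Write a scaled per-base coverage track (bedGraph)
#'
#' Per-base fragment pileup scaled by `1e7 / library_total` (the
#' 10,000,000-over-total-reads convention), with equal-value runs merged.
#'
#' @param fragments Tibble with `chrom`, `start`, `end`, sorted by
#'   (chrom, start).
#' @param library_total Total fragments in the full library used for the
#'   scale factor; defaults to `nrow(fragments)`.
#' @param path Optional bedGraph output path.
#' @return Tibble `chrom`, `start`, `end`, `value` (invisibly when `path`
#'   is given).
#' @export
write_coverage_track <- function(fragments, library_total = nrow(fragments),
                                 path = NULL) {
  check_cols(fragments, c("chrom", "start", "end"), "fragments")
  if (nrow(fragments) > 1) {
    o <- order(fragments$chrom, fragments$start)
    if (!identical(o, seq_len(nrow(fragments)))) {
      abort_field("write_coverage_track: fragments must be sorted by (chrom, start)")
    }
  }
  if (nrow(fragments) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), value = numeric())
  } else {
    scale <- 1e7 / library_total
    gr <- df_to_gr(fragments)
    cov <- GenomicRanges::coverage(gr)
    rows <- list()
    for (chrom in names(cov)) {
      r <- cov[[chrom]]
      v <- S4Vectors::runValue(r)
      ends <- cumsum(S4Vectors::runLength(r))
      starts <- c(0L, ends[-length(ends)])
      keep <- v > 0
      if (!any(keep)) next
      rows[[chrom]] <- tibble::tibble(chrom = chrom, start = starts[keep],
                                      end = ends[keep],
                                      value = v[keep] * scale)
    }
    out <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(chrom = character(), start = integer(),
                     end = integer(), value = numeric())
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(out))
  }
  out
}
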