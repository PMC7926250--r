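#' Pipeline configuration
#'
#' Collects every knob of the end-to-end demonstration pipeline. All
#' randomness flows from `seed`; the full config (including defaults) is
#' serialized verbatim into the output directory so a run is reproducible
#' from its own manifest.
#'
#' @param seed Master seed.
#' @param sim A [sim_config()] (defaults derive their seed from `seed`).
#' @param min_copies,min_specificity,max_span sgRNA search thresholds.
#' @param tpm_cutoff TPM cutoff for gene classification.
#' @param h3k27me3_threshold Numeric threshold or `"auto"` (KDE crossing).
#' @param alpha Significance level for the statistical calls.
#' @param run_sgrna,run_imaging Include the optional stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            min_copies = 20,
                            min_specificity = 19,
                            max_span = 1e6,
                            tpm_cutoff = 1,
                            h3k27me3_threshold = "auto",
                            alpha = 0.05,
                            run_sgrna = TRUE,
                            run_imaging = FALSE) {
  structure(list(seed = as.integer(seed), sim = sim,
                 min_copies = min_copies, min_specificity = min_specificity,
                 max_span = max_span, tpm_cutoff = tpm_cutoff,
                 h3k27me3_threshold = h3k27me3_threshold, alpha = alpha,
                 run_sgrna = run_sgrna, run_imaging = run_imaging),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> annotate -> count -> normalize -> fit -> compare
#' (+ optional sgRNA search) end to end, writing every intermediate table
#' as TSV plus a `manifest.tsv` with an MD5 checksum per output and the
#' serialized config (`config.yaml`). Re-running with the same config
#' produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`genome`,
#'   `fragments`, `counts`, `factors`, `tracks`, `fits`, `comparison`,
#'   `annotation`, `classified`, `sgrna`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config$sim

  genome <- simulate_genome(scfg)
  sim <- simulate_fragments(scfg, genome)

  # --- annotation layer -------------------------------------------------
  ann <- simulate_annotation(seed = scfg$seed + 2L,
                             chrom = scfg$induced_chrom,
                             chrom_len = scfg$chromosomes$length[
                               scfg$chromosomes$chrom == scfg$induced_chrom])
  k9 <- consensus_peaks(ann$peaks$k9ac)
  k4 <- consensus_peaks(ann$peaks$k4me3)
  thr <- config$h3k27me3_threshold
  if (identical(thr, "auto")) {
    act <- ann$h3k27me3_t0$signal[ann$truth$design %in%
                                    c("initially_active", "tpm_excluded",
                                      "expressed_without_marks")]
    ina <- ann$h3k27me3_t0$signal[ann$truth$design %in%
                                    c("bivalent", "silent", "single_mark")]
    thr <- tryCatch(h3k27me3_threshold(act, ina),
                    error = function(e) h3k27me3_default_threshold)
  }
  classified <- classify_genes(ann$transcripts, k9, k4, ann$h3k27me3_t0,
                               ann$tpm, threshold = thr)
  intergenic <- intergenic_windows(sim$windows[
    sim$windows$chrom == scfg$induced_chrom, ],
    classified, ann$enhancers)

  # --- allelic counting and normalization ------------------------------
  frags <- assign_alleles(sim$fragments, genome$snps)
  counts <- count_windows(frags, sim$windows)

  # TMM on B6 counts over autosomal consensus "peaks" (the autosomal
  # windows stand in for autosomal peak intervals in the toy genome)
  auto_counts <- counts |>
    dplyr::filter(.data$chrom != scfg$induced_chrom, .data$allele == "B6") |>
    dplyr::select(peak = "window", "sample_id", "count")
  factors <- tmm_factors(auto_counts)
  libsizes <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(library_size = sum(.data$count), .groups = "drop")
  factors <- dplyr::select(factors, -"library_size") |>
    dplyr::inner_join(libsizes, by = "sample_id")

  tracks <- normalize_tracks(counts, factors, sim$samples,
                             rescale_chrom = scfg$induced_chrom)

  # --- dynamics (fits use replicate-level tracks, fitted jointly) -------
  tracks_rep <- normalize_tracks(counts, factors, sim$samples,
                                 rescale_chrom = scfg$induced_chrom,
                                 collapse_replicates = FALSE)
  x_tracks <- tracks_rep |>
    dplyr::filter(.data$chrom == scfg$induced_chrom) |>
    dplyr::transmute(window = .data$window, mark = .data$mark,
                     timepoint = .data$timepoint,
                     value = .data$signal_t0sub)
  fits <- fit_accumulation(x_tracks)
  fits <- filter_fits(fits)
  fits <- cap_ed50(fits)

  comparison <- NULL
  if (length(scfg$marks) >= 2) {
    wide <- fits |>
      dplyr::select("window", "mark", "ed50_capped") |>
      tidyr::pivot_wider(names_from = "mark", values_from = "ed50_capped")
    m1 <- scfg$marks[1]; m2 <- scfg$marks[2]
    comparison <- tryCatch(compare_marks(wide[[m1]], wide[[m2]]),
                           error = function(e) NULL)
  }

  sgrna <- NULL
  if (config$run_sgrna) {
    sgrna <- sgrna_find(genome$hap1, scfg$induced_chrom,
                        min_copies = config$min_copies,
                        min_specificity = config$min_specificity,
                        max_span = config$max_span)
  }

  # --- write outputs ----------------------------------------------------
  outputs <- list(
    samples = sim$samples,
    snps = genome$snps,
    windows = sim$windows,
    gene_classification = classified,
    intergenic_windows = intergenic,
    counts = counts,
    tmm_factors = factors,
    tracks = tracks,
    fits = round_num(fits),
    sgrna_report = if (!is.null(sgrna)) sgrna$report
  )
  outputs <- outputs[!vapply(outputs, is.null, logical(1))]
  paths <- character()
  for (nm in names(outputs)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_plain(as.data.frame(outputs[[nm]]), p)
    paths[nm] <- p
  }
  if (!is.null(comparison)) {
    p <- file.path(out_dir, "mark_comparison.tsv")
    write_tsv_plain(tibble::tibble(
      n = comparison$n, statistic = comparison$statistic,
      p_value = signif(comparison$p_value, 10),
      median_diff = signif(comparison$median_diff, 10)), p)
    paths["mark_comparison"] <- p
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  paths["config"] <- cfg_path

  manifest <- tibble::tibble(
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths)))
  )
  write_tsv_plain(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(genome = genome, fragments = frags, counts = counts,
                 factors = factors, tracks = tracks, fits = fits,
                 comparison = comparison, annotation = ann,
                 classified = classified, intergenic = intergenic,
                 sgrna = sgrna, manifest = manifest,
                 h3k27me3_threshold_used = thr))
}

# round floats for byte-stable TSV output of fitted quantities
round_num <- function(df, digits = 10) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ signif(.x, digits)))
}

serialize_config <- function(config) {
  list(
    seed = config$seed,
    min_copies = config$min_copies,
    min_specificity = config$min_specificity,
    max_span = config$max_span,
    tpm_cutoff = config$tpm_cutoff,
    h3k27me3_threshold = config$h3k27me3_threshold,
    alpha = config$alpha,
    run_sgrna = config$run_sgrna,
    run_imaging = config$run_imaging,
    sim = list(
      seed = config$sim$seed,
      chromosomes = as.list(stats::setNames(config$sim$chromosomes$length,
                                            config$sim$chromosomes$chrom)),
      induced_chrom = config$sim$induced_chrom,
      n_snps_per_kb = config$sim$n_snps_per_kb,
      timepoints = config$sim$timepoints,
      marks = config$sim$marks,
      n_reps = config$sim$n_reps,
      window_width = config$sim$window_width,
      dispersion = config$sim$dispersion,
      fragment_length = config$sim$fragment_length,
      autosome_depth = config$sim$autosome_depth,
      base_error_rate = config$sim$base_error_rate
    )
  )
}
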