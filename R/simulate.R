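#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the inducible-Xist hybrid ESC time-course design the
#' package analyses: a DOX time course sampled at 0, 4, 8, 12 and 24 h in
#' biological duplicate, two histone marks whose induced (B6) allele
#' follows a steep four-parameter log-logistic accumulation, a SNP rate of
#' 2 per kb between the two haplotypes, and negative-binomial count noise
#' with dispersion 0.02.
#'
#' @param seed Integer RNG seed; all generator randomness flows from it.
#' @param chromosomes Tibble `chrom`, `length` (bp). Default: two 60-kb
#'   autosomes and a 200-kb X surrogate `"cX"`.
#' @param induced_chrom Chromosome carrying the inducible Xist allele.
#' @param n_snps_per_kb Expected SNPs per kb between haplotypes.
#' @param timepoints Hours; strictly increasing, must contain 0 and 24.
#' @param marks Character vector of mark names.
#' @param n_reps Biological replicates per (mark, timepoint).
#' @param window_width Analysis window width (bp).
#' @param windows_truth Optional tibble `mark`, `chrom`, `start`, `end`,
#'   `b`, `c`, `d`, `e` of true LL.4 parameters for the induced allele;
#'   default built by [default_windows_truth()].
#' @param dispersion Negative-binomial dispersion of window counts
#'   (0 = Poisson).
#' @param fragment_length Fragment length in bp (single length; the
#'   dinucleosome-scale size selection is approximated by one value).
#' @param autosome_depth Expected fragments per allele per autosomal
#'   window (time-constant).
#' @param base_error_rate Per-observed-SNP sequencing error rate (errors
#'   produce a third base, i.e. uninformative observations).
#' @param repeat_plants Tibble `chrom`, `start` (NA = placed
#'   deterministically), `unit` (22/23-nt, ending `"GG"`), `n_copies`
#'   (tandem), `n_off` (scattered single copies on other chromosomes).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = tibble::tibble(
                         chrom = c("chr1", "chr2", "cX"),
                         length = c(60000L, 60000L, 200000L)),
                       induced_chrom = "cX",
                       n_snps_per_kb = 2,
                       timepoints = c(0, 4, 8, 12, 24),
                       marks = c("H4K20me1", "H3K27me3"),
                       n_reps = 2L,
                       window_width = 10000L,
                       windows_truth = NULL,
                       dispersion = 0.02,
                       fragment_length = 150L,
                       autosome_depth = 100,
                       base_error_rate = 0,
                       repeat_plants = default_repeat_plants()) {
  if (any(chromosomes$length <= 0)) abort_field("sim_config: chromosome lengths must be > 0")
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort_field("sim_config: timepoints must be strictly increasing")
  }
  if (!0 %in% timepoints || !24 %in% timepoints) {
    abort_field("sim_config: timepoints must include 0 and 24")
  }
  if (!induced_chrom %in% chromosomes$chrom) {
    abort_field("sim_config: induced chromosome '%s' not in chromosome table",
                induced_chrom)
  }
  if (!is.null(repeat_plants) && nrow(repeat_plants) > 0) {
    klen <- nchar(repeat_plants$unit)
    if (any(!klen %in% c(22L, 23L)) || any(!endsWith(repeat_plants$unit, "GG"))) {
      abort_field("sim_config: repeat units must be 22 or 23 nt and end in 'GG'")
    }
  }
  if (dispersion < 0) abort_field("sim_config: dispersion must be >= 0")
  cfg <- list(seed = as.integer(seed), chromosomes = chromosomes,
              induced_chrom = induced_chrom, n_snps_per_kb = n_snps_per_kb,
              timepoints = timepoints, marks = marks,
              n_reps = as.integer(n_reps),
              window_width = as.integer(window_width),
              dispersion = dispersion,
              fragment_length = as.integer(fragment_length),
              autosome_depth = autosome_depth,
              base_error_rate = base_error_rate,
              repeat_plants = repeat_plants)
  cfg$windows_truth <- windows_truth %||% default_windows_truth(cfg)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: seed", x$seed, "|",
      nrow(x$chromosomes), "chromosomes |",
      length(x$marks), "marks x", length(x$timepoints), "timepoints x",
      x$n_reps, "reps\n")
  invisible(x)
}

#' Default per-window accumulation truth
#'
#' Builds the true LL.4 parameter table for the induced chromosome: a
#' steep accumulation (slope -4) from a baseline of 50 to a plateau of 150
#' expected fragments, with the inflection dose `e` increasing linearly
#' with distance from the chromosome midpoint (the Xist locus surrogate)
#' from 4 h proximally to 16 h distally — a spreading-gradient toy. The
#' second mark (when present) is delayed by 2 h at every window, mirroring
#' the earlier inflection of H4K20me1 relative to H3K27me3.
#'
#' @param config A partially built `sim_config` list.
#' @return Tibble `mark`, `chrom`, `start`, `end`, `b`, `c`, `d`, `e`.
#' @export
default_windows_truth <- function(config) {
  len <- config$chromosomes$length[config$chromosomes$chrom ==
                                     config$induced_chrom]
  tiles <- tile_genome(tibble::tibble(chrom = config$induced_chrom,
                                      size = len),
                       width = config$window_width)
  centre <- len / 2
  dist_frac <- abs((tiles$start + tiles$end) / 2 - centre) / centre
  purrr::imap_dfr(stats::setNames(seq_along(config$marks), config$marks),
                  function(i, mark) {
    tibble::tibble(mark = mark, chrom = tiles$chrom, start = tiles$start,
                   end = tiles$end, b = -4, c = 50, d = 150,
                   e = 4 + 12 * dist_frac + 2 * (i - 1))
  })
}

#' Default planted repeats
#'
#' One genuine chromosome-specific microsatellite (30 tandem copies of a
#' 23-mer on the X surrogate, no off-chromosome copies) — the recoverable
#' target.
#' @export
default_repeat_plants <- function() {
  tibble::tibble(chrom = "cX", start = NA_integer_,
                 unit = "ATGCATTGACCTGAGTCAATAGG", n_copies = 30L,
                 n_off = 0L)
}

#' Simulate the diploid toy genome
#'
#' Generates one random sequence per chromosome (haplotype 1, the B6
#' surrogate), plants the configured microsatellite repeats (tandem target
#' blocks plus scattered off-chromosome copies), then draws SNP positions
#' outside the repeat footprints — so a planted repeat can never overlap a
#' SNP — and substitutes the alternative base on haplotype 2 (Cast). The
#' two haplotypes differ only at SNP positions.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_genome`: list with `hap1`, `hap2` (named
#'   character vectors), `snps` (tibble `chrom`, `pos` 1-based, `allele1`,
#'   `allele2`), `repeats` (truth tibble `chrom`, `start`, `end`, `unit`,
#'   `n_copies`, `role` = target/off), and the `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  hap1 <- stats::setNames(
    vapply(config$chromosomes$length, function(L) {
      paste(sample(bases, L, replace = TRUE), collapse = "")
    }, character(1)),
    config$chromosomes$chrom
  )

  rep_truth <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), unit = character(),
                              n_copies = integer(), role = character())
  plants <- config$repeat_plants
  if (!is.null(plants) && nrow(plants) > 0) {
    for (i in seq_len(nrow(plants))) {
      p <- plants[i, ]
      L <- config$chromosomes$length[config$chromosomes$chrom == p$chrom]
      block <- strrep(p$unit, p$n_copies)
      if (nchar(block) > L) abort_field("simulate_genome: repeat block exceeds chromosome '%s'", p$chrom)
      start <- p$start
      if (is.na(start)) start <- as.integer((L - nchar(block)) %/% 2)
      substr(hap1[[p$chrom]], start + 1, start + nchar(block)) <- block
      rep_truth <- dplyr::bind_rows(rep_truth, tibble::tibble(
        chrom = p$chrom, start = as.integer(start),
        end = as.integer(start + nchar(block)), unit = p$unit,
        n_copies = p$n_copies, role = "target"))
      if (p$n_off > 0) {
        others <- setdiff(config$chromosomes$chrom, p$chrom)
        if (length(others) == 0) abort_field("simulate_genome: off-chromosome copies requested but only one chromosome")
        for (j in seq_len(p$n_off)) {
          oc <- others[(j - 1) %% length(others) + 1]
          Lo <- config$chromosomes$length[config$chromosomes$chrom == oc]
          # spread single copies deterministically along the chromosome
          pos <- as.integer((j * Lo) %/% (p$n_off + 1))
          pos <- min(pos, Lo - nchar(p$unit))
          substr(hap1[[oc]], pos + 1, pos + nchar(p$unit)) <- p$unit
          rep_truth <- dplyr::bind_rows(rep_truth, tibble::tibble(
            chrom = oc, start = pos, end = pos + nchar(p$unit),
            unit = p$unit, n_copies = 1L, role = "off"))
        }
      }
    }
  }

  snps <- purrr::pmap_dfr(config$chromosomes, function(chrom, length, ...) {
    n_snp <- round(length / 1000 * config$n_snps_per_kb)
    if (n_snp == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            allele1 = character(), allele2 = character()))
    }
    forbid <- rep(FALSE, length)
    rt <- rep_truth[rep_truth$chrom == chrom, ]
    for (k in seq_len(nrow(rt))) forbid[(rt$start[k] + 1):rt$end[k]] <- TRUE
    avail <- which(!forbid)
    pos <- sort(sample(avail, min(n_snp, length(avail))))
    a1 <- substring(hap1[[chrom]], pos, pos)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), character(1),
                 USE.NAMES = FALSE)
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   allele1 = a1, allele2 = a2)
  })

  hap2 <- hap1
  for (chrom in unique(snps$chrom)) {
    s <- snps[snps$chrom == chrom, ]
    seqc <- strsplit(hap2[[chrom]], "", fixed = TRUE)[[1]]
    seqc[s$pos] <- s$allele2
    hap2[[chrom]] <- paste(seqc, collapse = "")
  }

  structure(list(hap1 = hap1, hap2 = hap2, snps = snps,
                 repeats = rep_truth, config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("Synthetic diploid genome:", length(x$hap1), "chromosomes,",
      nrow(x$snps), "SNPs,", nrow(x$repeats), "planted repeat blocks\n")
  invisible(x)
}

#' Simulate allele-tagged fragments for the ChIP time course
#'
#' For every sample (mark x timepoint x replicate) and every analysis
#' window, the expected induced-allele (B6) fragment count follows the
#' configured LL.4 truth on the induced chromosome, the Cast allele stays
#' at the baseline `c`, and autosomal windows are time-constant at
#' `autosome_depth` for both alleles. Counts are drawn negative-binomially
#' (Poisson at dispersion 0), fragment positions uniformly within the
#' window, and each fragment records the bases it observes at the SNPs it
#' covers, read from its true haplotype (with optional sequencing error to
#' a third base).
#'
#' @param config A [sim_config()].
#' @param genome A [simulate_genome()] result.
#' @return List of class `sim_fragments`: `fragments` (tibble `chrom`,
#'   `start`, `end`, `sample_id`, `snp_bases`, `true_allele`), `samples`
#'   (sample sheet), `windows` (the tiling used), `truth` (the LL.4 truth
#'   table).
#' @export
simulate_fragments <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "sim_genome"))
  set.seed(config$seed + 1L)
  samples <- tidyr::expand_grid(mark = config$marks,
                                timepoint = config$timepoints,
                                replicate = seq_len(config$n_reps)) |>
    dplyr::mutate(sample_id = paste(.data$mark, .data$timepoint,
                                    .data$replicate, sep = "_")) |>
    dplyr::select("sample_id", "mark", "timepoint", "replicate")

  tiles <- tile_genome(stats::setNames(config$chromosomes$length,
                                       config$chromosomes$chrom),
                       width = config$window_width)
  truth <- config$windows_truth

  # Expected counts per (window, sample, allele)
  grid <- tidyr::expand_grid(samples, tiles) |>
    dplyr::left_join(truth, by = c("mark", "chrom", "start", "end"))
  on_x <- grid$chrom == config$induced_chrom
  grid$mu_B6 <- ifelse(on_x, NA_real_, config$autosome_depth)
  grid$mu_Cast <- ifelse(on_x, NA_real_, config$autosome_depth)
  if (any(on_x)) {
    if (anyNA(grid$e[on_x])) {
      abort_field("simulate_fragments: windows_truth does not cover every window on '%s'",
                  config$induced_chrom)
    }
    xg <- grid[on_x, ]
    grid$mu_B6[on_x] <- mapply(function(t, b, c, d, e) ll4(t, b, c, d, e),
                               xg$timepoint, xg$b, xg$c, xg$d, xg$e)
    grid$mu_Cast[on_x] <- xg$c
  }

  draw <- function(mu) {
    if (config$dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  grid$n_B6 <- draw(grid$mu_B6)
  grid$n_Cast <- draw(grid$mu_Cast)

  long <- grid |>
    dplyr::select("window", "chrom", "start", "end", "sample_id",
                  "n_B6", "n_Cast") |>
    tidyr::pivot_longer(c("n_B6", "n_Cast"), names_to = "true_allele",
                        values_to = "n", names_prefix = "n_")
  long <- long[long$n > 0, ]

  idx <- rep.int(seq_len(nrow(long)), long$n)
  fl <- config$fragment_length
  win_start <- long$start[idx]
  win_end <- long$end[idx]
  fstart <- win_start + floor(stats::runif(length(idx)) *
                                pmax(win_end - win_start - fl, 1))
  fragments <- tibble::tibble(
    chrom = long$chrom[idx],
    start = as.integer(fstart),
    end = as.integer(fstart + fl),
    sample_id = long$sample_id[idx],
    true_allele = long$true_allele[idx]
  )
  fragments <- fragments[order(fragments$chrom, fragments$start,
                               fragments$sample_id), ]
  fragments$snp_bases <- observed_snp_bases(fragments, genome,
                                            config$base_error_rate)
  structure(list(fragments = fragments, samples = samples, windows = tiles,
                 truth = truth),
            class = "sim_fragments")
}

# Bases each fragment observes at the SNPs it covers, from its true
# haplotype; errors flip to a third base (uninformative downstream).
observed_snp_bases <- function(fragments, genome, base_error_rate = 0) {
  snps <- genome$snps
  out <- rep("", nrow(fragments))
  bases <- c("A", "C", "G", "T")
  for (chrom in unique(fragments$chrom)) {
    fi <- which(fragments$chrom == chrom)
    s <- snps[snps$chrom == chrom, ]
    if (nrow(s) == 0) next
    fr <- IRanges::IRanges(fragments$start[fi] + 1L, fragments$end[fi])
    sp <- IRanges::IRanges(s$pos, s$pos)
    hits <- IRanges::findOverlaps(fr, sp)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
    base <- ifelse(fragments$true_allele[fi][q] == "B6",
                   s$allele1[sj], s$allele2[sj])
    if (base_error_rate > 0) {
      err <- stats::runif(length(base)) < base_error_rate
      if (any(err)) {
        base[err] <- vapply(base[err], function(b) {
          sample(setdiff(bases, b), 1)
        }, character(1), USE.NAMES = FALSE)
      }
    }
    pair <- paste0(s$pos[sj], ":", base)
    agg <- tapply(pair, q, paste, collapse = ";")
    out[fi[as.integer(names(agg))]] <- unname(agg)
  }
  out
}

#' Simulate replicated accumulation count tracks (fragment-free path)
#'
#' Draws per-window, per-timepoint, per-replicate counts directly from the
#' LL.4 truth with negative-binomial noise — the fast generator used for
#' fitting and mark-comparison studies where fragment-level detail is not
#' needed.
#'
#' @param n_windows Number of windows.
#' @param e_true True inflection doses (recycled over windows).
#' @param timepoints Hours.
#' @param b,c,d Remaining LL.4 truth (defaults: the generator's standard
#'   steep curve).
#' @param dispersion NB dispersion (default 0.02).
#' @param n_reps Replicates (default 2).
#' @return List with `tracks` (tibble `window`, `timepoint`, `replicate`,
#'   `value`) and `truth` (tibble `window`, `e`).
#' @export
simulate_tracks <- function(n_windows, e_true, timepoints = c(0, 4, 8, 12, 24),
                            b = -4, c = 50, d = 150, dispersion = 0.02,
                            n_reps = 2) {
  e_vec <- rep_len(e_true, n_windows)
  grid <- tidyr::expand_grid(window = seq_len(n_windows),
                             timepoint = timepoints,
                             replicate = seq_len(n_reps))
  mu <- ll4_by_e(grid$timepoint, b, c, d, e_vec[grid$window])
  grid$value <- if (dispersion == 0) stats::rpois(nrow(grid), mu)
  else stats::rnbinom(nrow(grid), mu = mu, size = 1 / dispersion)
  list(tracks = grid,
       truth = tibble::tibble(window = seq_len(n_windows), e = e_vec))
}

# vectorized ll4 over per-element e
ll4_by_e <- function(t, b, c, d, e) {
  g <- 1 / (1 + exp(b * (log(pmax(t, .Machine$double.xmin)) - log(e))))
  g[t == 0] <- if (b < 0) 0 else if (b > 0) 1 else 0.5
  c + (d - c) * g
}

#' Simulate the gene/peak/expression annotation layer
#'
#' Lays out genes of known truth category along a chromosome and emits the
#' evidence the window-annotation module consumes: two jittered replicate
#' peak sets per promoter mark (H3K9ac, H3K4me3) covering the TSSs of
#' marked genes, t0 expression (two TPM samples), an H3K27me3 premarking
#' signal drawn from a low-mode distribution for active genes and a
#' high-mode one for inactive genes, and a handful of enhancer intervals.
#'
#' @param n_genes Number of genes (default 60).
#' @param chrom Chromosome name (default `"cX"`).
#' @param chrom_len Length; genes are spaced evenly (default 10 kb
#'   spacing).
#' @param seed RNG seed.
#' @return List of class `sim_annotation`: `transcripts`, `peaks` (nested
#'   list `k9ac`/`k4me3` each with two replicate tibbles), `tpm`,
#'   `h3k27me3_t0`, `enhancers`, `truth` (tibble `gene_id`,
#'   `category`).
#' @export
simulate_annotation <- function(n_genes = 60, chrom = "cX",
                                chrom_len = NULL, seed = 1L) {
  set.seed(seed)
  spacing <- 10000L
  chrom_len <- chrom_len %||% ((n_genes + 2L) * spacing)
  n_genes <- min(n_genes, chrom_len %/% spacing - 2L)
  if (n_genes < 1) abort_field("simulate_annotation: chromosome too short for any gene")
  cats <- rep(c("initially_active", "silent", "bivalent", "tpm_excluded",
                "single_mark", "expressed_without_marks"),
              length.out = n_genes)
  gene_start <- (seq_len(n_genes)) * spacing
  strand <- rep(c("+", "-"), length.out = n_genes)
  gene_len <- 4000L

  transcripts <- purrr::map_dfr(seq_len(n_genes), function(i) {
    # two transcripts per gene; the second starts 500 bp in, so the gene
    # extent is still the union and at least one TSS sits at the 5' end
    tibble::tibble(
      gene_id = sprintf("g%03d", i),
      transcript_id = sprintf("g%03d.t%d", i, 1:2),
      chrom = chrom, strand = strand[i],
      start = c(gene_start[i], gene_start[i] + 500L),
      end = gene_start[i] + gene_len
    )
  })
  # TSS of the gene (5' end of the merged extent)
  gene_tss <- ifelse(strand == "+", gene_start, gene_start + gene_len - 1L)

  has_peaks <- cats %in% c("initially_active", "bivalent", "tpm_excluded")
  k9_only <- cats == "single_mark"
  peak_rep <- function(tss_sel, jitter) {
    tibble::tibble(chrom = chrom,
                   start = pmax(tss_sel - 300L + jitter, 0L),
                   end = tss_sel + 300L + jitter)
  }
  peaks <- list(
    k9ac = list(peak_rep(gene_tss[has_peaks | k9_only], -37L),
                peak_rep(gene_tss[has_peaks | k9_only], 52L)),
    k4me3 = list(peak_rep(gene_tss[has_peaks], 21L),
                 peak_rep(gene_tss[has_peaks], -44L))
  )

  tpm_mean <- dplyr::case_when(
    cats %in% c("initially_active", "bivalent") ~ stats::runif(n_genes, 5, 50),
    cats == "expressed_without_marks" ~ stats::runif(n_genes, 2, 20),
    TRUE ~ stats::runif(n_genes, 0, 0.5)
  )
  tpm <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes)),
                        tpm_1 = tpm_mean * stats::runif(n_genes, 0.9, 1.1),
                        tpm_2 = tpm_mean * stats::runif(n_genes, 0.9, 1.1))

  k27 <- ifelse(cats == "bivalent",
                stats::rnorm(n_genes, 0.10, 0.02),
                abs(stats::rnorm(n_genes, 0.010, 0.003)))
  h3k27me3_t0 <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes)),
                                signal = k27)

  enhancers <- tibble::tibble(
    chrom = chrom,
    start = as.integer(c(0.25, 0.75) * chrom_len),
    end = as.integer(c(0.25, 0.75) * chrom_len) + 800L
  )

  # expected categories after classification (bivalent / tpm_excluded /
  # single_mark / expressed_without_marks are all "excluded")
  truth <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    category = dplyr::case_when(
      cats == "initially_active" ~ "initially_active",
      cats == "silent" ~ "silent",
      TRUE ~ "excluded"
    ),
    design = cats
  )
  structure(list(transcripts = transcripts, peaks = peaks, tpm = tpm,
                 h3k27me3_t0 = h3k27me3_t0, enhancers = enhancers,
                 truth = truth, chrom = chrom, chrom_len = chrom_len),
            class = "sim_annotation")
}

#' Simulate a two-channel Xist/mintbody movie
#'
#' The Xist channel shows a disk-shaped domain appearing at `onset_frame`
#' and persisting; the mintbody channel has a uniform nuclear background
#' plus, from `onset_frame + delay_frames`, added intensity inside the
#' domain ramping over `ramp_frames` frames to a plateau enrichment ratio
#' of `amplitude` (in-domain mean over background). The default 3-frame
#' delay at 15 min/frame encodes a 45-min enrichment lag. Gaussian pixel
#' noise with `noise_sd` is added to both channels.
#'
#' @param onset_frame Frame (1-based) at which the Xist domain appears.
#' @param delay_frames Frames between Xist onset and mintbody enrichment.
#' @param amplitude Plateau enrichment ratio (> 0; 1 = no enrichment).
#' @param frames Total frames; must exceed `onset_frame + delay_frames`.
#' @param noise_sd Pixel noise SD (intensity units).
#' @param dim Frame dimensions `c(Y, X)`.
#' @param background Background intensity (default 100).
#' @param disk_radius Domain radius in pixels.
#' @param xist_intensity Domain intensity in the Xist channel.
#' @param ramp_frames Frames over which enrichment ramps to plateau
#'   (first enriched frame carries 1/ramp_frames of the full effect).
#' @param frame_interval Minutes per frame (truth bookkeeping only).
#' @return List of class `sim_movie`: `xist`, `mintbody` (arrays
#'   `(frames, Y, X)`), `truth` (list with `onset_frame`, `delay_frames`,
#'   `delay_min`, `amplitude`, `center`, `radius`).
#' @export
simulate_movie <- function(onset_frame, delay_frames, amplitude,
                           frames, noise_sd, dim = c(48L, 48L),
                           background = 100, disk_radius = 7,
                           xist_intensity = 6 * background,
                           ramp_frames = 4L, frame_interval = 15) {
  if (amplitude <= 0) abort_field("simulate_movie: amplitude must be > 0")
  if (onset_frame + delay_frames >= frames) {
    abort_field("simulate_movie: onset_frame + delay_frames must be < frames")
  }
  ny <- dim[1]; nx <- dim[2]
  cy <- ny / 2 + 0.5; cx <- nx / 2 + 0.5
  dy <- matrix(rep(seq_len(ny), nx), ny, nx) - cy
  dx <- matrix(rep(seq_len(nx), each = ny), ny, nx) - cx
  disk <- (dy^2 + dx^2) <= disk_radius^2

  xist <- array(background, c(frames, ny, nx))
  mint <- array(background, c(frames, ny, nx))
  for (f in seq_len(frames)) {
    if (f >= onset_frame) xist[f, , ][disk] <- xist_intensity
    enrich_start <- onset_frame + delay_frames
    if (f >= enrich_start) {
      ramp <- min(1, (f - enrich_start + 1) / ramp_frames)
      mint[f, , ][disk] <- background + ramp * (amplitude - 1) * background
    }
  }
  if (noise_sd > 0) {
    xist <- xist + array(stats::rnorm(length(xist), 0, noise_sd), base::dim(xist))
    mint <- mint + array(stats::rnorm(length(mint), 0, noise_sd), base::dim(mint))
  }
  structure(list(
    xist = xist, mintbody = mint,
    truth = list(onset_frame = onset_frame, delay_frames = delay_frames,
                 delay_min = delay_frames * frame_interval,
                 amplitude = amplitude, center = c(cy, cx),
                 radius = disk_radius)
  ), class = "sim_movie")
}

#' Write the simulated genome / tables to disk
#'
#' FASTA via Biostrings (haplotype 1 is the reference emitted for the
#' sgRNA search; haplotype 2 optionally alongside), TSVs via write.table
#' with fixed settings so outputs are byte-stable.
#'
#' @param genome A `sim_genome`.
#' @param path FASTA path.
#' @param haplotype 1 or 2.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path, haplotype = 1) {
  seqs <- if (haplotype == 1) genome$hap1 else genome$hap2
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param x Any tibble.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA into the named-character form used internally
#' @param path FASTA path.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dss), sub("\\s.*", "", names(dss)))
}
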