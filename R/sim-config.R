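#' Configuration for the synthetic genome generator
#'
#' The generator lays out a toy genome on fixed-width gene slots (2700 bp),
#' each holding one gene with its +1 nucleosome dyad, a promoter
#' nucleosome-depleted region (NDR), and flanking intergenic background, plus
#' a circular mitochondrial chromosome (and optionally a 2-micron plasmid)
#' carrying non-nucleosomal control sites. Methylation target sites (GATC or
#' CG) are placed at jittered intervals; every site carries a known
#' ground-truth first-order methylation rate derived from a decaying sine
#' wave phasing landscape, so downstream estimates can be checked exactly.
#'
#' @param n_genes number of protein-coding genes.
#' @param n_trna number of tRNA genes (with TFIIIB/TFIIIC/intron subregions).
#' @param n_chrom number of nuclear chromosomes to spread genes over.
#' @param chrom_lengths optional named vector of nuclear chromosome lengths
#'   (bp); when `NULL`, lengths are sized to fit the requested genes.
#' @param mt_length length of the circular mitochondrial chromosome (85.8 kb
#'   by default, matching yeast mtDNA).
#' @param plasmid_included,plasmid_length include a small circular plasmid
#'   chromosome methylated at the control rate.
#' @param motif methylation target motif: `"GATC"` (Dam) or `"CG"` (M.SssI).
#' @param mean_site_interval mean spacing between consecutive sites (bp);
#'   ~256 bp emulates the genomic GATC density, ~16 bp the CG density.
#' @param timepoints induction time course, minutes after SM addition;
#'   strictly increasing, all `>= 0`.
#' @param coverage mean molecules per site per timepoint (binomial noise).
#' @param noise `"none"` for exact first-order fractions, `"binomial"` for
#'   sampled fractions at the given coverage.
#' @param seed integer seed; identical config + seed gives identical output.
#' @param truth_params [sine_params()] generating landscape for gene bodies
#'   (normalized rate-ratio units; multiplied by `mt_rate`). Default: the
#'   wild-type phasing landscape (spacing 166.3 bp, amplitude 0.39, decay
#'   0.86/period, slope -0.12/kb, curve mean 0.80).
#' @param alt_truth_params optional second landscape assigned to a random
#'   fraction `alt_gene_frac` of coding genes (two-population genomes).
#' @param alt_gene_frac fraction of coding genes drawing from
#'   `alt_truth_params`.
#' @param mt_rate absolute first-order rate (per minute) of mtDNA control
#'   sites; also the unit of the normalized landscape.
#' @param ndr_rate_factor rate multiplier for promoter-NDR sites (`>= 1`);
#'   1.3 emulates NDR sites methylating ~1.3x faster than mtDNA.
#' @param ndr_window promoter NDR window in bp relative to the +1 dyad.
#' @param trna_rate_factors named multipliers (`tfiiib`, `tfiiic`, `intron`)
#'   of `mt_rate` for tRNA subregions; defaults encode TFIIIC ~1.5x and
#'   introns ~2x the TFIIIB rate.
#' @param trna_intron_frac fraction of tRNA genes carrying a single intron.
#' @param f0 pre-induction background methylated fraction (default 0).
#' @param fragment_min_length fragments shorter than this are prone to loss
#'   during library preparation (200 bp).
#' @param fragment_loss_prob probability that a sub-minimum fragment is lost.
#' @param fragment_trim_prob probability that a cut end loses its terminal
#'   base (the 'A' or 'T' of the blunt cut).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_trna = 12L, n_chrom = 4L,
                       chrom_lengths = NULL,
                       mt_length = 85800L,
                       plasmid_included = FALSE, plasmid_length = 6300L,
                       motif = c("GATC", "CG"),
                       mean_site_interval = 256,
                       timepoints = c(30, 60, 120, 240),
                       coverage = 100,
                       noise = c("none", "binomial"),
                       seed = 1L,
                       truth_params = NULL,
                       alt_truth_params = NULL, alt_gene_frac = 0,
                       mt_rate = 0.005,
                       ndr_rate_factor = 1.3,
                       ndr_window = c(-180L, -80L),
                       trna_rate_factors = c(tfiiib = 0.9, tfiiic = 1.35,
                                             intron = 1.8),
                       trna_intron_frac = 0.25,
                       f0 = 0,
                       fragment_min_length = 200L,
                       fragment_loss_prob = 0.8,
                       fragment_trim_prob = 0.1) {
  motif <- match.arg(motif)
  noise <- match.arg(noise)
  if (is.null(truth_params))
    truth_params <- params_from_descriptors(
      spacing_bp = 166.3, amplitude = 0.39, decay_per_period = 0.86,
      slope_per_kb = -0.12, adj_mean = 0.80)
  stopifnot(inherits(truth_params, "sine_params"))
  if (!is.null(alt_truth_params))
    stopifnot(inherits(alt_truth_params, "sine_params"))
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (mean_site_interval <= 0 || mt_length <= 0 || coverage <= 0)
    stop("lengths, intervals and coverage must all be > 0")
  if (any(timepoints < 0) || any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing and >= 0")
  if (mt_rate <= 0) stop("mt_rate must be > 0")
  if (ndr_rate_factor < 1) stop("ndr_rate_factor must be >= 1")
  if (noise == "binomial" && coverage < 1)
    stop("binomial noise requires coverage >= 1")
  if (alt_gene_frac < 0 || alt_gene_frac > 1)
    stop("alt_gene_frac must be in [0, 1]")
  if (alt_gene_frac > 0 && is.null(alt_truth_params))
    stop("alt_gene_frac > 0 requires alt_truth_params")
  if (f0 < 0 || f0 >= 1) stop("f0 must be in [0, 1)")
  if (fragment_min_length <= 0) stop("fragment_min_length must be > 0")

  slot_bp <- 2700L
  n_slots <- as.integer(n_genes + n_trna)
  if (is.null(chrom_lengths)) {
    per_chrom <- ceiling(n_slots / n_chrom)
    chrom_lengths <- rep(per_chrom * slot_bp, n_chrom)
    names(chrom_lengths) <- paste0("chr", utils::as.roman(seq_len(n_chrom)))
  } else {
    if (is.null(names(chrom_lengths)))
      names(chrom_lengths) <- paste0("chr",
                                     utils::as.roman(seq_along(chrom_lengths)))
    if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
    capacity <- sum(chrom_lengths %/% slot_bp)
    if (capacity < n_slots)
      stop(sprintf(
        "chromosomes too short: %d gene slots of %d bp needed, %d fit",
        n_slots, slot_bp, capacity))
  }

  structure(list(
    n_genes = as.integer(n_genes), n_trna = as.integer(n_trna),
    chrom_lengths = chrom_lengths, slot_bp = slot_bp,
    mt_length = as.integer(mt_length),
    plasmid_included = isTRUE(plasmid_included),
    plasmid_length = as.integer(plasmid_length),
    motif = motif, mean_site_interval = mean_site_interval,
    timepoints = as.numeric(timepoints), coverage = coverage, noise = noise,
    seed = as.integer(seed),
    truth_params = truth_params,
    alt_truth_params = alt_truth_params, alt_gene_frac = alt_gene_frac,
    mt_rate = mt_rate, ndr_rate_factor = ndr_rate_factor,
    ndr_window = as.integer(ndr_window),
    trna_rate_factors = trna_rate_factors,
    trna_intron_frac = trna_intron_frac,
    f0 = f0,
    fragment_min_length = as.integer(fragment_min_length),
    fragment_loss_prob = fragment_loss_prob,
    fragment_trim_prob = fragment_trim_prob
  ), class = "sim_config")
}
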