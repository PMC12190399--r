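#' Generate a synthetic genome with a known methylation-rate landscape
#'
#' Lays out coding genes (one per 2700-bp slot, both strands, +1 dyad
#' jittered around the slot center), a set of tRNA genes with
#' TFIIIB/TFIIIC/intron subregions, a circular mitochondrial chromosome and
#' optionally a plasmid; places methylation target sites at jittered
#' intervals; labels every site with exactly one region class; and attaches
#' ground-truth per-minute methylation rates from the configured decaying
#' sine wave landscape (see [truth_rates()]).
#'
#' Region classes: `mt`, `plasmid`, `promoter_NDR` (NDR window upstream of
#' the +1 dyad), `gene_body` (dyad-relative offsets in (-80, +1000]),
#' `tRNA_TFIIIB`, `tRNA_TFIIIC`, `tRNA_intron`, `tRNA_flank` (+/- 50 bp
#' around the tRNA locus), and `intergenic`.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `synthetic_genome` with elements `config`,
#'   `chroms` (chromosome table), `genes` (gene annotation,
#'   [read_genes()] conventions), and `sites` (one row per site with
#'   `region`, `gene_id`, dyad-relative `offset`, and `truth_rate`).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  slot_bp <- config$slot_bp

  chroms <- data.table(
    chrom = names(config$chrom_lengths),
    length = as.integer(config$chrom_lengths),
    circular = FALSE, kind = "nuclear")
  chroms <- rbind(chroms,
    data.table(chrom = "chrM", length = config$mt_length,
               circular = TRUE, kind = "mt"))
  if (config$plasmid_included)
    chroms <- rbind(chroms,
      data.table(chrom = "plasmid2micron", length = config$plasmid_length,
                 circular = TRUE, kind = "plasmid"))

  # --- gene slots -----------------------------------------------------
  nuc <- chroms[kind == "nuclear"]
  slot_tab <- nuc[, .(slot = seq_len(length %/% slot_bp)), by = .(chrom)]
  n_slots <- config$n_genes + config$n_trna
  slot_tab <- slot_tab[seq_len(n_slots)]
  slot_tab[, slot_start := (slot - 1L) * slot_bp]

  n_cod <- config$n_genes
  strands <- c(sample(rep(c("+", "-"), length.out = n_cod)),
               sample(rep(c("+", "-"), length.out = config$n_trna)))
  jitter <- sample(-20:20, n_slots, replace = TRUE)
  klass <- rep(c("coding", "tRNA"), c(n_cod, config$n_trna))

  genes <- copy(slot_tab)
  genes[, `:=`(gene_id = sprintf("g%05d", seq_len(n_slots)),
               strand = strands, klass = klass, jit = jitter)]
  genes[klass == "tRNA", gene_id := sprintf("t%05d", seq_len(.N))]

  # coding genes: dyad near the slot center, oriented so that the
  # [-1000, +1500] offset window stays inside the slot
  genes[klass == "coding",
        plus1_dyad := slot_start + ifelse(strand == "+", 1150L, 1550L) + jit]
  genes[klass == "coding" & strand == "+",
        `:=`(tss = plus1_dyad - 60L, end = plus1_dyad + 1000L)]
  genes[klass == "coding" & strand == "-",
        `:=`(tss = plus1_dyad + 60L, end = plus1_dyad - 1000L)]
  genes[, introns := ""]

  # tRNA genes: TSS near the slot center; some longer, some with an intron
  if (config$n_trna > 0L) {
    tsel <- which(genes$klass == "tRNA")
    base_len <- ifelse(runif(length(tsel)) < 0.2, 102L, 72L)
    has_intron <- runif(length(tsel)) < config$trna_intron_frac
    glen <- base_len + ifelse(has_intron, 20L, 0L)
    anchor <- genes$slot_start[tsel] + 1350L + genes$jit[tsel]
    plus <- genes$strand[tsel] == "+"
    genes$tss[tsel] <- anchor
    genes$end[tsel] <- ifelse(plus, anchor + glen, anchor - glen + 1L)
    genes$plus1_dyad[tsel] <- anchor
    intr <- character(length(tsel))
    for (i in which(has_intron)) {
      iv <- rel_to_genomic(anchor[i], genes$strand[tsel[i]], 39L, 58L)
      intr[i] <- sprintf("%d-%d", iv[1], iv[2])
    }
    genes$introns[tsel] <- intr
  }

  # two-population genomes: a random subset of coding genes draws its
  # rate landscape from alt_truth_params
  genes[, population := "main"]
  if (config$alt_gene_frac > 0) {
    n_alt <- floor(config$alt_gene_frac * n_cod)
    alt_idx <- sample(which(genes$klass == "coding"), n_alt)
    genes[alt_idx, population := "alt"]
  }
  genes[, c("jit") := NULL]
  setcolorder(genes, c("gene_id", "chrom", "strand", "tss", "plus1_dyad",
                       "end", "klass", "introns", "population",
                       "slot", "slot_start"))

  # --- site placement -------------------------------------------------
  motif_len <- nchar(config$motif)
  iv <- config$mean_site_interval
  site_list <- lapply(seq_len(nrow(chroms)), function(i) {
    L <- chroms$length[i]
    n_exp <- ceiling(L / iv * 1.4) + 10L
    gaps <- pmax(motif_len, round(runif(n_exp, 0.5, 1.5) * iv))
    pos <- round(runif(1, 0, iv)) + cumsum(gaps) - gaps[1]
    pos <- pos[pos <= L - motif_len]
    data.table(chrom = chroms$chrom[i], pos = as.integer(pos))
  })
  sites <- rbindlist(site_list)
  sites[, motif := config$motif]
  sites <- unique(sites, by = c("chrom", "pos"))
  setkey(sites, chrom, pos)

  # --- region labels and gene assignment ------------------------------
  sites[, `:=`(region = "intergenic", gene_id = NA_character_,
               offset = NA_integer_)]
  sites[chrom == "chrM", region := "mt"]
  sites[chrom == "plasmid2micron", region := "plasmid"]

  nuc_names <- nuc$chrom
  sites[chrom %in% nuc_names, slot := pos %/% slot_bp + 1L]
  cod <- genes[klass == "coding",
               .(chrom, slot, gene_id, strand, plus1_dyad)]
  sites[cod, on = c("chrom", "slot"),
        `:=`(g_id = i.gene_id, g_strand = i.strand, g_dyad = i.plus1_dyad)]
  sites[!is.na(g_id),
        offset := ifelse(g_strand == "+", pos - g_dyad, g_dyad - pos)]
  sites[!is.na(g_id) & offset >= -1000L & offset <= 1500L, gene_id := g_id]
  ndr <- config$ndr_window
  sites[!is.na(g_id) & offset >= ndr[1] & offset <= ndr[2],
        region := "promoter_NDR"]
  sites[!is.na(g_id) & offset > -80L & offset <= 1000L & region == "intergenic",
        region := "gene_body"]
  sites[, c("g_id", "g_strand", "g_dyad", "slot") := NULL]

  if (config$n_trna > 0L) {
    tg <- genes[klass == "tRNA"]
    regions <- make_trna_regions(tg)
    for (i in seq_len(nrow(tg))) {
      g <- tg[i]
      span <- gene_span(g$strand, g$tss, g$end)
      idx <- sites[chrom == g$chrom &
                     pos >= span[1] - 50L & pos < span[2] + 50L, which = TRUE]
      if (!length(idx)) next
      sites[idx, `:=`(region = "tRNA_flank", gene_id = g$gene_id,
                      offset = NA_integer_)]
      rg <- regions[gene_id == g$gene_id]
      for (j in seq_len(nrow(rg))) {
        lab <- paste0("tRNA_", rg$klass[j])
        sel <- idx[sites$pos[idx] >= rg$start[j] & sites$pos[idx] < rg$end[j]]
        if (length(sel)) sites[sel, region := lab]
      }
    }
  }

  genome <- structure(list(config = config, chroms = chroms,
                           genes = genes, sites = sites),
                      class = "synthetic_genome")
  genome$sites[, truth_rate := truth_rates(genome)]
  genome
}

# genomic half-open span of a gene locus under the package's strand
# convention (see read_genes)
gene_span <- function(strand, tss, end) {
  if (strand == "+") c(tss, end) else c(end, tss + 1L)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "synthetic genome: %d chroms (%s bp), %d genes (%d tRNA), %d %s sites\n",
    nrow(x$chroms), format(sum(x$chroms$length), big.mark = ","),
    nrow(x$genes), sum(x$genes$klass == "tRNA"), nrow(x$sites),
    x$config$motif))
  print(x$sites[, .N, by = region])
  invisible(x)
}

#' Ground-truth per-site methylation rates
#'
#' Evaluates the generating rate landscape at every site of a synthetic
#' genome. Gene-body sites get `mt_rate * f(offset)` where `f` is the
#' decaying sine wave landscape evaluated at the dyad-relative offset
#' clamped into `[-50, 1000]` (the landscape is not extrapolated outside
#' the window it describes); promoter-NDR and tRNA-flank sites get
#' `mt_rate * ndr_rate_factor`; mitochondrial, plasmid and intergenic sites
#' get `mt_rate` exactly; tRNA subregions get `mt_rate` times their
#' configured class factor.
#'
#' @param genome a `synthetic_genome`.
#' @param params,alt_params optional [sine_params()] overriding the
#'   config's landscapes (main and alt gene populations).
#' @param mt_rate,ndr_rate_factor,trna_rate_factors optional overrides.
#' @param clamp_range offset window outside which the landscape is clamped.
#' @param floor_frac lower floor for rates, as a fraction of `mt_rate`.
#' @return numeric vector of per-minute rates, aligned with `genome$sites`.
#' @export
truth_rates <- function(genome, params = NULL, alt_params = NULL,
                        mt_rate = NULL, ndr_rate_factor = NULL,
                        trna_rate_factors = NULL,
                        clamp_range = c(-50L, 1000L), floor_frac = 1e-4) {
  cfg <- genome$config
  params <- params %||% cfg$truth_params
  alt_params <- alt_params %||% cfg$alt_truth_params
  mt_rate <- mt_rate %||% cfg$mt_rate
  ndr_rate_factor <- ndr_rate_factor %||% cfg$ndr_rate_factor
  trna_rate_factors <- trna_rate_factors %||% cfg$trna_rate_factors

  check_positive_landscape <- function(p, label) {
    grid <- seq(clamp_range[1], clamp_range[2])
    if (min(sine_model_eval(p, grid)) <= 0)
      stop("configuration error: ", label,
           " landscape yields non-positive rates within the gene-body window")
  }
  check_positive_landscape(params, "main")
  if (!is.null(alt_params)) check_positive_landscape(alt_params, "alt")

  s <- genome$sites
  rate <- rep(mt_rate, nrow(s))
  rate[s$region %in% c("promoter_NDR", "tRNA_flank")] <-
    mt_rate * ndr_rate_factor
  rate[s$region == "tRNA_TFIIIB"] <- mt_rate * trna_rate_factors[["tfiiib"]]
  rate[s$region == "tRNA_TFIIIC"] <- mt_rate * trna_rate_factors[["tfiiic"]]
  rate[s$region == "tRNA_intron"] <- mt_rate * trna_rate_factors[["intron"]]

  gb <- which(s$region == "gene_body")
  if (length(gb)) {
    x <- pmin(pmax(s$offset[gb], clamp_range[1]), clamp_range[2])
    pop <- genome$genes$population[match(s$gene_id[gb], genome$genes$gene_id)]
    main_sel <- is.na(pop) | pop == "main"
    rate[gb[main_sel]] <- mt_rate * sine_model_eval(params, x[main_sel])
    if (any(!main_sel))
      rate[gb[!main_sel]] <- mt_rate * sine_model_eval(alt_params, x[!main_sel])
  }
  pmax(rate, mt_rate * floor_frac)
}
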