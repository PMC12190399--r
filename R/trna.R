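# map a 1-based TSS-relative coordinate (negative = upstream, +1 = first
# transcribed base; there is no 0) to the genomic 0-based base position
rel_base <- function(tss, strand, r) {
  stopifnot(all(r != 0))
  if (strand == "+") tss + r - (r > 0) else tss - r + (r > 0)
}

# 1-based inclusive relative interval [r1, r2] -> genomic 0-based half-open
rel_to_genomic <- function(tss, strand, r1, r2) {
  g1 <- rel_base(tss, strand, r1)
  g2 <- rel_base(tss, strand, r2)
  c(min(g1, g2), max(g1, g2) + 1L)
}

#' TFIIIB/TFIIIC/intron regions of tRNA genes
#'
#' The Pol III transcription complex protects two footprints on tRNA
#' genes: TFIIIB binds the promoter at -56 to -13 relative to the TSS
#' (TSS = +1), and TFIIIC binds from -2 to 10 bp past the gene end,
#' excluding the intron where present (the intron loops out of the
#' complex). Intervals are computed in gene orientation and projected to
#' genomic coordinates (0-based half-open); minus-strand genes are
#' mirrored.
#'
#' @param genes tRNA gene records (`gene_id`, `chrom`, `strand`, `tss`,
#'   `end`, `introns`; see [read_genes()] for the strand conventions).
#' @return data.table `(gene_id, chrom, klass, start, end)` with `klass`
#'   in `TFIIIB`, `TFIIIC`, `intron`. TFIIIB spans are always 44 bp;
#'   TFIIIC spans sum to gene length + 12 minus total intron length.
#' @export
make_trna_regions <- function(genes) {
  genes <- as.data.table(genes)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    L <- if (g$strand == "+") g$end - g$tss else g$tss - g$end + 1L
    if (L <= 0) stop("gene ", g$gene_id, " has non-positive length")
    span <- gene_span(g$strand, g$tss, g$end)
    introns <- if (is.list(genes$introns)) genes$introns[[i]] else
      parse_intervals(g$introns)[[1]]
    if (nrow(introns) > 0L &&
        (any(introns[, 1] < span[1]) || any(introns[, 2] > span[2])))
      stop("gene ", g$gene_id, ": intron outside the gene body")
    b <- rel_to_genomic(g$tss, g$strand, -56L, -13L)
    cc <- rel_to_genomic(g$tss, g$strand, -2L, L + 10L)
    cpieces <- interval_subtract(cc[1], cc[2], introns)
    rows <- rbind(
      data.table(klass = "TFIIIB", start = b[1], end = b[2]),
      data.table(klass = "TFIIIC", start = cpieces[, 1], end = cpieces[, 2]))
    if (nrow(introns) > 0L)
      rows <- rbind(rows, data.table(klass = "intron",
                                     start = introns[, 1],
                                     end = introns[, 2]))
    rows[, `:=`(gene_id = g$gene_id, chrom = g$chrom)]
    out[[i]] <- rows
  }
  res <- rbindlist(out)
  res[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(res$start < 0)) stop("region extends past the chromosome start")
  setcolorder(res, c("gene_id", "chrom", "klass", "start", "end"))
  res[]
}

#' Methylation kinetics of tRNA transcription-factor regions
#'
#' Labels sites by the tRNA region they fall in, summarizes normalized
#' rates per class, and reports the TFIIIC/TFIIIB and intron/TFIIIB rate
#' ratios (faster methylation = more dynamic factor occupancy). When a
#' time course is supplied, the per-class median trajectories are also
#' fitted with the first-order model.
#'
#' @param norm_rates table with `chrom`, `pos`, `ratio` (and optionally
#'   `estimable`).
#' @param regions [make_trna_regions()] output.
#' @param timecourse optional [methyl_timecourse()] for median-trajectory
#'   fits.
#' @return list: `summary` (per-class n/median/quartiles), `ratios` (named:
#'   `tfiiic_over_tfiiib`, `intron_over_tfiiib`; `NA` with a warning when a
#'   class is empty), and `trajectory_fits` when a time course was given.
#' @export
trna_kinetics <- function(norm_rates, regions, timecourse = NULL) {
  nr <- as.data.table(norm_rates)
  if ("estimable" %in% names(nr)) nr <- nr[estimable == TRUE]
  nr <- nr[is.finite(ratio)]
  lab <- label_by_regions(nr, regions)
  summ <- lab[!is.na(klass),
              .(n = .N,
                q25 = quantile(ratio, 0.25, names = FALSE),
                median = median(ratio),
                q75 = quantile(ratio, 0.75, names = FALSE)),
              by = klass][order(klass)]
  med <- function(k) {
    v <- summ[klass == k, median]
    if (!length(v)) {
      warning("no sites in tRNA region class ", k, "; ratio undefined")
      return(NA_real_)
    }
    v
  }
  mb <- med("TFIIIB")
  ratios <- c(tfiiic_over_tfiiib = med("TFIIIC") / mb,
              intron_over_tfiiib = if ("intron" %in% summ$klass)
                med("intron") / mb else NA_real_)
  res <- list(summary = summ, ratios = ratios)
  if (!is.null(timecourse)) {
    tc_lab <- label_by_regions(
      as.data.table(timecourse$sites)[, .(chrom, pos)], regions)
    res$trajectory_fits <- lapply(
      setNames(nm = unique(na.omit(tc_lab$klass))), function(k) {
        sel <- which(!is.na(tc_lab$klass) & tc_lab$klass == k)
        med_traj <- apply(timecourse$fractions[sel, , drop = FALSE], 2,
                          median, na.rm = TRUE)
        fit_first_order(matrix(med_traj, nrow = 1),
                        times = timecourse$times)
      })
  }
  res
}

# first matching region label per site (regions are disjoint by
# construction; intron pieces are carved out of TFIIIC)
label_by_regions <- function(sites, regions) {
  st <- as.data.table(sites)
  rg <- as.data.table(regions)[, .(chrom, start, end, klass)]
  st[, `:=`(s2 = pos, e2 = pos)]
  setkey(rg, chrom, start, end)
  ov <- foverlaps(st, rg, by.x = c("chrom", "s2", "e2"),
                  by.y = c("chrom", "start", "end"), mult = "first")
  # foverlaps treats ranges as closed; drop matches where pos == end
  ov[!is.na(klass) & pos >= end, klass := NA_character_]
  st[, klass := ov$klass]
  st[, c("s2", "e2") := NULL]
  st[]
}

#' TSS-aligned methylation rate map across tRNA genes
#'
#' Aligns intronless tRNA genes on their TSS (offset 0 = first transcribed
#' base, negative = upstream) and reports the mean and SD of the
#' normalized rate over contributing genes at each offset. Most tRNA genes
#' are ~72 bp, so a gene covers offsets `0 .. length-1`; the `[+72, +99]`
#' band comes only from genes long enough to cover it and is masked when
#' fewer than `min_genes_per_offset` genes contribute (the alignment
#' discontinuity). Offsets `>= +100` switch to a downstream frame anchored
#' at each gene's end (`position = gene end + offset - nominal_len`), so
#' the downstream flank lines up across genes of different lengths.
#'
#' @param norm_rates table with `chrom`, `pos`, `ratio`.
#' @param genes intronless tRNA gene records.
#' @param offsets plot window in aligned coordinates, default
#'   `c(-120, 200)`.
#' @param min_genes_per_offset mask threshold in the discontinuity band.
#' @param nominal_len nominal tRNA gene length (72 bp).
#' @return data.table `(offset, mean, sd, n_genes)`.
#' @export
trna_aligned_map <- function(norm_rates, genes, offsets = c(-120L, 200L),
                             min_genes_per_offset = 10L,
                             nominal_len = 72L) {
  genes <- as.data.table(genes)
  has_intron <- vapply(parse_intervals(
    if (is.character(genes$introns)) genes$introns else
      rep("", nrow(genes))), nrow, 1L) > 0L
  genes <- genes[!has_intron]
  if (nrow(genes) == 0L) stop("no intronless tRNA genes")
  nr <- as.data.table(norm_rates)
  if ("estimable" %in% names(nr)) nr <- nr[estimable == TRUE]
  nr <- nr[is.finite(ratio)]

  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    L <- if (g$strand == "+") g$end - g$tss else g$tss - g$end + 1L
    cand <- nr[chrom == g$chrom &
                 pos >= min(g$tss, g$end) - (abs(offsets[1]) + 200L) &
                 pos <= max(g$tss, g$end) + (offsets[2] + 200L)]
    if (nrow(cand) == 0L) next
    d <- if (g$strand == "+") cand$pos - g$tss else g$tss - cand$pos
    dd <- d - L                    # bp past the gene end (0 = first base)
    o2 <- dd + nominal_len         # downstream frame, begins at +100
    frame1 <- (d >= offsets[1] & d <= -1L) |
      (d >= 0L & d <= min(L - 1L, 99L))
    frame2 <- o2 >= 100L & o2 <= offsets[2]
    off <- c(d[frame1], o2[frame2])
    val <- c(cand$ratio[frame1], cand$ratio[frame2])
    if (!length(off)) next
    rows[[i]] <- data.table(gene = g$gene_id, offset = as.integer(off),
                            value = val)
  }
  allr <- rbindlist(rows)
  if (nrow(allr) == 0L) stop("no sites within the aligned window")
  map <- allr[, .(mean = mean(value),
                  sd = if (.N > 1L) sd(value) else 0,
                  n_genes = uniqueN(gene)), by = offset][order(offset)]
  map[offset >= 72L & offset <= 99L & n_genes < min_genes_per_offset,
      `:=`(mean = NA_real_, sd = NA_real_)]
  map[]
}
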