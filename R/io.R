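#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `strand`, `tss`,
#' `plus1_dyad`, `end`, `klass`, `introns`. Coordinates are 0-based.
#' Strand conventions: `tss` is the position of the first transcribed
#' base; for `+` genes `end` is the exclusive genomic end of the locus,
#' for `-` genes `end` is the (inclusive) genomic position of the last
#' transcribed base, so the locus spans `[end, tss + 1)`. `introns` is a
#' semicolon-separated list of genomic `start-end` half-open pairs (empty
#' for none). `plus1_dyad` is the +1 nucleosome dyad position (may be NA
#' for dyad-less classes such as tRNA).
#'
#' @param path TSV file (a leading `# phasekin` comment line is allowed).
#' @return data.table of validated gene records.
#' @export
read_genes <- function(path) {
  g <- read_pk_tsv(path)
  req <- c("gene_id", "chrom", "strand", "tss", "plus1_dyad", "end",
           "klass", "introns")
  miss <- setdiff(req, names(g))
  if (length(miss))
    stop("genes file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!g$strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand at line ", bad[1] + 1L, " (must be '+' or '-')")
  dup <- g$gene_id[duplicated(g$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(g$tss) | !is.finite(g$end))
  if (length(bad))
    stop("malformed coordinates at line ", bad[1] + 1L)
  g$introns <- as.character(g$introns)
  g$introns[is.na(g$introns)] <- ""
  # validates the interval syntax; errors name the offending string
  invisible(parse_intervals(g$introns))
  as.data.table(g)
}

#' Write a gene annotation table
#'
#' @param genes gene records (see [read_genes()]).
#' @param path output TSV.
#' @export
write_genes <- function(genes, path) {
  g <- as.data.table(genes)[, .(gene_id, chrom, strand, tss, plus1_dyad,
                                end, klass, introns)]
  write_pk_tsv(g, path)
}

#' Read / write bedGraph tracks
#'
#' Plain 4-column bedGraph (`chrom`, `start`, `end`, `value`), 0-based
#' half-open, no header.
#'
#' @param path file path.
#' @return data.table `(chrom, start, end, value)`.
#' @export
read_bedgraph <- function(path) {
  bg <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  bg[]
}

#' @param x a data.table with `chrom`, `value`, and either `pos` (scored
#'   base; written as `[pos, pos + 1)`) or `start`/`end`.
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(x, path) {
  x <- as.data.table(x)
  if (!"start" %in% names(x)) x <- x[, .(chrom, start = pos, end = pos + 1L,
                                         value = value)]
  fwrite(x[, .(chrom, start, end, value)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Write a site catalog or fragment set as BED
#'
#' @param x sites (`chrom`, `pos`, optional `motif`) or intervals
#'   (`chrom`, `start`, `end`).
#' @param path output file.
#' @param motif_len interval length written for site catalogs.
#' @export
write_bed <- function(x, path, motif_len = NULL) {
  x <- as.data.table(x)
  if (!"start" %in% names(x)) {
    ml <- motif_len %||% if ("motif" %in% names(x)) nchar(x$motif) else 1L
    x <- x[, .(chrom, start = pos, end = pos + ml)]
  }
  fwrite(x[, .(chrom, start, end)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Assemble a methylation time course from fraction tracks
#'
#' Either one bedGraph per timepoint (`paths` + `times`) or a long TSV
#' (`long` with columns `chrom`, `pos`, `time_min`, `fraction`). Sites
#' missing at some timepoints get `NA` there.
#'
#' @param paths bedGraph files, one per timepoint, same order as `times`.
#' @param times minutes after induction.
#' @param long long-format TSV path (alternative to `paths`).
#' @param sites optional site catalog (`chrom`, `pos`); defaults to the
#'   union of positions seen in the tracks.
#' @return a [methyl_timecourse()].
#' @export
read_fractions <- function(paths = NULL, times = NULL, long = NULL,
                           sites = NULL) {
  if (is.null(long)) {
    if (is.null(paths) || is.null(times))
      stop("supply either bedGraph paths + times, or a long TSV")
    if (length(paths) != length(times))
      stop(sprintf("%d fraction track(s) but %d timepoint(s)",
                   length(paths), length(times)))
    longdt <- rbindlist(lapply(seq_along(paths), function(i) {
      bg <- read_bedgraph(paths[i])
      data.table(chrom = bg$chrom, pos = bg$start, time_min = times[i],
                 fraction = bg$value)
    }))
  } else {
    longdt <- read_pk_tsv(long)
    req <- c("chrom", "pos", "time_min", "fraction")
    if (!all(req %in% names(longdt)))
      stop("long TSV needs columns: ", paste(req, collapse = ", "))
    times <- sort(unique(longdt$time_min))
  }
  bad <- longdt[fraction < 0 | fraction > 1]
  if (nrow(bad))
    stop(sprintf("fraction outside [0, 1] at site %s:%d",
                 bad$chrom[1], bad$pos[1]))
  if (is.null(sites)) {
    sites <- unique(longdt[, .(chrom, pos)])
    setkey(sites, chrom, pos)
  } else {
    sites <- as.data.table(sites)[, .(chrom, pos)]
  }
  mat <- matrix(NA_real_, nrow(sites), length(times),
                dimnames = list(NULL, as.character(times)))
  for (j in seq_along(times)) {
    sl <- longdt[time_min == times[j]]
    idx <- sites[sl[, .(chrom, pos)], on = c("chrom", "pos"), which = TRUE]
    ok <- !is.na(idx)
    mat[idx[ok], j] <- sl$fraction[ok]
  }
  methyl_timecourse(sites, times, mat)
}

#' Write a synthetic genome bundle to disk
#'
#' Emits the genome annotation TSV, site catalog BED, per-site truth-rate
#' TSV, per-timepoint fraction bedGraphs, and a key=value config file.
#'
#' @param genome a [make_genome()] result.
#' @param dir output directory (created if needed).
#' @param timecourse optional [methyl_timecourse()] whose columns are
#'   written as `fractions_t<min>.bedGraph`.
#' @return the directory, invisibly.
#' @export
write_genome <- function(genome, dir, timecourse = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genes(genome$genes, file.path(dir, "genes.tsv"))
  write_bed(genome$sites, file.path(dir, "sites.bed"))
  write_pk_tsv(genome$sites[, .(chrom, pos, region, gene_id, offset,
                                truth_rate)],
               file.path(dir, "truth_rates.tsv"))
  cfg <- genome$config
  scal <- Filter(function(v) is.atomic(v) && length(v) == 1L, unclass(cfg))
  writeLines(c(sprintf("# phasekin %s", pk_version()),
               sprintf("%s=%s", names(scal), vapply(scal, as.character,
                                                    character(1)))),
             file.path(dir, "config.txt"))
  if (!is.null(timecourse)) {
    for (j in seq_along(timecourse$times)) {
      bg <- data.table(chrom = timecourse$sites$chrom,
                       pos = timecourse$sites$pos,
                       value = timecourse$fractions[, j])
      write_bedgraph(bg[is.finite(value)],
                     file.path(dir, sprintf("fractions_t%g.bedGraph",
                                            timecourse$times[j])))
    }
  }
  invisible(dir)
}
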