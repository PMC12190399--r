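#' Find motif sites in nucleotide sequences
#'
#' Exact forward-strand matches of the motif; GATC and CG read the same on
#' both strands at the site level, so one strandless catalog suffices.
#'
#' @param sequences named character vector of uppercase sequences (names =
#'   chromosome names), or a single unnamed sequence (chromosome `"chr"`).
#' @param motif `"GATC"` or `"CG"`.
#' @return data.table `(chrom, pos, motif)`, `pos` 0-based position of the
#'   motif's first base, sorted by `(chrom, pos)`.
#' @export
find_motif_sites <- function(sequences, motif = c("GATC", "CG")) {
  motif <- match.arg(motif)
  if (is.null(names(sequences)))
    names(sequences) <- if (length(sequences) == 1L) "chr" else
      paste0("chr", seq_along(sequences))
  if (any(grepl("[^ACGT]", sequences)))
    warning("non-ACGT characters present; they never match the motif and are skipped")
  out <- lapply(names(sequences), function(nm) {
    hits <- gregexpr(motif, sequences[[nm]], fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    data.table(chrom = nm, pos = as.integer(hits) - 1L, motif = motif)
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(chrom = character(), pos = integer(),
                      motif = character())
  setkey(res, chrom, pos)
  res[]
}

#' Count diagnostic fragment ends at GATC half sites
#'
#' Implements the qDA-seq counting rule: for a GATC whose bases sit at
#' positions g, a, t, c (g = site `pos`), a fragment whose end coordinate is
#' `a + 1` ends on the A (blunt DpnI cut), one ending at `g + 1` ends on the
#' G (terminal A lost); a fragment starting at `t` begins with the T, one
#' starting at `c` begins with the C (terminal T lost). Fragment coverage of
#' the G and of the C is standard half-open base coverage
#' (`start <= base < end`), so cut fragments still cover the base they end
#' on and the count ratio estimates the methylated fraction directly.
#' Distances to the neighboring GATC on each flank are recorded for the
#' short-fragment loss filter (modular on circular chromosomes).
#'
#' @param fragments data.table `(chrom, start, end)`, 0-based half-open,
#'   sorted by `(chrom, start)`.
#' @param sites site catalog `(chrom, pos)` sorted by `(chrom, pos)`
#'   (GATC motif).
#' @param chrom_len optional named chromosome lengths (required for
#'   circular chromosomes).
#' @param circular character vector of circular chromosome names.
#' @return data.table: sites plus `ends_at_G`, `ends_at_A`, `starts_at_T`,
#'   `starts_at_C`, `cov_G`, `cov_C`, `neighbor_dist_left`,
#'   `neighbor_dist_right`.
#' @export
count_half_sites <- function(fragments, sites, chrom_len = NULL,
                             circular = character()) {
  fragments <- as.data.table(fragments)
  sites <- as.data.table(sites)
  if (is.unsorted_by(sites, c("chrom", "pos")))
    stop("sites must be sorted by (chrom, pos)")
  if (is.unsorted_by(fragments, c("chrom", "start")))
    stop("fragments must be sorted by (chrom, start)")
  if (nrow(fragments) && any(fragments$start >= fragments$end))
    stop("fragments must satisfy start < end")

  res <- copy(sites)
  nb <- neighbor_distances(res$chrom, res$pos, chrom_len, circular)
  res[, `:=`(neighbor_dist_left = nb$left, neighbor_dist_right = nb$right)]

  count_at <- function(keys, what) {
    # number of fragments whose start (or end) equals each key, per chrom
    tab <- fragments[, .N, by = c("chrom", what)]
    setnames(tab, what, "key")
    m <- tab[keys, on = c("chrom", "key"), x.N]
    fifelse(is.na(m), 0L, m)
  }
  kg <- res[, .(chrom, key = pos + 1L)]
  ka <- res[, .(chrom, key = pos + 2L)]
  res[, ends_at_G := count_at(kg, "end")]
  res[, ends_at_A := count_at(ka, "end")]
  res[, starts_at_T := count_at(res[, .(chrom, key = pos + 2L)], "start")]
  res[, starts_at_C := count_at(res[, .(chrom, key = pos + 3L)], "start")]

  # coverage of base p: #(start <= p) - #(end <= p)
  cov_at <- function(p, chrom) {
    out <- integer(length(p))
    for (cc in unique(chrom)) {
      fs <- sort(fragments[chrom == cc, start])
      fe <- sort(fragments[chrom == cc, end])
      sel <- which(chrom == cc)
      out[sel] <- findInterval(p[sel], fs) - findInterval(p[sel], fe)
    }
    out
  }
  res[, cov_G := cov_at(pos, chrom)]
  res[, cov_C := cov_at(pos + 3L, chrom)]
  res[]
}

is.unsorted_by <- function(dt, cols) {
  o <- do.call(order, dt[, cols, with = FALSE])
  !identical(o, seq_len(nrow(dt)))
}

#' Per-site methylated fraction from half-site counts
#'
#' The left half-site ratio is `(ends_at_G + ends_at_A) / cov_G`, valid
#' only when the neighboring GATC on the left is at least `min_neighbor_bp`
#' away (fragments shorter than that tend to be lost during sample
#' preparation, depressing the count); the right half-site ratio is
#' `(starts_at_T + starts_at_C) / cov_C` with the mirror-image validity
#' rule. The site's fraction pools the valid half-sites (sum of numerators
#' over sum of denominators), weighting each strand's evidence by its
#' coverage. Sites with no valid half-site or zero pooled coverage are
#' flagged as dropped.
#'
#' @param counts output of [count_half_sites()].
#' @param min_neighbor_bp minimum distance to the adjacent GATC for a
#'   half-site to be usable (200 bp).
#' @return `counts` with columns `frac_left`, `frac_right`, `fraction`,
#'   and `retained`; `fraction` is `NA` for dropped sites. Pooled ratios
#'   above 1 (possible when trimmed ends double-count) are clipped to 1
#'   with a warning.
#' @export
quantify_fractions <- function(counts, min_neighbor_bp = 200) {
  res <- copy(as.data.table(counts))
  res[, left_valid := neighbor_dist_left >= min_neighbor_bp]
  res[, right_valid := neighbor_dist_right >= min_neighbor_bp]
  res[, frac_left := fifelse(left_valid & cov_G > 0,
                             (ends_at_G + ends_at_A) / cov_G, NA_real_)]
  res[, frac_right := fifelse(right_valid & cov_C > 0,
                              (starts_at_T + starts_at_C) / cov_C, NA_real_)]
  num <- with(res, fifelse(left_valid, ends_at_G + ends_at_A, 0L) +
                fifelse(right_valid, starts_at_T + starts_at_C, 0L))
  den <- with(res, fifelse(left_valid, cov_G, 0L) +
                fifelse(right_valid, cov_C, 0L))
  res[, fraction := fifelse(den > 0, num / den, NA_real_)]
  res[, retained := !is.na(fraction)]
  if (any(res$fraction > 1, na.rm = TRUE)) {
    warning(sum(res$fraction > 1, na.rm = TRUE),
            " pooled ratio(s) > 1 clipped to 1 (trimmed-end double counting)")
    res[fraction > 1, fraction := 1]
  }
  res[, c("left_valid", "right_valid") := NULL]
  res[]
}
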