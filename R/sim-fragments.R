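#' Simulate DpnI-style restriction fragments
#'
#' Emulates the fragment population produced by digesting genomic DNA with
#' DpnI, which cuts GATC sites methylated on both strands to give blunt ends
#' between the A and the T (the left fragment ends on the A, the right
#' fragment begins with the T). Per simulated molecule (one full copy of
#' each chromosome), each GATC is methylated independently with its supplied
#' fraction; some cut ends lose their terminal base ('A' or 'T'); fragments
#' shorter than the configured minimum are lost with the configured
#' probability, emulating size selection losses.
#'
#' Circular chromosomes are linearized at coordinate 0 for fragment
#' emission; only the GATC motif is supported (CG methylation is read out
#' by sequencing, not by restriction digestion).
#'
#' @param genome a [make_genome()] result (GATC motif).
#' @param fractions per-site methylated fractions aligned with
#'   `genome$sites` (e.g. one column of a simulated time course).
#' @param n_molecules genome copies to digest.
#' @param seed optional seed.
#' @param trim_prob,min_len,loss_prob override the genome config's
#'   `fragment_trim_prob`, `fragment_min_length`, `fragment_loss_prob`.
#' @return data.table `(chrom, start, end)` of 0-based half-open fragments.
#' @export
simulate_fragments <- function(genome, fractions, n_molecules, seed = NULL,
                               trim_prob = NULL, min_len = NULL,
                               loss_prob = NULL) {
  cfg <- genome$config
  if (cfg$motif != "GATC")
    stop("fragment simulation models DpnI cutting and needs GATC sites")
  stopifnot(length(fractions) == nrow(genome$sites),
            all(fractions >= 0 & fractions <= 1))
  trim_prob <- trim_prob %||% cfg$fragment_trim_prob
  min_len <- min_len %||% cfg$fragment_min_length
  loss_prob <- loss_prob %||% cfg$fragment_loss_prob
  if (!is.null(seed)) set.seed(seed)
  if (nrow(genome$sites) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))

  out <- vector("list", nrow(genome$chroms))
  for (ci in seq_len(nrow(genome$chroms))) {
    cc <- genome$chroms$chrom[ci]
    L <- genome$chroms$length[ci]
    sel <- genome$sites$chrom == cc
    gpos <- genome$sites$pos[sel]
    fr <- fractions[sel]
    frag_s <- vector("list", n_molecules)
    frag_e <- vector("list", n_molecules)
    for (m in seq_len(n_molecules)) {
      cut <- gpos[runif(length(gpos)) < fr] + 2L  # blunt cut between A | T
      s <- c(0L, cut)
      e <- c(cut, L)
      nc <- length(cut)
      if (nc > 0L && trim_prob > 0) {
        tl <- runif(nc) < trim_prob  # left fragment loses terminal 'A'
        tr <- runif(nc) < trim_prob  # right fragment loses terminal 'T'
        e[seq_len(nc)][tl] <- e[seq_len(nc)][tl] - 1L
        s[1L + seq_len(nc)][tr] <- s[1L + seq_len(nc)][tr] + 1L
      }
      len <- e - s
      keep <- len > 0L & (len >= min_len | runif(length(s)) >= loss_prob)
      frag_s[[m]] <- s[keep]
      frag_e[[m]] <- e[keep]
    }
    ss <- unlist(frag_s); ee <- unlist(frag_e)
    out[[ci]] <- data.table(chrom = rep(cc, length(ss)),
                            start = as.integer(ss), end = as.integer(ee))
  }
  frags <- rbindlist(out)
  setkey(frags, chrom, start, end)
  frags[]
}
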