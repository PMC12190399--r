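test_that("motif sites are found at exact forward-strand matches", {
  expect_equal(find_motif_sites("AAGATCTT", "GATC")$pos, 2L)
  expect_equal(find_motif_sites("GATCGATC", "GATC")$pos, c(0L, 4L))
  expect_equal(find_motif_sites("ACGCGT", "CG")$pos, c(1L, 3L))
  expect_warning(res <- find_motif_sites("AANGATCT", "GATC"), "non-ACGT")
  expect_equal(res$pos, 3L)
})

test_that("half-site end counting follows the DpnI cut signatures", {
  st <- data.table::data.table(chrom = "chr", pos = 2L)

  # spanning fragment: covers the G and the C, no diagnostic ends
  span <- count_half_sites(
    data.table::data.table(chrom = "chr", start = 0L, end = 6L), st)
  expect_equal(span[, c(ends_at_G, ends_at_A, starts_at_T, starts_at_C)],
               rep(0L, 4))
  expect_equal(span[, c(cov_G, cov_C)], c(1L, 1L))

  # blunt cut between A and T
  cut <- count_half_sites(
    data.table::data.table(chrom = "chr", start = c(0L, 4L),
                           end = c(4L, 10L)), st)
  expect_equal(cut$ends_at_A, 1L)
  expect_equal(cut$starts_at_T, 1L)
  expect_equal(cut$ends_at_G, 0L)

  # trimmed ends: terminal A lost -> fragment ends on the G
  trim <- count_half_sites(
    data.table::data.table(chrom = "chr", start = 0L, end = 3L), st)
  expect_equal(trim$ends_at_G, 1L)

  expect_error(count_half_sites(
    data.table::data.table(chrom = "chr", start = c(5L, 0L), end = c(9L, 4L)),
    st), "sorted")
  expect_error(count_half_sites(
    data.table::data.table(chrom = "chr", start = 0L, end = 6L),
    data.table::data.table(chrom = "chr", pos = c(9L, 2L))), "sorted")
})

test_that("fraction pooling and the 200-bp half-site filter behave as specified", {
  counts <- data.table::data.table(
    chrom = "chr", pos = c(1000L, 2000L),
    ends_at_G = c(10L, 10L), ends_at_A = c(20L, 20L),
    starts_at_T = c(10L, 30L), starts_at_C = c(20L, 30L),
    cov_G = c(100L, 100L), cov_C = c(100L, 100L),
    neighbor_dist_left = c(500, 150), neighbor_dist_right = c(500, 500))
  q <- quantify_fractions(counts)
  # both half sites valid: pooled (30 + 30) / 200
  expect_equal(q$fraction[1], 0.30)
  # left neighbor too close: right ratio only
  expect_equal(q$fraction[2], 0.60)
  expect_true(all(q$retained))

  # no valid half-site -> dropped
  counts$neighbor_dist_right[2] <- 100
  q2 <- quantify_fractions(counts)
  expect_false(q2$retained[2])
  expect_true(is.na(q2$fraction[2]))

  # pooled ratio above 1 is clipped with a warning
  counts$neighbor_dist_right[2] <- 500
  counts$starts_at_T[2] <- 90L
  counts$starts_at_C[2] <- 90L
  counts$neighbor_dist_left[2] <- 100
  expect_warning(q3 <- quantify_fractions(counts), "clipped")
  expect_equal(q3$fraction[2], 1)
})

test_that("production counts equal the brute-force scan on small genomes", {
  set.seed(31)
  for (rep in 1:5) {
    L <- 10000L
    sites <- data.table::data.table(
      chrom = "chr", pos = sort(sample.int(L - 10L, 40L)))
    sites <- sites[c(TRUE, diff(pos) >= 4L)]
    start <- sort(sample.int(L - 1L, 300L, replace = TRUE)) - 1L
    frag <- data.table::data.table(
      chrom = "chr", start = start,
      end = pmin(start + sample(1:400, 300L, replace = TRUE), L))
    frag <- frag[start < end][order(start, end)]
    got <- count_half_sites(frag, sites)
    want <- brute_half_site_counts(frag, sites)
    for (col in names(want)) expect_equal(got[[col]], want[[col]], info = col)
  }
})

test_that("fragment order (among valid sortings) never changes counts", {
  set.seed(5)
  frag <- data.table::data.table(
    chrom = "chr", start = rep(c(0L, 10L, 10L), 4),
    end = c(14L, 30L, 25L, 14L, 30L, 25L, 13L, 30L, 25L, 14L, 31L, 25L))
  sites <- data.table::data.table(chrom = "chr", pos = c(8L, 20L))
  a <- count_half_sites(frag[order(start, end)], sites)
  b <- count_half_sites(frag[order(start, -as.integer(end))], sites)
  cols <- c("ends_at_G", "ends_at_A", "starts_at_T", "starts_at_C",
            "cov_G", "cov_C")
  expect_equal(as.data.frame(a)[cols], as.data.frame(b)[cols])
})

test_that("generator round trip recovers the methylated fraction", {
  g <- tiny_genome(seed = 9L, n_genes = 3L, mt_length = 2500L)
  ns <- nrow(g$sites)

  # fully unmethylated: one full-length fragment per molecule, fractions 0
  fr0 <- simulate_fragments(g, rep(0, ns), n_molecules = 20L, seed = 1L)
  expect_equal(nrow(fr0), 20L * nrow(g$chroms))
  expect_true(all(fr0$start == 0L))
  cnt0 <- count_half_sites(fr0, g$sites[, .(chrom, pos)],
                           chrom_len = setNames(g$chroms$length,
                                                g$chroms$chrom),
                           circular = g$chroms[circular == TRUE, chrom])
  q0 <- quantify_fractions(cnt0)
  expect_true(all(q0[retained == TRUE, fraction] == 0))

  # fully methylated, no trimming, no loss: boundaries exactly at cuts
  fr1 <- simulate_fragments(g, rep(1, ns), n_molecules = 5L, seed = 2L,
                            trim_prob = 0, loss_prob = 0)
  cuts <- sort(unique(fr1[start > 0L, start]))
  expect_setequal(cuts, sort(g$sites$pos + 2L))
  cnt1 <- count_half_sites(fr1, g$sites[, .(chrom, pos)],
                           chrom_len = setNames(g$chroms$length,
                                                g$chroms$chrom),
                           circular = g$chroms[circular == TRUE, chrom])
  q1 <- quantify_fractions(cnt1)
  expect_true(all(q1[retained == TRUE, fraction] == 1))

  # intermediate fraction, deep sampling, default trim/loss
  fr5 <- simulate_fragments(g, rep(0.5, ns), n_molecules = 3000L, seed = 3L)
  cnt5 <- count_half_sites(fr5, g$sites[, .(chrom, pos)],
                           chrom_len = setNames(g$chroms$length,
                                                g$chroms$chrom),
                           circular = g$chroms[circular == TRUE, chrom])
  q5 <- quantify_fractions(cnt5)
  # interior nuclear sites only: fragments touching the linear chromosome
  # boundary (and the linearization point of the circular mtDNA) are
  # subject to short-fragment loss the neighbor filter cannot see
  interior <- q5$retained & q5$chrom == "chrI" &
    q5$pos >= 250L & q5$pos <= g$chroms[chrom == "chrI", length] - 250L
  expect_gt(sum(interior), 5L)
  expect_lt(max(abs(q5$fraction[interior] - 0.5)), 0.03)
})
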