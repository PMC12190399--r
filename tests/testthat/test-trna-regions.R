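test_that("TFIIIB/TFIIIC intervals follow the -56/-13/-2/+10 footprint rules", {
  g <- data.table::data.table(gene_id = "t1", chrom = "chr", strand = "+",
                              tss = 500L, plus1_dyad = NA_integer_,
                              end = 572L, klass = "tRNA", introns = "")
  rg <- make_trna_regions(g)
  expect_equal(rg[klass == "TFIIIB", c(start, end)], c(444L, 488L))
  expect_equal(rg[klass == "TFIIIC", c(start, end)], c(498L, 582L))
  # TFIIIB footprint is always 44 bp; TFIIIC spans gene length + 12
  expect_equal(rg[klass == "TFIIIB", end - start], 44L)
  expect_equal(rg[klass == "TFIIIC", sum(end - start)], 72L + 12L)
})

test_that("minus-strand genes mirror and introns split TFIIIC", {
  gp <- data.table::data.table(gene_id = "tp", chrom = "chr", strand = "+",
                               tss = 500L, plus1_dyad = NA_integer_,
                               end = 572L, klass = "tRNA", introns = "")
  gm <- data.table::data.table(gene_id = "tm", chrom = "chr", strand = "-",
                               tss = 571L, plus1_dyad = NA_integer_,
                               end = 500L, klass = "tRNA", introns = "")
  rp <- make_trna_regions(gp)
  rm <- make_trna_regions(gm)
  # mirror around the locus (bases 500..571): spans must match reflected
  mirror <- function(s, e) c(500L + 571L - (e - 1L), 500L + 571L - s + 1L)
  for (k in c("TFIIIB", "TFIIIC")) {
    fwd <- rp[klass == k, .(start, end)]
    refl <- mirror(fwd$start, fwd$end)
    expect_equal(unlist(rm[klass == k, .(start, end)], use.names = FALSE),
                 refl, info = k)
  }

  gi <- data.table::copy(gp)[, `:=`(gene_id = "ti", end = 592L,
                                    introns = "530-560")]
  ri <- make_trna_regions(gi)
  cp <- ri[klass == "TFIIIC"][order(start)]
  expect_equal(nrow(cp), 2L)
  expect_equal(cp$start, c(498L, 560L))
  expect_equal(cp$end, c(530L, 602L))
  expect_equal(ri[klass == "intron", c(start, end)], c(530L, 560L))
  expect_equal(ri[klass == "TFIIIC", sum(end - start)], 92L + 12L - 30L)

  bad <- data.table::copy(gp)[, introns := "300-320"]
  expect_error(make_trna_regions(bad), "outside the gene body")
})

test_that("class kinetics reproduce constructed rate ratios", {
  g <- data.table::data.table(gene_id = "t1", chrom = "chr", strand = "+",
                              tss = 500L, plus1_dyad = NA_integer_,
                              end = 592L, klass = "tRNA",
                              introns = "530-560")
  rg <- make_trna_regions(g)
  mk_rates <- function(b, c_, i_) {
    pos <- c(450L, 460L, 470L, 505L, 520L, 565L, 580L, 535L, 550L)
    data.table::data.table(chrom = "chr", pos = pos,
                           ratio = rep(c(b, c_, i_), c(3, 4, 2)))
  }
  kin <- trna_kinetics(mk_rates(0.9, 1.35, 1.8), rg)
  expect_equal(unname(kin$ratios["tfiiic_over_tfiiib"]), 1.5)
  expect_equal(unname(kin$ratios["intron_over_tfiiib"]), 2.0)

  kin_eq <- trna_kinetics(mk_rates(1, 1, 1), rg)
  expect_equal(unname(kin_eq$ratios), c(1, 1))

  # empty class: ratio undefined with a warning
  no_b <- mk_rates(0.9, 1.35, 1.8)[pos >= 500L]
  expect_warning(kin_nb <- trna_kinetics(no_b, rg), "TFIIIB")
  expect_true(is.na(kin_nb$ratios["tfiiic_over_tfiiib"]))
})

test_that("generator round trip: trajectory fits match per-site class rates", {
  g <- make_genome(sim_config(n_genes = 2L, n_trna = 40L, n_chrom = 1L,
                              motif = "CG", mean_site_interval = 16,
                              mt_length = 3000L, seed = 53L,
                              trna_intron_frac = 0.5))
  tc <- genome_timecourse(g, noise = "none")
  r <- fit_first_order(tc)
  nr <- normalize_rates(r, mtdna_reference(r))
  regions <- make_trna_regions(g$genes[klass == "tRNA"])
  kin <- trna_kinetics(nr, regions, timecourse = tc)
  expect_equal(unname(kin$ratios["tfiiic_over_tfiiib"]), 1.5,
               tolerance = 1e-9)
  expect_equal(unname(kin$ratios["intron_over_tfiiib"]), 2.0,
               tolerance = 1e-9)
  # first-order fits on class-median trajectories agree with per-site
  # median rates within 1% on homogeneous data
  traj_b <- kin$trajectory_fits$TFIIIB$k_app
  traj_c <- kin$trajectory_fits$TFIIIC$k_app
  expect_lt(abs(traj_c / traj_b - 1.5), 0.015)
})

test_that("TSS-aligned maps honor the discontinuity band and brute-force means", {
  # three identical flat genes: flat map, zero SD
  genes <- data.table::data.table(
    gene_id = c("a", "b", "c"), chrom = "chr", strand = "+",
    tss = c(1000L, 3000L, 5000L), plus1_dyad = NA_integer_,
    end = c(1072L, 3072L, 5072L), klass = "tRNA", introns = "")
  pos <- as.integer(outer(c(-40L, -10L, 10L, 40L, 71L, 130L),
                          genes$tss, `+`))
  nr <- data.table::data.table(chrom = "chr", pos = sort(pos), ratio = 1.2)
  map <- trna_aligned_map(nr, genes, min_genes_per_offset = 2L)
  expect_true(all(map$mean == 1.2))
  expect_true(all(map$sd == 0))
  expect_true(all(map$n_genes == 3L))

  # length-72 genes cover nothing in the +72..+99 band
  expect_false(any(map$offset %in% 72:99))
  # a site 130 bp past the TSS (58 bp past the end) lands in the
  # downstream frame at offset 58 + 72 = 130
  expect_true(130L %in% map$offset)

  # brute-force mean at a mixed offset
  set.seed(61)
  nr2 <- data.table::copy(nr)[, ratio := runif(.N, 0.5, 2)]
  map2 <- trna_aligned_map(nr2, genes, min_genes_per_offset = 2L)
  at10 <- nr2[pos %in% (genes$tss + 10L), ratio]
  expect_equal(map2[offset == 10L, mean], mean(at10))
  expect_equal(map2[offset == 10L, sd], sd(at10))
})
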