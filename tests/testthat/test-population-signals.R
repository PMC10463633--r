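# Density overlays and regulatory summaries: DNMs, crossovers, PRDM9,
# variant ratios, expression breadth, compartments.

# one isochore spanning [0, 10 kb) with three intronless genes of 1/2/1 kb
.toy_iso <- function() {
  iso <- data.frame(id = "isoA", chrom = "chr1", start = 0L, end = 10000L,
                    gc_fraction = 0.4)
  g <- data.frame(gene_id = c("a", "b", "c"), symbol = c("a", "b", "c"),
                  chrom = "chr1", strand = "+",
                  start = c(1000L, 3000L, 7000L),
                  end = c(2000L, 5000L, 8000L),
                  tss = c(1000L, 3000L, 7000L),
                  cds_start = NA_integer_, cds_end = NA_integer_,
                  has_five_prime_utr = TRUE)
  gs <- new_gene_set(g, data.frame(gene_id = g$gene_id, start = g$start,
                                   end = g$end))
  list(iso = iso, genes = gs)
}

test_that("genic DNM density pools mutations over merged gene spans per kb", {
  t <- .toy_iso()
  dnms <- data.frame(chrom = "chr1",
                     pos = c(1500L, 1600L, 7100L, 7200L, 9500L))
  d <- dnm_density(dnms, t$iso, t$genes)
  expect_equal(d$genic_kb, 4)                       # 1 + 2 + 1 kb
  expect_equal(d$genic_dnm, 4L)                     # the 9.5 kb DNM is intergenic
  expect_equal(d$genic_density_per_kb, 1.0)
  expect_equal(d$iso_dnm, 5L)
  expect_equal(d$iso_density_per_kb, 0.5)
  # duplicates collapse; row order does not matter
  d2 <- dnm_density(dnms[c(3, 1, 2, 5, 4, 1), ], t$iso, t$genes)
  expect_equal(d2$genic_dnm, d$genic_dnm)
  # zero DNMs
  d0 <- dnm_density(dnms[0, ], t$iso, t$genes)
  expect_equal(d0$genic_dnm, 0L)
  expect_equal(d0$genic_density_per_kb, 0)
})

test_that("relative crossover rates normalise to a genomic mean of one", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                        end = c(1000L, 2000L), id = c("r1", "r2"))
  xo <- data.frame(chrom = "chr1",
                   start = c(100L, 300L, 700L, 1500L),
                   end = c(120L, 320L, 720L, 1520L),
                   sex = "maternal")
  cr <- crossover_rate(xo, regions)
  expect_equal(cr$rel_rate, c(1.5, 0.5))
  # no crossovers in a region gives 0
  expect_equal(crossover_rate(xo[4, ], regions)$rel_rate, c(0, 2))
  # length-weighted mean identity on a random complete tiling, both sexes
  set.seed(13)
  bounds <- sort(c(0L, sample(1:9999, 7), 10000L))
  reg <- data.frame(chrom = "chr1", start = bounds[-9], end = bounds[-1])
  pos <- sample(0:9999, 400, TRUE)
  xo2 <- data.frame(chrom = "chr1", start = pos, end = pos + 10L,
                    sex = sample(c("maternal", "paternal"), 400, TRUE))
  cr2 <- crossover_rate(xo2, reg)
  for (sx in c("maternal", "paternal")) {
    sub <- cr2[cr2$sex == sx, ]
    len <- reg$end - reg$start
    expect_equal(sum(sub$rel_rate * len) / sum(len), 1, tolerance = 1e-9)
  }
  expect_error(crossover_rate(xo, data.frame(chrom = "chr1", start = c(0L, 500L),
                                             end = c(1000L, 1500L))),
               "disjoint")
})

test_that("midpoint assignment uses the median of the refined interval", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                        end = c(1000L, 2000L), id = c("r1", "r2"))
  # interval [900, 1300): midpoint 1100 -> r2 despite starting in r1
  xo <- data.frame(chrom = "chr1", start = 900L, end = 1300L, sex = "paternal")
  cr <- crossover_rate(xo, regions)
  expect_equal(cr$count[cr$region_id == "r2"], 1L)
  expect_equal(cr$count[cr$region_id == "r1"], 0L)
})

test_that("PRDM9 top-fraction filter keeps ceiling(f n) peaks with ties at the cut", {
  t <- .toy_iso()
  set.seed(14)
  peaks <- data.frame(chrom = "chr1",
                      start = seq(100L, 2000L, by = 100L)[1:20],
                      end = seq(200L, 2100L, by = 100L)[1:20],
                      enrichment = sample(seq(1, 20)))
  pe <- prdm9_enrichment(peaks, t$iso, t$genes, top_fraction = 0.10)
  expect_equal(attr(pe, "n_retained"), 2L)
  expect_equal(attr(pe, "cutoff"), 19)
  # all-tied enrichments are all retained at the boundary value
  peaks$enrichment <- 5
  pe2 <- prdm9_enrichment(peaks, t$iso, t$genes, top_fraction = 0.10)
  expect_equal(attr(pe2, "n_retained"), 20L)
  # a peak whose midpoint is intergenic contributes nothing
  lone <- data.frame(chrom = "chr1", start = 9000L, end = 9200L, enrichment = 7)
  pe3 <- prdm9_enrichment(lone, t$iso, t$genes, top_fraction = 1)
  expect_equal(pe3$sum_enrichment, 0)
  # a genic-midpoint peak contributes its full enrichment
  genic <- data.frame(chrom = "chr1", start = 1400L, end = 1600L, enrichment = 7)
  pe4 <- prdm9_enrichment(genic, t$iso, t$genes, top_fraction = 1)
  expect_equal(pe4$sum_enrichment, 7)
  expect_equal(pe4$density_per_kb, 7 / 4)
})

test_that("variant ratios handle zero synonymous counts as specified", {
  rec <- data.frame(gene_id = c("a", "b", "c"),
                    syn = c(2L, 0L, 3L), missense = c(4L, 2L, 0L),
                    lof = c(1L, 1L, 0L))
  vr <- variant_ratio(rec)
  expect_equal(vr$per_gene$ratio, c(2.5, NA, 0))
  expect_equal(vr$pooled$ratio, (4 + 1 + 2 + 1) / 5)   # syn-0 gene still pools
  # all genes synonymous-only: pooled ratio 0
  vr0 <- variant_ratio(data.frame(gene_id = "x", syn = 5L, missense = 0L,
                                  lof = 0L))
  expect_equal(vr0$pooled$ratio, 0)
  # grouping splits the pool
  vg <- variant_ratio(rec, group = c("g1", "g1", "g2"))
  expect_equal(vg$pooled$ratio[vg$pooled$group == "g1"], 8 / 2)
  expect_equal(vg$pooled$ratio[vg$pooled$group == "g2"], 0)
})

test_that("expression breadth counts tissues at or above the threshold", {
  m <- rbind(a = c(5, 4.9, 100), b = c(0, 0, 0), c = c(1, 2, 3))
  eb <- expression_breadth(m, threshold = 5)
  expect_equal(eb$tissues_expressed, c(2L, 0L, 0L))
  expect_equal(expression_breadth(m, threshold = 0)$tissues_expressed[3], 3L)
  expect_error(expression_breadth(rbind(c(-1, 2))), "non-negative")
})

test_that("compartment consensus uses nearest midpoints and the 21-tissue bins", {
  # tissue calls: A compartment [0, 1000), B [1000, 3000)
  one_tissue <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                           end = c(1000L, 3000L), compartment = c("A", "B"))
  calls_allA <- rep(list(one_tissue), 21)
  pts <- data.frame(id = c("p1", "p2"), chrom = "chr1", pos = c(400L, 2100L))
  cc <- compartment_consensus(calls_allA, pts)
  # p1 nearer midpoint 500 (A); p2 nearer midpoint 2000 (B)
  expect_equal(cc$a_count, c(21L, 0L))
  expect_equal(cc$bin, c("always A", "always B"))
  # 15 of 21 -> mostly A; 10 -> equal; 3 -> mostly B
  flip <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                     end = c(1000L, 3000L), compartment = c("B", "A"))
  cc15 <- compartment_consensus(c(rep(list(one_tissue), 15), rep(list(flip), 6)), pts)
  expect_equal(cc15$a_count[1], 15L)
  expect_equal(cc15$bin[1], "mostly A")
  cc10 <- compartment_consensus(c(rep(list(one_tissue), 10), rep(list(flip), 11)), pts)
  expect_equal(cc10$bin[1], "equal")
  cc3 <- compartment_consensus(c(rep(list(one_tissue), 3), rep(list(flip), 18)), pts)
  expect_equal(cc3$bin[1], "mostly B")
  # a tissue without calls on the chromosome is skipped, T adjusted
  other <- data.frame(chrom = "chr9", start = 0L, end = 100L, compartment = "A")
  cc_adj <- compartment_consensus(c(rep(list(one_tissue), 4), list(other)), pts)
  expect_equal(cc_adj$t_used, c(4L, 4L))
  # helper point builders
  expect_equal(midpoints(data.frame(id = "r", chrom = "chr1", start = 0L,
                                    end = 10L))$pos, 5L)
})
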