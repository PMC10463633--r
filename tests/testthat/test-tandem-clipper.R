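# Bookend-delimited tandem-array extraction and feature GC decomposition.

test_that("locate_cluster counts only fully contained non-bookend genes", {
  gs <- .clip_fixture()
  reg <- locate_cluster(.bookends, gs)
  expect_equal(reg$status, "profiled")
  expect_equal(c(reg$start, reg$end), c(3000L, 20000L))
  expect_equal(sort(reg$gene_ids), c("par1", "par2", "par3"))
  expect_equal(reg$paralog_count, 3L)   # straddle crosses the boundary
  # inclusive mode extends over the bookends
  reg_i <- locate_cluster(.bookends, gs, inclusive = TRUE)
  expect_equal(c(reg_i$start, reg_i$end), c(1000L, 22000L))
  # straddle still protrudes past the right bookend's end, bookends stay out
  expect_false(any(c("straddle", "bkL", "bkR") %in% reg_i$gene_ids))
})

test_that("bookend edge cases: adjacency, scaffold splits and overlap errors", {
  gs <- .clip_fixture()
  adj <- data.frame(gene = c("x", "y"), scaffold = "sc1",
                    start = c(100L, 300L), end = c(300L, 500L))
  reg <- locate_cluster(adj, gs)
  expect_equal(reg$paralog_count, 0L)
  expect_equal(c(reg$start, reg$end), c(300L, 300L))   # empty span allowed
  split <- .bookends; split$scaffold <- c("sc1", "sc2")
  expect_equal(locate_cluster(split, gs)$status, "skipped:different-scaffold")
  ovl <- data.frame(gene = c("x", "y"), scaffold = "sc1",
                    start = c(100L, 200L), end = c(400L, 600L))
  expect_error(locate_cluster(ovl, gs), "overlap")
  same <- data.frame(gene = c("x", "x"), scaffold = "sc1",
                     start = c(1L, 10L), end = c(5L, 20L))
  expect_error(locate_cluster(same, gs), "distinct")
})

test_that("feature partition identities hold to the base pair", {
  gs <- .clip_fixture()
  reg <- locate_cluster(.bookends, gs)
  fb <- partition_features(reg, gs)
  bp <- function(df) sum(df$end - df$start)
  expect_equal(bp(fb$genic) + bp(fb$intergenic), reg$end - reg$start)
  expect_equal(bp(fb$exonic) + bp(fb$intronic), bp(fb$genic))
  expect_equal(bp(fb$intronic), 1000)     # par2's single intron
  # promoters only for 5'-UTR-bearing genes (par1 and par2, not par3)
  expect_equal(bp(fb$promoter), 2000)
  # membership oracle: genic and intergenic are complementary per base
  m_genic <- oracle_membership(reg$start, reg$end, fb$genic)
  m_inter <- oracle_membership(reg$start, reg$end, fb$intergenic)
  expect_true(all(xor(m_genic, m_inter)))
  m_ex <- oracle_membership(reg$start, reg$end, fb$exonic)
  m_in <- oracle_membership(reg$start, reg$end, fb$intronic)
  expect_true(all((m_ex | m_in) == m_genic))
  expect_false(any(m_ex & m_in))
})

test_that("partitions match the per-base oracle on randomized annotations", {
  set.seed(17)
  for (rep in 1:5) {
    gs <- random_gene_set(6, 120000)
    lo <- min(gs$genes$start) - 2000L; hi <- max(gs$genes$end) + 2000L
    bk <- data.frame(gene = c("L", "R"), scaffold = "chr1",
                     start = c(lo - 1500L, hi), end = c(lo, hi + 1500L))
    reg <- locate_cluster(bk, gs)
    expect_equal(reg$paralog_count, 6L)
    fb <- partition_features(reg, gs)
    m_genic <- oracle_membership(reg$start, reg$end, fb$genic)
    truth <- oracle_membership(reg$start, reg$end,
                               gs$genes[, c("start", "end")])
    expect_identical(m_genic, truth)
    m_ex <- oracle_membership(reg$start, reg$end, fb$exonic)
    truth_ex <- oracle_membership(reg$start, reg$end,
                                  gs$exons[, c("start", "end")])
    expect_identical(m_ex, truth_ex)
    m_in <- oracle_membership(reg$start, reg$end, fb$intronic)
    expect_identical(m_in, truth & !truth_ex)
  }
})

test_that("intronless regions have an empty intronic set", {
  g <- data.frame(gene_id = "solo", symbol = "solo", chrom = "s", strand = "+",
                  start = 500L, end = 900L, tss = 500L,
                  cds_start = NA_integer_, cds_end = NA_integer_,
                  has_five_prime_utr = FALSE)
  gs <- new_gene_set(g, data.frame(gene_id = "solo", start = 500L, end = 900L))
  bk <- data.frame(gene = c("l", "r"), scaffold = "s",
                   start = c(0L, 1000L), end = c(100L, 1100L))
  fb <- partition_features(locate_cluster(bk, gs), gs)
  expect_equal(nrow(fb$intronic), 0)
  expect_equal(nrow(fb$promoter), 0)      # no annotated 5' UTR
})

test_that("cluster GC profiles match per-base oracles and qualitative ordering", {
  gs <- .clip_fixture()
  reg <- locate_cluster(.bookends, gs)
  # build a sequence where promoters are GC-rich over an AT background
  set.seed(18)
  seq <- random_dna(25000, 0.35)
  fb <- partition_features(reg, gs)
  for (r in seq_len(nrow(fb$promoter))) {
    a <- fb$promoter$start[r]; b <- fb$promoter$end[r]
    substr(seq, a + 1, b) <- random_dna(b - a, 0.75)
  }
  prof <- cluster_gc_profile(reg, gs, c(sc1 = seq))
  expect_equal(prof$cluster_gc, oracle_gc(seq, reg$start, reg$end))
  expect_equal(prof$intronic_gc, oracle_gc_intervals(seq, fb$intronic))
  expect_equal(prof$promoter_gc, oracle_gc_intervals(seq, fb$promoter))
  expect_equal(prof$cds_gc, oracle_gc_intervals(seq, fb$cds))
  expect_gt(prof$promoter_gc, prof$cluster_gc)
  expect_equal(prof$log_paralog, log(3))
  expect_equal(prof$genome_gc, oracle_gc(seq))
  # an all-GC toy region scores 1 everywhere defined
  gc_seq <- strrep("G", 25000)
  prof1 <- cluster_gc_profile(reg, gs, c(sc1 = gc_seq))
  expect_equal(prof1$cluster_gc, 1)
  expect_equal(prof1$intronic_gc, 1)
})

test_that("clip_panel accounts for every species exactly once", {
  gs <- .clip_fixture()
  set.seed(19)
  seq <- random_dna(25000, 0.4)
  bk <- rbind(cbind(species = "spA", .bookends),
              cbind(species = "spB",
                    data.frame(gene = c("bkL", "bkR"),
                               scaffold = c("sc1", "sc9"),
                               start = c(1000L, 20000L),
                               end = c(3000L, 22000L))),
              cbind(species = "spC", .bookends[1, ]))
  genomes <- list(spA = list(genes = gs, seqs = c(sc1 = seq)),
                  spB = list(genes = gs, seqs = c(sc1 = seq)),
                  spC = list(genes = gs, seqs = c(sc1 = seq)))
  res <- clip_panel(bk, genomes)
  expect_setequal(res$log$species, c("spA", "spB", "spC"))
  expect_equal(sort(res$log$status),
               sort(c("profiled", "skipped:different-scaffold",
                      "skipped:missing-bookend")))
  expect_equal(nrow(res$panel), 1)
  expect_equal(res$panel$paralog_count, 3L)
})
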