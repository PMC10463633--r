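# Generators: determinism, calibration against analytic targets, and
# round-tripping through the standard formats.

test_that("make_genome hits per-block GC within binomial error and validates input", {
  g <- make_genome(data.frame(length_bp = c(50000, 50000),
                              target_gc = c(0.30, 0.60)), seed = 1)
  expect_equal(nchar(g$seq[[1]]), 100000)
  for (i in 1:2) {
    p <- g$blocks$target_gc[i]; L <- g$blocks$length_bp[i]
    se <- sqrt(p * (1 - p) / L)
    expect_lt(abs(g$blocks$gc[i] - p), 3 * se)
  }
  expect_error(make_genome(data.frame(length_bp = 100, target_gc = 0)),
               "target_gc")
  expect_error(make_genome(data.frame(length_bp = 0, target_gc = 0.5)),
               "length")
})

test_that("make_genome is byte-identical under a fixed seed (FASTA round trip)", {
  spec <- data.frame(length_bp = c(10000, 10000), target_gc = c(0.35, 0.55),
                     cpg_depletion = c(0.2, 1))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(make_genome(spec, seed = 99), f1)
  write_genome_fasta(make_genome(spec, seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_genome_fasta(f1)
  expect_identical(back[["chr1"]], make_genome(spec, seed = 99)$seq[["chr1"]])
})

test_that("CpG thinning reduces CpG frequency by roughly the requested multiplier", {
  spec <- data.frame(length_bp = 200000, target_gc = 0.5)
  full <- make_genome(spec, seed = 3)
  spec$cpg_depletion <- 0.2
  thin <- make_genome(spec, seed = 3)
  r_full <- oracle_cpg_count(full$seq[[1]]) / nchar(full$seq[[1]])
  r_thin <- oracle_cpg_count(thin$seq[[1]]) / nchar(thin$seq[[1]])
  expect_lt(abs(r_thin / r_full - 0.2), 0.05)
  # composition-preserving: GC identical
  expect_equal(gc_content(thin$seq[[1]]), gc_content(full$seq[[1]]))
})

test_that("plant_genes places arrays in their home blocks and round-trips GFF3", {
  g <- make_genome(data.frame(length_bp = c(120000, 60000),
                              target_gc = c(0.32, 0.58)), seed = 2)
  pl <- plant_genes(g, data.frame(prefix = c("OR", "HOX"), n_genes = c(10, 3),
                                  home_block = c(1, 2),
                                  promoter_cpg_obs_exp = c(0.25, 1.0)),
                    seed = 7)
  or <- pl$genes$genes[grepl("^OR", pl$genes$genes$gene_id), ]
  expect_equal(nrow(or), 10)
  expect_true(all(or$tss >= g$blocks$start[1] & or$tss < g$blocks$end[1]))
  # no overlaps among planted genes
  gg <- pl$genes$genes[order(pl$genes$genes$start), ]
  expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))

  f <- tempfile(fileext = ".gff3")
  write_gff3(pl$genes, f)
  back <- read_gff3_genes(f)
  o1 <- pl$genes$genes[order(pl$genes$genes$start), ]
  o2 <- back$genes[order(back$genes$start), ]
  expect_equal(o2$start, o1$start)
  expect_equal(o2$end, o1$end)
  expect_equal(o2$strand, o1$strand)
  expect_equal(o2$tss, o1$tss)
  expect_true(all(o2$has_five_prime_utr))
  expect_equal(nrow(back$exons), nrow(pl$genes$exons))
})

test_that("planted promoters achieve the requested CpG obs/exp on average", {
  # mean over replicate singletons within +/- 0.15, checked by the naive
  # counting oracle on the emitted promoter windows
  for (target in c(0.25, 1.0)) {
    devs <- vapply(1:10, function(s) {
      g <- make_genome(data.frame(length_bp = 40000, target_gc = 0.55), seed = s)
      pl <- plant_genes(g, data.frame(prefix = "SNG", n_genes = 1,
                                      home_block = 1,
                                      promoter_cpg_obs_exp = target), seed = s)
      gi <- pl$genes$genes[1, ]
      pw <- if (gi$strand == "+") c(gi$tss - 750, gi$tss + 250)
            else c(gi$tss - 250, gi$tss + 750)
      win <- substr(pl$genome$seq[[1]], pw[1] + 1, pw[2])
      v <- strsplit(win, "")[[1]]
      obs <- oracle_cpg_count(win)
      expd <- sum(v == "C") * sum(v == "G") / length(v)
      obs / expd
    }, 0)
    expect_lt(abs(mean(devs) - target), 0.15)
  }
})

test_that("plant_genes handles empty arrays and rejects overfull blocks", {
  g <- make_genome(data.frame(length_bp = 50000, target_gc = 0.4), seed = 1)
  pl <- plant_genes(g, data.frame(prefix = "X", n_genes = 0, home_block = 1,
                                  promoter_cpg_obs_exp = 1))
  expect_equal(length(pl$genes), 0)
  expect_error(
    plant_genes(g, data.frame(prefix = "X", n_genes = 20, home_block = 1,
                              promoter_cpg_obs_exp = 1)),
    "block 1")
})

test_that("DNM simulation is CpG-biased by the requested multiplier", {
  g <- make_genome(data.frame(length_bp = c(250000, 250000),
                              target_gc = c(0.35, 0.55)), seed = 11)
  ev <- simulate_events(g, dnm_base_rate = 2e-3, dnm_cpg_multiplier = 10,
                        crossover_base_rate = 0, prdm9_peak_rate = 0, seed = 12)
  seq <- g$seq[[1]]
  v <- strsplit(seq, "")[[1]]
  is_cpg <- logical(length(v))
  cg <- which(v[-length(v)] == "C" & v[-1] == "G")
  is_cpg[cg] <- TRUE; is_cpg[cg + 1] <- TRUE
  at_cpg <- is_cpg[ev$dnm$pos + 1]
  n1 <- sum(at_cpg); n0 <- sum(!at_cpg)
  rate_ratio <- (n1 / sum(is_cpg)) / (n0 / sum(!is_cpg))
  se_log <- sqrt(1 / n1 + 1 / n0)
  expect_gt(n1 + n0, 500)
  expect_lt(abs(log(rate_ratio) - log(10)), 3 * se_log)
})

test_that("crossover intensity responds to block GC as specified", {
  g <- make_genome(data.frame(length_bp = rep(100000, 4),
                              target_gc = c(0.3, 0.4, 0.5, 0.6)), seed = 5)
  ev <- simulate_events(g, dnm_base_rate = 0, crossover_base_rate = 5e-4,
                        crossover_gc_slope = 4, prdm9_peak_rate = 0, seed = 6)
  mid <- floor((ev$crossover$start + ev$crossover$end) / 2)
  counts <- vapply(seq_len(4), function(i)
    sum(mid >= g$blocks$start[i] & mid < g$blocks$end[i]), 0L)
  expect_true(all(diff(counts) > 0))   # monotone in block GC
  # null slope: block counts consistent with uniform (chi-square)
  ev0 <- simulate_events(g, dnm_base_rate = 0, crossover_base_rate = 5e-4,
                         crossover_gc_slope = 0, prdm9_peak_rate = 0, seed = 6)
  mid0 <- floor((ev0$crossover$start + ev0$crossover$end) / 2)
  c0 <- vapply(seq_len(4), function(i)
    sum(mid0 >= g$blocks$start[i] & mid0 < g$blocks$end[i]), 0L)
  expect_gt(stats::chisq.test(c0)$p.value, 0.01)
  # degenerate: zero rate
  ev_none <- simulate_events(g, dnm_base_rate = 0, crossover_base_rate = 0,
                             prdm9_peak_rate = 0, seed = 1)
  expect_equal(nrow(ev_none$dnm), 0)
  expect_equal(nrow(ev_none$crossover), 0)
})

test_that("species panels are deterministic and carry the generating model", {
  set.seed(20); tr <- ape::rcoal(16)
  p1 <- simulate_species_panel(tr, b = -0.02, seed = 3)
  p2 <- simulate_species_panel(tr, b = -0.02, seed = 3)
  expect_identical(p1$table, p2$table)
  expect_true(all(p1$table$paralog_count >= 1))
  expect_true(all(p1$table$cluster_gc > 0 & p1$table$cluster_gc < 1))
  expect_error(simulate_species_panel(ape::rcoal(3)), "4 tips")
  # non-ultrametric accepted with warning
  tr2 <- tr; tr2$edge.length[1] <- tr2$edge.length[1] * 3
  expect_warning(simulate_species_panel(tr2, seed = 1), "ultrametric")
})

test_that("PGLS recovers a null slope and lambda = 0 from generated panels", {
  set.seed(30); tr <- ape::rcoal(48)
  cover <- logical(40); lam <- numeric(40)
  for (s in 1:40) {
    pan <- simulate_species_panel(tr, b = 0, bm_sigma2_resid = 4e-4,
                                  lambda_true = 0, seed = 1000 + s)
    fit <- pgls(cluster_gc ~ log_paralog, pan$table, tr)
    cover[s] <- abs(coef(fit)[2]) < 2 * fit$se[2]
    lam[s] <- fit$lambda
  }
  expect_gte(mean(cover), 0.80)
  expect_lt(median(lam), 0.2)
})
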