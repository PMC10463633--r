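# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (per-base loops, explicit formulas) so they share no
# code with the implementation paths they check.

# GC fraction by explicit per-base counting.
oracle_gc <- function(seq, start = 0L, end = nchar(seq)) {
  v <- strsplit(substr(seq, start + 1L, end), "")[[1]]
  v <- v[v != "N"]
  if (!length(v)) return(NA_real_)
  sum(v %in% c("G", "C")) / length(v)
}

# GC over a union of 0-based half-open intervals via per-base membership.
oracle_gc_intervals <- function(seq, ivs) {
  if (nrow(ivs) == 0L) return(NA_real_)
  v <- strsplit(seq, "")[[1]]
  member <- logical(length(v))
  for (r in seq_len(nrow(ivs))) {
    a <- max(0L, ivs$start[r]); b <- min(length(v), ivs$end[r])
    if (b > a) member[(a + 1L):b] <- TRUE
  }
  v <- v[member]; v <- v[v != "N"]
  if (!length(v)) return(NA_real_)
  sum(v %in% c("G", "C")) / length(v)
}

# Exhaustive scan of the weighted GC divergence delta(i) over all split
# points of [a, b); returns the 0-based argmax split coordinate.
oracle_delta_argmax <- function(seq, a = 0L, b = nchar(seq)) {
  v <- strsplit(substr(seq, a + 1L, b), "")[[1]]
  gc <- as.numeric(cumsum(v %in% c("G", "C") & v != "N"))
  nn <- as.numeric(cumsum(v != "N"))
  n <- length(v)
  best <- -Inf; best_i <- NA_integer_
  for (i in 1:(n - 1)) {
    nL <- nn[i]; nR <- nn[n] - nn[i]
    if (nL == 0 || nR == 0) next
    pL <- gc[i] / nL; pR <- (gc[n] - gc[i]) / nR
    d <- nL * nR / (nL + nR) * (pL - pR)^2
    if (d > best) { best <- d; best_i <- i }
  }
  a + best_i
}

# Count CG dinucleotides by explicit pairwise loop.
oracle_cpg_count <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  if (length(v) < 2L) return(0L)
  sum(v[-length(v)] == "C" & v[-1] == "G")
}

# Per-base membership vectors for a feature partition over a region.
oracle_membership <- function(region_start, region_end, ivs) {
  m <- logical(region_end - region_start)
  for (r in seq_len(nrow(ivs))) {
    a <- max(region_start, ivs$start[r]); b <- min(region_end, ivs$end[r])
    if (b > a) m[(a - region_start + 1L):(b - region_start)] <- TRUE
  }
  m
}

# random uppercase DNA of length n at GC fraction g
random_dna <- function(n, g = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)), collapse = "")
}

# A small random gene_set on one chromosome of length L: random spans,
# strands, exon structures and CDSs (assumes the caller seeded the RNG).
random_gene_set <- function(n_genes, L, chrom = "chr1") {
  genes <- list(); exons <- list()
  for (i in seq_len(n_genes)) {
    len <- sample(2000:6000, 1)
    s <- sample(30000:(L - len - 30000), 1)
    e <- s + len
    strand <- sample(c("+", "-"), 1)
    k <- sample(1:5, 1)
    bnd <- sort(sample(seq(s + 50L, e - 50L, by = 25L), 2L * (k - 1L)))
    ex_s <- c(s, bnd[seq_along(bnd) %% 2 == 0])
    ex_e <- c(bnd[seq_along(bnd) %% 2 == 1], e)
    gid <- sprintf("rg%03d", i)
    genes[[i]] <- data.frame(
      gene_id = gid, symbol = gid, chrom = chrom, strand = strand,
      start = s, end = e, tss = if (strand == "+") s else e - 1L,
      cds_start = s + 150L, cds_end = e - 150L,
      has_five_prime_utr = TRUE, stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid, start = ex_s, end = ex_e)
  }
  new_gene_set(do.call(rbind, genes), do.call(rbind, exons))
}

# Planted three-class metagene trajectory mixture: flat AT (0.35), flat GC
# (0.60), and promoter-peaked (0.55 peak over a 0.42 baseline), Gaussian
# noise sd 0.03, with class labels returned for recovery scoring.
planted_trajectories <- function(n_per_class = 300, ncol_flank = 20,
                                 body_bins = 100, sd = 0.03) {
  p <- 2 * ncol_flank + body_bins
  peak <- rep(0.42, p)
  peak[(ncol_flank - 5):(ncol_flank + 10)] <- 0.55
  mu <- rbind(rep(0.35, p), peak, rep(0.60, p))
  lab <- rep(1:3, each = n_per_class)
  M <- mu[lab, ] + matrix(rnorm(3 * n_per_class * p, 0, sd), ncol = p)
  M[] <- pmin(1, pmax(0, M))
  rownames(M) <- sprintf("g%04d", seq_len(nrow(M)))
  attr(M, "flank_windows") <- ncol_flank
  attr(M, "body_bins") <- body_bins
  list(traj = M, labels = lab)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
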