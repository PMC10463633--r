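# Synthetic genomes, gene plants and event tables with known truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: an isochore mosaic of blocks with distinct target GC, CpG-depleted
# background sequence, tandem gene arrays planted in chosen blocks with
# controlled promoter CpG observed/expected, CpG-biased de novo mutations,
# GC-correlated crossovers and PRDM9 peaks, and Brownian multi-species trait
# panels. Every generator is a pure function of its arguments including the
# seed.

.check_fraction <- function(x, name, open = TRUE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (any(is.na(x)) || bad)
    stop(sprintf("%s must be in %s", name, if (open) "(0,1)" else "[0,1]"),
         call. = FALSE)
}

#' Generate a mosaic genome of GC-homogeneous blocks
#'
#' Draws i.i.d. bases within each block at the block's target GC, then thins
#' CpG dinucleotides by composition-preserving swaps (CG -> GC) so the CpG
#' frequency is approximately `cpg_depletion` times the i.i.d. expectation.
#' This emulates the isochore mosaic (roughly 30--70% GC in real genomes)
#' together with the genome-wide CpG deficit.
#'
#' @param blocks data.frame with columns `length_bp` (positive integers),
#'   `target_gc` (fractions strictly inside (0,1)) and optionally
#'   `cpg_depletion` (multipliers in \[0,1\]; default 1 = no thinning).
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param chrom Chromosome name for the single emitted sequence.
#' @return An object of class `synth_genome`: a list with `seq` (named
#'   character vector of one chromosome) and `blocks`, the truth table of
#'   0-based half-open block coordinates with target and empirical GC.
#' @examples
#' g <- make_genome(data.frame(length_bp = c(5000, 5000),
#'                             target_gc = c(0.3, 0.6)), seed = 1)
#' g$blocks
#' @export
make_genome <- function(blocks, seed = 1L, chrom = "chr1") {
  stopifnot(is.data.frame(blocks), nrow(blocks) >= 1L,
            all(c("length_bp", "target_gc") %in% names(blocks)))
  if (any(blocks$length_bp < 1L))
    stop("zero-length block: every length_bp must be a positive integer")
  .check_fraction(blocks$target_gc, "target_gc", open = TRUE)
  if (is.null(blocks$cpg_depletion)) blocks$cpg_depletion <- 1
  .check_fraction(blocks$cpg_depletion, "cpg_depletion", open = FALSE)

  set.seed(as.integer(seed))
  pieces <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    L <- as.integer(blocks$length_bp[i]); g <- blocks$target_gc[i]
    v <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2))
    dep <- blocks$cpg_depletion[i]
    if (dep < 1 && L >= 2L) {
      # composition-preserving CG -> GC swaps can create fresh CpGs at the
      # swap boundaries, so thin iteratively toward the target count
      target <- dep * (L - 1) * (g / 2)^2
      for (pass in 1:25) {
        idx <- which(v[-L] == "C" & v[-1L] == "G")
        excess <- length(idx) - target
        if (excess < 1) break
        sw <- if (length(idx) <= excess) idx
              else sample(idx, ceiling(excess))
        v[sw] <- "G"; v[sw + 1L] <- "C"
      }
    }
    pieces[i] <- paste(v, collapse = "")
  }
  seq <- paste(pieces, collapse = "")
  ends <- cumsum(blocks$length_bp)
  truth <- data.frame(
    chrom = chrom,
    start = as.integer(ends - blocks$length_bp),
    end = as.integer(ends),
    length_bp = as.integer(blocks$length_bp),
    target_gc = blocks$target_gc,
    cpg_depletion = blocks$cpg_depletion
  )
  cums <- .seq_cums(seq)
  truth$gc <- mapply(function(s, e) .gc_window(cums, s, e), truth$start, truth$end)
  out <- list(seq = stats::setNames(seq, chrom), blocks = truth,
              seed = as.integer(seed))
  class(out) <- "synth_genome"
  out
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("synth_genome: %s, %d bp in %d blocks (GC %.3f)\n",
              names(x$seq)[1], nchar(x$seq[[1]]), nrow(x$blocks),
              gc_content(x$seq[[1]])))
  print(x$blocks)
  invisible(x)
}

# Accept either a synth_genome or a named character vector of chromosomes.
.get_seqs <- function(x) {
  if (inherits(x, "synth_genome")) x$seq
  else if (is.character(x) && !is.null(names(x))) x
  else stop("expected a synth_genome or a named character vector of sequences")
}

#' Write / read a genome as FASTA
#'
#' 60-column wrapped FASTA via Biostrings.
#'
#' @param genome A `synth_genome` or named character vector of sequences.
#' @param path Output file.
#' @return `write_genome_fasta` returns `path` invisibly; `read_genome_fasta`
#'   returns a named character vector of uppercase sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- .get_seqs(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

# Synthesize a promoter-like sequence of length L at composition `gc` whose
# CpG observed/expected ratio approximates `target_oe`: thinning by CG->GC
# swaps when over target, planting CG dinucleotides when under.
.synth_promoter <- function(L, gc, target_oe) {
  v <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  for (iter in 1:4) {
    obs <- sum(v[-L] == "C" & v[-1L] == "G")
    nc <- sum(v == "C"); ng <- sum(v == "G")
    expd <- nc * ng / L
    if (expd <= 0) break
    r <- obs / expd
    if (abs(r - target_oe) < 0.02) break
    if (r > target_oe) {
      idx <- which(v[-L] == "C" & v[-1L] == "G")
      sw <- idx[stats::runif(length(idx)) < 1 - target_oe / r]
      if (length(sw)) { v[sw] <- "G"; v[sw + 1L] <- "C" }
    } else {
      need <- round((target_oe - r) * expd)
      if (need < 1) break
      cand <- sample.int(L - 1L)
      taken <- logical(L); placed <- 0L
      for (i in cand) {
        if (placed >= need) break
        if (taken[i] || taken[i + 1L]) next
        if (v[i] == "C" && v[i + 1L] == "G") next
        v[i] <- "C"; v[i + 1L] <- "G"
        taken[i] <- taken[i + 1L] <- TRUE
        placed <- placed + 1L
      }
    }
  }
  paste(v, collapse = "")
}

# Strand-aware promoter window around a TSS point coordinate, 0-based
# half-open: plus [tss-up, tss+down), minus [tss-down, tss+up).
.promoter_window <- function(tss, strand, up = 750L, down = 250L) {
  if (strand == "+") c(tss - up, tss + down) else c(tss - down, tss + up)
}

#' Plant tandem gene arrays and singletons into a synthetic genome
#'
#' Places non-overlapping gene models inside their home blocks, with exon /
#' intron structure, a 5' UTR, and a promoter sequence synthesized to a
#' requested CpG observed/expected ratio and spliced over the background.
#' This emulates tandem arrays of same-prefix paralogs (for example
#' AT-block olfactory-receptor-style arrays) versus scattered singletons.
#'
#' @param genome A `synth_genome` from [make_genome()].
#' @param arrays data.frame with one row per array: `prefix` (unique strings),
#'   `n_genes` (>= 0), `home_block` (1-based block index),
#'   `promoter_cpg_obs_exp`, and optionally `gene_length_bp` (default 6000)
#'   and `exon_count` (default 4).
#' @param singleton_fraction Fraction of all planted genes that should be
#'   auto-generated singletons (unique prefixes, spread across blocks
#'   round-robin, promoter obs/exp 1). Default 0.
#' @param seed Integer seed.
#' @return List with `genome` (promoters spliced in), `genes` (a `gene_set`),
#'   and `truth` (data.frame of gene_id, symbol, prefix, array id, home block,
#'   target obs/exp).
#' @export
plant_genes <- function(genome, arrays, singleton_fraction = 0, seed = 1L) {
  stopifnot(inherits(genome, "synth_genome"), is.data.frame(arrays))
  req <- c("prefix", "n_genes", "home_block", "promoter_cpg_obs_exp")
  stopifnot(all(req %in% names(arrays)))
  if (anyDuplicated(arrays$prefix)) stop("array prefixes must be unique")
  if (is.null(arrays$gene_length_bp)) arrays$gene_length_bp <- 6000L
  if (is.null(arrays$exon_count)) arrays$exon_count <- 4L

  if (singleton_fraction > 0) {
    n_arr <- sum(arrays$n_genes)
    n_single <- round(singleton_fraction / (1 - singleton_fraction) * n_arr)
    if (n_single > 0) {
      extra <- data.frame(
        prefix = sprintf("SGL%s", LETTERS[seq_len(n_single)]),
        n_genes = 1L,
        home_block = rep(seq_len(nrow(genome$blocks)), length.out = n_single),
        promoter_cpg_obs_exp = 1,
        gene_length_bp = 6000L, exon_count = 4L)
      arrays <- rbind(arrays, extra)
    }
  }

  set.seed(as.integer(seed))
  chrom <- names(genome$seq)[1]
  seq <- genome$seq[[1]]
  blocks <- genome$blocks

  # Footprint per gene: promoter headroom + body + trailing spacer, so that
  # measured promoter windows of neighbours never overlap.
  margin <- 2000L; spacer <- 2600L
  genes <- list(); exons <- list(); truth <- list(); k <- 0L

  for (b in sort(unique(arrays$home_block))) {
    rows <- arrays[arrays$home_block == b, , drop = FALSE]
    if (b < 1 || b > nrow(blocks)) stop(sprintf("home_block %d does not exist", b))
    bl <- blocks[b, ]
    need <- sum(rows$n_genes * (rows$gene_length_bp + spacer)) + 2L * margin
    if (need > bl$length_bp)
      stop(sprintf("block %d (%d bp) cannot host %d genes needing %d bp",
                   b, bl$length_bp, sum(rows$n_genes), need))
    slack <- bl$length_bp - need
    # random extra gaps between consecutive genes, deterministic under seed
    n_b <- sum(rows$n_genes)
    gaps <- if (n_b > 0) { w <- stats::runif(n_b); floor(slack * w / sum(w)) } else integer(0)
    cursor <- bl$start + margin
    gi <- 0L
    for (a in seq_len(nrow(rows))) {
      ar <- rows[a, ]
      if (ar$n_genes == 0L) next
      for (j in seq_len(ar$n_genes)) {
        gi <- gi + 1L; k <- k + 1L
        cursor <- cursor + gaps[gi]
        len <- as.integer(ar$gene_length_bp)
        s <- as.integer(cursor + 1300L)   # promoter headroom
        e <- s + len
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        tss <- if (strand == "+") s else e - 1L
        # exon layout: exon_count exons totalling ~40% of the body,
        # first exon starts at the gene start, last ends at the gene end
        ke <- max(1L, as.integer(ar$exon_count))
        ex_len <- max(150L, as.integer(floor(len * 0.4 / ke)))
        if (ke > 1L) {
          intron <- (len - ke * ex_len) / (ke - 1L)
          if (intron < 50) { ex_len <- as.integer(floor(len * 0.3 / ke)); intron <- (len - ke * ex_len) / (ke - 1L) }
          ex_start <- s + as.integer(round((seq_len(ke) - 1L) * (ex_len + intron)))
          ex_end <- ex_start + ex_len
          ex_end[ke] <- e; ex_start[ke] <- e - ex_len
        } else { ex_start <- s; ex_end <- e }
        # CDS leaves UTRs on both ends (inside first/last exon)
        utr5 <- min(200L, ex_len %/% 2L)
        if (strand == "+") { cds_s <- s + utr5; cds_e <- e - utr5 }
        else { cds_s <- s + utr5; cds_e <- e - utr5 }
        sym <- paste0(ar$prefix, j)
        gid <- sprintf("%s_g%04d", ar$prefix, j)
        genes[[k]] <- data.frame(
          gene_id = gid, symbol = sym, chrom = chrom, strand = strand,
          start = s, end = e, tss = tss,
          cds_start = cds_s, cds_end = cds_e,
          has_five_prime_utr = TRUE, stringsAsFactors = FALSE)
        exons[[k]] <- data.frame(gene_id = gid, start = ex_start, end = ex_end)
        truth[[k]] <- data.frame(
          gene_id = gid, symbol = sym, prefix = ar$prefix,
          array_id = paste0("array_", ar$prefix), home_block = b,
          target_obs_exp = ar$promoter_cpg_obs_exp, stringsAsFactors = FALSE)
        # splice a promoter with the requested CpG obs/exp over the background
        pw <- .promoter_window(tss, strand)
        prom <- .synth_promoter(pw[2] - pw[1], bl$target_gc, ar$promoter_cpg_obs_exp)
        substr(seq, pw[1] + 1L, pw[2]) <- prom
        cursor <- e + 1300L   # trailing half of the spacer
      }
    }
  }

  genome$seq[[1]] <- seq
  gs <- if (k == 0L) .empty_gene_set(chrom) else
    new_gene_set(do.call(rbind, genes), do.call(rbind, exons))
  list(genome = genome, genes = gs,
       truth = if (k == 0L) NULL else do.call(rbind, truth))
}

#' Simulate de novo mutations, crossovers and PRDM9 peaks on a genome
#'
#' De novo mutations are per-site Bernoulli draws whose rate is multiplied at
#' CpG sites (either base of a CG dinucleotide), emulating deamination-driven
#' CpG hypermutability. Crossover and PRDM9 intensities scale per block as
#' exp(slope * block GC), emulating reduced recombination in AT-rich
#' isochores. Crossovers are emitted as refined intervals of configurable
#' width centred on the sampled point, with i.i.d. maternal/paternal labels.
#'
#' @param genome A `synth_genome` (blocks supply the GC used for the slopes).
#' @param dnm_base_rate Per-bp probability of a DNM at a non-CpG site.
#' @param dnm_cpg_multiplier Rate multiplier (>= 1) at CpG sites.
#' @param crossover_base_rate Per-bp crossover intensity at GC = 0.
#' @param crossover_gc_slope Log-linear GC slope of crossover intensity.
#' @param crossover_interval_bp Width of the emitted crossover interval.
#' @param maternal_fraction Probability a crossover is labelled maternal.
#' @param prdm9_peak_rate Per-bp PRDM9 peak intensity at GC = 0.
#' @param prdm9_gc_slope Log-linear GC slope of peak intensity.
#' @param prdm9_peak_bp Width of emitted peaks.
#' @param seed Integer seed.
#' @return List of data.frames: `dnm` (chrom, pos, study), `crossover`
#'   (chrom, start, end, sex), `prdm9` (chrom, start, end, enrichment).
#' @export
simulate_events <- function(genome,
                            dnm_base_rate = 5e-4, dnm_cpg_multiplier = 10,
                            crossover_base_rate = 1e-4, crossover_gc_slope = 2,
                            crossover_interval_bp = 1000L, maternal_fraction = 0.5,
                            prdm9_peak_rate = 5e-5, prdm9_gc_slope = 2,
                            prdm9_peak_bp = 300L, seed = 1L) {
  stopifnot(inherits(genome, "synth_genome"),
            dnm_base_rate >= 0, dnm_cpg_multiplier >= 1,
            crossover_base_rate >= 0, prdm9_peak_rate >= 0)
  set.seed(as.integer(seed))
  chrom <- names(genome$seq)[1]
  seq <- genome$seq[[1]]
  L <- nchar(seq)

  # DNMs: per-site Bernoulli, CpG sites at multiplied rate
  dnm <- data.frame(chrom = character(0), pos = integer(0), study = character(0))
  if (dnm_base_rate > 0) {
    r <- charToRaw(seq)
    isC <- r == as.raw(67L); isG <- r == as.raw(71L)
    cpg_site <- logical(L)
    cg <- which(isC[-L] & isG[-1L])
    cpg_site[cg] <- TRUE; cpg_site[cg + 1L] <- TRUE
    p <- ifelse(cpg_site, pmin(1, dnm_base_rate * dnm_cpg_multiplier), dnm_base_rate)
    hit <- which(stats::runif(L) < p)
    if (length(hit))
      dnm <- data.frame(chrom = chrom, pos = hit - 1L, study = "sim")
  }

  # block-wise Poisson processes with log-linear GC intensity
  .block_points <- function(base, slope) {
    out <- integer(0)
    for (i in seq_len(nrow(genome$blocks))) {
      bl <- genome$blocks[i, ]
      lam <- base * exp(slope * bl$gc) * bl$length_bp
      n <- stats::rpois(1, lam)
      if (n > 0)
        out <- c(out, as.integer(floor(stats::runif(n, bl$start, bl$end))))
    }
    sort(out)
  }

  xo <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   sex = character(0))
  if (crossover_base_rate > 0) {
    ctr <- .block_points(crossover_base_rate, crossover_gc_slope)
    if (length(ctr)) {
      h <- as.integer(crossover_interval_bp) %/% 2L
      xo <- data.frame(chrom = chrom,
                       start = pmax(0L, ctr - h),
                       end = pmin(L, ctr + h),
                       sex = ifelse(stats::runif(length(ctr)) < maternal_fraction,
                                    "maternal", "paternal"))
    }
  }

  pk <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   enrichment = numeric(0))
  if (prdm9_peak_rate > 0) {
    ctr <- .block_points(prdm9_peak_rate, prdm9_gc_slope)
    if (length(ctr)) {
      h <- as.integer(prdm9_peak_bp) %/% 2L
      pk <- data.frame(chrom = chrom,
                       start = pmax(0L, ctr - h), end = pmin(L, ctr + h),
                       enrichment = stats::rlnorm(length(ctr), 0, 1))
    }
  }
  list(dnm = dnm, crossover = xo, prdm9 = pk)
}

#' Simulate a multi-species tandem-array panel on a phylogeny
#'
#' Log paralog counts evolve by Brownian motion on the tree; cluster GC is
#' `a + b * log(paralog_count)` plus a phylogenetic residual drawn from a
#' Brownian covariance whose off-diagonals are scaled by `lambda_true`
#' (Pagel's lambda transform). This emulates the cross-species log-linear
#' relationship between array GC and paralog number that the PGLS module
#' estimates.
#'
#' @param tree A rooted `phylo` tree with branch lengths (>= 4 tips).
#'   Non-ultrametric trees are accepted with a warning.
#' @param a,b Intercept and slope (GC per unit natural-log paralog count).
#' @param bm_sigma2_logN Brownian rate of log paralog count.
#' @param bm_sigma2_resid Brownian rate of the GC residual.
#' @param lambda_true Pagel's lambda of the residual covariance, in \[0,1\].
#' @param root_log_paralog Root state of log paralog count.
#' @param seed Integer seed.
#' @return List with `table` (species, paralog_count, log_paralog,
#'   cluster_gc), `tree`, and `truth` (the generating parameters plus the
#'   number of GC values clamped into (0,1)).
#' @export
simulate_species_panel <- function(tree, a = 0.45, b = -0.02,
                                   bm_sigma2_logN = 0.5,
                                   bm_sigma2_resid = 4e-4,
                                   lambda_true = 1,
                                   root_log_paralog = log(20), seed = 1L) {
  stopifnot(inherits(tree, "phylo"), lambda_true >= 0, lambda_true <= 1,
            bm_sigma2_logN >= 0, bm_sigma2_resid >= 0)
  if (length(tree$tip.label) < 4L) stop("tree must have at least 4 tips")
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    warning("tree is not ultrametric; lambda transform is still defined")
  set.seed(as.integer(seed))
  C <- ape::vcv(tree)
  n <- nrow(C)
  z <- root_log_paralog +
    drop(t(chol(bm_sigma2_logN * C + diag(1e-12, n))) %*% stats::rnorm(n))
  paralog <- pmax(1L, as.integer(round(exp(z))))
  Cl <- C * lambda_true; diag(Cl) <- diag(C)
  eps <- drop(t(chol(bm_sigma2_resid * Cl + diag(1e-12, n))) %*% stats::rnorm(n))
  gc <- a + b * log(paralog) + eps
  clamped <- sum(gc <= 0 | gc >= 1)
  gc <- pmin(0.99, pmax(0.01, gc))
  list(
    table = data.frame(species = rownames(C), paralog_count = paralog,
                       log_paralog = log(paralog), cluster_gc = gc,
                       stringsAsFactors = FALSE),
    tree = tree,
    truth = list(a = a, b = b, lambda = lambda_true,
                 bm_sigma2_logN = bm_sigma2_logN,
                 bm_sigma2_resid = bm_sigma2_resid, n_clamped = clamped)
  )
}
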