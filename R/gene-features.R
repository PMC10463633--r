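# Per-gene local sequence features: feature-wise GC, metagene GC
# trajectories, and promoter CpG observed/expected scores.
#
# The promoter window is -750/+250 bp around the TSS in transcript
# orientation; every GC quantity excludes N bases from both numerator and
# denominator and is strand-symmetric (G+C is its own reverse complement),
# so no reverse-complementing is ever needed -- only coordinate arithmetic.

#' Feature-wise GC content for each gene
#'
#' Computes GC fractions over the promoter (-750/+250 around the TSS,
#' strand-aware), 1-kb and 25-kb flanks (both sides, excluding the gene
#' body), exons, introns (body minus exons), CDS (exons intersected with the
#' CDS span) and the whole body (TSS--TES). Windows are truncated at
#' chromosome ends; a feature with no called base is `NA`.
#'
#' @param genes A `gene_set`.
#' @param seqs Named character vector of chromosome sequences, or a
#'   `synth_genome`.
#' @return data.frame with one row per gene: gene_id, promoter_gc,
#'   flank1_gc, flank25_gc, exon_gc, intron_gc, cds_gc, body_gc.
#' @export
feature_gc <- function(genes, seqs) {
  stopifnot(inherits(genes, "gene_set"))
  seqs <- .get_seqs(seqs)
  cums_by_chrom <- lapply(seqs, .seq_cums)
  g <- genes$genes
  out <- data.frame(gene_id = g$gene_id,
                    promoter_gc = NA_real_, flank1_gc = NA_real_,
                    flank25_gc = NA_real_, exon_gc = NA_real_,
                    intron_gc = NA_real_, cds_gc = NA_real_,
                    body_gc = NA_real_)
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    cums <- cums_by_chrom[[gi$chrom]]
    if (is.null(cums)) { warning("no sequence for ", gi$chrom); next }
    pw <- .promoter_window(gi$tss, gi$strand)
    if (min(pw[2], cums$len) <= max(pw[1], 0L))
      warning("empty promoter window for ", gi$gene_id)
    out$promoter_gc[i] <- .gc_window(cums, pw[1], pw[2])
    out$flank1_gc[i] <- .gc_intervals(cums,
      c(gi$start - 1000L, gi$end), c(gi$start, gi$end + 1000L))
    out$flank25_gc[i] <- .gc_intervals(cums,
      c(gi$start - 25000L, gi$end), c(gi$start, gi$end + 25000L))
    ex <- genes$exons[genes$exons$gene_id == gi$gene_id, , drop = FALSE]
    out$exon_gc[i] <- .gc_intervals(cums, ex$start, ex$end)
    intr <- .setdiff_intervals(data.frame(start = gi$start, end = gi$end),
                               ex[, c("start", "end")])
    out$intron_gc[i] <- .gc_intervals(cums, intr$start, intr$end)
    if (!is.na(gi$cds_start)) {
      cds <- .intersect_intervals(ex[, c("start", "end")],
                                  data.frame(start = gi$cds_start, end = gi$cds_end))
      out$cds_gc[i] <- .gc_intervals(cums, cds$start, cds$end)
    }
    out$body_gc[i] <- .gc_window(cums, gi$start, gi$end)
  }
  out
}

#' Metagene GC trajectory matrix
#'
#' For each gene: GC fractions in fixed `window_bp` non-overlapping windows
#' over the upstream flank, `body_bins` equal-width bins over the gene body
#' (TSS to TES, scaled so rows are comparable across gene lengths), and
#' fixed windows over the downstream flank. Index 1 is the 5' end for every
#' gene regardless of strand. Windows with no called base (or entirely off
#' the contig) are `NA`.
#'
#' @param genes A `gene_set`.
#' @param seqs Named character vector of sequences or a `synth_genome`.
#' @param body_bins Number of scaled body bins (default 100).
#' @param flank_bp Flank length in bp on each side (default 1000).
#' @param window_bp Fixed flank window width (default 50).
#' @return Numeric matrix, one row per gene (rownames = gene_id), with
#'   `2 * flank_bp / window_bp + body_bins` columns; attribute
#'   `flank_windows` records the per-flank window count.
#' @export
gc_trajectory <- function(genes, seqs, body_bins = 100L, flank_bp = 1000L,
                          window_bp = 50L) {
  stopifnot(inherits(genes, "gene_set"), flank_bp %% window_bp == 0)
  seqs <- .get_seqs(seqs)
  cums_by_chrom <- lapply(seqs, .seq_cums)
  nf <- as.integer(flank_bp / window_bp)
  g <- genes$genes
  M <- matrix(NA_real_, nrow(g), 2L * nf + body_bins,
              dimnames = list(g$gene_id, NULL))
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    cums <- cums_by_chrom[[gi$chrom]]
    if (is.null(cums)) next
    if (gi$end - gi$start < 1L) stop("gene of zero length: ", gi$gene_id)
    left <- vapply(seq_len(nf) - 1L, function(k)
      .gc_window(cums, gi$start - flank_bp + k * window_bp,
                 gi$start - flank_bp + (k + 1L) * window_bp), 0)
    w <- (gi$end - gi$start) / body_bins
    body <- vapply(seq_len(body_bins), function(k)
      .gc_window(cums, gi$start + floor((k - 1L) * w),
                 gi$start + ceiling(k * w)), 0)
    right <- vapply(seq_len(nf) - 1L, function(k)
      .gc_window(cums, gi$end + k * window_bp,
                 gi$end + (k + 1L) * window_bp), 0)
    v <- c(left, body, right)
    if (gi$strand == "-") v <- rev(v)
    M[i, ] <- v
  }
  attr(M, "flank_windows") <- nf
  attr(M, "body_bins") <- as.integer(body_bins)
  M
}

#' CpG observed/expected score of a sequence window
#'
#' Observed = count of CG dinucleotides; expected = nC * nG / L with L the
#' number of called bases (Gardiner-Garden form). The ratio is `NA`
#' (undefined, not zero) when the expectation is zero.
#'
#' @param seq Character scalar (e.g. a promoter window).
#' @return List with `observed`, `expected`, `obs_exp`.
#' @examples
#' cpg_score("CGCG")  # observed 2, expected 1, obs_exp 2
#' @export
cpg_score <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  obs <- .cpg_count(seq, 0L, L)
  bc <- .base_counts(seq, 0L, L)
  n_called <- sum(bc)
  expd <- if (n_called > 0) bc[["C"]] * bc[["G"]] / n_called else 0
  list(observed = obs, expected = expd,
       obs_exp = if (expd > 0) obs / expd else NA_real_)
}

#' Promoter CpG observed/expected per gene
#'
#' Applies [cpg_score()] to each gene's -750/+250 promoter window
#' (strand-aware, clipped at contig ends). CpG dinucleotides are counted on
#' the plus strand of the reference; the CG dinucleotide class is
#' strand-symmetric.
#'
#' @param genes A `gene_set`.
#' @param seqs Named character vector of sequences or a `synth_genome`.
#' @return data.frame: gene_id, observed_cpg, expected_cpg, obs_exp.
#' @export
cpg_obs_exp <- function(genes, seqs) {
  stopifnot(inherits(genes, "gene_set"))
  seqs <- .get_seqs(seqs)
  g <- genes$genes
  out <- data.frame(gene_id = g$gene_id, observed_cpg = NA_integer_,
                    expected_cpg = NA_real_, obs_exp = NA_real_)
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    seq <- seqs[[gi$chrom]]
    if (is.null(seq)) next
    pw <- .promoter_window(gi$tss, gi$strand)
    a <- max(0L, pw[1]); b <- min(nchar(seq), pw[2])
    if (b <= a) { warning("empty promoter window for ", gi$gene_id); next }
    sc <- cpg_score(substr(seq, a + 1L, b))
    out$observed_cpg[i] <- sc$observed
    out$expected_cpg[i] <- sc$expected
    out$obs_exp[i] <- sc$obs_exp
  }
  out
}
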