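# Recursive GC-divergence segmentation of a chromosome into isochores.
#
# For the current segment [a, b), every split point i is scored by the
# weighted squared GC difference
#
#     delta(i) = (nL * nR / N) * (pL - pR)^2
#
# with nL, nR the called (non-N) base counts and pL, pR the GC fractions of
# the two sides, N = nL + nR. The best split i* = argmax delta(i) is accepted
# iff the scaled halting statistic
#
#     s(i*) = 4 * delta(i*) / (p * (1 - p)),   p = parent GC fraction
#
# exceeds the threshold t0 and both children are at least min_segment_bp
# long; accepted children are segmented recursively. s is approximately four
# times the binomial log-likelihood-ratio statistic for a single changepoint,
# which makes t0 a scale-free, length-aware halting rule: homogeneous
# sequence stays whole no matter how long it is, while a genuine GC shift
# grows s linearly with segment length. The default t0 = 275 reproduces the
# isochore-scale resolution used for hg38 (4328 isochores).
#
# Runs of >= hard_gap_bp N bases are hard assembly gaps: they are never part
# of a segment and cannot be crossed by one. After segmentation, segments
# that are mostly N are removed; removed gaps shorter than
# gap_filter_fraction of the input are dropped from the gap report entirely
# ("filtered out"), longer ones are reported alongside the isochores.

# Vectorised argmax of delta(i) over all splits of [a, b).
.best_split <- function(cums, a, b) {
  if (b - a < 2L) return(NULL)
  i <- (a + 1L):(b - 1L)
  nL <- cums$base[i + 1L] - cums$base[a + 1L]
  gL <- cums$gc[i + 1L] - cums$gc[a + 1L]
  nTot <- cums$base[b + 1L] - cums$base[a + 1L]
  gTot <- cums$gc[b + 1L] - cums$gc[a + 1L]
  nR <- nTot - nL; gR <- gTot - gL
  ok <- nL > 0L & nR > 0L
  if (!any(ok)) return(NULL)
  delta <- rep(-Inf, length(i))
  delta[ok] <- (nL[ok] * nR[ok] / nTot) * (gL[ok] / nL[ok] - gR[ok] / nR[ok])^2
  j <- which.max(delta)                       # ties: lowest coordinate
  p <- gTot / nTot
  s <- if (p <= 0 || p >= 1) -Inf else 4 * delta[j] / (p * (1 - p))
  list(split = i[j], delta = delta[j], s = s)
}

# Segment one gap-free piece [a, b); returns integer breakpoints (excluding
# a and b). Iterative stack in place of recursion.
.segment_piece <- function(cums, a, b, t0, min_bp) {
  brk <- integer(0)
  stack <- list(c(a, b))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    bs <- .best_split(cums, seg[1], seg[2])
    if (is.null(bs) || !is.finite(bs$s) || bs$s <= t0) next
    if (bs$split - seg[1] < min_bp || seg[2] - bs$split < min_bp) next
    brk <- c(brk, bs$split)
    stack[[length(stack) + 1L]] <- c(seg[1], bs$split)
    stack[[length(stack) + 1L]] <- c(bs$split, seg[2])
  }
  sort(brk)
}

#' Segment a chromosome into isochores
#'
#' Recursive binary segmentation on GC content (see the package vignette for
#' the divergence statistic and halting rule). N bases are excluded from all
#' GC fractions; runs of at least `hard_gap_bp` Ns are assembly gaps that no
#' segment may cross.
#'
#' @param seq Character scalar over A/C/G/T/N (case-insensitive), or a
#'   `synth_genome` (its single chromosome is used).
#' @param t0 Halting threshold (dimensionless; default 275).
#' @param min_segment_bp Minimum child segment length in bp (default 3000).
#' @param gap_filter_fraction Gaps shorter than this fraction of the input
#'   are filtered out of the gap report (default 0.01).
#' @param hard_gap_bp Minimum N-run length treated as a hard gap (default 1000).
#' @param chrom Chromosome name attached to the output.
#' @return data.frame of isochores (`id`, `chrom`, `start`, `end`,
#'   `gc_fraction`; 0-based half-open, disjoint, sorted) with attribute
#'   `removed_gaps`, a data.frame of removed intervals (`why` is
#'   `hard_gap` or `mostly_n`, `filtered` marks gaps below the reporting
#'   threshold). Empty or all-N input gives zero rows.
#' @examples
#' g <- make_genome(data.frame(length_bp = c(20000, 20000),
#'                             target_gc = c(0.3, 0.6)), seed = 1)
#' segment_sequence(g, min_segment_bp = 3000)
#' @export
segment_sequence <- function(seq, t0 = 275, min_segment_bp = 3000L,
                             gap_filter_fraction = 0.01, hard_gap_bp = 1000L,
                             chrom = NULL) {
  if (inherits(seq, "synth_genome")) {
    if (is.null(chrom)) chrom <- names(seq$seq)[1]
    seq <- seq$seq[[1]]
  }
  if (is.null(chrom)) chrom <- "chr1"
  stopifnot(is.character(seq), length(seq) == 1L, t0 > 0, min_segment_bp >= 1)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence alphabet must be A/C/G/T/N")
  L <- nchar(seq)
  empty <- data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      gc_fraction = numeric(0))
  gaps0 <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), why = character(0),
                      filtered = logical(0))
  if (L == 0L) { attr(empty, "removed_gaps") <- gaps0; return(empty) }

  cums <- .seq_cums(seq)
  hard <- .n_runs(seq, min_run = as.integer(hard_gap_bp))
  # gap-free pieces between hard gaps
  cuts <- c(0L, as.vector(t(as.matrix(hard[, c("start", "end")]))), L)
  pieces <- matrix(cuts, ncol = 2L, byrow = TRUE)

  segs <- list(); removed <- list()
  if (nrow(hard))
    removed[[1L]] <- data.frame(chrom = chrom, start = hard$start,
                                end = hard$end, why = "hard_gap")
  for (r in seq_len(nrow(pieces))) {
    a <- pieces[r, 1L]; b <- pieces[r, 2L]
    if (b <= a) next
    brk <- .segment_piece(cums, a, b, t0, as.integer(min_segment_bp))
    bounds <- c(a, brk, b)
    for (k in seq_len(length(bounds) - 1L)) {
      s <- bounds[k]; e <- bounds[k + 1L]
      nb <- .cum_count(cums$base, s, e)
      if (nb < 0.5 * (e - s)) {
        removed[[length(removed) + 1L]] <-
          data.frame(chrom = chrom, start = s, end = e, why = "mostly_n")
      } else {
        segs[[length(segs) + 1L]] <-
          data.frame(chrom = chrom, start = s, end = e,
                     gc_fraction = .gc_window(cums, s, e))
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else empty[, -1L]
  if (nrow(out)) {
    out <- out[order(out$start), , drop = FALSE]
    out <- cbind(id = sprintf("%s_iso%04d", chrom, seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
  } else out <- empty
  rg <- if (length(removed)) do.call(rbind, removed) else gaps0[, 1:4]
  if (nrow(rg)) rg$filtered <- (rg$end - rg$start) < gap_filter_fraction * L
  else rg$filtered <- logical(0)
  attr(out, "removed_gaps") <- rg[order(rg$start), , drop = FALSE]
  out
}

#' Rank isochores by GC and bin them into deciles
#'
#' Rank 1 is the highest-GC isochore; decile 1 holds the most AT-rich tenth
#' (decile index increases with GC). Bin sizes differ by at most one; ties
#' in GC are broken by (chrom, start).
#'
#' @param isochores data.frame from [segment_sequence()] (possibly
#'   concatenated across chromosomes) with `gc_fraction` populated.
#' @return The same data.frame with `rank` and `decile` columns added.
#' @export
rank_and_decile <- function(isochores) {
  stopifnot(is.data.frame(isochores), "gc_fraction" %in% names(isochores))
  K <- nrow(isochores)
  if (K == 0L) { isochores$rank <- integer(0); isochores$decile <- integer(0); return(isochores) }
  if (K < 10L) warning("fewer than 10 isochores; some deciles will be empty")
  o_desc <- order(-isochores$gc_fraction, isochores$chrom, isochores$start)
  isochores$rank[o_desc] <- seq_len(K)
  o_asc <- order(isochores$gc_fraction, isochores$chrom, isochores$start)
  sizes <- rep(K %/% 10L, 10L)
  extra <- K %% 10L
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  isochores$decile[o_asc] <- rep(1:10, times = sizes)
  isochores
}

#' Assign each gene to its home isochore by TSS
#'
#' A gene's home isochore is the unique isochore whose half-open span
#' contains its transcription start site. Genes whose TSS falls in a removed
#' gap (or on a chromosome absent from the isochore set, with a warning) are
#' unassigned (`NA`).
#'
#' @param genes A `gene_set` or data.frame with gene_id, chrom, tss.
#' @param isochores data.frame with id, chrom, start, end.
#' @return Character vector of isochore ids named by gene_id (`NA` =
#'   unassigned).
#' @export
assign_home_isochore <- function(genes, isochores) {
  g <- if (inherits(genes, "gene_set")) genes$genes else genes
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(g)))
  out <- stats::setNames(rep(NA_character_, nrow(g)), g$gene_id)
  miss_chr <- setdiff(unique(g$chrom), unique(isochores$chrom))
  if (length(miss_chr))
    warning("no isochores on chromosome(s): ", paste(miss_chr, collapse = ", "))
  for (ch in intersect(unique(g$chrom), unique(isochores$chrom))) {
    iso <- isochores[isochores$chrom == ch, , drop = FALSE]
    iso <- iso[order(iso$start), , drop = FALSE]
    gi <- which(g$chrom == ch)
    idx <- findInterval(g$tss[gi], iso$start)
    hit <- idx >= 1L & g$tss[gi] < iso$end[pmax(idx, 1L)]
    out[gi[hit]] <- iso$id[idx[hit]]
  }
  out
}

#' Write isochores as a BED4+ track
#'
#' Columns: chrom, start, end, name (= rank), score (= floor(1000 * GC)),
#' then gc_fraction and decile as extra columns.
#'
#' @param isochores Ranked isochore data.frame (see [rank_and_decile()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isochores_bed <- function(isochores, path) {
  stopifnot(all(c("rank", "decile") %in% names(isochores)))
  bed <- data.frame(isochores$chrom, isochores$start, isochores$end,
                    isochores$rank, floor(1000 * isochores$gc_fraction),
                    round(isochores$gc_fraction, 6), isochores$decile)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
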