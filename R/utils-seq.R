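# Internal sequence helpers.
#
# Sequences are plain uppercase character strings over {A,C,G,T,N}; all
# coordinates are 0-based half-open [start, end) unless a function says
# otherwise. GFF3 (1-based closed) is converted at the I/O boundary only.

# Per-base flags for a chromosome string: is the base G/C, and is it a
# called (non-N) base. Computed once per chromosome and reused.
.seq_flags <- function(seq) {
  r <- charToRaw(seq)
  list(
    is_gc   = r == as.raw(71L) | r == as.raw(67L),   # 'G', 'C'
    is_base = r != as.raw(78L)                       # not 'N'
  )
}

# Cumulative GC / non-N counts with a leading 0, so that counts over
# [start, end) are cum[end + 1] - cum[start + 1].
.seq_cums <- function(seq) {
  fl <- .seq_flags(seq)
  list(
    gc   = c(0, cumsum(as.integer(fl$is_gc & fl$is_base))),
    base = c(0, cumsum(as.integer(fl$is_base))),
    len  = nchar(seq)
  )
}

.cum_count <- function(cum, start, end) cum[end + 1L] - cum[start + 1L]

# GC fraction of [start, end) on a chromosome, N bases excluded from both
# numerator and denominator; NA when the window holds no called base.
.gc_window <- function(cums, start, end) {
  start <- max(0L, as.integer(start)); end <- min(cums$len, as.integer(end))
  if (end <= start) return(NA_real_)
  nb <- .cum_count(cums$base, start, end)
  if (nb == 0L) return(NA_real_)
  .cum_count(cums$gc, start, end) / nb
}

#' GC fraction of a DNA string
#'
#' Fraction of called (non-N) bases that are G or C. Strand-symmetric.
#'
#' @param seq Character scalar over the alphabet A/C/G/T/N (case-insensitive).
#' @return A fraction in \[0, 1\], or `NA` if the string has no called base.
#' @examples
#' gc_content("GGCC")   # 1
#' gc_content("ACGTN")  # 0.5, the N is excluded
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cums <- .seq_cums(toupper(seq))
  .gc_window(cums, 0L, cums$len)
}

# GC fraction over a union of disjoint [start, end) intervals (two integer
# vectors), N-excluded, NA when the union has no called base.
.gc_intervals <- function(cums, starts, ends) {
  if (length(starts) == 0L) return(NA_real_)
  starts <- pmax(0L, as.integer(starts)); ends <- pmin(cums$len, as.integer(ends))
  keep <- ends > starts
  if (!any(keep)) return(NA_real_)
  nb <- sum(.cum_count(cums$base, starts[keep], ends[keep]))
  if (nb == 0L) return(NA_real_)
  sum(.cum_count(cums$gc, starts[keep], ends[keep])) / nb
}

# Runs of N of at least `min_run` bp: data.frame(start, end), 0-based half-open.
.n_runs <- function(seq, min_run = 1L) {
  r <- charToRaw(seq) == as.raw(78L)
  if (!any(r)) return(data.frame(start = integer(0), end = integer(0)))
  rl <- rle(r)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths
  keep <- rl$values & rl$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

# Count occurrences of the dinucleotide CG in [start, end) of a chromosome
# string (plus strand; CpG is strand-symmetric as a dinucleotide class).
.cpg_count <- function(seq, start, end) {
  if (end - start < 2L) return(0L)
  win <- substr(seq, start + 1L, end)
  m <- gregexpr("CG", win, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

# Base composition of [start, end): counts of A, C, G, T (N ignored).
.base_counts <- function(seq, start, end) {
  win <- substr(seq, start + 1L, end)
  r <- charToRaw(win)
  c(A = sum(r == as.raw(65L)), C = sum(r == as.raw(67L)),
    G = sum(r == as.raw(71L)), T = sum(r == as.raw(84L)))
}

# Clip intervals to [0, len) and drop empties. df has start/end columns.
.clip_intervals <- function(df, len) {
  df$start <- pmax(0L, df$start); df$end <- pmin(len, df$end)
  df[df$end > df$start, , drop = FALSE]
}
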