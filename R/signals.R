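# Population-genetic and regulatory overlays on isochores and genes: DNM
# densities, crossover rates, PRDM9 enrichment, rare-variant ratios,
# expression breadth, and A/B compartment consensus.

# midpoint of a refined interval ("median of the two endpoints")
.interval_mid <- function(start, end) as.integer(floor((start + end) / 2))

# assign positions to disjoint regions of one chromosome set; returns region
# row index or NA
.assign_to_regions <- function(chrom, pos, regions) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    r <- which(regions$chrom == ch)
    if (!length(r)) next
    rr <- r[order(regions$start[r])]
    p <- which(chrom == ch)
    fi <- findInterval(pos[p], regions$start[rr])
    hit <- fi >= 1L & pos[p] < regions$end[rr[pmax(fi, 1L)]]
    idx[p[hit]] <- rr[fi[hit]]
  }
  idx
}

# merged [start,tes) gene spans per isochore, from home-isochore assignment
.genic_spans_by_isochore <- function(genes, isochores) {
  g <- if (inherits(genes, "gene_set")) genes$genes else genes
  home <- assign_home_isochore(g, isochores)
  spans <- data.frame(iso = home[g$gene_id], chrom = g$chrom,
                      start = pmin(g$start, g$end), end = pmax(g$start, g$end))
  spans <- spans[!is.na(spans$iso), , drop = FALSE]
  lapply(split(spans, spans$iso), function(df) {
    u <- .union_intervals(df[, c("start", "end")])
    u$chrom <- df$chrom[1]
    u
  })
}

#' De novo mutation density per isochore
#'
#' Pools DNMs (deduplicated by chrom/pos) over each isochore's genic space
#' (the merged TSS--TES spans of its home genes) and over the whole
#' isochore, and reports both densities per kb. Isochores with no genes get
#' `NA` genic density.
#'
#' @param dnms data.frame with chrom, pos (0-based).
#' @param isochores Isochore data.frame (id, chrom, start, end).
#' @param genes A `gene_set` (or genes data.frame with gene_id, chrom, tss,
#'   start, end).
#' @return data.frame: isochore_id, genic_dnm, genic_kb,
#'   genic_density_per_kb, iso_dnm, iso_kb, iso_density_per_kb.
#' @export
dnm_density <- function(dnms, isochores, genes) {
  stopifnot(all(c("chrom", "pos") %in% names(dnms)))
  d <- unique(dnms[, c("chrom", "pos")])
  spans <- .genic_spans_by_isochore(genes, isochores)
  out <- data.frame(isochore_id = isochores$id,
                    genic_dnm = NA_integer_, genic_kb = NA_real_,
                    genic_density_per_kb = NA_real_,
                    iso_dnm = 0L, iso_kb = (isochores$end - isochores$start) / 1000,
                    iso_density_per_kb = NA_real_)
  idx <- .assign_to_regions(d$chrom, d$pos, isochores)
  tab <- table(factor(idx, levels = seq_len(nrow(isochores))))
  out$iso_dnm <- as.integer(tab)
  out$iso_density_per_kb <- out$iso_dnm / out$iso_kb
  for (iso in names(spans)) {
    i <- match(iso, isochores$id)
    if (is.na(i)) next
    sp <- spans[[iso]]
    kb <- sum(sp$end - sp$start) / 1000
    dd <- d[d$chrom == sp$chrom[1], , drop = FALSE]
    n <- 0L
    if (nrow(dd) && nrow(sp))
      n <- sum(vapply(dd$pos, function(p) any(p >= sp$start & p < sp$end), NA))
    out$genic_dnm[i] <- n
    out$genic_kb[i] <- kb
    out$genic_density_per_kb[i] <- if (kb > 0) n / kb else NA_real_
  }
  out
}

#' Sex-specific relative crossover rates over regions
#'
#' Each crossover is assigned to the region containing the midpoint of its
#' refined interval. The relative rate of a region is its per-bp count
#' divided by the per-bp genomic average for that sex, so the length-weighted
#' mean over a complete tiling is exactly 1.
#'
#' @param crossovers data.frame with chrom, start, end, sex
#'   ("maternal"/"paternal").
#' @param regions Disjoint regions: data.frame with chrom, start, end and
#'   optionally id.
#' @param include_unassigned Count crossovers falling outside all regions in
#'   the genomic-average denominator (default TRUE).
#' @param standardize "relative" (genome mean 1, default) or "zscore"
#'   (rates standardized across regions within sex).
#' @return data.frame, one row per region x sex: region_id, sex, count,
#'   rate_per_kb, rel_rate (or zscore).
#' @export
crossover_rate <- function(crossovers, regions, include_unassigned = TRUE,
                           standardize = c("relative", "zscore")) {
  standardize <- match.arg(standardize)
  stopifnot(all(c("chrom", "start", "end", "sex") %in% names(crossovers)),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (is.null(regions$id))
    regions$id <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  # regions must be disjoint
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop("regions must be disjoint")
  }
  mid <- .interval_mid(crossovers$start, crossovers$end)
  idx <- .assign_to_regions(crossovers$chrom, mid, regions)
  len <- regions$end - regions$start
  tot_len <- sum(len)
  out <- list()
  for (sx in unique(crossovers$sex)) {
    sel <- crossovers$sex == sx
    counts <- as.integer(table(factor(idx[sel], levels = seq_len(nrow(regions)))))
    tot <- if (include_unassigned) sum(sel) else sum(counts)
    dens <- counts / len
    gavg <- tot / tot_len
    res <- data.frame(region_id = regions$id, sex = sx, count = counts,
                      rate_per_kb = dens * 1000,
                      rel_rate = if (gavg > 0) dens / gavg else NA_real_,
                      stringsAsFactors = FALSE)
    if (standardize == "zscore")
      res$zscore <- as.numeric(scale(res$rate_per_kb))
    out[[sx]] <- res
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-gene relative crossover rates over gene +/- flank windows
#'
#' Gene-level variant of [crossover_rate()]: each gene's window is its span
#' extended by `flank_bp` on both sides; windows may overlap, and a
#' crossover midpoint contributes to every window containing it. The
#' genomic average per sex uses the total crossover count over
#' `genome_bp` bases.
#'
#' @param crossovers data.frame with chrom, start, end, sex.
#' @param genes A `gene_set`.
#' @param genome_bp Named numeric of chromosome lengths (or a single total).
#' @param flank_bp Flank on each side (default 25000).
#' @return data.frame: gene_id, sex, count, rel_rate.
#' @export
crossover_gene_rate <- function(crossovers, genes, genome_bp, flank_bp = 25000L) {
  g <- if (inherits(genes, "gene_set")) genes$genes else genes
  mid <- .interval_mid(crossovers$start, crossovers$end)
  win_s <- pmax(0L, g$start - flank_bp); win_e <- g$end + flank_bp
  tot_bp <- sum(genome_bp)
  out <- list()
  for (sx in unique(crossovers$sex)) {
    sel <- crossovers$sex == sx
    gavg <- sum(sel) / tot_bp
    counts <- vapply(seq_len(nrow(g)), function(i)
      sum(crossovers$chrom[sel] == g$chrom[i] &
            mid[sel] >= win_s[i] & mid[sel] < win_e[i]), 0L)
    out[[sx]] <- data.frame(gene_id = g$gene_id, sex = sx, count = counts,
                            rel_rate = (counts / (win_e - win_s)) / gavg,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' PRDM9 peak enrichment over isochore genic space
#'
#' Retains the top `top_fraction` of peaks by enrichment score (all peaks
#' tied at the cutoff value are included), then adds each retained peak's
#' full enrichment to the isochore whose genic span (merged TSS--TES union
#' of its home genes) contains the peak midpoint. Reports the raw sum and
#' the sum per genic kb.
#'
#' @param peaks data.frame with chrom, start, end, enrichment (> 0).
#' @param isochores Isochore data.frame.
#' @param genes A `gene_set`.
#' @param top_fraction Fraction of peaks retained (default 0.10).
#' @return data.frame: isochore_id, sum_enrichment, genic_kb,
#'   density_per_kb; attributes `n_retained` and `cutoff`.
#' @export
prdm9_enrichment <- function(peaks, isochores, genes, top_fraction = 0.10) {
  stopifnot(all(c("chrom", "start", "end", "enrichment") %in% names(peaks)),
            all(peaks$enrichment > 0))
  out <- data.frame(isochore_id = isochores$id, sum_enrichment = 0,
                    genic_kb = NA_real_, density_per_kb = NA_real_)
  n <- nrow(peaks)
  if (n == 0L) { attr(out, "n_retained") <- 0L; return(out) }
  kth <- ceiling(top_fraction * n)
  cutoff <- sort(peaks$enrichment, decreasing = TRUE)[kth]
  keep <- peaks[peaks$enrichment >= cutoff, , drop = FALSE]
  spans <- .genic_spans_by_isochore(genes, isochores)
  mid <- .interval_mid(keep$start, keep$end)
  for (iso in names(spans)) {
    i <- match(iso, isochores$id)
    if (is.na(i)) next
    sp <- spans[[iso]]
    out$genic_kb[i] <- sum(sp$end - sp$start) / 1000
    inside <- keep$chrom == sp$chrom[1] &
      vapply(mid, function(p) any(p >= sp$start & p < sp$end), NA)
    out$sum_enrichment[i] <- sum(keep$enrichment[inside])
    out$density_per_kb[i] <- out$sum_enrichment[i] / out$genic_kb[i]
  }
  attr(out, "n_retained") <- nrow(keep)
  attr(out, "cutoff") <- cutoff
  out
}

#' Non-synonymous / synonymous rare-variant ratios
#'
#' Per gene: (missense + LoF) / synonymous, missing when the gene has no
#' synonymous variants. Pooled per group: sum(missense + LoF) / sum(syn),
#' which is robust to per-gene zeros (a syn = 0 gene still contributes its
#' non-synonymous counts to the pooled numerator).
#'
#' @param records data.frame with gene_id, syn, missense, lof and optionally
#'   pli.
#' @param group Optional grouping vector (same length as rows) or column
#'   name in `records`.
#' @return List with `per_gene` (gene_id, ratio) and `pooled` (group,
#'   nonsyn, syn, ratio; a single "all" group when `group` is NULL).
#' @export
variant_ratio <- function(records, group = NULL) {
  stopifnot(all(c("gene_id", "syn", "missense", "lof") %in% names(records)))
  nonsyn <- records$missense + records$lof
  per_gene <- data.frame(gene_id = records$gene_id,
                         ratio = ifelse(records$syn > 0, nonsyn / records$syn,
                                        NA_real_))
  if (is.null(group)) grp <- rep("all", nrow(records))
  else if (is.character(group) && length(group) == 1L && group %in% names(records))
    grp <- records[[group]]
  else grp <- group
  agg_n <- tapply(nonsyn, grp, sum)
  agg_s <- tapply(records$syn, grp, sum)
  pooled <- data.frame(group = names(agg_n), nonsyn = as.numeric(agg_n),
                       syn = as.numeric(agg_s),
                       ratio = ifelse(agg_s > 0, agg_n / agg_s,
                                      ifelse(agg_n > 0, NA_real_, 0)),
                       row.names = NULL, stringsAsFactors = FALSE)
  # all-synonymous group: pooled numerator 0 -> ratio 0
  pooled$ratio[agg_n == 0 & agg_s > 0] <- 0
  list(per_gene = per_gene, pooled = pooled)
}

#' Expression breadth: tissues expressed per gene
#'
#' Counts, per gene, the tissues whose expression is at least `threshold`
#' (inclusive). The threshold unit follows the input matrix (TPM by
#' convention).
#'
#' @param mat Numeric gene x tissue matrix (rownames = gene_id), values >= 0.
#' @param threshold Expression cutoff (default 5).
#' @return data.frame: gene_id, tissues_expressed, threshold, n_tissues.
#' @export
expression_breadth <- function(mat, threshold = 5) {
  stopifnot(is.matrix(mat) || is.data.frame(mat))
  m <- as.matrix(mat)
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  data.frame(gene_id = rownames(m),
             tissues_expressed = as.integer(rowSums(m >= threshold, na.rm = TRUE)),
             threshold = threshold, n_tissues = ncol(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

# consensus bin from a_count of t tissues; exact integer cuts at t = 21
# (always A / 14-20 / 7-13 / 1-6 / always B), scaled proportionally otherwise
.ab_bin <- function(a, t) {
  if (t <= 0L) return(NA_character_)
  hi <- if (t == 21L) 14L else max(2L, round(14 * t / 21))
  mid <- if (t == 21L) 7L else max(1L, round(7 * t / 21))
  if (a == t) "always A"
  else if (a >= hi) "mostly A"
  else if (a >= mid) "equal"
  else if (a >= 1L) "mostly B"
  else "always B"
}

#' A/B compartment consensus across tissues
#'
#' For each query point (gene TSS or isochore midpoint) and each tissue, the
#' point takes the label of the compartment whose midpoint is nearest; the
#' A-count across tissues is binned into always A / mostly A / equal /
#' mostly B / always B (integer cuts 21 / 14--20 / 7--13 / 1--6 / 0 for 21
#' tissues, scaled proportionally otherwise). Tissues with no calls on a
#' point's chromosome are skipped for that point and its tissue total
#' adjusted.
#'
#' @param calls Named list (one element per tissue) of data.frames with
#'   chrom, start, end, compartment ("A"/"B").
#' @param points data.frame with id, chrom, pos.
#' @return data.frame: id, a_count, t_used, bin.
#' @export
compartment_consensus <- function(calls, points) {
  stopifnot(is.list(calls), all(c("id", "chrom", "pos") %in% names(points)))
  a_count <- integer(nrow(points)); t_used <- integer(nrow(points))
  for (tis in calls) {
    stopifnot(all(c("chrom", "start", "end", "compartment") %in% names(tis)))
    mids <- .interval_mid(tis$start, tis$end)
    for (ch in unique(points$chrom)) {
      sel <- which(tis$chrom == ch)
      p <- which(points$chrom == ch)
      if (!length(sel) || !length(p)) next
      o <- order(mids[sel]); m <- mids[sel][o]
      lab <- tis$compartment[sel][o]
      fi <- findInterval(points$pos[p], m)
      lo <- pmax(fi, 1L); hi <- pmin(fi + 1L, length(m))
      nearest <- ifelse(abs(points$pos[p] - m[lo]) <= abs(m[hi] - points$pos[p]),
                        lo, hi)
      t_used[p] <- t_used[p] + 1L
      a_count[p] <- a_count[p] + (lab[nearest] == "A")
    }
  }
  data.frame(id = points$id, a_count = a_count, t_used = t_used,
             bin = mapply(.ab_bin, a_count, t_used),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Query points for compartment assignment
#'
#' `tss_points()` gives each gene's TSS; `midpoints()` gives region
#' midpoints (e.g. isochores).
#'
#' @param genes A `gene_set`.
#' @return data.frame: id, chrom, pos.
#' @export
tss_points <- function(genes) {
  g <- if (inherits(genes, "gene_set")) genes$genes else genes
  data.frame(id = g$gene_id, chrom = g$chrom, pos = g$tss,
             stringsAsFactors = FALSE)
}

#' @rdname tss_points
#' @param regions data.frame with id, chrom, start, end.
#' @export
midpoints <- function(regions) {
  data.frame(id = regions$id, chrom = regions$chrom,
             pos = .interval_mid(regions$start, regions$end),
             stringsAsFactors = FALSE)
}
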