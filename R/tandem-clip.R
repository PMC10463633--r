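# Syntenic tandem-array extraction across species from orthologous bookend
# genes, with feature-level GC decomposition of each array region.

#' Locate a tandem-array region between bookend orthologs
#'
#' The region is the span strictly between the two bookend genes (the
#' bookends themselves are excluded; `inclusive = TRUE` extends the span to
#' cover them, for sensitivity analyses). Genes are counted only when fully
#' contained in the span. Bookends on different scaffolds mean the array is
#' not contiguously assembled: the species is skipped, not an error.
#'
#' @param bookends data.frame of exactly two rows: gene, scaffold, start,
#'   end (0-based half-open).
#' @param genes A `gene_set` for the species' annotation (only gene, mRNA,
#'   CDS, exon and UTR features are ever represented in a `gene_set`).
#' @param species Optional species label carried through.
#' @param inclusive Include the bookend genes in the span (default FALSE).
#' @return Object of class `cluster_region`: list with `status`
#'   ("profiled" or "skipped:different-scaffold"), and when profiled:
#'   `species`, `scaffold`, `start`, `end`, `gene_ids`, `paralog_count`.
#'   Overlapping bookends are an error.
#' @export
locate_cluster <- function(bookends, genes, species = NA_character_,
                           inclusive = FALSE) {
  stopifnot(is.data.frame(bookends), nrow(bookends) == 2L,
            all(c("gene", "scaffold", "start", "end") %in% names(bookends)),
            inherits(genes, "gene_set"))
  if (bookends$gene[1] == bookends$gene[2])
    stop("bookends must be two distinct genes")
  if (bookends$scaffold[1] != bookends$scaffold[2]) {
    out <- list(status = "skipped:different-scaffold", species = species)
    class(out) <- "cluster_region"
    return(out)
  }
  b <- bookends[order(bookends$start), ]
  if (b$end[1] > b$start[2])
    stop("bookend genes overlap: ", paste(b$gene, collapse = ", "))
  span <- if (inclusive) c(b$start[1], b$end[2]) else c(b$end[1], b$start[2])
  g <- genes$genes
  contained <- g$chrom == b$scaffold[1] &
    g$start >= span[1] & g$end <= span[2] &
    !(g$symbol %in% b$gene) & !(g$gene_id %in% b$gene)
  out <- list(status = "profiled", species = species,
              scaffold = b$scaffold[1], start = span[1], end = span[2],
              gene_ids = g$gene_id[contained],
              paralog_count = sum(contained))
  class(out) <- "cluster_region"
  out
}

#' @export
print.cluster_region <- function(x, ...) {
  if (x$status != "profiled") {
    cat("cluster_region [", x$status, "]\n", sep = "")
  } else {
    cat(sprintf("cluster_region %s:%d-%d, %d contained genes\n",
                x$scaffold, x$start, x$end, x$paralog_count))
  }
  invisible(x)
}

#' Partition a cluster region into feature interval sets
#'
#' Produces merged, sorted interval sets clipped to the region: genic
#' (merged contained-gene spans), intergenic (region minus genic), exonic,
#' intronic (genic minus exonic), cds, and promoter (-750/+250 strand-aware
#' windows, only for genes with an annotated 5' UTR). Genic and intergenic
#' tile the region exactly; intronic and exonic tile the genic set.
#'
#' @param region A profiled `cluster_region`.
#' @param genes The `gene_set` the region was located in.
#' @return Named list of data.frames (start, end): genic, intergenic,
#'   exonic, intronic, cds, promoter.
#' @export
partition_features <- function(region, genes) {
  stopifnot(inherits(region, "cluster_region"), region$status == "profiled",
            inherits(genes, "gene_set"))
  reg <- data.frame(start = region$start, end = region$end)
  gs <- .subset_gene_set(genes, region$gene_ids)
  g <- gs$genes
  clip <- function(df) .intersect_intervals(df, reg)
  genic <- clip(.union_intervals(g[, c("start", "end")]))
  intergenic <- .setdiff_intervals(reg, genic)
  exonic <- clip(.union_intervals(gs$exons[, c("start", "end")]))
  intronic <- .setdiff_intervals(genic, exonic)
  has_cds <- !is.na(g$cds_start)
  cds <- if (any(has_cds)) {
    pieces <- lapply(which(has_cds), function(i) {
      ex <- gs$exons[gs$exons$gene_id == g$gene_id[i], c("start", "end")]
      .intersect_intervals(ex, data.frame(start = g$cds_start[i],
                                          end = g$cds_end[i]))
    })
    clip(.union_intervals(do.call(rbind, pieces)))
  } else data.frame(start = integer(0), end = integer(0))
  gp <- g[g$has_five_prime_utr, , drop = FALSE]
  promoter <- if (nrow(gp)) {
    pw <- t(mapply(.promoter_window, gp$tss, gp$strand))
    clip(.union_intervals(data.frame(start = pw[, 1], end = pw[, 2])))
  } else data.frame(start = integer(0), end = integer(0))
  list(genic = genic, intergenic = intergenic, exonic = exonic,
       intronic = intronic, cds = cds, promoter = promoter)
}

#' GC profile of a cluster region
#'
#' GC fraction (N-excluded) of the whole cluster span and of each feature
#' set, plus the genome-wide GC and the natural log of the paralog count
#' (missing for empty clusters).
#'
#' @param region A profiled `cluster_region`.
#' @param genes The species' `gene_set`.
#' @param seqs Named character vector of scaffold sequences or a
#'   `synth_genome`.
#' @param genome_gc Optional precomputed genome GC; computed over all
#'   supplied sequences when NULL.
#' @param features Optional precomputed [partition_features()] result.
#' @return One-row data.frame: species, paralog_count, log_paralog,
#'   cluster_gc, intergenic_gc, intronic_gc, promoter_gc, cds_gc, genome_gc.
#' @export
cluster_gc_profile <- function(region, genes, seqs, genome_gc = NULL,
                               features = NULL) {
  stopifnot(inherits(region, "cluster_region"), region$status == "profiled")
  seqs <- .get_seqs(seqs)
  seq <- seqs[[region$scaffold]]
  if (is.null(seq)) stop("no sequence for scaffold ", region$scaffold)
  cums <- .seq_cums(seq)
  if (is.null(features)) features <- partition_features(region, genes)
  if (is.null(genome_gc)) {
    tot <- vapply(seqs, function(s) {
      cc <- .seq_cums(s)
      c(cc$gc[cc$len + 1L], cc$base[cc$len + 1L])
    }, numeric(2))
    genome_gc <- sum(tot[1, ]) / sum(tot[2, ])
  }
  fgc <- function(df) .gc_intervals(cums, df$start, df$end)
  data.frame(
    species = region$species,
    paralog_count = region$paralog_count,
    log_paralog = if (region$paralog_count >= 1) log(region$paralog_count)
                  else NA_real_,
    cluster_gc = .gc_window(cums, region$start, region$end),
    intergenic_gc = fgc(features$intergenic),
    intronic_gc = fgc(features$intronic),
    promoter_gc = fgc(features$promoter),
    cds_gc = fgc(features$cds),
    genome_gc = genome_gc,
    stringsAsFactors = FALSE)
}

#' Clip a tandem array across a species panel
#'
#' Runs [locate_cluster()] + [cluster_gc_profile()] for every species in a
#' bookend table. Every species ends in exactly one state: profiled,
#' skipped:different-scaffold, or skipped:missing-bookend (fewer than two
#' bookend rows). Clusters whose paralog count exceeds three times the
#' panel median are flagged (`count_outlier`), with no automatic action.
#'
#' @param bookend_table data.frame: species, gene, scaffold, start, end
#'   (two rows per species).
#' @param genomes Named list (by species) of lists with elements `genes`
#'   (a `gene_set`) and `seqs` (named character vector of scaffolds).
#' @param inclusive Passed to [locate_cluster()].
#' @return List with `panel` (one row per profiled species, the
#'   [cluster_gc_profile()] columns plus `count_outlier`) and `log`
#'   (species, status).
#' @export
clip_panel <- function(bookend_table, genomes, inclusive = FALSE) {
  stopifnot(all(c("species", "gene", "scaffold", "start", "end") %in%
                  names(bookend_table)))
  rows <- list(); log <- list()
  for (sp in unique(bookend_table$species)) {
    bk <- bookend_table[bookend_table$species == sp, , drop = FALSE]
    gm <- genomes[[sp]]
    if (nrow(bk) < 2L || is.null(gm)) {
      log[[sp]] <- "skipped:missing-bookend"
      next
    }
    reg <- locate_cluster(bk[1:2, c("gene", "scaffold", "start", "end")],
                          gm$genes, species = sp, inclusive = inclusive)
    log[[sp]] <- reg$status
    if (reg$status != "profiled") next
    rows[[sp]] <- cluster_gc_profile(reg, gm$genes, gm$seqs)
  }
  panel <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
           else NULL
  if (!is.null(panel)) {
    med <- stats::median(panel$paralog_count)
    panel$count_outlier <- panel$paralog_count > 3 * med
  }
  list(panel = panel,
       log = data.frame(species = names(log), status = unlist(log),
                        row.names = NULL, stringsAsFactors = FALSE))
}
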