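# Gene-model container: one curated transcript per gene (MANE-style
# semantics), held relationally as a genes table plus an exons table.
# Coordinates are 0-based half-open internally; GFF3 is converted at I/O.

#' Construct a gene set
#'
#' @param genes data.frame with columns gene_id, symbol, chrom, strand
#'   (+/-), start, end, tss (0-based point coordinate of the transcription
#'   start), cds_start, cds_end (NA for non-coding), has_five_prime_utr.
#' @param exons data.frame with columns gene_id, start, end.
#' @return Object of class `gene_set`.
#' @export
new_gene_set <- function(genes, exons) {
  stopifnot(is.data.frame(genes), is.data.frame(exons),
            all(c("gene_id", "chrom", "strand", "start", "end", "tss") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (is.null(genes$cds_start)) genes$cds_start <- NA_integer_
  if (is.null(genes$cds_end)) genes$cds_end <- NA_integer_
  if (is.null(genes$has_five_prime_utr)) genes$has_five_prime_utr <- TRUE
  bad <- exons$start >= exons$end
  if (any(bad)) stop("exons must satisfy start < end")
  # exons sorted within gene, inside the gene span
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  m <- match(exons$gene_id, genes$gene_id)
  if (anyNA(m)) stop("exon rows reference unknown gene_id")
  if (any(exons$start < genes$start[m] - 0L) || any(exons$end > genes$end[m]))
    stop("exons must lie within their gene span")
  rownames(genes) <- NULL; rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_set")
}

.empty_gene_set <- function(chrom = character(0)) {
  new_gene_set(
    data.frame(gene_id = character(0), symbol = character(0),
               chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0), tss = integer(0),
               cds_start = integer(0), cds_end = integer(0),
               has_five_prime_utr = logical(0)),
    data.frame(gene_id = character(0), start = integer(0), end = integer(0)))
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  print(utils::head(x$genes))
  invisible(x)
}

#' @export
length.gene_set <- function(x) nrow(x$genes)

# subset a gene_set by gene_id
.subset_gene_set <- function(gs, ids) {
  new_gene_set(gs$genes[gs$genes$gene_id %in% ids, , drop = FALSE],
               gs$exons[gs$exons$gene_id %in% ids, , drop = FALSE])
}

#' Write a gene set as GFF3
#'
#' Emits gene / mRNA / exon / CDS / five_prime_UTR rows (version 3 header)
#' through rtracklayer. The five_prime_UTR row spans TSS to CDS start in
#' transcript orientation and is only written for genes flagged as having
#' an annotated 5' UTR.
#'
#' @param gs A `gene_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  g <- gs$genes
  rows <- list()
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    mrna_id <- paste0(gi$gene_id, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      type = c("gene", "mRNA"), start = gi$start, end = gi$end,
      strand = gi$strand, chrom = gi$chrom,
      ID = c(gi$gene_id, mrna_id), Name = gi$symbol,
      Parent = c(NA, gi$gene_id), stringsAsFactors = FALSE)
    ex <- gs$exons[gs$exons$gene_id == gi$gene_id, , drop = FALSE]
    if (nrow(ex)) rows[[length(rows) + 1L]] <- data.frame(
      type = "exon", start = ex$start, end = ex$end, strand = gi$strand,
      chrom = gi$chrom, ID = sprintf("%s.e%d", mrna_id, seq_len(nrow(ex))),
      Name = NA, Parent = mrna_id, stringsAsFactors = FALSE)
    if (!is.na(gi$cds_start)) {
      cds <- .intersect_intervals(ex[, c("start", "end")],
                                  data.frame(start = gi$cds_start, end = gi$cds_end))
      if (nrow(cds)) rows[[length(rows) + 1L]] <- data.frame(
        type = "CDS", start = cds$start, end = cds$end, strand = gi$strand,
        chrom = gi$chrom, ID = paste0(mrna_id, ".cds"), Name = NA,
        Parent = mrna_id, stringsAsFactors = FALSE)
      if (isTRUE(gi$has_five_prime_utr)) {
        u <- if (gi$strand == "+") c(gi$start, gi$cds_start) else c(gi$cds_end, gi$end)
        if (u[2] > u[1]) rows[[length(rows) + 1L]] <- data.frame(
          type = "five_prime_UTR", start = u[1], end = u[2], strand = gi$strand,
          chrom = gi$chrom, ID = paste0(mrna_id, ".utr5"), Name = NA,
          Parent = mrna_id, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Name <- df$Name
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file via rtracklayer, retaining only gene, mRNA, CDS, exon,
#' five_prime_UTR and three_prime_UTR rows, and rebuilds one gene model per
#' gene (first mRNA per gene when several are present). A gene is flagged
#' `has_five_prime_utr` when a five_prime_UTR row is present, or when the
#' CDS 5' edge differs from the TSS.
#'
#' @param path GFF3 file.
#' @return A `gene_set` (coordinates 0-based half-open).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in%
    c("gene", "mRNA", "CDS", "exon", "five_prime_UTR", "three_prime_UTR")
  gr <- gr[keep]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    ID = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    Name = if (is.null(gr$Name)) NA_character_ else as.character(gr$Name),
    Parent = if (is.null(gr$Parent)) NA_character_ else
      vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, ""),
    stringsAsFactors = FALSE)

  gens <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  mrna <- mrna[!duplicated(mrna$Parent), , drop = FALSE]   # one model per gene
  genes <- list(); exons <- list()
  for (i in seq_len(nrow(gens))) {
    gi <- gens[i, ]
    mi <- mrna[!is.na(mrna$Parent) & mrna$Parent == gi$ID, , drop = FALSE]
    mid <- if (nrow(mi)) mi$ID[1] else gi$ID
    ch <- df[!is.na(df$Parent) & df$Parent == mid, , drop = FALSE]
    ex <- ch[ch$type == "exon", , drop = FALSE]
    cds <- ch[ch$type == "CDS", , drop = FALSE]
    utr5 <- ch[ch$type == "five_prime_UTR", , drop = FALSE]
    tss <- if (gi$strand == "+") gi$start else gi$end - 1L
    cds_s <- if (nrow(cds)) min(cds$start) else NA_integer_
    cds_e <- if (nrow(cds)) max(cds$end) else NA_integer_
    has5 <- nrow(utr5) > 0 ||
      (!is.na(cds_s) && (if (gi$strand == "+") cds_s > gi$start else cds_e < gi$end))
    genes[[i]] <- data.frame(
      gene_id = gi$ID, symbol = if (is.na(gi$Name)) gi$ID else gi$Name,
      chrom = gi$chrom, strand = gi$strand, start = gi$start, end = gi$end,
      tss = tss, cds_start = cds_s, cds_end = cds_e,
      has_five_prime_utr = has5, stringsAsFactors = FALSE)
    exons[[i]] <- if (nrow(ex))
      data.frame(gene_id = gi$ID, start = ex$start, end = ex$end)
    else data.frame(gene_id = gi$ID, start = gi$start, end = gi$end)
  }
  new_gene_set(do.call(rbind, genes), do.call(rbind, exons))
}

# Interval helpers on start/end data.frames (0-based half-open).
.intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  ia <- IRanges::IRanges(a$start + 1L, a$end)
  ib <- IRanges::IRanges(b$start + 1L, b$end)
  ov <- IRanges::intersect(IRanges::reduce(ia), IRanges::reduce(ib))
  data.frame(start = IRanges::start(ov) - 1L, end = IRanges::end(ov))
}

.union_intervals <- function(a) {
  if (nrow(a) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  r <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

.setdiff_intervals <- function(a, b) {
  if (nrow(a) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  ia <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
  if (nrow(b) == 0L)
    return(data.frame(start = IRanges::start(ia) - 1L, end = IRanges::end(ia)))
  ib <- IRanges::reduce(IRanges::IRanges(b$start + 1L, b$end))
  d <- IRanges::setdiff(ia, ib)
  data.frame(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}
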