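# Gene classification by iterative 3x3 k-means on GC trajectories, gene-name
# prefix derivation, Shannon prefix diversity, and tandem-neighbour counts.

# Deterministic k-means: rows are ordered by (row mean, then columns) and
# initial centers are taken at quantile-spread positions of that ordering;
# Lloyd iterations with fixed centers are independent of row order, so the
# partition (and every gene's final label) is invariant under permutation of
# the input rows. Several deterministic starts are tried and the best
# within-cluster sum of squares kept.
.kmeans_det <- function(x, k, starts = 10L, iter_max = 100L) {
  n <- nrow(x)
  ux <- unique(x)
  if (nrow(ux) < k) return(rep(1L, n))     # degenerate: one cluster
  ord <- do.call(order, c(list(rowMeans(x)), as.data.frame(x)))
  xs <- x[ord, , drop = FALSE]
  best <- NULL
  for (s in seq_len(starts)) {
    pos <- ((seq_len(k) - 1L) + s / (starts + 1)) / k
    idx <- unique(pmin(n, 1L + floor(pos * n)))
    ctr <- unique(xs[idx, , drop = FALSE])
    if (nrow(ctr) < k) next
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = ctr, iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) return(rep(1L, n))
  best$cluster
}

# Mean GC over the promoter-region columns of the trajectory: the upstream
# flank windows covering -750..0 plus the first 5% of body bins (covering
# roughly +0..+250 for typical gene lengths).
.promoter_cols <- function(nf, body_bins) {
  c(max(1L, nf - 14L):nf, nf + seq_len(max(1L, round(0.05 * body_bins))))
}

#' Iterative 3x3 k-means classification of GC trajectories
#'
#' k-means (k = 3) over all trajectory rows, then k = 3 again within each
#' top-level cluster. Labels follow the GC-ordering convention: top clusters
#' are numbered so mean promoter-region GC decreases with the index (and
#' likewise for subclusters within each top cluster), so cluster "3.3" is
#' the most AT-biased. Missing values (N-only windows) are imputed by linear
#' interpolation along the row before clustering. The clustering is
#' deterministic and invariant under permutation of the input rows.
#'
#' @param traj Trajectory matrix from [gc_trajectory()] (rownames = gene_id).
#' @param k Top-level and sub-level cluster count (default 3).
#' @param seed Unused (kept for interface stability; the implementation is
#'   deterministic).
#' @return data.frame: gene_id, top_cluster (integer), sub_cluster ("i.j").
#' @export
iterative_kmeans <- function(traj, k = 3L, seed = 1234L) {
  stopifnot(is.matrix(traj))
  if (nrow(traj) < k * k)
    stop("need at least ", k * k, " trajectories to form ", k, "x", k, " clusters")
  nf <- attr(traj, "flank_windows"); if (is.null(nf)) nf <- 20L
  bb <- attr(traj, "body_bins"); if (is.null(bb)) bb <- ncol(traj) - 2L * nf
  x <- t(apply(traj, 1L, function(r) {
    if (!anyNA(r)) return(r)
    if (all(is.na(r))) return(rep(0.5, length(r)))
    idx <- which(!is.na(r))
    stats::approx(idx, r[idx], xout = seq_along(r), rule = 2)$y
  }))
  pcols <- .promoter_cols(nf, bb)
  pcols <- pcols[pcols <= ncol(x)]

  top_raw <- .kmeans_det(x, k)
  # relabel top clusters by decreasing promoter-region GC
  pscore <- vapply(sort(unique(top_raw)), function(cl)
    mean(x[top_raw == cl, pcols, drop = FALSE]), 0)
  lev <- sort(unique(top_raw))[order(-pscore)]
  top <- match(top_raw, lev)

  sub <- integer(nrow(x))
  for (cl in seq_along(lev)) {
    rows <- which(top == cl)
    sr <- if (length(rows) >= k) .kmeans_det(x[rows, , drop = FALSE], k)
          else rep(1L, length(rows))
    ps <- vapply(sort(unique(sr)), function(s)
      mean(x[rows[sr == s], pcols, drop = FALSE]), 0)
    slev <- sort(unique(sr))[order(-ps)]
    sub[rows] <- match(sr, slev)
  }
  data.frame(gene_id = rownames(traj), top_cluster = top,
             sub_cluster = sprintf("%d.%d", top, sub),
             stringsAsFactors = FALSE)
}

#' Derive gene-family prefixes from gene symbols
#'
#' Well-annotated gene symbols share a family prefix; the derivation is:
#' (1) apply the renaming map (symbol-level overrides, e.g. legacy to
#' current nomenclature); (2) replace every digit -- and any other
#' non-letter character such as a hyphen -- with "_"; (3) truncate at the
#' first "_" (so CSN2A becomes CSN); (4) if a single letter remains, consult
#' the single-letter override table; (5) apply family-merge overrides (e.g.
#' KCNT and KCNQ both to KCN). Steps 1, 4 and 5 are driven by injectable
#' tables; see [prefix_overrides()].
#'
#' @param symbols Character vector of gene symbols.
#' @param overrides List with elements `renames`, `single_letter`, `merges`
#'   (named character vectors, may be empty), as from [prefix_overrides()].
#' @return data.frame: symbol, prefix, override_applied. Errors if a symbol
#'   reduces to an empty prefix (e.g. a symbol of only digits).
#' @examples
#' derive_prefix(c("CSN2A", "KRTAP4-5", "ABC"))
#' @export
derive_prefix <- function(symbols, overrides = prefix_overrides()) {
  stopifnot(is.character(symbols), all(nchar(symbols) > 0))
  ren <- overrides$renames; sl <- overrides$single_letter; mg <- overrides$merges
  hit <- rep(FALSE, length(symbols))
  s <- symbols
  m <- match(s, names(ren))
  hit[!is.na(m)] <- TRUE
  s[!is.na(m)] <- ren[m[!is.na(m)]]
  s <- gsub("[^A-Za-z_]", "_", s)
  s <- sub("_.*$", "", s)
  bad <- nchar(s) == 0L
  if (any(bad))
    stop("symbol(s) reduce to an empty prefix: ",
         paste(symbols[bad], collapse = ", "))
  one <- nchar(s) == 1L
  m <- match(s, names(sl))
  repl <- one & !is.na(m)
  hit[repl] <- TRUE
  s[repl] <- sl[m[repl]]
  m <- match(s, names(mg))
  hit[!is.na(m)] <- TRUE
  s[!is.na(m)] <- mg[m[!is.na(m)]]
  data.frame(symbol = symbols, prefix = s, override_applied = hit,
             stringsAsFactors = FALSE)
}

#' Load prefix override tables
#'
#' Reads the three editable two-column TSVs (`from`, `to`) shipped under
#' `inst/extdata`: symbol renames, single-letter prefix groupings, and
#' family merges. Pass file paths to substitute your own tables, or `NA` to
#' disable one.
#'
#' @param renames,single_letter,merges TSV paths; defaults are the packaged
#'   tables.
#' @return List of three named character vectors.
#' @export
prefix_overrides <- function(
    renames = system.file("extdata", "prefix_renames.tsv", package = "isobloom"),
    single_letter = system.file("extdata", "prefix_single_letter.tsv", package = "isobloom"),
    merges = system.file("extdata", "prefix_merges.tsv", package = "isobloom")) {
  read1 <- function(p) {
    if (length(p) != 1L || is.na(p) || p == "" || !file.exists(p))
      return(stats::setNames(character(0), character(0)))
    df <- utils::read.delim(p, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  }
  list(renames = read1(renames), single_letter = read1(single_letter),
       merges = read1(merges))
}

#' Shannon diversity (bits) of a categorical composition
#'
#' H = sum over categories of p * log2(1/p). Zero iff a single category;
#' bounded above by log2 of the number of categories.
#'
#' @param counts Non-negative counts (or proportions) per category.
#' @return H in bits.
#' @examples
#' shannon_h(c(1, 1, 1, 1))  # 2 bits
#' shannon_h(c(2, 1, 1))     # 1.5 bits
#' @export
shannon_h <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(NA_real_)
  p <- counts / sum(counts)
  sum(p * log2(1 / p))
}

#' Per-isochore gene-name prefix diversity
#'
#' Shannon's H (bits) over the prefix composition of each isochore holding
#' at least `min_genes` genes; smaller isochores are omitted.
#'
#' @param genes data.frame with columns gene_id, prefix, isochore_id (NA
#'   isochore rows are dropped).
#' @param min_genes Minimum genes per isochore (default 10).
#' @return data.frame: isochore_id, gene_count, prefix_count, shannon_h,
#'   min_genes.
#' @export
prefix_diversity <- function(genes, min_genes = 10L) {
  stopifnot(all(c("gene_id", "prefix", "isochore_id") %in% names(genes)))
  g <- genes[!is.na(genes$isochore_id), , drop = FALSE]
  if (nrow(g) == 0L)
    return(data.frame(isochore_id = character(0), gene_count = integer(0),
                      prefix_count = integer(0), shannon_h = numeric(0),
                      min_genes = integer(0)))
  sp <- split(g$prefix, g$isochore_id)
  sp <- sp[lengths(sp) >= min_genes]
  data.frame(
    isochore_id = names(sp),
    gene_count = unname(lengths(sp)),
    prefix_count = unname(vapply(sp, function(p) length(unique(p)), 0L)),
    shannon_h = unname(vapply(sp, function(p) shannon_h(table(p)), 0)),
    min_genes = as.integer(min_genes),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Tandem-neighbour counts per gene
#'
#' A gene's tandem neighbours are the other genes sharing its prefix within
#' its home isochore. Counts are binned 0 / 1--4 / >=5; genes without a home
#' isochore get `NA`.
#'
#' @param genes data.frame with gene_id, prefix, isochore_id.
#' @return data.frame: gene_id, neighbor_count, bin (factor "0", "1-4", ">=5").
#' @export
tandem_neighbor_count <- function(genes) {
  stopifnot(all(c("gene_id", "prefix", "isochore_id") %in% names(genes)))
  key <- paste(genes$isochore_id, genes$prefix, sep = "\r")
  n <- as.integer(ave(seq_along(key), key, FUN = length)) - 1L
  n[is.na(genes$isochore_id)] <- NA_integer_
  bin <- cut(n, breaks = c(-0.5, 0.5, 4.5, Inf), labels = c("0", "1-4", ">=5"))
  data.frame(gene_id = genes$gene_id, neighbor_count = n, bin = bin,
             stringsAsFactors = FALSE)
}

#' Multigene score of an isochore
#'
#' Fraction of the isochore's genes having at least one same-prefix
#' neighbour in the isochore. This quantifies how much of an isochore's gene
#' content sits in local duplications; the exact form of such a score is a
#' package convention (configurable via `min_neighbors`).
#'
#' @param genes data.frame with gene_id, prefix, isochore_id.
#' @param min_neighbors Minimum same-prefix neighbours for a gene to count
#'   as multigene (default 1).
#' @return data.frame: isochore_id, gene_count, multigene_score.
#' @export
multigene_score <- function(genes, min_neighbors = 1L) {
  nb <- tandem_neighbor_count(genes)
  g <- genes[!is.na(genes$isochore_id), , drop = FALSE]
  nbk <- nb$neighbor_count[!is.na(genes$isochore_id)]
  sp <- split(nbk >= min_neighbors, g$isochore_id)
  data.frame(isochore_id = names(sp), gene_count = unname(lengths(sp)),
             multigene_score = unname(vapply(sp, mean, 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}
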