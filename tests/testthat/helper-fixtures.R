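# Shared hand-traced tandem-array fixture: a scaffold with two bookend
# genes and four genes between them, one straddling the right boundary.

.clip_fixture <- function() {
  mk_gene <- function(id, s, e, strand = "+", utr = TRUE) {
    data.frame(gene_id = id, symbol = id, chrom = "sc1", strand = strand,
               start = s, end = e, tss = if (strand == "+") s else e - 1L,
               cds_start = s + 100L, cds_end = e - 100L,
               has_five_prime_utr = utr, stringsAsFactors = FALSE)
  }
  genes <- rbind(mk_gene("bkL", 1000L, 3000L),
                 mk_gene("par1", 5000L, 8000L),
                 mk_gene("par2", 10000L, 13000L, "-"),
                 mk_gene("par3", 15000L, 18000L, utr = FALSE),
                 mk_gene("straddle", 19000L, 23000L),
                 mk_gene("bkR", 20000L, 22000L))
  # give par2 two exons so the intronic set is non-empty
  exons <- rbind(
    data.frame(gene_id = "bkL", start = 1000L, end = 3000L),
    data.frame(gene_id = "par1", start = 5000L, end = 8000L),
    data.frame(gene_id = "par2", start = c(10000L, 12000L),
               end = c(11000L, 13000L)),
    data.frame(gene_id = "par3", start = 15000L, end = 18000L),
    data.frame(gene_id = "straddle", start = 19000L, end = 23000L),
    data.frame(gene_id = "bkR", start = 20000L, end = 22000L))
  # bkR overlaps straddle, which is fine: bookends only delimit the span
  new_gene_set(genes[genes$gene_id != "straddle" | TRUE, ], exons)
}

.bookends <- data.frame(gene = c("bkL", "bkR"), scaffold = "sc1",
                        start = c(1000L, 20000L), end = c(3000L, 22000L))

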