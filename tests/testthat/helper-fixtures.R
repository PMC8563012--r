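# Small builders shared across tests. All fixtures are constructed in
# code; nothing is read from disk unless a test writes it first.

make_junctions <- function(cell_id, donor_pos, acceptor_pos, count,
                           gene = "g1", chrom = "chr1", strand = "+") {
  data.frame(cell_id = cell_id, gene = gene, chrom = chrom,
             strand = strand, donor_pos = as.integer(donor_pos),
             acceptor_pos = as.integer(acceptor_pos),
             count = as.integer(count), stringsAsFactors = FALSE)
}

# Population containing every possible cell with n reads split between
# the two partners of a single donor anchor: cell j sends j reads to the
# farther partner (j = 0..n). Used for the exhaustive PSI-monotonicity
# checks.
two_partner_population <- function(n, near = 500L, far = 2000L,
                                   anchor = 100L) {
  rows <- lapply(0:n, function(j) {
    cell <- sprintf("c%02d", j)
    out <- NULL
    if (n - j > 0) {
      out <- rbind(out, make_junctions(cell, anchor, near, n - j))
    }
    if (j > 0) {
      out <- rbind(out, make_junctions(cell, anchor, far, j))
    }
    out
  })
  do.call(rbind, rows)
}

# Minimal object that walks like a spliz fit, for analyses that only
# consume $scores and $cells.
fake_spliz_fit <- function(scores, cells = NULL) {
  structure(list(scores = scores, models = NULL, junctions = NULL,
                 cells = cells, min_reads = 5), class = "spliz")
}

make_cells <- function(cell_id, cell_type, tissue = "lung",
                       compartment = "immune", individual = "ind1",
                       pseudotime = NULL) {
  df <- data.frame(cell_id = cell_id, individual = individual,
                   tissue = tissue, compartment = compartment,
                   cell_type = cell_type, stringsAsFactors = FALSE)
  if (!is.null(pseudotime)) df$pseudotime <- pseudotime
  df
}

# A toy GTF with one gene, two transcripts (t2 skips the middle exon),
# and CDS on t1. Returned as the path to a temp file.
write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  attr1 <- 'gene_id "gA"; transcript_id "t1";'
  attr2 <- 'gene_id "gA"; transcript_id "t2";'
  lines <- c(
    paste("chr1", "test", "exon", 100, 200, ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "test", "exon", 300, 400, ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "test", "exon", 500, 600, ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "test", "CDS", 150, 200, ".", "+", "0", attr1,
          sep = "\t"),
    paste("chr1", "test", "CDS", 300, 400, ".", "+", "0", attr1,
          sep = "\t"),
    paste("chr1", "test", "CDS", 500, 550, ".", "+", "0", attr1,
          sep = "\t"),
    paste("chr1", "test", "exon", 100, 200, ".", "+", ".", attr2,
          sep = "\t"),
    paste("chr1", "test", "exon", 500, 600, ".", "+", ".", attr2,
          sep = "\t"))
  writeLines(lines, path)
  path
}
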