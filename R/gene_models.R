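#' Read gene models from a GTF file
#'
#' Parses exon (and, when present, CDS) features into per-gene transcript
#' models used to classify splice sites by annotation status. Intervals
#' are 1-based and closed, as in GTF.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on exon features.
#' @return A named list of gene models (class `gene_model_set`). Each
#'   element holds `gene_id`, `strand`, `transcripts` (a named list of
#'   exon `data.frame`s with `start`, `end`, sorted and non-overlapping)
#'   and `cds` (same shape, possibly empty).
#' @export
read_gene_models <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    warning(sprintf("%s: empty annotation file", path), call. = FALSE)
    return(structure(list(), class = "gene_model_set"))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  feat <- as.data.frame(gr)
  feat <- feat[feat$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(feat) == 0L) {
    warning(sprintf("%s: no exon features", path), call. = FALSE)
    return(structure(list(), class = "gene_model_set"))
  }
  if (is.null(feat$transcript_id) || anyNA(feat$transcript_id)) {
    stop(sprintf("%s: exon/CDS feature without transcript_id", path),
         call. = FALSE)
  }
  if (is.null(feat$gene_id) || anyNA(feat$gene_id)) {
    stop(sprintf("%s: exon/CDS feature without gene_id", path),
         call. = FALSE)
  }
  models <- lapply(split(feat, feat$gene_id), function(g) {
    strands <- unique(as.character(g$strand))
    if (length(strands) != 1L) {
      stop(sprintf("gene %s: features on mixed strands", g$gene_id[1]),
           call. = FALSE)
    }
    tidy <- function(rows) {
      ex <- rows[order(rows$start), c("start", "end"), drop = FALSE]
      rownames(ex) <- NULL
      if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
        stop(sprintf("gene %s: overlapping intervals within a transcript",
                     g$gene_id[1]), call. = FALSE)
      }
      ex
    }
    exons <- lapply(split(g[g$type == "exon", , drop = FALSE],
                          g$transcript_id[g$type == "exon"]), tidy)
    cds_rows <- g[g$type == "CDS", , drop = FALSE]
    cds <- if (nrow(cds_rows) > 0L) {
      lapply(split(cds_rows, cds_rows$transcript_id), tidy)
    } else list()
    list(gene_id = g$gene_id[1], strand = strands, transcripts = exons,
         cds = cds)
  })
  structure(models, class = "gene_model_set")
}

#' Classify a splice site against gene models
#'
#' Determines whether a splice site sits at an annotated exon boundary,
#' whether that boundary is annotated as alternatively spliced, and which
#' transcript region it falls in.
#'
#' A site is at an annotated boundary when its position exactly matches an
#' exon start or end (1-based) in any transcript of the gene. It counts as
#' annotated alternative when the boundary is present in a proper nonempty
#' subset of the gene's transcripts, or when the annotated transcript
#' structure joins it to more than one partner boundary. The region is the
#' most coding-like region of any transcript containing the position
#' (precedence CDS > UTR); positions inside a transcript span but outside
#' all its exons (and positions in exons of non-coding transcripts) are
#' `non_coding`; positions in no transcript are `intergenic`.
#'
#' @param chrom,pos Site coordinate.
#' @param gene Gene identifier to look up in `models`.
#' @param models A `gene_model_set` from [read_gene_models()].
#' @return A one-row `data.frame`: `at_annotated_exon_boundary`,
#'   `annotated_alternative`, `region` (one of `CDS`, `UTR5`, `UTR3`,
#'   `non_coding`, `intergenic`).
#' @export
classify_site <- function(chrom, pos, gene, models) {
  out <- data.frame(at_annotated_exon_boundary = FALSE,
                    annotated_alternative = FALSE,
                    region = "intergenic", stringsAsFactors = FALSE)
  gm <- models[[gene]]
  if (is.null(gm)) {
    message(sprintf("classify_site: gene %s absent from gene models", gene))
    return(out)
  }
  n_tx <- length(gm$transcripts)
  has_boundary <- vapply(gm$transcripts, function(ex) {
    pos %in% ex$start || pos %in% ex$end
  }, logical(1))
  out$at_annotated_exon_boundary <- any(has_boundary)
  if (out$at_annotated_exon_boundary) {
    subset_rule <- sum(has_boundary) < n_tx
    partners <- annotated_partners(gm, pos)
    out$annotated_alternative <- subset_rule || length(partners) > 1L
  }
  out$region <- site_region(gm, pos)
  out
}

# Partner boundaries joined to `pos` by annotated introns: within each
# transcript consecutive exons (end_i, start_{i+1}) define a junction.
annotated_partners <- function(gm, pos) {
  partners <- integer(0)
  for (ex in gm$transcripts) {
    if (nrow(ex) < 2L) next
    don <- ex$end[-nrow(ex)]
    acc <- ex$start[-1]
    partners <- c(partners, acc[don == pos], don[acc == pos])
  }
  unique(partners)
}

site_region <- function(gm, pos) {
  best <- "intergenic"
  rank <- c(intergenic = 0, non_coding = 1, UTR3 = 2, UTR5 = 3, CDS = 4)
  for (tx in names(gm$transcripts)) {
    ex <- gm$transcripts[[tx]]
    span <- pos >= min(ex$start) && pos <= max(ex$end)
    if (!span) next
    in_exon <- any(pos >= ex$start & pos <= ex$end)
    cds <- gm$cds[[tx]]
    region <- if (!in_exon || is.null(cds) || nrow(cds) == 0L) {
      "non_coding"
    } else if (any(pos >= cds$start & pos <= cds$end)) {
      "CDS"
    } else if (pos < min(cds$start)) {
      if (gm$strand == "+") "UTR5" else "UTR3"
    } else if (pos > max(cds$end)) {
      if (gm$strand == "+") "UTR3" else "UTR5"
    } else {
      "non_coding"  # exonic gap between CDS parts; should not occur
    }
    if (rank[region] > rank[best]) best <- region
  }
  best
}

#' @rdname classify_site
#' @param sites `data.frame` with columns `gene`, `chrom`, `pos` (e.g.
#'   from [spliz_sites()]).
#' @export
classify_sites <- function(sites, models) {
  status <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    classify_site(sites$chrom[i], sites$pos[i], sites$gene[i], models)
  }))
  cbind(sites, status)
}
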