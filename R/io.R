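#' Read a junction count table
#'
#' Reads the canonical 7-column tab-separated interchange format for
#' per-cell splice-junction UMI counts. Columns (header required):
#' `cell_id`, `gene`, `chrom`, `strand`, `donor_pos`, `acceptor_pos`,
#' `count`. Coordinates are 1-based; donor/acceptor roles are taken from
#' the columns, never re-derived from strand. Counts are UMI-deduplicated
#' junctional read counts and must be positive integers.
#'
#' Duplicate (cell, junction) rows are an error rather than being summed:
#' silent aggregation would hide upstream junction-caller bugs.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` of validated junction records (one row per
#'   (cell, junction), `count >= 1`).
#' @seealso [write_junction_table()], [spliz()]
#' @export
read_junction_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(
                            cell_id = "character", gene = "character",
                            chrom = "character", strand = "character",
                            donor_pos = "integer", acceptor_pos = "integer",
                            count = "integer"))
  validate_junction_table(df, source = path)
}

#' @rdname read_junction_table
#' @param junctions A junction `data.frame` to validate. Row numbers in
#'   error messages refer to data rows (header excluded).
#' @export
validate_junction_table <- function(junctions, source = "junction table") {
  required <- c("cell_id", "gene", "chrom", "strand",
                "donor_pos", "acceptor_pos", "count")
  missing <- setdiff(required, names(junctions))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", source,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  junctions <- junctions[, required]
  bad_row <- function(what, idx) {
    stop(sprintf("%s: %s at data row %d", source, what, idx[1]),
         call. = FALSE)
  }
  na_any <- which(!stats::complete.cases(junctions))
  if (length(na_any) > 0L) bad_row("malformed row (missing value)", na_any)
  bad <- which(!junctions$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    bad_row(sprintf("unknown strand symbol '%s'", junctions$strand[bad[1]]),
            bad)
  }
  bad <- which(junctions$count <= 0L)
  if (length(bad) > 0L) bad_row("count must be >= 1", bad)
  bad <- which(junctions$donor_pos < 1L | junctions$acceptor_pos < 1L)
  if (length(bad) > 0L) bad_row("positions must be >= 1", bad)
  bad <- which(junctions$donor_pos == junctions$acceptor_pos)
  if (length(bad) > 0L) bad_row("donor and acceptor positions coincide", bad)
  key <- paste(junctions$cell_id, junctions$gene, junctions$chrom,
               junctions$donor_pos, junctions$acceptor_pos, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    bad_row("duplicate (cell, junction) record (refusing to sum counts)",
            dup)
  }
  junctions
}

#' Write a junction count table
#'
#' @param junctions Validated junction `data.frame`.
#' @param path Output path (tab-separated, with header).
#' @export
write_junction_table <- function(junctions, path) {
  junctions <- validate_junction_table(junctions)
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-cell annotations
#'
#' Reads a comma- or tab-separated table with columns `cell_id`,
#' `individual`, `tissue`, `compartment`, `cell_type` and an optional
#' `pseudotime` column (nonnegative reals; missing entries stay `NA`).
#' Compartments must come from the vocabulary
#' `immune`, `epithelial`, `endothelial`, `stromal`; the catch-all label
#' `other` is accepted only when `allow_other = TRUE`.
#'
#' @param path Path to the annotation file; the separator is sniffed from
#'   the header line (tab wins over comma).
#' @param allow_other Accept the `other` compartment label.
#' @return A `data.frame` with one row per cell; `pseudotime` present only
#'   if the input had the column.
#' @export
read_cell_annotations <- function(path, allow_other = TRUE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_cell_annotations(df, allow_other = allow_other, source = path)
}

#' @rdname read_cell_annotations
#' @param cells Annotation `data.frame` to validate.
#' @export
validate_cell_annotations <- function(cells, allow_other = TRUE,
                                      source = "cell annotations") {
  required <- c("cell_id", "individual", "tissue", "compartment",
                "cell_type")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", source,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dup <- which(duplicated(cells$cell_id))
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate cell_id '%s'", source,
                 cells$cell_id[dup[1]]), call. = FALSE)
  }
  vocab <- compartment_vocabulary(allow_other)
  bad <- which(!cells$compartment %in% vocab)
  if (length(bad) > 0L) {
    stop(sprintf("%s: unknown compartment label '%s'", source,
                 cells$compartment[bad[1]]), call. = FALSE)
  }
  if ("pseudotime" %in% names(cells)) {
    pt <- cells$pseudotime
    if (!is.numeric(pt) || any(pt < 0, na.rm = TRUE)) {
      stop(sprintf("%s: pseudotime must be nonnegative numeric", source),
           call. = FALSE)
    }
  }
  cells
}

compartment_vocabulary <- function(allow_other = TRUE) {
  v <- c("immune", "epithelial", "endothelial", "stromal")
  if (allow_other) c(v, "other") else v
}

#' @rdname read_cell_annotations
#' @export
write_cell_annotations <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cross-species coordinate map
#'
#' Consumes a LiftOver-style mapping as data: a tab-separated table with
#' columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`. Only coordinates that
#' were successfully and uniquely converted are retained: any source or
#' target coordinate appearing more than once is dropped (with a logged
#' count), so the retained map is injective in both directions.
#'
#' @param path Path to the mapping file.
#' @return A `data.frame` of retained coordinate pairs, class
#'   `coordinate_map`.
#' @export
read_coordinate_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("chrom_a", "pos_a", "chrom_b", "pos_b")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as_coordinate_map(df[, required])
}

#' @rdname read_coordinate_map
#' @param pairs `data.frame` with columns `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`.
#' @export
as_coordinate_map <- function(pairs) {
  key_a <- paste(pairs$chrom_a, pairs$pos_a, sep = ":")
  key_b <- paste(pairs$chrom_b, pairs$pos_b, sep = ":")
  multi_a <- key_a %in% key_a[duplicated(key_a)]
  multi_b <- key_b %in% key_b[duplicated(key_b)]
  drop <- multi_a | multi_b
  if (any(drop)) {
    message(sprintf("coordinate map: dropped %d non-uniquely mapped pair(s)",
                    sum(drop)))
  }
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coordinate_map", "data.frame")
  out
}

#' @rdname read_coordinate_map
#' @export
write_coordinate_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Map coordinates across species
#'
#' @param map A `coordinate_map`.
#' @param chrom,pos Coordinates in the source species (vectors).
#' @param reverse Map from species B back to species A.
#' @return A `data.frame` with `chrom`, `pos` of mapped coordinates and
#'   `mapped` logical; unmapped entries carry `NA`.
#' @export
map_coordinates <- function(map, chrom, pos, reverse = FALSE) {
  if (reverse) {
    from <- paste(map$chrom_b, map$pos_b, sep = ":")
    to_chrom <- map$chrom_a; to_pos <- map$pos_a
  } else {
    from <- paste(map$chrom_a, map$pos_a, sep = ":")
    to_chrom <- map$chrom_b; to_pos <- map$pos_b
  }
  idx <- match(paste(chrom, pos, sep = ":"), from)
  data.frame(chrom = to_chrom[idx], pos = to_pos[idx],
             mapped = !is.na(idx), stringsAsFactors = FALSE)
}
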