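#' Locus tables
#'
#' A locus table is the package's tidy representation of a curated gene
#' family: one row per exon segment, with columns `locus_id`, `short_name`,
#' `chromosome`, `strand`, `exon`, `start`, `end`. Coordinates are 1-based
#' fully-closed genomic intervals throughout (the convention of both curated
#' locus tables and GFF3), segments are stored in ascending genomic order
#' regardless of strand, and the chromosome is the two-digit field encoded in
#' accessions of the form `Vitvi08g00007` (a synthetic prefix such as `Synt`
#' is accepted as an equivalent).
#'
#' @name locus_table
NULL

locus_id_pattern <- "^[A-Za-z]+([0-9]{2})g[0-9]{5}$"

chromosome_from_id <- function(locus_id) {
  m <- regmatches(locus_id, regexec(locus_id_pattern, locus_id))
  vapply(m, function(x) if (length(x) == 2L) as.integer(x[2L]) else NA_integer_,
         integer(1))
}

# Split a position cell like "115793-116261, 116647-117596" into a segment
# tibble. Hyphen-minus, en dash and minus sign are all accepted separators.
parse_position_cell <- function(cell, row_label) {
  spans <- strsplit(cell, ",")[[1L]]
  spans <- trimws(spans)
  spans <- spans[nzchar(spans)]
  if (length(spans) == 0L) {
    abort(paste0("no exon segment in position cell for ", row_label))
  }
  parts <- strsplit(spans, "[-–−]")
  bad <- vapply(parts, function(p) length(p) != 2L || anyNA(suppressWarnings(as.numeric(p))),
                logical(1))
  if (any(bad)) {
    abort(paste0("malformed span '", spans[bad][1L], "' in position cell for ",
                 row_label))
  }
  start <- vapply(parts, function(p) as.numeric(trimws(p[1L])), numeric(1))
  end <- vapply(parts, function(p) as.numeric(trimws(p[2L])), numeric(1))
  if (any(end < start)) {
    abort(paste0("span with end < start in position cell for ", row_label))
  }
  tibble::tibble(start = start, end = end)
}

normalize_strand <- function(strand) {
  out <- ifelse(strand %in% c("-", "−", "–"), "-",
                ifelse(strand == "+", "+", NA_character_))
  if (anyNA(out)) abort("strand must be '+' or '-'")
  out
}

#' Read a tab-separated locus table
#'
#' Parses a curated locus table with columns `locus_id`, `short_name`,
#' `strand` and `position`, where `position` holds comma-separated
#' `start-end` spans (1-based inclusive; en dashes are accepted). An optional
#' `chromosome` column overrides the chromosome parsed from the locus ID, and
#' an optional free-text `notes` column is carried along. Rows with malformed
#' spans or duplicated locus IDs are rejected with an error naming the row.
#'
#' @param path Path to a tab-separated locus table.
#' @return A [locus_table] tibble with one row per exon segment.
#' @export
#' @examples
#' tab <- read_locus_table(grasfam_example("gras_table1.tsv"))
#' dplyr::n_distinct(tab$locus_id)
read_locus_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("locus_id", "short_name", "strand", "position")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(paste0("locus table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0L) return(empty_locus_table())
  if (anyDuplicated(raw$locus_id)) {
    dup <- raw$locus_id[duplicated(raw$locus_id)][1L]
    abort(paste0("duplicate locus_id '", dup, "' in locus table"))
  }
  segs <- purrr::map2(raw$position, raw$locus_id, parse_position_cell)
  out <- tibble::tibble(
    locus_id = rep(raw$locus_id, vapply(segs, nrow, integer(1))),
    short_name = rep(raw$short_name, vapply(segs, nrow, integer(1))),
    strand = rep(normalize_strand(raw$strand), vapply(segs, nrow, integer(1))),
    dplyr::bind_rows(segs)
  )
  chrom <- if ("chromosome" %in% names(raw)) {
    rep(as.integer(raw$chromosome), vapply(segs, nrow, integer(1)))
  } else {
    chromosome_from_id(out$locus_id)
  }
  out <- out |>
    dplyr::mutate(chromosome = chrom) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(exon = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("locus_id", "short_name", "chromosome", "strand",
                  "exon", "start", "end")
  if ("notes" %in% names(raw)) {
    notes <- tibble::tibble(locus_id = raw$locus_id, notes = raw$notes)
    out <- dplyr::left_join(out, notes, by = "locus_id")
  }
  validate_locus_table(out)
}

empty_locus_table <- function() {
  tibble::tibble(locus_id = character(), short_name = character(),
                 chromosome = integer(), strand = character(),
                 exon = integer(), start = numeric(), end = numeric())
}

#' Validate a locus table
#'
#' Checks the locus-table invariants: every segment has `start <= end`,
#' segments within a locus are sorted and non-overlapping, every locus has at
#' least one segment, and the chromosome matches the two-digit field of the
#' locus ID when the ID follows the accession pattern.
#'
#' @param loci A [locus_table] tibble.
#' @return The table, invisibly unchanged, or an error.
#' @export
validate_locus_table <- function(loci) {
  if (nrow(loci) == 0L) return(loci)
  if (any(loci$end < loci$start)) {
    abort("locus table has a segment with end < start")
  }
  by_locus <- split(loci, loci$locus_id)
  for (lt in by_locus) {
    if (is.unsorted(lt$start, strictly = FALSE)) {
      abort(paste0("segments of ", lt$locus_id[1L], " are not sorted by start"))
    }
    if (nrow(lt) > 1L && any(lt$start[-1L] <= lt$end[-nrow(lt)])) {
      abort(paste0("segments of ", lt$locus_id[1L], " overlap"))
    }
    id_chrom <- chromosome_from_id(lt$locus_id[1L])
    if (!is.na(id_chrom) && any(lt$chromosome != id_chrom)) {
      abort(paste0("chromosome of ", lt$locus_id[1L],
                   " does not match the field encoded in its ID"))
    }
  }
  loci
}

#' Write a locus table
#'
#' Inverse of [read_locus_table()]: segments are collapsed back into
#' comma-separated `start-end` position cells. Output is UTF-8 with LF line
#' endings. A `chromosome` column is written only when some locus ID does not
#' itself encode the chromosome.
#'
#' @param loci A [locus_table] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path) {
  validate_locus_table(loci)
  wide <- loci |>
    dplyr::group_by(.data$locus_id, .data$short_name, .data$chromosome, .data$strand) |>
    dplyr::summarise(
      position = paste(sprintf("%d-%d", as.integer(.data$start), as.integer(.data$end)),
                       collapse = ", "),
      .groups = "drop"
    )
  # preserve original row order
  wide <- wide[match(unique(loci$locus_id), wide$locus_id), ]
  encode_ok <- !anyNA(chromosome_from_id(wide$locus_id)) &&
    all(chromosome_from_id(wide$locus_id) == wide$chromosome)
  cols <- if (encode_ok) c("locus_id", "short_name", "strand", "position")
          else c("locus_id", "short_name", "chromosome", "strand", "position")
  readr::write_tsv(wide[, cols], path)
  invisible(path)
}

#' Path to a bundled example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
grasfam_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "grasfam"))
  } else {
    system.file("extdata", file, package = "grasfam", mustWork = TRUE)
  }
}

#' Read gene models from GFF3
#'
#' Builds a [locus_table] from `gene` and `exon` features of a GFF3 file,
#' grouping exons under their gene parent. GFF3 coordinates are 1-based
#' inclusive, matching the locus-table convention, so no conversion is
#' applied. Exons without a resolvable gene parent are an error. Segments are
#' stored in ascending genomic order also for minus-strand genes.
#'
#' @param path Path to a GFF3 file.
#' @return A [locus_table] tibble.
#' @export
read_family_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  types <- tolower(df$type)
  genes <- df[types == "gene", , drop = FALSE]
  exons <- df[types == "exon", , drop = FALSE]
  if (nrow(genes) == 0L && nrow(exons) == 0L) return(empty_locus_table())
  parent <- vapply(exons$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  if (anyNA(parent)) abort("GFF3 exon feature without a Parent attribute")
  if (!all(parent %in% genes$ID)) {
    abort("GFF3 exon feature whose Parent is not a gene in the file")
  }
  gi <- match(parent, genes$ID)
  name <- if ("Name" %in% names(genes)) genes$Name else genes$ID
  name <- ifelse(is.na(name), genes$ID, name)
  out <- tibble::tibble(
    locus_id = genes$ID[gi],
    short_name = name[gi],
    chromosome = as.integer(gsub("[^0-9]", "", as.character(exons$seqnames))),
    strand = as.character(genes$strand[gi]),
    start = as.numeric(exons$start),
    end = as.numeric(exons$end)
  ) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(exon = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("locus_id", "short_name", "chromosome", "strand",
                  "exon", "start", "end")
  # gene file order, segments ascending within each locus
  out <- out[order(match(out$locus_id, genes$ID), out$start), ]
  validate_locus_table(out)
}

#' Write gene models as GFF3
#'
#' @param loci A [locus_table] tibble.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_family_gff3 <- function(loci, path, source = "grasfam") {
  validate_locus_table(loci)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (id in unique(loci$locus_id)) {
    lt <- loci[loci$locus_id == id, ]
    chrom <- paste0("chr", lt$chromosome[1L])
    gene_line <- paste(chrom, source, "gene",
                       format(min(lt$start), scientific = FALSE),
                       format(max(lt$end), scientific = FALSE),
                       ".", lt$strand[1L], ".",
                       paste0("ID=", id, ";Name=", lt$short_name[1L]),
                       sep = "\t")
    exon_lines <- paste(chrom, source, "exon",
                        format(lt$start, scientific = FALSE),
                        format(lt$end, scientific = FALSE),
                        ".", lt$strand[1L], ".",
                        paste0("ID=", id, ".exon", lt$exon, ";Parent=", id),
                        sep = "\t")
    writeLines(c(gene_line, exon_lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read a paralogous-segment map
#'
#' The map pairs chromosome intervals descended from ancestral
#' polyploidization events, as a 6-column tab-separated file
#' (`chrom_a start_a end_a chrom_b start_b end_b`, 1-based inclusive).
#' Pairs are unordered: lookups treat (A, B) and (B, A) alike.
#'
#' @param path Path to the map file.
#' @return A tibble with one row per interval pair.
#' @export
read_segment_map <- function(path) {
  map <- readr::read_tsv(path, comment = "#",
                         col_types = "iddidd", progress = FALSE)
  names(map) <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
  validate_segment_map(map)
}

#' @rdname read_segment_map
#' @param map A segment-map tibble.
#' @export
validate_segment_map <- function(map) {
  if (any(map$end_a < map$start_a) || any(map$end_b < map$start_b)) {
    abort("segment map has an interval with end < start")
  }
  map
}

#' @rdname read_segment_map
#' @export
write_segment_map <- function(map, path) {
  validate_segment_map(map)
  readr::write_tsv(map, path)
  invisible(path)
}
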