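#' Protein records
#'
#' Proteins are carried as tibbles with columns `id`, `sequence`, `genome`
#' and `subfamily`. Sequences are uppercase strings over the 20 amino-acid
#' letters plus `X`; GRAS proteins are typically 400-700 residues, but length
#' is deliberately not enforced (truncated members are biologically real and
#' are flagged downstream, not rejected).
#'
#' @name protein_records
NULL

aa_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

normalize_protein <- function(sequence, id = NULL) {
  up <- toupper(sequence)
  bad <- gsub(paste0("[", paste(aa_letters, collapse = ""), "X]"), "", up)
  if (any(nzchar(bad))) {
    warn(paste0("illegal residue character(s) replaced by X",
                if (!is.null(id)) paste0(" in ", paste(id[nzchar(bad)], collapse = ", "))))
    up <- vapply(up, function(s) {
      chars <- strsplit(s, "")[[1L]]
      chars[!chars %in% c(aa_letters, "X")] <- "X"
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  up
}

#' Read a protein FASTA file
#'
#' Record IDs are the first whitespace-delimited token of each header and
#' file order is preserved. Lowercase residues are uppercased; characters
#' outside the 20-letter amino-acid alphabet plus `X` are replaced by `X`
#' with a warning. An empty file or an empty sequence is an error.
#'
#' @param path Path to a FASTA file.
#' @param genome Optional genome identifier stored with every record.
#' @return A [protein_records] tibble.
#' @export
read_protein_fasta <- function(path, genome = NA_character_) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no FASTA records in ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for record ", ids[!nzchar(seqs)][1L]))
  }
  tibble::tibble(id = ids,
                 sequence = normalize_protein(unname(seqs), ids),
                 genome = genome,
                 subfamily = NA_character_)
}

#' Write protein records as FASTA
#'
#' Sequences are wrapped at 60 columns; output is UTF-8 with LF line endings,
#' so writing and re-reading a record set is byte-stable.
#'
#' @param proteins A [protein_records] tibble (columns `id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con, sep = "\n")
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con, sep = "\n")
  }
  invisible(path)
}
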