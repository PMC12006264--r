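#' Read protein sequences from a FASTA file
#'
#' Reads ungapped protein sequences into a tibble, one row per record.
#' Residues must be drawn from the 20 canonical one-letter codes plus `X`
#' (unknown); gap characters are rejected because gapped records belong in an
#' alignment, not a sequence set (see [read_alignment()]).
#'
#' @param path Path to a FASTA file.
#' @param species Optional character vector recycled across records and stored
#'   in the `species` column; defaults to the record id.
#' @return A tibble with columns `id`, `species`, `residues` in file order.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "MKV"), tf)
#' read_fasta(tf)
read_fasta <- function(path, species = NULL) {
  recs <- parse_fasta(path)
  bad <- stringr::str_detect(recs$seq, "-")
  if (any(bad)) {
    abort(sprintf(
      "gap character '-' in record '%s' (line %d): gapped records must be read with read_alignment()",
      recs$id[which(bad)[1]], recs$line[which(bad)[1]]
    ))
  }
  validate_residues(recs$seq, recs$id, recs$line)
  tibble::tibble(
    id = recs$id,
    species = if (is.null(species)) recs$id else rep_len(species, nrow(recs)),
    residues = recs$seq
  )
}

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA file into an alignment frame: a tibble with one row
#' per sequence and the gapped string in `aligned`. All rows must have equal
#' length, no column may be all gaps, and ungapping any row must give a valid
#' protein sequence.
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @return A tibble of class `aln_frame` with columns `id`, `aligned` and an
#'   `n_columns` attribute.
#' @export
read_alignment <- function(path) {
  recs <- parse_fasta(path)
  validate_residues(stringr::str_remove_all(recs$seq, "-"), recs$id, recs$line)
  new_alignment(recs$id, recs$seq)
}

#' Build an alignment frame from gapped strings
#'
#' @param ids Character vector of row identifiers.
#' @param aligned Character vector of equal-length gapped sequences.
#' @return An `aln_frame` tibble.
#' @export
new_alignment <- function(ids, aligned) {
  stopifnot(length(ids) == length(aligned), !anyDuplicated(ids))
  lens <- stringr::str_length(aligned)
  if (length(unique(lens)) > 1L) {
    off <- ids[lens != lens[1]]
    abort(sprintf(
      "ragged alignment: rows %s differ in length from row '%s' (%d columns)",
      paste0("'", off, "'", collapse = ", "), ids[1], lens[1]
    ))
  }
  mat <- alignment_matrix_chr(aligned)
  all_gap <- which(colSums(mat != "-") == 0L)
  if (length(all_gap) > 0L) {
    abort(sprintf(
      "alignment column(s) %s contain only gaps",
      paste(all_gap, collapse = ", ")
    ))
  }
  out <- tibble::tibble(id = as.character(ids), aligned = as.character(aligned))
  attr(out, "n_columns") <- unname(lens[1])
  class(out) <- c("aln_frame", class(out))
  out
}

#' Number of columns of an alignment frame
#' @param frame An `aln_frame`.
#' @return Integer column count.
#' @export
n_columns <- function(frame) {
  attr(frame, "n_columns") %||% unique(stringr::str_length(frame$aligned))
}

#' Write sequences or an alignment to FASTA
#'
#' @param x A tibble with `id` and either `residues` (sequences) or `aligned`
#'   (alignment rows).
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  seqs <- if ("aligned" %in% names(x)) x$aligned else x$residues
  lines <- purrr::map2(x$id, seqs, function(id, s) {
    body <- if (is.finite(width) && stringr::str_length(s) > width) {
      substring(s, seq(1, stringr::str_length(s), width),
                pmin(seq(width, stringr::str_length(s) + width - 1, width),
                     stringr::str_length(s)))
    } else s
    c(paste0(">", id), body)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Drop gaps from one alignment row
#'
#' @param frame An `aln_frame`.
#' @param id Row identifier.
#' @return The ungapped sequence string.
#' @export
ungap <- function(frame, id) {
  stringr::str_remove_all(aln_row(frame, id), "-")
}

# ---- internal helpers --------------------------------------------------------

parse_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", raw) & !grepl("^;", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) abort(sprintf("empty FASTA file: %s", path))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    abort(sprintf("malformed FASTA: line %d is not a header", lineno[1]))
  }
  grp <- cumsum(is_hdr)
  ids <- stringr::str_trim(sub("^>\\s*", "", lines[is_hdr]))
  ids <- stringr::str_extract(ids, "^\\S+")
  if (anyNA(ids) || any(ids == "")) {
    bad <- lineno[is_hdr][which(is.na(ids) | ids == "")[1]]
    abort(sprintf("malformed FASTA header at line %d", bad))
  }
  seqs <- vapply(
    split(lines[!is_hdr], grp[!is_hdr]),
    function(x) paste0(toupper(gsub("\\s", "", x)), collapse = ""),
    character(1)
  )
  # records with a header but no body
  full <- as.character(seq_along(ids))
  seqs <- seqs[full]
  seqs[is.na(seqs)] <- ""
  empty <- which(seqs == "")
  if (length(empty) > 0L) {
    abort(sprintf(
      "record '%s' (line %d) has no sequence",
      ids[empty[1]], lineno[is_hdr][empty[1]]
    ))
  }
  tibble::tibble(id = ids, seq = unname(seqs), line = lineno[is_hdr])
}

validate_residues <- function(seqs, ids, lines) {
  ok_chars <- paste0(c(AA_CODES, "X"), collapse = "")
  bad <- stringr::str_detect(seqs, paste0("[^", ok_chars, "]"))
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- stringr::str_extract(seqs[i], paste0("[^", ok_chars, "]"))
    abort(sprintf(
      "illegal residue character '%s' in record '%s' (starting line %d)",
      ch, ids[i], lines[i]
    ))
  }
  invisible(TRUE)
}

alignment_matrix_chr <- function(aligned) {
  do.call(rbind, stringr::str_split(aligned, ""))
}

aln_row <- function(frame, id) {
  i <- match(id, frame$id)
  if (is.na(i)) {
    abort(sprintf(
      "id '%s' not in alignment (rows: %s)", id,
      paste(frame$id, collapse = ", ")
    ))
  }
  frame$aligned[i]
}
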