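# Sequence records, collections, FASTA and association-table I/O.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Construct a sequence record
#'
#' A `seq_record` holds one genome: an id, an ordered set of contig strings
#' (uppercase DNA), a role, and the total length in nucleotides.
#'
#' @param id Record identifier, non-empty string.
#' @param contigs Character vector of DNA contig sequences.
#' @param role One of `"host"`, `"phage"`, `"plasmid"`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, contigs, role = c("host", "phage", "plasmid")) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  contigs <- toupper(as.character(contigs))
  .validate_dna(contigs, id)
  structure(
    list(id = id, contigs = contigs, role = role,
         length = sum(nchar(contigs))),
    class = "seq_record")
}

.validate_dna <- function(contigs, id) {
  for (i in seq_along(contigs)) {
    bad <- regexpr(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")),
                   contigs[[i]])
    if (bad != -1L)
      stop(sprintf(
        "non-IUPAC character '%s' at position %d of contig %d in '%s'",
        substr(contigs[[i]], bad, bad), bad, i, id))
  }
  invisible(TRUE)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s] %d contig(s), %d nt\n",
              x$id, x$role, length(x$contigs), x$length))
  invisible(x)
}

#' Bundle sequence records into a collection
#'
#' @param records List of [seq_record()] objects with unique ids.
#' @return A named list of class `seq_collection` (names are record ids).
#' @export
seq_collection <- function(records) {
  ids <- vapply(records, function(r) r$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate sequence id: '%s'", dup[[1]]))
  structure(setNames(records, ids), class = "seq_collection")
}

#' @export
print.seq_collection <- function(x, ...) {
  cat(sprintf("<seq_collection> %d record(s), %.0f nt total\n",
              length(x), sum(vapply(x, function(r) r$length, numeric(1)))))
  invisible(x)
}

#' @export
`[.seq_collection` <- function(x, i) {
  seq_collection(unclass(x)[i])
}

#' Read genome sequences from FASTA
#'
#' Loads plain or gzip-compressed FASTA. In `"per-file"` mode all records in
#' the file become contigs of a single genome named after the file stem (the
#' convention for multi-contig host assemblies); in `"per-record"` mode every
#' FASTA record is its own genome, named by the header token before the first
#' whitespace (the convention for phage/plasmid collections). Sequences are
#' uppercased on load; soft-masking is ignored.
#'
#' @param path Path to a FASTA file.
#' @param role Role assigned to all loaded records (`"host"`, `"phage"`,
#'   `"plasmid"`).
#' @param concatenate `"per-file"` or `"per-record"` (see above).
#' @return A [seq_collection()].
#' @export
read_fasta <- function(path, role = c("host", "phage", "plasmid"),
                       concatenate = c("per-record", "per-file")) {
  role <- match.arg(role)
  concatenate <- match.arg(concatenate)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) .rescan_fasta_error(path, conditionMessage(e))),
    # Biostrings drops invalid letters with a warning; the io contract is to
    # fail naming the offending character and its position
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        .rescan_fasta_error(path, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) stop(sprintf("no sequences in %s", path))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (concatenate == "per-file") {
    stem <- tools::file_path_sans_ext(basename(path), compression = TRUE)
    seq_collection(list(seq_record(stem, unname(seqs), role)))
  } else {
    seq_collection(mapply(function(id, s) seq_record(id, s, role),
                          ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
}

# When Biostrings rejects a file, locate the first offending character so the
# error names it with its within-record position.
.rescan_fasta_error <- function(path, original) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (!is.null(lines)) {
    pos <- 0L
    rec <- NULL
    for (ln in lines) {
      if (startsWith(ln, ">")) { rec <- sub("\\s.*$", "", substring(ln, 2)); pos <- 0L; next }
      ln <- toupper(ln)
      bad <- regexpr(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), ln)
      if (bad != -1L)
        stop(sprintf("non-IUPAC character '%s' at position %d of record '%s'",
                     substr(ln, bad, bad), pos + bad, rec %||% "?"),
             call. = FALSE)
      pos <- pos + nchar(ln)
    }
  }
  stop(sprintf("cannot parse FASTA %s: %s", path, original), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a collection to FASTA
#'
#' Multi-contig records are written as one FASTA record per contig, headers
#' `id` (single contig) or `id|contig<i>`.
#'
#' @param collection A [seq_collection()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(collection, path) {
  seqs <- character(0)
  for (rec in collection) {
    nm <- if (length(rec$contigs) == 1L) rec$id else
      sprintf("%s|contig%d", rec$id, seq_along(rec$contigs))
    seqs <- c(seqs, setNames(rec$contigs, nm))
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path,
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a phage/plasmid-to-host association table
#'
#' Expects a TSV with header columns `element_id`, `role`, `host_group` and
#' optionally `lifestyle` (values `lytic`/`lysogenic`, case-insensitive;
#' empty = unlabelled query). Extra columns are preserved.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with normalized columns; `lifestyle` is `NA` where
#'   absent.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("element_id", "role", "host_group")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(sprintf("association table missing column(s): %s",
                 paste(missing, collapse = ", ")))
  bad_role <- setdiff(unique(tab$role), c("phage", "plasmid"))
  if (length(bad_role))
    stop(sprintf("unknown element role '%s' (expected phage or plasmid)",
                 bad_role[[1]]))
  if (!"lifestyle" %in% names(tab)) tab$lifestyle <- NA_character_
  ls <- tolower(trimws(as.character(tab$lifestyle)))
  ls[!nzchar(ls) | is.na(ls)] <- NA_character_
  bad <- setdiff(unique(ls[!is.na(ls)]), c("lytic", "lysogenic"))
  if (length(bad))
    stop(sprintf("unknown lifestyle value '%s' (expected lytic or lysogenic)",
                 bad[[1]]))
  tab$lifestyle <- ls
  tab
}
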