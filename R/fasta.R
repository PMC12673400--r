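#' Construct a table of protein records
#'
#' The package's working container for sequence sets is a plain data frame
#' with one row per sequence and columns `id`, `sequence`, `role`, `source`.
#' `role` tracks provenance through the pipeline: training corpora are
#' `"base"` or `"finetune"`, model output is `"generated"`, and screened
#' survivors are `"candidate"`.
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of sequences (validated and uppercased).
#' @param role One of `"base"`, `"finetune"`, `"generated"`, `"candidate"`;
#'   recycled across records.
#' @param source Free-text provenance; recycled.
#' @return A `pf_records` data frame.
#' @export
protein_records <- function(id, sequence, role = "base", source = "") {
  role <- match.arg(role, c("base", "finetune", "generated", "candidate"))
  if (length(id) != length(sequence)) {
    stop2("`id` and `sequence` must have the same length")
  }
  if (anyDuplicated(id)) {
    stop2("duplicate record ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- vapply(sequence, validate_sequence, character(1L), USE.NAMES = FALSE)
  out <- data.frame(
    id = as.character(id),
    sequence = sequence,
    role = role,
    source = rep_len(as.character(source), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pf_records", "data.frame")
  out
}

#' Read protein records from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file. Record ids are
#' the header text up to the first whitespace; the remainder of the header is
#' kept as `source`. Sequences are uppercased and validated against the
#' canonical 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param role Role assigned to every record (see [protein_records()]).
#' @param skip_invalid If `TRUE`, records containing non-canonical residues
#'   are dropped with a warning instead of raising an error.
#' @return A `pf_records` data frame in file order.
#' @export
read_fasta <- function(path, role = "base", skip_invalid = FALSE) {
  role <- match.arg(role, c("base", "finetune", "generated", "candidate"))
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stop2("FASTA file is empty: ", path)
  first <- nonempty[1L]
  if (!startsWith(lines[first], ">")) {
    stop2(sprintf("malformed FASTA: line %d does not start a record ('%s')",
                  first, substr(lines[first], 1L, 40L)))
  }
  headers <- which(startsWith(lines, ">"))
  blank_id <- headers[!nzchar(trimws(sub("^>", "", lines[headers])))]
  if (length(blank_id)) {
    stop2(sprintf("malformed FASTA: empty header at line %d", blank_id[1L]))
  }

  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop2("FASTA file contains no records: ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- trimws(sub("^\\S+\\s*", "", full))
  seqs <- as.character(set)

  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    ok <- tryCatch({ seqs[i] <- validate_sequence(seqs[i]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      if (skip_invalid) {
        warning(sprintf("dropping record '%s': %s", ids[i], conditionMessage(ok)),
                call. = FALSE)
        keep[i] <- FALSE
      } else {
        stop2(sprintf("record '%s': %s", ids[i], conditionMessage(ok)))
      }
    }
  }
  if (!any(keep)) stop2("no valid records left after filtering: ", path)
  protein_records(ids[keep], seqs[keep], role = role, source = desc[keep])
}

#' Write protein records to a FASTA file
#'
#' @param records A `pf_records` data frame.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(inherits(records, "pf_records"), nrow(records) >= 1L)
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' @export
print.pf_records <- function(x, ...) {
  cat(sprintf("<pf_records> %d sequence(s), roles: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  lens <- nchar(x$sequence)
  cat(sprintf("  lengths: %d-%d (median %g)\n", min(lens), max(lens),
              stats::median(lens)))
  utils::head(as.data.frame(x)[, c("id", "role")], 5L) |> print()
  invisible(x)
}
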