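#' The canonical residue alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter order,
#' `ACDEFGHIKLMNPQRSTVWY`. Integer codes used throughout the package are
#' 0-based positions in this ordering, so `A` encodes to 0 and `Y` to 19.
#' Non-canonical symbols (`X`, `B`, `Z`, `U`, `*`, gaps) have no code: the
#' model vocabulary has exactly 20 symbols and no wildcard or pad token.
#'
#' @return Character vector of 20 single-letter residue codes.
#' @export
#' @examples
#' residue_alphabet()
residue_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# letter -> 0-based code lookup, built once at load time
.alphabet_index <- local({
  idx <- seq_len(20L) - 1L
  names(idx) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  idx
})

#' Validate a peptide or protein sequence
#'
#' Uppercases the input and checks that every character is one of the 20
#' canonical amino acids. The first offending character is reported with its
#' 1-based position.
#'
#' @param seq Single character string.
#' @return The validated, uppercased sequence.
#' @export
#' @examples
#' validate_sequence("acdy")
validate_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop2("`seq` must be a single character string")
  }
  if (!nzchar(seq)) stop2("sequence is empty")
  up <- toupper(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% residue_alphabet())
  if (length(bad)) {
    stop2(sprintf(
      "non-canonical residue '%s' at position %d (alphabet is %s)",
      chars[bad[1L]], bad[1L], paste(residue_alphabet(), collapse = "")
    ))
  }
  up
}

#' Integer-encode a validated sequence
#'
#' Maps each residue to its 0-based index in [residue_alphabet()], so
#' `"ACD"` becomes `c(0, 1, 2)`.
#'
#' @param seq Validated sequence string (see [validate_sequence()]).
#' @return Integer vector in `0:19`, one element per residue.
#' @seealso [decode_sequence()]
#' @export
#' @examples
#' encode_sequence("KLVFF")
encode_sequence <- function(seq) {
  seq <- validate_sequence(seq)
  unname(.alphabet_index[strsplit(seq, "", fixed = TRUE)[[1L]]])
}

#' Decode integer codes back to a residue string
#'
#' @param codes Integer vector with values in `0:19`.
#' @return Character string over the canonical alphabet.
#' @export
#' @examples
#' decode_sequence(c(8, 9, 17, 4, 4))
decode_sequence <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) == 0L) stop2("`codes` is empty")
  if (anyNA(codes) || any(codes < 0L | codes > 19L)) {
    stop2("codes must be integers in 0..19")
  }
  paste(residue_alphabet()[codes + 1L], collapse = "")
}
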