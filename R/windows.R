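#' Build sliding next-residue training windows from one encoded sequence
#'
#' Applies a sliding window of `window` residues: the first `window - 1`
#' integer codes form the context and the final code is the prediction
#' target. A sequence of length `L >= window` yields exactly
#' `L - window + 1` windows; shorter sequences yield none (with a warning),
#' since the vocabulary has no pad token.
#'
#' @param encoded Integer vector of residue codes in `0:19`
#'   (see [encode_sequence()]).
#' @param window Window length in residues; context length is `window - 1`.
#'   Default 35 (34-residue context).
#' @return A `pf_windows` object: list with `context` (n x (window-1) integer
#'   matrix) and `target` (length-n integer vector).
#' @export
#' @examples
#' w <- make_windows(encode_sequence(strrep("ACDEFGH", 10)))
#' nrow(w$context)
make_windows <- function(encoded, window = 35L) {
  window <- as.integer(window)
  if (!is_count(window) || window < 2L) stop2("`window` must be an integer >= 2")
  encoded <- as.integer(encoded)
  if (anyNA(encoded) || (length(encoded) && any(encoded < 0L | encoded > 19L))) {
    stop2("encoded values must lie in 0..19")
  }
  L <- length(encoded)
  n <- L - window + 1L
  if (n < 1L) {
    warning(sprintf("sequence of length %d is shorter than window %d; no windows",
                    L, window), call. = FALSE)
    out <- list(context = matrix(integer(0), nrow = 0L, ncol = window - 1L),
                target = integer(0), window = window)
    class(out) <- "pf_windows"
    return(out)
  }
  ctx <- matrix(0L, nrow = n, ncol = window - 1L)
  for (j in seq_len(window - 1L)) ctx[, j] <- encoded[j:(j + n - 1L)]
  out <- list(context = ctx, target = encoded[window:(window + n - 1L)],
              window = window)
  class(out) <- "pf_windows"
  out
}

#' Build the pooled training-window set for a corpus
#'
#' Encodes every record and concatenates its sliding windows. The total
#' window count equals `sum(pmax(0, L - window + 1))` over record lengths.
#'
#' @param records A `pf_records` data frame.
#' @param window Window length in residues (default 35).
#' @return A `pf_windows` object covering the whole corpus; the attribute
#'   `"per_record"` holds a data frame of `id`, `length`, `n_windows`.
#' @export
corpus_windows <- function(records, window = 35L) {
  stopifnot(inherits(records, "pf_records"))
  parts <- vector("list", nrow(records))
  counts <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    parts[[i]] <- suppressWarnings(
      make_windows(encode_sequence(records$sequence[i]), window)
    )
    counts[i] <- length(parts[[i]]$target)
  }
  if (sum(counts) == 0L) {
    stop2("no record is long enough for window size ", window)
  }
  out <- list(
    context = do.call(rbind, lapply(parts, `[[`, "context")),
    target = unlist(lapply(parts, `[[`, "target"), use.names = FALSE),
    window = as.integer(window)
  )
  attr(out, "per_record") <- data.frame(
    id = records$id, length = nchar(records$sequence), n_windows = counts,
    stringsAsFactors = FALSE
  )
  class(out) <- "pf_windows"
  out
}

#' @export
print.pf_windows <- function(x, ...) {
  cat(sprintf("<pf_windows> %d window(s), context length %d\n",
              length(x$target), ncol(x$context)))
  invisible(x)
}
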