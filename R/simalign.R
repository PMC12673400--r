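# Novelty scoring by pairwise global alignment against the fine-tuning
# references, and the final similarity-based shortlist.
#
# Alignments are Needleman-Wunsch with affine gaps via
# Biostrings::pairwiseAlignment (BLOSUM62, gap open 10, gap extend 0.5 --
# EMBOSS-needle-like defaults). Percent identity uses the full alignment
# length, gap columns included, as the denominator; tools differ here and
# shorter-sequence denominators inflate identity.

#' Alignment parameters
#'
#' @param substitution_matrix Name of a substitution matrix bundled with
#'   Biostrings (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A `pf_align_params` list.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  cfg <- list(substitution_matrix = substitution_matrix,
              gap_open = as.numeric(gap_open),
              gap_extend = as.numeric(gap_extend))
  if (cfg$gap_open < 0 || cfg$gap_extend < 0) {
    stop2("gap penalties must be non-negative")
  }
  class(cfg) <- "pf_align_params"
  cfg
}

#' Percent identity of a global pairwise alignment
#'
#' Aligns two sequences end-to-end (Needleman-Wunsch, affine gaps) and
#' returns `100 * identical columns / alignment length` with gap columns
#' counted in the denominator. Identical sequences score exactly 100;
#' swapping the arguments changes the value only through tie-breaking among
#' co-optimal alignments.
#'
#' @param a,b Sequence strings (validated internally).
#' @param params An [align_params()].
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("ACDE", "ACDF")
percent_identity <- function(a, b, params = align_params()) {
  a <- validate_sequence(a)
  b <- validate_sequence(b)
  stopifnot(inherits(params, "pf_align_params"))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "", fixed = TRUE)[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "", fixed = TRUE)[[1L]]
  100 * sum(pa == sa & pa != "-") / length(pa)
}

#' Candidate-by-reference percent-identity table
#'
#' Computes the full matrix of pairwise global-alignment identities between
#' every candidate and every reference; deterministic given the parameters.
#'
#' @param candidates,refs `pf_records` data frames.
#' @param params An [align_params()].
#' @return Numeric matrix (candidates x references) with id dimnames and
#'   attribute `"params"`.
#' @export
identity_table <- function(candidates, refs, params = align_params()) {
  stopifnot(inherits(candidates, "pf_records"), inherits(refs, "pf_records"))
  if (!nrow(candidates) || !nrow(refs)) stop2("empty candidate or reference set")
  m <- matrix(NA_real_, nrow(candidates), nrow(refs),
              dimnames = list(candidates$id, refs$id))
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(refs))) {
      m[i, j] <- percent_identity(candidates$sequence[i], refs$sequence[j],
                                  params)
    }
  }
  attr(m, "params") <- params
  m
}

#' Shortlist configuration
#'
#' @param keep Maximum number of candidates in the final shortlist
#'   (default 11).
#' @param novelty_ceiling Candidates whose similarity statistic reaches this
#'   percent identity are excluded as insufficiently novel (default 60).
#' @param rank_by Similarity statistic per candidate: `"max_identity"`
#'   (default) or `"mean_identity"` across the references.
#' @return A `pf_shortlist_config` list.
#' @export
shortlist_config <- function(keep = 11L, novelty_ceiling = 60,
                             rank_by = c("max_identity", "mean_identity")) {
  rank_by <- match.arg(rank_by)
  cfg <- list(keep = as.integer(keep),
              novelty_ceiling = as.numeric(novelty_ceiling),
              rank_by = rank_by)
  if (!is_positive_count(cfg$keep)) stop2("`keep` must be >= 1")
  if (!(cfg$novelty_ceiling > 0 && cfg$novelty_ceiling <= 100)) {
    stop2("`novelty_ceiling` must lie in (0, 100]")
  }
  class(cfg) <- "pf_shortlist_config"
  cfg
}

#' Final similarity-based shortlist
#'
#' Ranks candidates by their similarity statistic against the references
#' (highest first -- the shortlist favours candidates sharing the most
#' signal with validated peptides), excludes any at or above the novelty
#' ceiling, and truncates to `keep`. Ties break by candidate id. A warning
#' is emitted when fewer than `keep` candidates qualify.
#'
#' @param candidates A `pf_records` data frame covered by `table`'s rows.
#' @param table An [identity_table()] over these candidates.
#' @param config A [shortlist_config()].
#' @return The shortlisted `pf_records` rows, with attribute `"similarity"`
#'   (a data frame of id and statistic in shortlist order).
#' @export
shortlist <- function(candidates, table, config = shortlist_config()) {
  stopifnot(inherits(candidates, "pf_records"), is.matrix(table))
  if (!all(candidates$id %in% rownames(table))) {
    stop2("identity table does not cover all candidates")
  }
  stat <- switch(config$rank_by,
    max_identity = apply(table[candidates$id, , drop = FALSE], 1L, max),
    mean_identity = rowMeans(table[candidates$id, , drop = FALSE])
  )
  qual <- stat < config$novelty_ceiling
  if (sum(qual) < config$keep) {
    warning(sprintf("only %d candidate(s) fall below the novelty ceiling (%g%%); shortlist is short of keep=%d",
                    sum(qual), config$novelty_ceiling, config$keep), call. = FALSE)
  }
  ids <- candidates$id[qual]
  ord <- order(-stat[qual], ids)
  sel_ids <- ids[ord][seq_len(min(config$keep, length(ids)))]
  out <- candidates[match(sel_ids, candidates$id), , drop = FALSE]
  class(out) <- c("pf_records", "data.frame")
  attr(out, "similarity") <- data.frame(id = sel_ids,
                                        statistic = unname(stat[sel_ids]),
                                        stringsAsFactors = FALSE)
  out
}

#' Write an identity table as TSV
#'
#' Candidate rows, reference columns, mirroring the conventional
#' identity-matrix layout.
#'
#' @param table An [identity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_table <- function(table, path) {
  df <- data.frame(candidate = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
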