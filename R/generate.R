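# Candidate-pool generation by seeded autoregressive greedy decoding.
#
# Greedy decoding is deterministic per seed context, so pool diversity comes
# entirely from where the seed windows are drawn. Decoding is batched: all
# pool members advance one residue per model call, which keeps generation of
# a 1,000-sequence pool to ~max_len forward passes.

#' Generation configuration
#'
#' Defaults reproduce the reference pool: 1,000 peptides with target lengths
#' drawn uniformly from 80-100 residues, seeded from the fine-tuning corpus.
#'
#' @param n_sequences Number of peptides to generate.
#' @param min_len,max_len Inclusive bounds on the emitted peptide length.
#' @param seed_source Which corpus role supplies seed windows: `"finetune"`,
#'   `"base"`, or `"both"`.
#' @param rng_seed Integer seed for seed-window sampling and length draws.
#' @param include_seed If `TRUE`, the 34-residue seed window is kept as a
#'   prefix of the emitted peptide; by default peptides consist solely of
#'   model-generated residues.
#' @param dedupe Drop duplicate peptides (keeping first occurrence). Off by
#'   default: the reference pool is a flat count.
#' @return A `pf_generation_config` list.
#' @export
generation_config <- function(n_sequences = 1000L,
                              min_len = 80L,
                              max_len = 100L,
                              seed_source = c("finetune", "base", "both"),
                              rng_seed = 42L,
                              include_seed = FALSE,
                              dedupe = FALSE) {
  seed_source <- match.arg(seed_source)
  cfg <- list(
    n_sequences = as.integer(n_sequences),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    seed_source = seed_source,
    rng_seed = as.integer(rng_seed),
    include_seed = isTRUE(include_seed),
    dedupe = isTRUE(dedupe)
  )
  if (!is_positive_count(cfg$n_sequences)) stop2("`n_sequences` must be >= 1")
  if (cfg$min_len < 2L || cfg$min_len > cfg$max_len) {
    stop2("need 2 <= min_len <= max_len")
  }
  class(cfg) <- "pf_generation_config"
  cfg
}

# all (record, offset) pairs able to supply a context window
seed_universe <- function(records, context_len) {
  lens <- nchar(records$sequence)
  eligible <- which(lens >= context_len)
  if (!length(eligible)) {
    stop2("no sequence of length >= ", context_len, " to seed from")
  }
  counts <- lens[eligible] - context_len + 1L
  list(eligible = eligible, counts = counts, total = sum(counts))
}

#' Draw a random seed context from a corpus
#'
#' Samples uniformly over all (sequence, start-offset) pairs that can supply
#' a contiguous window of `context_len` residues, then returns that window
#' integer-encoded. Uses the caller's RNG stream.
#'
#' @param records A `pf_records` data frame to seed from.
#' @param context_len Window length in residues (default 34, matching the
#'   default model context).
#' @return Integer vector of length `context_len` with values in `0:19`.
#' @export
make_seed <- function(records, context_len = 34L) {
  stopifnot(inherits(records, "pf_records"))
  context_len <- as.integer(context_len)
  u <- seed_universe(records, context_len)
  pick <- sample.int(u$total, 1L)
  cum <- cumsum(u$counts)
  k <- which(pick <= cum)[1L]
  offset <- pick - c(0L, cum)[k]
  rec <- u$eligible[k]
  encode_sequence(substr(records$sequence[rec], offset, offset + context_len - 1L))
}

# Batched greedy decode: ctx is an n x context_len matrix of 0-based codes;
# emits `steps` residues per row. Argmax ties resolve to the lowest residue
# index (max.col ties.method = "first"), deterministically across platforms.
greedy_decode <- function(model, ctx, steps) {
  out <- matrix(0L, nrow = nrow(ctx), ncol = steps)
  for (s in seq_len(steps)) {
    pr <- model_forward(model, ctx)$probs
    nxt <- max.col(pr, ties.method = "first") - 1L
    out[, s] <- nxt
    ctx <- cbind(ctx[, -1L, drop = FALSE], nxt)
  }
  out
}

#' Generate one peptide by greedy decoding
#'
#' Starting from a seed context, repeatedly appends the argmax of the
#' model's next-residue distribution (context always the last
#' `window - 1` residues) until `target_len` new residues have been
#' emitted. Deterministic given model and seed context.
#'
#' @param model A trained (or untrained) `pf_model`.
#' @param seed Integer context of length `window - 1` (see [make_seed()]).
#' @param target_len Number of residues to emit.
#' @param include_seed Prepend the decoded seed window to the output.
#' @param id Record identifier.
#' @return A single-row `pf_records` data frame with role `"generated"`.
#' @export
generate_one <- function(model, seed, target_len, include_seed = FALSE,
                         id = "GEN_0001") {
  stopifnot(inherits(model, "pf_model"))
  seed <- as.integer(seed)
  Tlen <- model$config$window - 1L
  if (length(seed) != Tlen) stop2("seed context must have length ", Tlen)
  if (!is_positive_count(target_len)) stop2("`target_len` must be positive")
  emitted <- greedy_decode(model, matrix(seed, nrow = 1L), as.integer(target_len))
  codes <- if (include_seed) c(seed, emitted[1L, ]) else emitted[1L, ]
  protein_records(id, decode_sequence(codes), role = "generated",
                  source = "greedy decoding")
}

#' Generate the candidate pool
#'
#' Draws `n_sequences` seed windows from the chosen corpus, a target length
#' per peptide uniformly from `[min_len, max_len]`, and greedy-decodes all
#' peptides in lock-step batches. Record ids are `GEN_0001`, `GEN_0002`, ...
#' in generation order. The whole pool is a deterministic function of the
#' model, the corpus and `rng_seed`.
#'
#' @param model A trained `pf_model`.
#' @param records Corpus supplying seed windows (filtered by
#'   `config$seed_source` role).
#' @param config A [generation_config()].
#' @return A `pf_records` data frame of `n_sequences` generated peptides.
#' @export
generate_pool <- function(model, records, config = generation_config()) {
  stopifnot(inherits(model, "pf_model"), inherits(records, "pf_records"),
            inherits(config, "pf_generation_config"))
  pool_src <- switch(config$seed_source,
    finetune = records[records$role == "finetune", , drop = FALSE],
    base = records[records$role == "base", , drop = FALSE],
    both = records
  )
  class(pool_src) <- class(records)
  if (!nrow(pool_src)) {
    stop2("no records with role '", config$seed_source, "' to seed from")
  }
  Tlen <- model$config$window - 1L
  n <- config$n_sequences

  res <- with_seed(config$rng_seed, {
    seeds <- matrix(0L, nrow = n, ncol = Tlen)
    for (i in seq_len(n)) seeds[i, ] <- make_seed(pool_src, Tlen)
    lens <- sample_range(config$min_len, config$max_len, n)
    list(seeds = seeds, lens = lens)
  })

  emitted <- greedy_decode(model, res$seeds, max(res$lens))
  width <- max(4L, nchar(as.character(n)))
  ids <- sprintf(paste0("GEN_%0", width, "d"), seq_len(n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    codes <- emitted[i, seq_len(res$lens[i])]
    if (config$include_seed) codes <- c(res$seeds[i, ], codes)
    seqs[i] <- decode_sequence(codes)
  }
  out <- protein_records(ids, seqs, role = "generated", source = "greedy decoding")
  if (config$dedupe) {
    keep <- !duplicated(out$sequence)
    if (!all(keep)) {
      message(sprintf("dedupe: dropped %d duplicate peptide(s)", sum(!keep)))
    }
    out <- out[keep, , drop = FALSE]
    class(out) <- c("pf_records", "data.frame")
  }
  out
}
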