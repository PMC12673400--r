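# Synthetic corpora with planted, exactly recoverable structure.
#
# Two generators: a motif corpus shaped like the real training data (a
# handful of long base proteins plus short fine-tuning peptides, with a
# deterministic k-mer motif planted at a controlled rate), and a
# deterministic-successor corpus in which every residue has exactly one
# successor, giving next-residue prediction an exact oracle.

#' Specification for a synthetic motif corpus
#'
#' Defaults emulate the shape of the reference training data: 7 base
#' proteins of 230-1,019 residues and 6 fine-tuning peptides of at most 100
#' residues, with the amyloid-beta recognition core `KLVFF` planted as the
#' learnable motif.
#'
#' @param n_base,n_finetune Record counts for the two corpora.
#' @param base_len_range Length range (inclusive) of base sequences.
#' @param finetune_len_range Length range of fine-tuning peptides.
#' @param motif Alphabet-valid peptide string planted into the background.
#' @param motif_rate Expected motif insertions per 100 residues.
#' @param rng_seed Integer seed; the corpus is a pure function of the spec.
#' @return A `pf_motif_spec` list.
#' @export
motif_corpus_spec <- function(n_base = 7L, n_finetune = 6L,
                              base_len_range = c(230L, 1019L),
                              finetune_len_range = c(50L, 100L),
                              motif = "KLVFF", motif_rate = 5,
                              rng_seed = 42L) {
  spec <- list(n_base = as.integer(n_base),
               n_finetune = as.integer(n_finetune),
               base_len_range = as.integer(base_len_range),
               finetune_len_range = as.integer(finetune_len_range),
               motif = validate_sequence(motif),
               motif_rate = as.numeric(motif_rate),
               rng_seed = as.integer(rng_seed))
  if (!is_positive_count(spec$n_base) || !is_positive_count(spec$n_finetune)) {
    stop2("record counts must be positive")
  }
  for (f in c("base_len_range", "finetune_len_range")) {
    r <- spec[[f]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L) {
      stop2("`", f, "` must be an ordered positive pair")
    }
  }
  if (spec$motif_rate < 0) stop2("`motif_rate` must be non-negative")
  class(spec) <- "pf_motif_spec"
  spec
}

random_residues <- function(n) {
  sample(residue_alphabet(), n, replace = TRUE)
}

# Overwrite the motif at n ~ Pois(rate * L / 100) non-overlapping random
# positions (greedy placement so no insertion clobbers another).
plant_motif <- function(chars, motif, rate) {
  L <- length(chars)
  k <- nchar(motif)
  if (rate <= 0 || L < k) return(chars)
  n_ins <- stats::rpois(1L, rate * L / 100)
  if (n_ins == 0L) return(chars)
  mchars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  candidates <- sample.int(L - k + 1L)
  occupied <- logical(L)
  placed <- 0L
  for (s in candidates) {
    if (placed >= n_ins) break
    span <- s:(s + k - 1L)
    if (any(occupied[span])) next
    chars[span] <- mchars
    occupied[span] <- TRUE
    placed <- placed + 1L
  }
  chars
}

#' Generate a synthetic motif corpus
#'
#' Sequences are uniform-random over the 20-letter alphabet with the motif
#' overwritten at Poisson-distributed positions at the specified rate.
#' Referentially transparent: the same spec always yields the same corpus.
#'
#' @param spec A [motif_corpus_spec()].
#' @return List with `base` and `finetune` `pf_records` data frames.
#' @export
motif_corpus <- function(spec = motif_corpus_spec()) {
  stopifnot(inherits(spec, "pf_motif_spec"))
  with_seed(spec$rng_seed, {
    gen <- function(n, range, role, prefix) {
      lens <- sample_range(range[1L], range[2L], n)
      seqs <- vapply(lens, function(L) {
        paste(plant_motif(random_residues(L), spec$motif, spec$motif_rate),
              collapse = "")
      }, character(1L))
      protein_records(sprintf("%s_%02d", prefix, seq_len(n)), seqs,
                      role = role, source = "synthetic motif corpus")
    }
    list(base = gen(spec$n_base, spec$base_len_range, "base", "SYNBASE"),
         finetune = gen(spec$n_finetune, spec$finetune_len_range, "finetune",
                        "SYNFT"))
  })
}

#' Generate a deterministic-successor corpus
#'
#' Draws a random permutation of the alphabet as a first-order successor
#' map (every residue has exactly one successor), then emits sequences that
#' follow the map from random start residues. Any context therefore has a
#' unique correct next residue -- an exact oracle for next-residue
#' prediction and a memorisation limit test for the model.
#'
#' @param rng_seed Integer seed.
#' @param n Number of sequences.
#' @param length Length of each sequence (>= 35 for default-window
#'   training).
#' @return List with `records` (a `pf_records` data frame) and `successor`
#'   (named character vector mapping each residue to its unique successor).
#' @export
deterministic_successor_corpus <- function(rng_seed = 42L, n = 6L,
                                           length = 120L) {
  if (!is_positive_count(n)) stop2("`n` must be positive")
  length <- as.integer(length)
  if (length < 35L) stop2("`length` must be >= 35")
  with_seed(rng_seed, {
    ab <- residue_alphabet()
    succ <- stats::setNames(sample(ab), ab)
    seqs <- vapply(seq_len(n), function(i) {
      ch <- character(length)
      ch[1L] <- sample(ab, 1L)
      for (t in 2:length) ch[t] <- succ[[ch[t - 1L]]]
      paste(ch, collapse = "")
    }, character(1L))
    list(records = protein_records(sprintf("SUCC_%02d", seq_len(n)), seqs,
                                   role = "base",
                                   source = "deterministic successor corpus"),
         successor = succ)
  })
}
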