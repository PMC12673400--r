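# Independent oracles used across the suite. Each one recomputes a result
# by a route unrelated to the package implementation: an external ProtParam
# implementation, exhaustive alignment enumeration, or brute-force counting.

# GRAVY and instability index via biopython's ProtParam (independent
# reference implementation of the same published scales).
protparam_reference <- function(seqs) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(seqs, f)
  code <- paste0(
    "import sys\n",
    "from Bio.SeqUtils.ProtParam import ProteinAnalysis\n",
    "for line in open(sys.argv[1]):\n",
    "    pa = ProteinAnalysis(line.strip())\n",
    "    print('%.10f\\t%.10f' % (pa.gravy(), pa.instability_index()))\n"
  )
  out <- system2("python", c("-c", shQuote(code), f), stdout = TRUE)
  df <- utils::read.table(text = out, sep = "\t")
  names(df) <- c("gravy", "instability")
  df
}

# Exhaustive global-alignment enumeration with affine gaps (gap of length k
# costs open + k * ext). Returns the optimal score and the set of percent
# identities achieved by score-optimal alignments. Feasible for len <= 6.
brute_force_alignment <- function(a, b, open = 10, ext = 0.5,
                                  submat = NULL) {
  if (is.null(submat)) {
    submat <- get(utils::data("BLOSUM62", package = "Biostrings",
                              envir = environment()))
  }
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- new.env()
  best$score <- -Inf
  best$pids <- numeric(0)
  rec <- function(i, j, score, state, ident, len) {
    if (i > length(A) && j > length(B)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$pids <- 100 * ident / len
      } else if (abs(score - best$score) <= 1e-9) {
        best$pids <- unique(c(best$pids, 100 * ident / len))
      }
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, score + submat[A[i], B[j]], "m",
          ident + (A[i] == B[j]), len + 1L)
    }
    if (i <= length(A)) {  # gap in b (consume A[i])
      pen <- ext + if (state == "gb") 0 else open
      rec(i + 1L, j, score - pen, "gb", ident, len + 1L)
    }
    if (j <= length(B)) {  # gap in a (consume B[j])
      pen <- ext + if (state == "ga") 0 else open
      rec(i, j + 1L, score - pen, "ga", ident, len + 1L)
    }
  }
  rec(1L, 1L, 0, "none", 0L, 0L)
  list(score = best$score, pids = best$pids)
}

# Brute-force stage-1 composite ranking: per-metric ranks by explicit
# pairwise counting (ties to the earlier index), composite = rank sum,
# final order by composite then index.
brute_force_stage1_order <- function(entropy, gravy, instability) {
  n <- length(entropy)
  count_rank <- function(x, decreasing = FALSE) {
    sapply(seq_len(n), function(i) {
      better <- sapply(seq_len(n), function(j) {
        if (j == i) return(FALSE)
        if (decreasing) {
          x[j] > x[i] || (x[j] == x[i] && j < i)
        } else {
          x[j] < x[i] || (x[j] == x[i] && j < i)
        }
      })
      1L + sum(better)
    })
  }
  comp <- count_rank(entropy, decreasing = TRUE) + count_rank(gravy) +
    count_rank(instability)
  order(comp, seq_len(n))
}

# Brute-force stage-2 selection: smallest centroid distances, ties by
# generation index.
brute_force_stage2_pick <- function(dist, gen_index, keep) {
  ord <- order(dist, gen_index)
  sort(ord[seq_len(min(keep, length(ord)))])
}

random_peptides <- function(n, len_range = c(10L, 80L)) {
  lens <- seq(len_range[1L], len_range[2L])
  replicate(n, paste(sample(residue_alphabet(),
                            lens[sample.int(length(lens), 1L)],
                            replace = TRUE), collapse = ""))
}
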