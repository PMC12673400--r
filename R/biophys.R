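# Screening metrics: Shannon entropy, GRAVY, Guruprasad instability index.
#
# The two empirical scales are embedded verbatim from the primary literature:
# hydropathy values from Kyte & Doolittle (1982) J Mol Biol 157:105-132, and
# the 400-entry dipeptide instability weight table (DIWV) from Guruprasad,
# Reddy & Pandit (1990) Protein Eng 4:155-161. Row/column order follows the
# package alphabet ACDEFGHIKLMNPQRSTVWY.

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 canonical residues; positive
#'   values are hydrophobic, range `[-4.5, 4.5]`.
#' @export
kyte_doolittle_scale <- function() .kd_scale

.kd_scale <- local({
  v <- c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
         1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)
  names(v) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  v
})

#' Guruprasad dipeptide instability weights (DIWV)
#'
#' @return 20 x 20 numeric matrix; entry `[a, b]` is the instability weight
#'   of the ordered dipeptide `ab`.
#' @export
instability_weights <- function() .diwv

.diwv <- local({
  m <- matrix(c(
    1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
    1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
    1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
    1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
    -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
    1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
    1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
    13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
    1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
    20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
    1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
    1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
    1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
    1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
    1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
    -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
    24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
  ), nrow = 20L, byrow = TRUE)
  ab <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  dimnames(m) <- list(ab, ab)
  m
})

#' Shannon entropy of residue composition
#'
#' `H = -sum(p_a * log2(p_a))` over the empirical residue frequencies of the
#' sequence, in bits. A homopolymer scores 0; a sequence using all 20
#' residues equally scores `log2(20) ~ 4.32`. Order-independent.
#'
#' @param seq Sequence string (validated/uppercased internally).
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy("AACC")
shannon_entropy <- function(seq) {
  seq <- validate_sequence(seq)
  p <- table(strsplit(seq, "", fixed = TRUE)[[1L]]) / nchar(seq)
  -sum(p * log2(p))
}

#' GRAVY: grand average of hydropathy
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values over all residues.
#'
#' @inheritParams shannon_entropy
#' @return Mean hydropathy, in `[-4.5, 4.5]`.
#' @export
#' @examples
#' gravy("KLVFF")
gravy <- function(seq) {
  seq <- validate_sequence(seq)
  mean(.kd_scale[strsplit(seq, "", fixed = TRUE)[[1L]]])
}

#' Guruprasad instability index
#'
#' `I = (10 / L) * sum of DIWV weights over the L - 1 adjacent dipeptides`.
#' Values above 40 conventionally flag a peptide as unstable in vitro.
#' Requires at least two residues (the dipeptide sum is otherwise empty).
#'
#' @inheritParams shannon_entropy
#' @return Instability index (dimensionless).
#' @export
#' @examples
#' instability_index("KLVFFAE")
instability_index <- function(seq) {
  seq <- validate_sequence(seq)
  L <- nchar(seq)
  if (L < 2L) stop2("instability index requires at least 2 residues")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  (10 / L) * sum(.diwv[cbind(chars[-L], chars[-1L])])
}

#' Full biophysical profile of a sequence
#'
#' Bundles the three screening metrics plus the conventional stability call
#' (`stable` is `TRUE` iff the instability index is at most 40).
#'
#' @inheritParams shannon_entropy
#' @return A `pf_profile` list: `entropy` (bits), `gravy`, `instability`,
#'   `stable`.
#' @export
biophys_profile <- function(seq) {
  seq <- validate_sequence(seq)
  inst <- instability_index(seq)
  out <- list(entropy = shannon_entropy(seq), gravy = gravy(seq),
              instability = inst, stable = inst <= 40)
  class(out) <- "pf_profile"
  out
}

#' Profile every record in a set
#'
#' @param records A `pf_records` data frame.
#' @return Data frame with columns `id`, `length`, `entropy`, `gravy`,
#'   `instability`, `stable`, in record order.
#' @export
profile_records <- function(records) {
  stopifnot(inherits(records, "pf_records"))
  profs <- lapply(records$sequence, biophys_profile)
  data.frame(
    id = records$id,
    length = nchar(records$sequence),
    entropy = vapply(profs, `[[`, numeric(1L), "entropy"),
    gravy = vapply(profs, `[[`, numeric(1L), "gravy"),
    instability = vapply(profs, `[[`, numeric(1L), "instability"),
    stable = vapply(profs, `[[`, logical(1L), "stable"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.pf_profile <- function(x, ...) {
  cat(sprintf("<pf_profile> entropy %.3f bits, GRAVY %+.3f, instability %.2f (%s)\n",
              x$entropy, x$gravy, x$instability,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}
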