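# Two-stage physicochemical screening funnel.
#
# Stage 1 ranks each batch by a composite rank-sum over the three metrics
# (entropy high, GRAVY low, instability low) and keeps the top
# `stage1_keep`. Stage 2 keeps, per batch, the `stage2_keep` survivors
# closest (Euclidean, raw units) to the centroid of the fine-tuning
# reference profiles in the (GRAVY, instability) plane.

#' Screening configuration
#'
#' Defaults reproduce the reference funnel: 5 batches of 200, top 10 per
#' batch after stage 1 (50 candidates), 5 per batch after stage 2 (25
#' candidates).
#'
#' @param n_batches Number of contiguous batches the pool is split into.
#' @param stage1_keep Candidates kept per batch by the composite rank.
#' @param stage2_keep Candidates kept per batch by centroid distance.
#' @param standardize_features Z-score GRAVY and instability (against the
#'   pooled stage-1 survivors) before computing stage-2 distances. Off by
#'   default: the raw-unit distance matches the reference procedure, which
#'   lets instability (range ~0-100) outweigh GRAVY (~ +/-4.5).
#' @param gravy_mode `"low"` ranks GRAVY ascending in stage 1;
#'   `"moderate"` ranks by absolute deviation from the reference-set mean
#'   GRAVY instead (requires references at screening time).
#' @return A `pf_screen_config` list.
#' @export
screen_config <- function(n_batches = 5L, stage1_keep = 10L, stage2_keep = 5L,
                          standardize_features = FALSE,
                          gravy_mode = c("low", "moderate")) {
  gravy_mode <- match.arg(gravy_mode)
  cfg <- list(n_batches = as.integer(n_batches),
              stage1_keep = as.integer(stage1_keep),
              stage2_keep = as.integer(stage2_keep),
              standardize_features = isTRUE(standardize_features),
              gravy_mode = gravy_mode)
  if (!is_positive_count(cfg$n_batches)) stop2("`n_batches` must be >= 1")
  if (!is_count(cfg$stage1_keep) || !is_count(cfg$stage2_keep)) {
    stop2("keep counts must be non-negative integers")
  }
  if (cfg$stage2_keep > cfg$stage1_keep) {
    stop2("`stage2_keep` must not exceed `stage1_keep`")
  }
  class(cfg) <- "pf_screen_config"
  cfg
}

#' Partition a pool into contiguous batches
#'
#' Splits in generation order; sizes differ by at most one, with earlier
#' batches taking the remainder (11 into 5 gives 3,2,2,2,2).
#'
#' @param pool A `pf_records` data frame.
#' @param n_batches Number of batches.
#' @return Integer vector of batch labels (1-based), one per record.
#' @export
partition_pool <- function(pool, n_batches) {
  stopifnot(inherits(pool, "pf_records"))
  n <- nrow(pool)
  n_batches <- as.integer(n_batches)
  if (!is_positive_count(n_batches)) stop2("`n_batches` must be >= 1")
  if (n_batches > n) stop2("more batches (", n_batches, ") than sequences (", n, ")")
  base <- n %/% n_batches
  extra <- n %% n_batches
  sizes <- rep(base, n_batches) + c(rep(1L, extra), rep(0L, n_batches - extra))
  rep(seq_len(n_batches), times = sizes)
}

# rank with ties resolved by earlier position (generation order)
rank_first <- function(x) rank(x, ties.method = "first")

#' Composite stage-1 ranking of one batch
#'
#' Assigns within-batch 1-based ranks per metric -- entropy descending,
#' GRAVY ascending (or distance from the reference mean GRAVY under
#' `gravy_mode = "moderate"`), instability ascending -- and sums them into a
#' composite score. Lower composite is better; all ties (per metric and on
#' the composite) break toward the earlier generation index.
#'
#' @param metrics Data frame with columns `entropy`, `gravy`, `instability`
#'   (one row per batch member, in generation order).
#' @param gravy_center Optional reference mean GRAVY for `"moderate"` mode.
#' @param gravy_mode See [screen_config()].
#' @return `metrics` with added `rank_entropy`, `rank_gravy`,
#'   `rank_instability`, `composite`, and `stage1_order` (1 = best).
#' @export
stage1_rank <- function(metrics, gravy_center = NULL,
                        gravy_mode = c("low", "moderate")) {
  gravy_mode <- match.arg(gravy_mode)
  stopifnot(all(c("entropy", "gravy", "instability") %in% names(metrics)))
  gr <- if (gravy_mode == "moderate") {
    if (is.null(gravy_center)) stop2("`gravy_center` required for gravy_mode='moderate'")
    abs(metrics$gravy - gravy_center)
  } else {
    metrics$gravy
  }
  metrics$rank_entropy <- rank_first(-metrics$entropy)
  metrics$rank_gravy <- rank_first(gr)
  metrics$rank_instability <- rank_first(metrics$instability)
  metrics$composite <- metrics$rank_entropy + metrics$rank_gravy +
    metrics$rank_instability
  ord <- order(metrics$composite, seq_len(nrow(metrics)))
  metrics$stage1_order <- integer(nrow(metrics))
  metrics$stage1_order[ord] <- seq_len(nrow(metrics))
  metrics
}

#' Reference centroid in the (GRAVY, instability) plane
#'
#' Component-wise arithmetic mean of the profiles of the fine-tuning
#' reference sequences; invariant to reference order.
#'
#' @param refs A `pf_records` data frame of reference peptides.
#' @return A `pf_centroid` list: `gravy_mean`, `instability_mean`, `n_refs`.
#' @export
reference_centroid <- function(refs) {
  stopifnot(inherits(refs, "pf_records"))
  if (!nrow(refs)) stop2("reference set is empty")
  pr <- profile_records(refs)
  out <- list(gravy_mean = mean(pr$gravy),
              instability_mean = mean(pr$instability),
              n_refs = nrow(refs))
  class(out) <- "pf_centroid"
  out
}

#' Euclidean distance from a profile to the reference centroid
#'
#' `sqrt((G - G_centroid)^2 + (I - I_centroid)^2)` in raw feature units.
#'
#' @param gravy,instability Feature values of the candidate.
#' @param centroid A [reference_centroid()].
#' @return Non-negative distance (vectorised over candidates).
#' @export
centroid_distance <- function(gravy, instability, centroid) {
  stopifnot(inherits(centroid, "pf_centroid"))
  sqrt((gravy - centroid$gravy_mean)^2 + (instability - centroid$instability_mean)^2)
}

#' Run the full two-stage screening funnel
#'
#' Partitions the pool, profiles every peptide, applies the composite
#' stage-1 ranking per batch, then the stage-2 centroid-distance selection
#' per batch, and assembles a funnel report carrying every intermediate
#' value. With the default configuration and a 1,000-peptide pool this
#' yields 50 stage-1 and 25 stage-2 survivors.
#'
#' @param pool A `pf_records` data frame (usually from [generate_pool()]).
#' @param refs Fine-tuning reference records (role `"finetune"`).
#' @param config A [screen_config()].
#' @return A `pf_funnel` list: `candidates` (surviving records, role
#'   `"candidate"`), `report` (per-peptide data frame with batch, metrics,
#'   ranks, distance and survival flags), `centroid`, and counts `n_input`,
#'   `n_stage1`, `n_stage2`.
#' @export
screen_pool <- function(pool, refs, config = screen_config()) {
  stopifnot(inherits(pool, "pf_records"), inherits(refs, "pf_records"),
            inherits(config, "pf_screen_config"))
  batch <- partition_pool(pool, config$n_batches)
  prof <- profile_records(pool)
  centroid <- reference_centroid(refs)
  gravy_center <- if (config$gravy_mode == "moderate") {
    mean(profile_records(refs)$gravy)
  } else {
    NULL
  }

  report <- cbind(prof, batch = batch, gen_index = seq_len(nrow(pool)))
  ranked <- vector("list", config$n_batches)
  for (b in seq_len(config$n_batches)) {
    rb <- report[report$batch == b, , drop = FALSE]
    rk <- stage1_rank(rb[, c("entropy", "gravy", "instability")],
                      gravy_center = gravy_center,
                      gravy_mode = config$gravy_mode)
    rb <- cbind(rb, rk[, c("rank_entropy", "rank_gravy", "rank_instability",
                           "composite", "stage1_order")])
    keep_n <- min(config$stage1_keep, nrow(rb))
    if (keep_n < config$stage1_keep) {
      warning(sprintf("batch %d has only %d sequence(s); keeping all", b, nrow(rb)),
              call. = FALSE)
    }
    rb$survived_stage1 <- rb$stage1_order <= keep_n
    ranked[[b]] <- rb
  }
  report <- do.call(rbind, ranked)
  if (config$stage1_keep == 0L) {
    warning("stage1_keep is 0; the funnel output is empty", call. = FALSE)
  }

  report$centroid_distance <- if (config$standardize_features) {
    s1 <- report[report$survived_stage1, , drop = FALSE]
    gs <- stats::sd(s1$gravy); is <- stats::sd(s1$instability)
    if (!isTRUE(gs > 0)) gs <- 1
    if (!isTRUE(is > 0)) is <- 1
    sqrt(((report$gravy - centroid$gravy_mean) / gs)^2 +
           ((report$instability - centroid$instability_mean) / is)^2)
  } else {
    centroid_distance(report$gravy, report$instability, centroid)
  }

  report$survived_stage2 <- FALSE
  for (b in seq_len(config$n_batches)) {
    sel <- which(report$batch == b & report$survived_stage1)
    if (!length(sel)) next
    ord <- sel[order(report$centroid_distance[sel], report$gen_index[sel])]
    report$survived_stage2[ord[seq_len(min(config$stage2_keep, length(ord)))]] <- TRUE
  }

  # restore generation order for the report; candidates keep that order too
  report <- report[order(report$gen_index), , drop = FALSE]
  rownames(report) <- NULL
  cand_idx <- report$gen_index[report$survived_stage2]
  candidates <- pool[cand_idx, , drop = FALSE]
  candidates$role <- "candidate"
  class(candidates) <- c("pf_records", "data.frame")

  out <- list(candidates = candidates, report = report, centroid = centroid,
              n_input = nrow(pool),
              n_stage1 = sum(report$survived_stage1),
              n_stage2 = sum(report$survived_stage2),
              config = config)
  class(out) <- "pf_funnel"
  out
}

#' @export
print.pf_funnel <- function(x, ...) {
  cat(sprintf("<pf_funnel> %d -> %d (stage 1) -> %d (stage 2) candidates\n",
              x$n_input, x$n_stage1, x$n_stage2))
  cat(sprintf("  reference centroid: GRAVY %+.3f, instability %.2f (n=%d)\n",
              x$centroid$gravy_mean, x$centroid$instability_mean,
              x$centroid$n_refs))
  invisible(x)
}
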