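# End-to-end orchestration: train -> generate -> screen -> align, with
# machine-readable artifacts and a manifest sufficient to reproduce the run.

#' Assemble a full pipeline run configuration
#'
#' One integer seed governs the entire run: it seeds model initialisation
#' and training (via the model config) and, offset by a fixed constant,
#' pool generation. Sub-configurations may be overridden individually.
#'
#' @param seed Global integer seed for the run.
#' @param model A [model_config()]; its `rng_seed` is replaced by `seed`.
#' @param generation A [generation_config()]; its `rng_seed` is replaced by
#'   `seed + 1000`.
#' @param screen A [screen_config()].
#' @param shortlist A [shortlist_config()].
#' @param align An [align_params()].
#' @return A `pf_run_config` list.
#' @export
run_config <- function(seed = 42L,
                       model = model_config(),
                       generation = generation_config(),
                       screen = screen_config(),
                       shortlist = shortlist_config(),
                       align = align_params()) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop2("`seed` must be an integer")
  model$rng_seed <- seed
  generation$rng_seed <- seed + 1000L
  cfg <- list(seed = seed, model = model, generation = generation,
              screen = screen, shortlist = shortlist, align = align)
  class(cfg) <- "pf_run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys are `seed` plus `model`, `generation`,
#' `screen`, `shortlist` and `align` blocks whose entries override the
#' corresponding constructor defaults.
#'
#' @param path YAML file.
#' @return A `pf_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) do.call(ctor, if (is.null(block)) list() else block)
  run_config(
    seed = if (is.null(y$seed)) 42L else y$seed,
    model = build(model_config, y$model),
    generation = build(generation_config, y$generation),
    screen = build(screen_config, y$screen),
    shortlist = build(shortlist_config, y$shortlist),
    align = build(align_params, y$align)
  )
}

as_records_input <- function(x, role, what) {
  if (inherits(x, "pf_records")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      stop2(sprintf("%s FASTA not found: %s (required for training/screening)",
                    what, x))
    }
    return(read_fasta(x, role = role))
  }
  stop2("`", what, "` must be a pf_records data frame or a FASTA path")
}

#' Run the full design funnel
#'
#' Executes the pipeline end to end: window construction, two-phase model
#' training, pool generation by greedy decoding, the two-stage
#' physicochemical funnel, percent-identity scoring against the fine-tuning
#' references, and the final similarity shortlist. All artifacts are written
#' under `out_dir`; the report JSON and FASTA outputs are byte-reproducible
#' given the same configuration and seed.
#'
#' @param base,finetune Training corpora: `pf_records` data frames or FASTA
#'   paths (roles `"base"` / `"finetune"`).
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output.
#' @param config A [run_config()].
#' @param verbose Narrate stage progress to standard error.
#' @return A `pf_run` list: `model`, `pool`, `funnel` (see [screen_pool()]),
#'   `identity` matrix, `shortlist` records, and `paths` of written files.
#' @export
run_pipeline <- function(base, finetune, out_dir = NULL,
                         config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pf_run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  base <- as_records_input(base, "base", "base")
  finetune <- as_records_input(finetune, "finetune", "finetune")

  say("[train] building windows (window = %d)", config$model$window)
  wb <- corpus_windows(base, config$model$window)
  wf <- corpus_windows(finetune, config$model$window)
  say("[train] %d base / %d fine-tune windows", length(wb$target), length(wf$target))

  model <- build_model(config$model)
  say("[train] base phase: %d epochs, batch %d",
      config$model$epochs_base, config$model$batch_base)
  model <- train_phase(model, wb, "base")
  say("[train] fine-tune phase: %d epochs, batch %d",
      config$model$epochs_finetune, config$model$batch_finetune)
  model <- train_phase(model, wf, "finetune")

  say("[generate] %d peptides, lengths %d-%d", config$generation$n_sequences,
      config$generation$min_len, config$generation$max_len)
  corpus <- rbind(base, finetune)
  class(corpus) <- c("pf_records", "data.frame")
  pool <- generate_pool(model, corpus, config$generation)

  say("[screen] funnel: %d batches, keep %d then %d per batch",
      config$screen$n_batches, config$screen$stage1_keep,
      config$screen$stage2_keep)
  funnel <- screen_pool(pool, finetune, config$screen)
  say("[screen] %d -> %d -> %d", funnel$n_input, funnel$n_stage1, funnel$n_stage2)

  say("[align] identity of %d candidates vs %d references",
      nrow(funnel$candidates), nrow(finetune))
  idt <- identity_table(funnel$candidates, finetune, config$align)
  final <- shortlist(funnel$candidates, idt, config$shortlist)
  say("[align] shortlisted %d candidate(s)", nrow(final))

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$checkpoint <- file.path(out_dir, "model.ckpt")
    save_checkpoint(model, paths$checkpoint)
    paths$pool <- file.path(out_dir, "pool.fasta")
    write_fasta(pool, paths$pool)
    paths$candidates <- file.path(out_dir, "candidates.fasta")
    write_fasta(funnel$candidates, paths$candidates)
    if (nrow(final)) {
      paths$shortlist <- file.path(out_dir, "shortlist.fasta")
      write_fasta(final, paths$shortlist)
    }
    paths$metrics <- file.path(out_dir, "metrics.tsv")
    utils::write.table(funnel$report, paths$metrics, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$identity <- file.path(out_dir, "identity.tsv")
    write_identity_table(idt, paths$identity)
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(run_report(funnel, final, model), paths$report,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(run_manifest(config, base, finetune), paths$manifest,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  out <- list(model = model, pool = pool, funnel = funnel, identity = idt,
              shortlist = final, config = config, paths = paths)
  class(out) <- "pf_run"
  out
}

run_report <- function(funnel, final, model) {
  hist <- model$history
  last_of <- function(ph, col) {
    h <- hist[hist$phase == ph, col]
    if (length(h)) h[length(h)] else NULL
  }
  list(
    counts = list(n_input = funnel$n_input, n_stage1 = funnel$n_stage1,
                  n_stage2 = funnel$n_stage2, n_shortlist = nrow(final)),
    training = list(
      base_final_loss = last_of("base", "loss"),
      base_final_accuracy = last_of("base", "accuracy"),
      finetune_final_loss = last_of("finetune", "loss"),
      finetune_final_accuracy = last_of("finetune", "accuracy")
    ),
    centroid = list(gravy_mean = funnel$centroid$gravy_mean,
                    instability_mean = funnel$centroid$instability_mean,
                    n_refs = funnel$centroid$n_refs),
    candidates = funnel$report[funnel$report$survived_stage2,
                               c("id", "batch", "length", "entropy", "gravy",
                                 "instability", "composite",
                                 "centroid_distance")],
    shortlist = attr(final, "similarity")
  )
}

run_manifest <- function(config, base, finetune) {
  list(
    package = "pepfunnel",
    package_version = as.character(utils::packageVersion("pepfunnel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = list(
      model = unclass(config$model),
      generation = unclass(config$generation),
      screen = unclass(config$screen),
      shortlist = unclass(config$shortlist),
      align = unclass(config$align)
    ),
    inputs = list(
      base = list(n = nrow(base), ids = base$id),
      finetune = list(n = nrow(finetune), ids = finetune$id)
    )
  )
}

#' Render a human-readable funnel summary
#'
#' @param run A `pf_run` from [run_pipeline()].
#' @param top Number of shortlist rows to display.
#' @return Character vector of report lines (also printable via `cat`).
#' @export
report_render <- function(run, top = 11L) {
  stopifnot(inherits(run, "pf_run"))
  f <- run$funnel
  lines <- c(
    "Peptide design funnel",
    sprintf("  pool: %d generated peptides", f$n_input),
    sprintf("  stage 1 (composite entropy/GRAVY/instability rank): %d", f$n_stage1),
    sprintf("  stage 2 (distance to reference centroid G=%.3f, I=%.2f): %d",
            f$centroid$gravy_mean, f$centroid$instability_mean, f$n_stage2),
    sprintf("  shortlist (percent identity vs references): %d", nrow(run$shortlist))
  )
  sim <- attr(run$shortlist, "similarity")
  if (is.null(sim) || !nrow(sim)) {
    lines <- c(lines, "  no qualifying candidates in the shortlist")
  } else {
    rep_rows <- f$report[match(sim$id, f$report$id), ]
    lines <- c(lines, "", sprintf("  %-12s %6s %8s %8s %11s %9s",
                                  "id", "len", "entropy", "GRAVY", "instability",
                                  "max.id%"))
    for (i in seq_len(min(top, nrow(sim)))) {
      lines <- c(lines, sprintf("  %-12s %6d %8.3f %+8.3f %11.2f %9.2f",
                                sim$id[i], rep_rows$length[i],
                                rep_rows$entropy[i], rep_rows$gravy[i],
                                rep_rows$instability[i], sim$statistic[i]))
    }
  }
  lines
}

#' @export
print.pf_run <- function(x, ...) {
  cat(paste(report_render(x), collapse = "\n"), "\n")
  invisible(x)
}
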