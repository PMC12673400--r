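random_records <- function(n, len_range = c(20L, 60L), prefix = "P") {
  protein_records(sprintf("%s%03d", prefix, seq_len(n)),
                  random_peptides(n, len_range), role = "generated")
}

test_that("partition_pool splits contiguously with remainder-first sizes", {
  set.seed(41)
  p1000 <- random_records(1000L, c(20L, 30L))
  b <- partition_pool(p1000, 5L)
  expect_identical(as.integer(table(b)), rep(200L, 5L))
  expect_true(all(diff(b) >= 0))  # contiguous in generation order

  p10 <- random_records(10L)
  expect_identical(as.integer(table(partition_pool(p10, 5L))), rep(2L, 5L))
  p11 <- random_records(11L)
  expect_identical(as.integer(table(partition_pool(p11, 5L))),
                   c(3L, 2L, 2L, 2L, 2L))
  expect_error(partition_pool(p10, 11L), "more batches")
})

test_that("stage1_rank matches brute-force rank-sum ordering on random batches", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    metrics <- data.frame(entropy = round(runif(n, 2, 4.3), 2),
                          gravy = round(runif(n, -3, 3), 2),
                          instability = round(runif(n, 10, 80), 1))
    # inject ties occasionally
    if (n >= 4) metrics$entropy[2] <- metrics$entropy[1]
    rk <- stage1_rank(metrics)
    got <- order(rk$stage1_order)
    want <- brute_force_stage1_order(metrics$entropy, metrics$gravy,
                                     metrics$instability)
    expect_identical(got, want)
  }
})

test_that("a triple-dominant sequence gets composite 3 and identical sequences keep input order", {
  metrics <- data.frame(entropy = c(4.0, 3.0, 2.0),
                        gravy = c(-2.0, 0.0, 1.0),
                        instability = c(10, 20, 30))
  rk <- stage1_rank(metrics)
  expect_identical(rk$composite[1], 3L)
  expect_identical(rk$stage1_order[1], 1L)

  dup <- data.frame(entropy = c(3, 3), gravy = c(1, 1), instability = c(5, 5))
  rkd <- stage1_rank(dup)
  expect_identical(rkd$stage1_order, c(1L, 2L))  # earlier index first
})

test_that("reference centroid is the arithmetic mean and is order invariant", {
  refs <- protein_records(c("r1", "r2"), c("KLVFFAEDVG", "PPPPEEEEGG"),
                          role = "finetune")
  cen <- reference_centroid(refs)
  pr <- profile_records(refs)
  expect_equal(cen$gravy_mean, mean(pr$gravy))
  expect_equal(cen$instability_mean, mean(pr$instability))

  refs_rev <- refs[2:1, ]; class(refs_rev) <- class(refs)
  cen2 <- reference_centroid(refs_rev)
  expect_equal(cen$gravy_mean, cen2$gravy_mean)
  expect_equal(cen$instability_mean, cen2$instability_mean)

  single <- refs[1, ]; class(single) <- class(refs)
  cs <- reference_centroid(single)
  expect_equal(cs$gravy_mean, pr$gravy[1])
  expect_error(reference_centroid(refs[0, ]), "empty")
})

test_that("centroid distance is Euclidean in raw units", {
  cen <- structure(list(gravy_mean = 3, instability_mean = 4, n_refs = 1L),
                   class = "pf_centroid")
  expect_equal(centroid_distance(0, 0, cen), 5)  # 3-4-5 triangle
  expect_equal(centroid_distance(3, 4, cen), 0)
  expect_equal(centroid_distance(6, 8, cen), centroid_distance(0, 0, cen))
})

test_that("stage-2 selection matches brute-force sorting by distance", {
  set.seed(43)
  pool <- random_records(20L)
  refs <- protein_records("ref", random_peptides(1, c(30L, 30L)),
                          role = "finetune")
  fun <- screen_pool(pool, refs, screen_config(n_batches = 2L,
                                               stage1_keep = 10L,
                                               stage2_keep = 5L))
  rep1 <- fun$report[fun$report$batch == 1 & fun$report$survived_stage1, ]
  picked <- rep1$gen_index[rep1$survived_stage2]
  want <- rep1$gen_index[brute_force_stage2_pick(rep1$centroid_distance,
                                                 rep1$gen_index, 5L)]
  expect_identical(sort(picked), sort(want))
})

test_that("the funnel conserves candidates and reproduces profile values exactly", {
  set.seed(44)
  pool <- random_records(60L)
  refs <- protein_records(c("r1", "r2"), random_peptides(2, c(40L, 60L)),
                          role = "finetune")
  fun <- screen_pool(pool, refs, screen_config(n_batches = 3L,
                                               stage1_keep = 8L,
                                               stage2_keep = 4L))
  expect_identical(fun$n_stage1, 24L)
  expect_identical(fun$n_stage2, 12L)
  # conservation: stage 2 subset of stage 1 subset of pool; no duplicates
  r <- fun$report
  expect_true(all(r$id[r$survived_stage2] %in% r$id[r$survived_stage1]))
  expect_true(all(fun$candidates$id %in% pool$id))
  expect_false(anyDuplicated(fun$candidates$id) > 0)
  expect_identical(fun$candidates$sequence,
                   pool$sequence[match(fun$candidates$id, pool$id)])
  # report metrics are bit-identical to biophys profiles
  expect_identical(r$gravy,
                   vapply(pool$sequence[r$gen_index], gravy, numeric(1),
                          USE.NAMES = FALSE))
  # stage-2 survivors pass through unchanged when keep equals group size
  all_through <- screen_pool(pool, refs,
                             screen_config(n_batches = 3L, stage1_keep = 6L,
                                           stage2_keep = 6L))
  r2 <- all_through$report
  expect_identical(r2$survived_stage1, r2$survived_stage2)
})

test_that("underfull batches clamp with a warning and default counts give 50 then 25", {
  set.seed(45)
  small <- random_records(4L)
  refs <- protein_records("r", random_peptides(1, c(30L, 30L)), role = "finetune")
  expect_warning(fun <- screen_pool(small, refs,
                                    screen_config(n_batches = 1L,
                                                  stage1_keep = 10L,
                                                  stage2_keep = 2L)),
                 "keeping all")
  expect_identical(fun$n_stage1, 4L)

  pool <- random_records(1000L, c(20L, 30L))
  fun5 <- screen_pool(pool, refs)
  expect_identical(fun5$n_input, 1000L)
  expect_identical(fun5$n_stage1, 50L)
  expect_identical(fun5$n_stage2, 25L)

  expect_error(screen_config(stage1_keep = 3L, stage2_keep = 5L), "stage2_keep")
})
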