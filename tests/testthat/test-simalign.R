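test_that("percent identity handles identity, disjoint and near-identical pairs", {
  expect_equal(percent_identity("KLVFFAE", "KLVFFAE"), 100)
  expect_equal(percent_identity("AAAA", "CCCC"), 0)
  expect_equal(percent_identity("ACDE", "ACDF"), 75)
  expect_error(percent_identity("", "AC"), "empty")
})

test_that("alignment score and identity match exhaustive enumeration on short sequences", {
  set.seed(51)
  params <- align_params()
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  for (rep in 1:12) {
    a <- paste(sample(residue_alphabet(), sample(2:6, 1), TRUE), collapse = "")
    b <- paste(sample(residue_alphabet(), sample(2:6, 1), TRUE), collapse = "")
    oracle <- brute_force_alignment(a, b, params$gap_open, params$gap_extend,
                                    b62)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      type = "global")
    expect_equal(Biostrings::score(aln), oracle$score, tolerance = 1e-9)
    pid <- percent_identity(a, b, params)
    expect_true(any(abs(pid - oracle$pids) < 1e-6),
                info = sprintf("%s vs %s: pid %.3f not among optimal {%s}",
                               a, b, pid,
                               paste(round(oracle$pids, 3), collapse = ", ")))
  }
})

test_that("percent identity is symmetric up to co-optimal tie-breaking", {
  set.seed(52)
  for (rep in 1:10) {
    a <- random_peptides(1, c(8L, 25L))
    b <- random_peptides(1, c(8L, 25L))
    expect_lte(abs(percent_identity(a, b) - percent_identity(b, a)), 0.5)
  }
  set.seed(53)
  for (s in random_peptides(5, c(5L, 40L))) {
    expect_equal(percent_identity(s, s), 100)
  }
})

test_that("identity_table covers the full cartesian grid deterministically", {
  set.seed(54)
  cands <- protein_records(sprintf("c%d", 1:4), random_peptides(4, c(15L, 30L)),
                           role = "candidate")
  refs <- protein_records(sprintf("r%d", 1:3), random_peptides(3, c(15L, 30L)),
                          role = "finetune")
  tab <- identity_table(cands, refs)
  expect_identical(dim(tab), c(4L, 3L))
  expect_true(all(tab >= 0 & tab <= 100))
  expect_identical(tab, identity_table(cands, refs))

  # row permutation follows candidate permutation
  perm <- c(3L, 1L, 4L, 2L)
  cp <- cands[perm, ]; class(cp) <- class(cands)
  tp <- identity_table(cp, refs)
  attr(tp, "params") <- NULL  # subsetting tab drops the params attribute
  expect_identical(tp, tab[perm, ])

  one <- identity_table(cands[1, ] |> structure(class = class(cands)),
                        cands[1, ] |> structure(class = class(cands)))
  expect_equal(as.numeric(one), 100)
  expect_error(identity_table(cands[0, ] |> structure(class = class(cands)),
                              refs), "empty")
})

test_that("shortlist keeps the highest-similarity candidates below the novelty ceiling", {
  cands <- protein_records(sprintf("c%d", 1:5),
                           c("KLVFFAEDVGSNKGAIIGLM", "ACDEFGHIKLMNPQRSTVWY",
                             "KLVFFAEDVGSNKGAIIGLA", "YWVTSRQPNMLKIHGFEDCA",
                             "KLVFFKLVFFKLVFFKLVFF"),
                           role = "candidate")
  tab <- matrix(c(95, 40, 62, 20, 35), nrow = 5, ncol = 1,
                dimnames = list(cands$id, "ref"))
  sl <- shortlist(cands, tab, shortlist_config(keep = 2L, novelty_ceiling = 60))
  # c1 (95) and c3 (62) excluded by the ceiling; c2 (40) then c5 (35) lead
  expect_identical(sl$id, c("c2", "c5"))
  sim <- attr(sl, "similarity")
  expect_equal(sim$statistic, c(40, 35))

  # keep = 1 against brute-force maximum among qualifiers
  sl1 <- shortlist(cands, tab, shortlist_config(keep = 1L, novelty_ceiling = 60))
  qual <- tab[, 1] < 60
  expect_identical(sl1$id, names(which.max(tab[qual, 1])))

  # warning when fewer qualify than keep
  expect_warning(shortlist(cands, tab, shortlist_config(keep = 5L)),
                 "short of keep")

  # a 100%-identity candidate is always excluded
  tab2 <- tab; tab2["c2", 1] <- 100
  sl2 <- suppressWarnings(shortlist(cands, tab2, shortlist_config(keep = 5L)))
  expect_false("c2" %in% sl2$id)

  # shortlist is a subset of its input
  expect_true(all(sl$id %in% cands$id))
  expect_error(shortlist_config(keep = 0), "keep")
  expect_error(shortlist_config(novelty_ceiling = 0), "novelty_ceiling")
})

test_that("mean-identity ranking is available as an alternative statistic", {
  cands <- protein_records(c("a", "b"),
                           c("KLVFFAEDVGSNKGAIIGLM", "YWVTSRQPNMLKIHGFEDCA"),
                           role = "candidate")
  tab <- matrix(c(10, 30, 50, 20), nrow = 2,
                dimnames = list(c("a", "b"), c("r1", "r2")))
  sl <- suppressWarnings(
    shortlist(cands, tab, shortlist_config(keep = 2L, rank_by = "mean_identity")))
  expect_identical(attr(sl, "similarity")$statistic, c(30, 25))
})
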