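test_that("automatic starting threshold is the floored minimum similarity", {
  lib <- sample_library(c("AAAA", "AAAT"), c(3L, 2L))
  expect_equal(gamma_start_auto(lib), 75)
  # identical sequences collapse to one: no clustering needed
  one <- sample_library(rep("ACGT", 5))
  expect_equal(gamma_start_auto(one, gamma_end = 97), 97)
})

test_that("a single replicate follows the insertion rules", {
  set.seed(31)
  # gamma below the minimum pairwise similarity: one giant cluster
  seqs <- replicate(6, random_seq(50))
  counts <- stats::setNames(sample(2:20, 6), seqs)
  sm <- similarity_matrix(seqs)
  lab <- cluster_replicate(counts, gamma = floor(min(sm)), simmat = sm)
  expect_equal(length(unique(lab)), 1L)

  # gamma 100 with mutually dissimilar sequences: one cluster each
  lab100 <- cluster_replicate(counts, gamma = 100, simmat = sm)
  expect_equal(length(unique(lab100)), 6L)
  expect_equal(unname(lab100), names(counts))

  # a rare 1-off variant joins its source and the cluster keeps the
  # dominant label
  a <- random_seq(100)
  a1 <- mutate_sub(a, 50)
  counts2 <- stats::setNames(c(10L, 1L), c(a, a1))
  lab2 <- cluster_replicate(counts2, gamma = 97)
  expect_equal(unname(lab2), c(a, a))
})

test_that("modal clustering is deterministic and covers every sequence", {
  set.seed(32)
  seqs <- replicate(5, random_seq(60))
  counts <- stats::setNames(sample(2:30, 5), seqs)
  cl1 <- modal_clusters(counts, gamma = 80, replicates = 50, seed = 7)
  cl2 <- modal_clusters(counts, gamma = 80, replicates = 50, seed = 7)
  expect_identical(cl1, cl2)
  members <- unlist(lapply(cl1, function(c) names(c$members)))
  expect_setequal(members, seqs)
  expect_equal(anyDuplicated(members), 0L)
  # deterministic configuration equals any single replicate
  lab <- cluster_replicate(counts, gamma = 100)
  cl100 <- modal_clusters(counts, gamma = 100, replicates = 10, seed = 1)
  expect_equal(length(cl100), length(unique(lab)))
})

test_that("cluster classification reproduces the worked arithmetic", {
  # dominant 73 / subdominant 42 in a 330-read library: fails dominance
  giant <- stclust:::.new_cluster(c(AAA = 73L, CCC = 42L, GGG = 25L))
  expect_equal(dominance_ratio(giant), 73 / 42)
  expect_equal(classify_cluster(giant, 330, theta = 0.045, delta = 4),
               "ambiguous")
  # single sequence of 4 reads: dominance passes (infinite), size fails
  tiny <- stclust:::.new_cluster(c(TTTT = 4L))
  expect_equal(dominance_ratio(tiny), Inf)
  expect_equal(classify_cluster(tiny, 330, theta = 0.045, delta = 4),
               "small")
  # 41 reads with 30/3 dominance: passes both
  good <- stclust:::.new_cluster(c(AC = 30L, GT = 3L, TG = 3L, CA = 3L,
                                   AG = 2L))
  expect_equal(classify_cluster(good, 330, theta = 0.045, delta = 4),
               "good")
})

test_that("ambiguous splitting assigns reads proportionally", {
  amb <- stclust:::.new_cluster(
    stats::setNames(c(73L, 38L, 20L, 9L),
                    c(strrep("A", 8), strrep("C", 8), strrep("G", 7),
                      strrep("T", 6))))
  expect_equal(amb$size, 140L)
  parts <- split_ambiguous(amb, library_size = 330, theta = 0.045,
                           expected_len = 8)
  expect_equal(vapply(parts, function(p) p$size, numeric(1)), c(92, 48))
  expect_equal(vapply(parts, function(p) p$status, character(1)),
               c("good", "good"))
  # dominant share of the top-two reads
  expect_equal(round(100 * 73 / (73 + 38), 1), 65.8)

  # symmetric counts split evenly
  even <- stclust:::.new_cluster(c(AAAA = 5L, CCCC = 5L))
  parts <- split_ambiguous(even, 100, 0.03, 4)
  expect_equal(sort(vapply(parts, function(p) p$size, numeric(1))), c(5, 5))

  # wrong-length dominant: third most frequent stands in as subdominant
  mix <- stclust:::.new_cluster(c(AAAA = 50L, CCCCC = 30L, GGGG = 20L))
  parts <- split_ambiguous(mix, 200, 0.045, 4)
  expect_setequal(vapply(parts, function(p) p$label, character(1)),
                  c("AAAA", "GGGG"))
  expect_equal(sum(vapply(parts, function(p) p$size, numeric(1))), 100)

  # fewer than two correct-length members: kept whole as small
  lone <- stclust:::.new_cluster(c(AAAA = 5L, CCC = 4L))
  expect_warning(parts <- split_ambiguous(lone, 100, 0.03, 4),
                 "fewer than two")
  expect_equal(length(parts), 1L)
  expect_equal(parts[[1]]$status, "small")
})

test_that("run_stc handles degenerate libraries", {
  expect_equal(length(run_stc(sample_library(character(0)))$good), 0L)
  one <- sample_library(rep("ACGTACGT", 10), sample_id = "A")
  cs <- run_stc(one, stc_params(theta = 0.05, delta = 4, expected_len = 8,
                                seed = 1))
  expect_equal(length(cs$good), 1L)
  expect_equal(cs$good[[1]]$label, "ACGTACGT")
})

test_that("a single low-threshold round matches hand computation", {
  set.seed(33)
  seqs <- replicate(3, random_seq(40))
  lib <- sample_library(rep(seqs, c(30L, 10L, 4L)), sample_id = "A")
  sm <- similarity_matrix(names(lib$counts))
  g0 <- floor(min(sm)) - 1
  p <- stc_params(theta = 0.05, delta = 2, gamma_start = g0, gamma_end = g0,
                  expected_len = 40, seed = 5)
  cs <- run_stc(lib, p)
  # one round, one all-inclusive cluster; 30/10 = 3 > 2 so it is good
  expect_equal(nrow(cs$logs), 1L)
  expect_equal(length(cs$good), 1L)
  expect_equal(cs$good[[1]]$size, 44)
  expect_equal(cs$good[[1]]$dominant_count, 30)
  expect_equal(cs$good[[1]]$subdominant_count, 10)
})

test_that("stepwise clustering partitions reads, is deterministic, and
           never splits identical reads", {
  cfg <- sim_config(n_samples = 2, alleles_per_sample = 5,
                    library_size = 300, seed = 41)
  sim <- simulate_run(cfg)
  for (s in names(sim$libraries)) {
    lib <- combine_library(sim$libraries[[s]], 213)$library
    p <- stc_params(seed = 17)
    cs <- run_stc(lib, p)
    # partition: every read in exactly one good or small cluster
    all_members <- unlist(lapply(c(cs$good, cs$small),
                                 function(c) c$members))
    expect_equal(sum(all_members), lib$library_size)
    # round logs monotone
    expect_true(all(diff(cs$logs$reads_left) <= 0))
    expect_true(all(diff(cs$logs$sequences_left) <= 0))
    # determinism
    cs2 <- run_stc(lib, p)
    expect_identical(summary(cs), summary(cs2))
  }
})

test_that("well-separated simulated alleles give one good cluster each", {
  ok <- 0L
  for (seed in c(101, 102, 103)) {
    cfg <- sim_config(n_samples = 1, alleles_per_sample = 6,
                      library_size = 400, min_allele_divergence = 10,
                      p_indel = 0.005, p_sub = 0.005, seed = seed)
    sim <- simulate_run(cfg)
    lib <- combine_library(sim$libraries[[1]], 213)$library
    cs <- run_stc(lib, stc_params(theta = 1 / 22, delta = 4, seed = seed))
    labels <- vapply(cs$good, function(c) c$label, character(1))
    if (setequal(labels, sim$genotypes[[1]])) ok <- ok + 1L
  }
  expect_gte(ok, 3L)
})
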