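# minimal cluster-set stand-ins for phase-4 unit tests
fake_cluster <- function(label, size) list(label = label, size = size)
fake_cs <- function(id, good = character(0), good_sizes = NULL,
                    small = list(), lib_size = 300) {
  if (is.null(good_sizes)) good_sizes <- rep(50, length(good))
  structure(list(sample_id = id,
                 good = Map(fake_cluster, good, good_sizes),
                 small = small, library_size = lib_size),
            class = "stc_clusterset")
}

test_that("small clusters are promoted only when common elsewhere and
           large enough", {
  A <- strrep("ACGT", 4)
  B <- strrep("GGCA", 4)
  css <- list(
    X = fake_cs("X", good = B, small = list(fake_cluster(A, 4),
                                            fake_cluster("TTTTTTTT", 5))),
    S1 = fake_cs("S1", good = c(A, B)),
    S2 = fake_cs("S2", good = A),
    S3 = fake_cs("S3", good = c(A, B)))
  gt <- promote_dropped(css, epsilon = 3, min_dropped_reads = 3)
  gx <- gt$genotypes$X
  # A labels good clusters in 3 other samples -> promoted as dropped
  expect_true(A %in% gx$sequence)
  expect_equal(gx$origin[gx$sequence == A], "dropped")
  # the artifact sequence labels no good cluster anywhere -> not promoted
  expect_false("TTTTTTTT" %in% gx$sequence)
  # good clusters always carry through
  expect_true(B %in% gx$sequence)

  # a 1-read small cluster never promotes, however common the allele
  css$X$small[[1]] <- fake_cluster(A, 1)
  gt1 <- promote_dropped(css, epsilon = 3, min_dropped_reads = 3)
  expect_false(A %in% gt1$genotypes$X$sequence)

  # the focal sample's own good cluster does not count toward epsilon
  css2 <- list(
    X = fake_cs("X", small = list(fake_cluster(A, 5))),
    S1 = fake_cs("S1", good = A),
    S2 = fake_cs("S2", good = A))
  expect_false(A %in% promote_dropped(css2, epsilon = 3,
                                      min_dropped_reads = 3)$genotypes$X$sequence)
  expect_true(A %in% promote_dropped(css2, epsilon = 2,
                                     min_dropped_reads = 3)$genotypes$X$sequence)
})

test_that("raising epsilon never adds promoted alleles", {
  set.seed(51)
  alleles <- replicate(4, random_seq(12))
  css <- lapply(1:6, function(k) {
    good <- sample(alleles, sample(1:3, 1))
    small <- lapply(sample(alleles, sample(0:2, 1)),
                    function(a) fake_cluster(a, sample(3:10, 1)))
    fake_cs(paste0("S", k), good = good, small = small)
  })
  names(css) <- paste0("S", 1:6)
  n_promoted <- vapply(1:4, function(eps) {
    gt <- promote_dropped(css, epsilon = eps, min_dropped_reads = 3)
    sum(vapply(gt$genotypes, function(g) sum(g$origin == "dropped"),
               integer(1)))
  }, integer(1))
  expect_true(all(diff(n_promoted) <= 0))
})

test_that("single-crossover recombinants are detected exactly", {
  out <- find_recombinant_candidates(c("AAAAAA", "TTTTTT", "AAATTT"))
  hit <- out[out$daughter == "AAATTT", ]
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$parent_a[1], "AAAAAA")
  expect_equal(hit$parent_b[1], "TTTTTT")
  expect_equal(hit$breakpoint[1], 3L)
  # a daughter identical to a parent never qualifies
  expect_false("AAAAAA" %in% out$daughter)
  expect_false("TTTTTT" %in% out$daughter)

  # unrelated triple: brute force over all breakpoints finds nothing,
  # and neither does the implementation
  set.seed(52)
  tri <- replicate(3, random_seq(30))
  brute <- function(d, a, b) {
    dd <- strsplit(d, "")[[1]]; aa <- strsplit(a, "")[[1]]
    bb <- strsplit(b, "")[[1]]
    any(vapply(1:29, function(k)
      all(dd[1:k] == aa[1:k]) && all(dd[(k + 1):30] == bb[(k + 1):30]),
      logical(1)))
  }
  manual <- any(vapply(1:3, function(d) {
    others <- setdiff(1:3, d)
    any(brute(tri[d], tri[others[1]], tri[others[2]]),
        brute(tri[d], tri[others[2]], tri[others[1]]))
  }, logical(1)))
  expect_false(manual)
  expect_equal(nrow(find_recombinant_candidates(tri)), 0L)
})

test_that("chimeras are those recombinants that always co-occur with
           parents", {
  A <- strrep("A", 12); B <- strrep("T", 12)
  D <- paste0(strrep("A", 6), strrep("T", 6))  # crossover of A and B
  mk <- function(id, alleles) fake_cs(id, good = alleles)
  # D occurs in 4 samples, always with both parents -> chimera
  css <- list(S1 = mk("S1", c(A, B, D)), S2 = mk("S2", c(A, B, D)),
              S3 = mk("S3", c(A, B, D)), S4 = mk("S4", c(A, B, D)))
  gt <- promote_dropped(css, epsilon = 3)
  res <- classify_chimeras(gt)
  row <- res$report[res$report$allele == D, ]
  expect_equal(row$n_occurrences, 4L)
  expect_equal(row$percent_with_parents, 100)
  expect_true(row$is_chimera)
  expect_false(any(vapply(res$genotypes$genotypes,
                          function(g) D %in% g$sequence, logical(1))))

  # D also occurs without its parents -> naturally segregating, kept
  C <- strrep("G", 12)
  css$S5 <- mk("S5", c(D, C, mutate_sub(C, 3)))
  gt2 <- promote_dropped(css, epsilon = 3)
  res2 <- classify_chimeras(gt2)
  row2 <- res2$report[res2$report$allele == D, ]
  expect_false(row2$is_chimera)
  expect_lt(row2$percent_with_parents, 100)
  expect_true(D %in% res2$genotypes$genotypes$S5$sequence)

  # permuting sample order changes nothing
  res3 <- classify_chimeras(promote_dropped(rev(css), epsilon = 3))
  expect_equal(res3$report[order(res3$report$allele), ],
               res2$report[order(res2$report$allele), ],
               ignore_attr = TRUE)
})

test_that("the length screen removes only unexpected lengths and reports
           them", {
  A <- strrep("AC", 6); B <- strrep("GT", 6); short <- strrep("A", 11)
  css <- list(S1 = fake_cs("S1", good = c(A, short)),
              S2 = fake_cs("S2", good = B))
  gt <- promote_dropped(css, epsilon = 1)
  scr <- length_screen(gt, expected_len = 12)
  expect_equal(scr$removed, short)
  expect_false(short %in% scr$genotypes$genotypes$S1$sequence)
  expect_true(A %in% scr$genotypes$genotypes$S1$sequence)
  # all expected lengths: identity
  scr2 <- length_screen(scr$genotypes, expected_len = 12)
  expect_equal(length(scr2$removed), 0L)
})

test_that("diagnostics expose drop rates and degenerate correlations", {
  A <- strrep("AAGG", 3); B <- strrep("CCTT", 3)
  css <- list(
    S1 = fake_cs("S1", good = c(A, B), good_sizes = c(150, 40),
                 lib_size = 300),
    S2 = fake_cs("S2", good = A, good_sizes = 160,
                 small = list(fake_cluster(B, 6)), lib_size = 300),
    S3 = fake_cs("S3", good = A, good_sizes = 140,
                 small = list(fake_cluster(B, 8)), lib_size = 300),
    S4 = fake_cs("S4", good = c(A, B), good_sizes = c(150, 30),
                 lib_size = 300))
  gt <- promote_dropped(css, epsilon = 1, min_dropped_reads = 3)
  diag <- stc_diagnostics(gt)
  cat <- diag$catalog
  # B dropped twice out of four occurrences; A never dropped
  expect_equal(cat$drop_rate[cat$sequence == B], 0.5)
  expect_equal(cat$drop_rate[cat$sequence == A], 0)
  expect_lt(cat$mean_rel_size[cat$sequence == B],
            cat$mean_rel_size[cat$sequence == A])
  # only one allele ever dropped: too few points, correlation absent
  expect_true(is.na(diag$drop_efficiency_cor$estimate))
  # identical library sizes: zero variance, correlation absent
  expect_true(is.na(diag$size_allele_cor$estimate))
})

test_that("genotype matrix and allele table are consistent", {
  A <- strrep("AT", 5); B <- strrep("CG", 5); C <- strrep("GA", 5)
  css <- list(S1 = fake_cs("S1", good = c(A, B)),
              S2 = fake_cs("S2", good = c(A, C)))
  gt <- promote_dropped(css, epsilon = 1)
  out <- assemble_outputs(gt)
  expect_equal(dim(out$matrix), c(2L, 3L))
  expect_equal(unname(rowSums(out$matrix)), c(2, 2))
  # the shared allele occupies the first (most frequent) column
  expect_equal(out$alleles$sequence[1], A)
  expect_equal(unname(out$matrix[, 1]), c(1L, 1L))
  # FASTA round-trips
  fa <- tempfile(fileext = ".fasta")
  assemble_outputs(gt, fasta = fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), 3L)
  expect_setequal(as.character(back), c(A, B, C))

  empty <- promote_dropped(list(S1 = fake_cs("S1")), epsilon = 1)
  out0 <- assemble_outputs(empty)
  expect_equal(ncol(out0$matrix), 0L)
  expect_equal(nrow(out0$alleles), 0L)
})
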