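# Independent oracles and small-data generators used across tests.

# Dynamic-programming global aligner, written independently of the package
# (match +1, mismatch -1, gap -2 per column; among optimal-score alignments
# the one with fewest gap columns). Given the score and the gap-column
# count, the full difference profile is determined arithmetically.
oracle_align <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(A); lb <- length(B)
  S <- matrix(-Inf, la + 1, lb + 1)
  G <- matrix(Inf, la + 1, lb + 1)
  S[1, 1] <- 0; G[1, 1] <- 0
  for (i in 1:(la + 1)) {
    for (j in 1:(lb + 1)) {
      if (i == 1 && j == 1) next
      sc <- c(); gp <- c()
      if (i > 1 && j > 1) {
        sc <- c(sc, S[i - 1, j - 1] + if (A[i - 1] == B[j - 1]) 1 else -1)
        gp <- c(gp, G[i - 1, j - 1])
      }
      if (i > 1) { sc <- c(sc, S[i - 1, j] - 2); gp <- c(gp, G[i - 1, j] + 1) }
      if (j > 1) { sc <- c(sc, S[i, j - 1] - 2); gp <- c(gp, G[i, j - 1] + 1) }
      best <- max(sc)
      S[i, j] <- best
      G[i, j] <- min(gp[sc == best])
    }
  }
  score <- S[la + 1, lb + 1]; gaps <- G[la + 1, lb + 1]
  msum <- (la + lb - gaps) / 2          # aligned (non-gap) columns
  mat <- (msum + score + 2 * gaps) / 2  # from score = mat - sub - 2*gaps
  list(score = score, gaps = gaps, n_matches = mat, n_substitutions = msum - mat,
       n_columns = msum + gaps, similarity = 100 * mat / (msum + gaps))
}

# literal-rule reimplementation of phase 2 for tiny libraries, using the
# DP oracle above for the difference profiles
oracle_combine <- function(counts, expected_len) {
  pair_type <- function(a, b) {
    o <- oracle_align(a, b)
    dlen <- nchar(a) - nchar(b)
    g <- o$gaps; s <- o$n_substitutions
    if (g == 1 && s == 0) return("I")
    if (g == 2 && dlen == 0 && s == 0) return("II")
    if (g == 1 && s == 1) return("III")
    if (g == 1 && s == 2) return("IV")
    "V"
  }
  repeat {
    changed_sweep <- FALSE
    for (tp in c("I", "II", "III", "IV")) {
      repeat {
        seqs <- names(counts)
        if (length(seqs) < 2) break
        cand <- NULL
        for (x in seq_along(seqs)) for (y in seq_along(seqs)) {
          if (x >= y) next
          a <- seqs[x]; b <- seqs[y]
          if (pair_type(a, b) != tp) next
          if (tp == "II") {
            if (nchar(a) != expected_len || nchar(b) != expected_len) next
            first <- if (counts[a] >= counts[b]) a else b
            second <- setdiff(c(a, b), first)
          } else {
            ok_a <- nchar(a) == expected_len
            ok_b <- nchar(b) == expected_len
            if (ok_a == ok_b) next
            first <- if (ok_a) a else b
            second <- if (ok_a) b else a
          }
          if (counts[first] <= counts[second]) next
          cand <- rbind(cand, data.frame(first = first, second = second,
                                         stringsAsFactors = FALSE))
        }
        if (is.null(cand)) break
        pick <- NULL
        for (s2 in unique(cand$second)) {
          g <- cand[cand$second == s2, , drop = FALSE]
          if (nrow(g) > 1) {
            cc <- counts[g$first]
            if (sum(cc == max(cc)) > 1) next
            g <- g[which.max(cc), , drop = FALSE]
          }
          pick <- rbind(pick, g)
        }
        if (is.null(pick)) break
        pick <- pick[order(pick$second), , drop = FALSE]
        applied <- FALSE
        for (k in seq_len(nrow(pick))) {
          f <- pick$first[k]; s2 <- pick$second[k]
          if (!(f %in% names(counts)) || !(s2 %in% names(counts))) next
          if (counts[f] <= counts[s2]) next
          counts[f] <- counts[f] + counts[s2]
          counts <- counts[names(counts) != s2]
          applied <- TRUE
        }
        if (!applied) break
        changed_sweep <- TRUE
      }
    }
    if (!changed_sweep) break
  }
  counts[order(names(counts))]
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_sub <- function(seq, pos = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(pos)) pos <- sample(length(ch), 1)
  ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
  paste(ch, collapse = "")
}

mutate_del <- function(seq, pos = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(pos)) pos <- sample(length(ch), 1)
  paste(ch[-pos], collapse = "")
}

mutate_ins <- function(seq, pos = NULL, base = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(pos)) pos <- sample(length(ch), 1)
  if (is.null(base)) base <- sample(c("A", "C", "G", "T"), 1)
  paste(append(ch, base, after = pos), collapse = "")
}

# small library: a few "alleles" plus derived artifacts, as counts
random_small_library <- function(n_alleles = 2, len = 10, n_artifacts = 4,
                                 sample_id = "T") {
  alleles <- replicate(n_alleles, random_seq(len))
  counts <- stats::setNames(sample(10:40, n_alleles, replace = TRUE), alleles)
  for (k in seq_len(n_artifacts)) {
    src <- sample(alleles, 1)
    art <- switch(sample(3, 1), mutate_sub(src), mutate_del(src),
                  mutate_ins(src))
    counts[art] <- if (art %in% names(counts))
      counts[[art]] + sample(3, 1) else sample(3, 1)
  }
  sample_library(names(counts), unname(counts), sample_id = sample_id)
}
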