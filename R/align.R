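# Pairwise global alignment, difference profiles and percent similarity.
#
# All downstream phases consume the same fixed alignment scheme: end-to-end
# (Needleman-Wunsch) alignment with match +1, mismatch -1 and a linear gap
# cost of 2 per gap column. Every gap column counts as one indel, so a
# length-2 gap contributes 2 indels.

# substitution matrix over the read alphabet (N never matches anything else)
.stc_submat <- local({
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- 1
  m
})

.as_dna <- function(x) Biostrings::DNAStringSet(x)

#' Globally align two sequences and profile their differences
#'
#' Aligns `a` and `b` end-to-end under the package's fixed scoring scheme
#' (match +1, mismatch -1, gap -2 per column) and counts insertions (bases
#' present in `b` but not `a`), deletions (bases present in `a` but not `b`)
#' and substitutions on that alignment. Each gap column counts as one indel.
#'
#' @param a,b Non-empty nucleotide strings (alphabet `ACGTN`).
#' @return A list with integer components `n_insertions`, `n_deletions`,
#'   `n_substitutions`, `n_matches`, `n_columns` and numeric `similarity`
#'   (percent of alignment columns that are matches).
#' @examples
#' align_and_diff("AAAT", "AAT")   # one deletion
#' align_and_diff("ACGT", "AGGT")  # one substitution
#' @export
align_and_diff <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L, nzchar(a), nzchar(b))
  d <- .pair_diff_core(a, b)
  as.list(d)
}

# core vectorised differ over parallel pattern/subject vectors.
# Gap counts are derived arithmetically from the vectorised accessors
# (extracting aligned strings is far too slow at scale): with linear gap
# cost 2, score = matches - mismatches - 2 * gap_columns, so
#   gap_columns       = (matches - mismatches - score) / 2
#   gap_in_pattern - gap_in_subject = width(subject) - width(pattern)
# which determines both sides. Terminal gaps are included (the alignment
# is end-to-end), unlike Biostrings::nindel() which ignores them.
# Returns a matrix with columns gap_p, gap_s, sub, match, cols.
.diff_batch <- function(patterns, subjects) {
  p <- .as_dna(patterns)
  s <- .as_dna(subjects)
  aln <- Biostrings::pairwiseAlignment(
    pattern = p, subject = s, type = "global",
    substitutionMatrix = .stc_submat, gapOpening = 0, gapExtension = 2)
  nmat <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  gaps <- as.integer(round((nmat - nmis - Biostrings::score(aln)) / 2))
  dw <- Biostrings::width(s) - Biostrings::width(p)
  gap_p <- (gaps + dw) %/% 2L
  gap_s <- gaps - gap_p
  cbind(gap_p = gap_p, gap_s = gap_s, sub = nmis, match = nmat,
        cols = nmat + nmis + gaps)
}

.pair_diff_core <- function(a, b) {
  m <- .diff_batch(b, a)  # pattern = b, subject = a
  # a gap in the aligned pattern (b) marks a base of `a` absent from `b`,
  # i.e. a deletion; a gap in the aligned subject (a) marks an insertion
  list(n_insertions = unname(m[1L, "gap_s"]),
       n_deletions = unname(m[1L, "gap_p"]),
       n_substitutions = unname(m[1L, "sub"]),
       n_matches = unname(m[1L, "match"]),
       n_columns = unname(m[1L, "cols"]),
       similarity = unname(100 * m[1L, "match"] / m[1L, "cols"]))
}

#' Percent similarity between two sequences
#'
#' 100 x matches / alignment columns under the fixed global alignment used
#' throughout the package. Symmetric; 100 if and only if the sequences are
#' identical.
#'
#' @inheritParams align_and_diff
#' @return A numeric scalar in (0, 100].
#' @export
seq_similarity <- function(a, b) {
  unname(.pair_diff_core(a, b)[["similarity"]])
}

#' Difference profiles for all sequence pairs
#'
#' Enumerates all unordered pairs of `seqs` (optionally restricted to pairs
#' whose lengths differ by at most `max_len_diff`, since pairs differing by
#' two or more indels are never combinable) and returns their alignment
#' difference counts.
#'
#' @param seqs Character vector of unique sequences.
#' @param max_len_diff Maximum absolute length difference for a pair to be
#'   aligned; pairs beyond it are omitted.
#' @return A data frame with columns `i`, `j` (indices into `seqs`, `i < j`),
#'   `ins`, `del`, `sub` (counts oriented as `seqs[j]` relative to `seqs[i]`),
#'   `match`, `cols`, `sim`.
#' @keywords internal
pair_diff_table <- function(seqs, max_len_diff = Inf) {
  n <- length(seqs)
  empty <- data.frame(i = integer(), j = integer(), ins = integer(),
                      del = integer(), sub = integer(), match = integer(),
                      cols = integer(), sim = numeric())
  if (n < 2L) return(empty)
  lens <- nchar(seqs)
  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- sequence((n - 1L):1L, from = 2L:n)
  if (is.finite(max_len_diff)) {
    keep <- abs(lens[jj] - lens[ii]) <= max_len_diff
    ii <- ii[keep]; jj <- jj[keep]
  }
  if (!length(ii)) return(empty)
  # chunk the vectorised alignment call to bound memory
  chunk <- 25000L
  out <- vector("list", ceiling(length(ii) / chunk))
  for (k in seq_along(out)) {
    sel <- ((k - 1L) * chunk + 1L):min(k * chunk, length(ii))
    m <- .diff_batch(seqs[jj[sel]], seqs[ii[sel]])  # pattern j, subject i
    out[[k]] <- data.frame(i = ii[sel], j = jj[sel],
                           ins = m[, "gap_s"], del = m[, "gap_p"],
                           sub = m[, "sub"], match = m[, "match"],
                           cols = m[, "cols"],
                           sim = 100 * m[, "match"] / m[, "cols"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise percent-similarity matrix
#'
#' @param seqs Character vector of unique sequences.
#' @return A symmetric numeric matrix (percent similarity, 100 on the
#'   diagonal) with `seqs` as dimnames.
#' @export
similarity_matrix <- function(seqs) {
  n <- length(seqs)
  sim <- matrix(100, n, n, dimnames = list(seqs, seqs))
  if (n < 2L) return(sim)
  tab <- pair_diff_table(seqs)
  sim[cbind(tab$i, tab$j)] <- tab$sim
  sim[cbind(tab$j, tab$i)] <- tab$sim
  sim
}
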