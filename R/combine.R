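# Phase 2: pair-type classification and combination of length-variant
# artifacts (mostly homopolymer indels) into their correct-length sources.
#
# Pair types, from the counts on the fixed global alignment:
#   I   exactly one indel, no substitutions
#   II  exactly one insertion plus one deletion, no substitutions
#   III one indel and one substitution
#   IV  one indel and two substitutions
#   V   everything else (never combined)

#' Classify a sequence pair by its difference profile
#'
#' @param diff A difference profile from [align_and_diff()] (or a list with
#'   `n_insertions`, `n_deletions`, `n_substitutions`).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @examples
#' classify_pair(align_and_diff("ACGGT", "ACGT"))  # "I"
#' @export
classify_pair <- function(diff) {
  ins <- diff$n_insertions
  del <- diff$n_deletions
  sub <- diff$n_substitutions
  tot <- ins + del
  if (ins == 1L && del == 1L && sub == 0L) return("II")
  if (tot == 1L) {
    if (sub == 0L) return("I")
    if (sub == 1L) return("III")
    if (sub == 2L) return("IV")
  }
  "V"
}

.pair_type_vec <- function(ins, del, sub) {
  tot <- ins + del
  type <- rep("V", length(ins))
  type[tot == 1L & sub == 0L] <- "I"
  type[ins == 1L & del == 1L & sub == 0L] <- "II"
  type[tot == 1L & sub == 1L] <- "III"
  type[tot == 1L & sub == 2L] <- "IV"
  type
}

#' Combine near-identical length-variant artifacts into their sources
#'
#' Processes pair types I, II, III and IV in that order. A pair is combined
#' (the reads of the second, derived member are converted into reads of the
#' first) when: (1) the first member has the expected amplicon length;
#' (2) the first member is strictly more common than the second at the time
#' of combination; and (3) for a derived member appearing in several
#' candidate pairs of one type, the conflict rule applies: by default the
#' pair with the most common first member is combined (an exact read-count
#' tie skips the member); in `"strict"` mode such members are never
#' combined. For types I, III and IV the first member is the correct-length
#' sequence (pairs where neither member has the expected length are not
#' combinable); for type II, where both members share a length (required to
#' equal `expected_len`), the first member is the more common sequence.
#'
#' Sweeps over the four types are repeated until no further combination
#' applies, so the operation is idempotent; total read count is always
#' conserved.
#'
#' @param lib A [sample_library()] (phase-1 output).
#' @param expected_len Expected amplicon length in bp (e.g. 213).
#' @param conflict `"most_common"` (default) or `"strict"`.
#' @return A list with `library` (the combined `stc_library`) and
#'   `records`, a data frame of combinations (`absorbed`, `target`,
#'   `pair_type`, `reads_moved`).
#' @export
combine_library <- function(lib, expected_len,
                            conflict = c("most_common", "strict")) {
  stopifnot(inherits(lib, "stc_library"), expected_len > 0L)
  conflict <- match.arg(conflict)
  counts <- lib$counts
  seqs <- names(counts)
  empty_rec <- data.frame(absorbed = character(), target = character(),
                          pair_type = character(), reads_moved = integer(),
                          stringsAsFactors = FALSE)
  if (length(seqs) < 2L) {
    return(list(library = lib, records = empty_rec))
  }

  # pairs with length difference >= 2 can never be types I-IV
  tab <- pair_diff_table(seqs, max_len_diff = 1L)
  if (nrow(tab)) {
    tab$type <- .pair_type_vec(tab$ins, tab$del, tab$sub)
    tab <- tab[tab$type != "V", , drop = FALSE]
  }
  if (!nrow(tab)) {
    return(list(library = lib, records = empty_rec))
  }
  tab$seq_i <- seqs[tab$i]
  tab$seq_j <- seqs[tab$j]
  lens <- nchar(seqs)
  tab$len_i <- lens[tab$i]
  tab$len_j <- lens[tab$j]

  records <- empty_rec
  repeat {
    changed_sweep <- FALSE
    for (tp in c("I", "II", "III", "IV")) {
      repeat {
        sub <- tab[tab$type == tp &
                     tab$seq_i %in% names(counts) &
                     tab$seq_j %in% names(counts), , drop = FALSE]
        if (!nrow(sub)) break
        # orient each pair as (first = source, second = derived)
        if (tp == "II") {
          ok <- sub$len_i == expected_len & sub$len_j == expected_len
          sub <- sub[ok, , drop = FALSE]
          if (!nrow(sub)) break
          ci <- counts[sub$seq_i]; cj <- counts[sub$seq_j]
          first <- ifelse(ci >= cj, sub$seq_i, sub$seq_j)
          second <- ifelse(ci >= cj, sub$seq_j, sub$seq_i)
          keep <- counts[first] > counts[second]  # ties never combine
        } else {
          i_ok <- sub$len_i == expected_len
          j_ok <- sub$len_j == expected_len
          one <- xor(i_ok, j_ok)  # both/neither correct length: not combinable
          sub <- sub[one, , drop = FALSE]
          if (!nrow(sub)) break
          first <- ifelse(sub$len_i == expected_len, sub$seq_i, sub$seq_j)
          second <- ifelse(sub$len_i == expected_len, sub$seq_j, sub$seq_i)
          keep <- counts[first] > counts[second]
        }
        cand <- data.frame(first = first, second = second,
                           stringsAsFactors = FALSE)[keep, , drop = FALSE]
        if (!nrow(cand)) break
        # conflict rule for derived members in several candidate pairs
        chosen <- lapply(split(cand, cand$second), function(g) {
          if (nrow(g) > 1L) {
            if (conflict == "strict") return(NULL)
            cc <- counts[g$first]
            top <- which(cc == max(cc))
            if (length(top) > 1L) return(NULL)  # tie: skip
            g <- g[top, , drop = FALSE]
          }
          g
        })
        chosen <- do.call(rbind, chosen)
        if (is.null(chosen) || !nrow(chosen)) break
        chosen <- chosen[order(chosen$second), , drop = FALSE]
        applied <- FALSE
        for (k in seq_len(nrow(chosen))) {
          f <- chosen$first[k]; s <- chosen$second[k]
          if (!(f %in% names(counts)) || !(s %in% names(counts))) next
          if (counts[f] <= counts[s]) next
          moved <- unname(counts[s])
          counts[f] <- counts[f] + counts[s]
          counts <- counts[names(counts) != s]
          records <- rbind(records, data.frame(
            absorbed = s, target = f, pair_type = tp, reads_moved = moved,
            stringsAsFactors = FALSE))
          applied <- TRUE
        }
        if (!applied) break
        changed_sweep <- TRUE
      }
    }
    if (!changed_sweep) break
  }
  out <- sample_library(names(counts), unname(counts),
                        sample_id = lib$sample_id)
  rownames(records) <- NULL
  list(library = out, records = records)
}
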