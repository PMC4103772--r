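# Phase 3: stepwise threshold clustering.
#
# Reads are clustered in repeated rounds at an increasing similarity
# threshold gamma. After each round clusters are classified good / small /
# ambiguous by the size (theta) and dominance (delta) criteria; good and
# small clusters are exempt from further rounds while ambiguous clusters
# are pooled and re-clustered at the next gamma. Residual ambiguous
# clusters after the last round are split on their two most frequent
# correct-length sequences.

#' Clustering parameters
#'
#' @param theta Size threshold: minimum fraction of the sample library a
#'   cluster must hold to be classified good (default 1/22).
#' @param delta Dominance threshold: the dominant/subdominant read-count
#'   ratio must exceed this for a cluster not to be ambiguous (default
#'   0.82/0.18, the ratio implied by the expected error-free read
#'   fraction).
#' @param gamma_start Starting similarity threshold in percent, or
#'   `"auto"` (floor of the minimum pairwise similarity in the library).
#' @param gamma_step Increment per round, percent (default 1).
#' @param gamma_end Final threshold, percent (default 97; stopping slightly
#'   below 100 keeps minor-error artifacts attached to their clusters).
#' @param replicates Clustering replicates per round used for the modal
#'   assignment (default 100).
#' @param epsilon Phase-4 commonness: a sequence must label good clusters
#'   in at least this many other samples for a small cluster to be
#'   promoted (default 3).
#' @param min_dropped_reads Minimum total reads for a small cluster to be
#'   promotable (default 3).
#' @param expected_len Expected amplicon length in bp (default 213).
#' @param seed Optional integer seed making a run fully deterministic.
#' @return An object of class `stc_params`.
#' @export
stc_params <- function(theta = 1 / 22, delta = 0.82 / 0.18,
                       gamma_start = "auto", gamma_step = 1,
                       gamma_end = 97, replicates = 100L, epsilon = 3L,
                       min_dropped_reads = 3L, expected_len = 213L,
                       seed = NULL) {
  stopifnot(theta > 0, theta < 1, delta > 1, gamma_step > 0,
            gamma_end <= 100, replicates >= 1L, epsilon >= 1L,
            min_dropped_reads >= 1L, expected_len >= 1L)
  if (!identical(gamma_start, "auto")) {
    stopifnot(is.numeric(gamma_start), gamma_start <= gamma_end)
  }
  structure(list(theta = theta, delta = delta, gamma_start = gamma_start,
                 gamma_step = gamma_step, gamma_end = gamma_end,
                 replicates = as.integer(replicates),
                 epsilon = as.integer(epsilon),
                 min_dropped_reads = as.integer(min_dropped_reads),
                 expected_len = as.integer(expected_len), seed = seed),
            class = "stc_params")
}

#' @export
print.stc_params <- function(x, ...) {
  cat("STC parameters\n")
  cat(sprintf("  theta (size)        %.4f\n", x$theta))
  cat(sprintf("  delta (dominance)   %.2f\n", x$delta))
  cat("  gamma               ",
      if (identical(x$gamma_start, "auto")) "auto" else x$gamma_start,
      " -> ", x$gamma_end, " by ", x$gamma_step, "\n", sep = "")
  cat("  replicates          ", x$replicates, "\n", sep = "")
  cat("  epsilon / min reads ", x$epsilon, " / ", x$min_dropped_reads,
      "\n", sep = "")
  cat("  expected length     ", x$expected_len, " bp\n", sep = "")
  invisible(x)
}

#' Recommended starting thresholds
#'
#' `recommend_delta()` returns the dominance threshold implied by the
#' expected fraction of error-free reads (default 0.82 for pyrosequencing):
#' the dominant/subdominant ratio in a one-allele cluster is expected to be
#' at least `error_free / (1 - error_free)`. `recommend_theta()` returns
#' the size threshold `1 / (max alleles x safety)`: one over the maximum
#' expected allele count (twice the locus count, all heterozygous), divided
#' again by a safety constant to allow for amplification bias.
#'
#' @param error_free Expected fraction of error-free reads.
#' @param n_loci Number of co-amplified loci.
#' @param safety Safety constant dividing the minimum expected cluster
#'   share (default 2).
#' @return A numeric scalar.
#' @export
recommend_delta <- function(error_free = 0.82) {
  stopifnot(error_free > 0.5, error_free < 1)
  error_free / (1 - error_free)
}

#' @rdname recommend_delta
#' @export
recommend_theta <- function(n_loci = 6, safety = 2) {
  stopifnot(n_loci >= 1, safety >= 1)
  1 / (2 * n_loci * safety)
}

#' Automatic starting similarity threshold
#'
#' The similarity between the two most dissimilar sequences in the library,
#' floored to an integer percent. With fewer than two unique sequences no
#' clustering is needed and `gamma_end` is returned.
#'
#' @param lib A [sample_library()].
#' @param gamma_end Upper clamp (default 97).
#' @param simmat Optional precomputed [similarity_matrix()].
#' @return Integer percent.
#' @export
gamma_start_auto <- function(lib, gamma_end = 97, simmat = NULL) {
  seqs <- names(lib$counts)
  if (length(seqs) < 2L) return(gamma_end)
  if (is.null(simmat)) simmat <- similarity_matrix(seqs)
  min_sim <- min(simmat[upper.tri(simmat)])
  min(floor(min_sim), gamma_end)
}

.new_cluster <- function(members, formed_at_gamma = NA_real_) {
  # members: named integer counts
  ord <- order(-members, names(members))
  members <- members[ord]
  structure(list(
    members = members,
    label = names(members)[1L],
    dominant_seq = names(members)[1L],
    dominant_count = unname(members[1L]),
    subdominant_seq = if (length(members) > 1L) names(members)[2L] else NA_character_,
    subdominant_count = if (length(members) > 1L) unname(members[2L]) else NA_integer_,
    size = sum(members),
    status = NA_character_,
    formed_at_gamma = formed_at_gamma), class = "stc_cluster")
}

#' @export
print.stc_cluster <- function(x, ...) {
  cat("Cluster ", substr(x$label, 1L, 24L),
      if (nchar(x$label) > 24L) "...", " (", x$size, " reads, ",
      length(x$members), " sequences",
      if (!is.na(x$status)) paste0(", ", x$status),
      if (!is.na(x$formed_at_gamma)) paste0(", gamma ", x$formed_at_gamma),
      ")\n", sep = "")
  invisible(x)
}

#' One clustering replicate
#'
#' Runs a single sequential clustering pass at threshold `gamma` and
#' returns the cluster label (the final dominant sequence of its cluster)
#' for every unique sequence. Uses the current R random number state.
#'
#' @param counts Named integer vector: read count per unique sequence.
#' @param gamma Similarity threshold in percent.
#' @param simmat Optional precomputed [similarity_matrix()] over
#'   `names(counts)`.
#' @return A character vector of labels, parallel to `counts`.
#' @export
cluster_replicate <- function(counts, gamma, simmat = NULL) {
  seqs <- names(counts)
  if (is.null(simmat)) simmat <- similarity_matrix(seqs)
  lexrank <- rank(seqs, ties.method = "first") - 1L
  lab <- stc_cluster_replicate(as.integer(counts),
                               simmat[seqs, seqs, drop = FALSE],
                               gamma, as.integer(lexrank))
  stats::setNames(seqs[lab], seqs)
}

#' Modal clusters over replicates
#'
#' Repeats the clustering `replicates` times from random read orders and
#' assigns each sequence to its modal (most frequent) cluster label;
#' sequences sharing a modal label form one cluster. Labels are treated as
#' opaque group keys (no transitive merging).
#'
#' @inheritParams cluster_replicate
#' @param replicates Number of replicates.
#' @param seed Optional integer seed.
#' @param formed_at_gamma Gamma recorded on the returned clusters.
#' @return A list of cluster objects.
#' @export
modal_clusters <- function(counts, gamma, replicates = 100L, seed = NULL,
                           simmat = NULL, formed_at_gamma = gamma) {
  seqs <- names(counts)
  stopifnot(length(seqs) >= 1L, all(counts > 0L))
  if (!is.null(seed)) set.seed(seed)
  if (length(seqs) == 1L) {
    return(list(.new_cluster(stats::setNames(as.integer(counts), seqs),
                             formed_at_gamma)))
  }
  if (is.null(simmat)) simmat <- similarity_matrix(seqs)
  lexrank <- rank(seqs, ties.method = "first") - 1L
  lab <- stc_modal_labels(as.integer(counts),
                          simmat[seqs, seqs, drop = FALSE],
                          gamma, as.integer(replicates),
                          as.integer(lexrank))
  groups <- split(seq_along(seqs), lab)
  out <- lapply(groups, function(ix) {
    .new_cluster(stats::setNames(as.integer(counts[ix]), seqs[ix]),
                 formed_at_gamma)
  })
  # deterministic order: decreasing size then label
  sizes <- vapply(out, function(cl) cl$size, numeric(1L))
  labels <- vapply(out, function(cl) cl$label, character(1L))
  unname(out[order(-sizes, labels)])
}

#' Classify a cluster as good, small or ambiguous
#'
#' A cluster is good when it holds at least a fraction `theta` of the
#' sample library and its dominant/subdominant read-count ratio exceeds
#' `delta`; small when it passes dominance but fails size; ambiguous when
#' it fails dominance (whatever its size). Single-sequence clusters have an
#' infinite dominance ratio.
#'
#' @param cluster A cluster (from [modal_clusters()]).
#' @param library_size Fixed denominator for the size criterion: the
#'   post-filter sample library size.
#' @param theta,delta Thresholds, see [stc_params()].
#' @return `"good"`, `"small"` or `"ambiguous"`.
#' @export
classify_cluster <- function(cluster, library_size, theta, delta) {
  stopifnot(library_size >= cluster$size)
  ratio <- dominance_ratio(cluster)
  if (ratio <= delta) return("ambiguous")
  if (cluster$size / library_size >= theta) "good" else "small"
}

#' @rdname classify_cluster
#' @export
dominance_ratio <- function(cluster) {
  if (is.na(cluster$subdominant_count)) return(Inf)
  cluster$dominant_count / cluster$subdominant_count
}

#' Split a residual ambiguous cluster
#'
#' An ambiguous cluster left after the final round is divided into two
#' sub-clusters sized in proportion to the read counts of its two most
#' frequent correct-length sequences; each sub-cluster is then classified
#' good or small by the size criterion alone. Sequences of unexpected
#' length are skipped when choosing the dominant pair (the third most
#' frequent sequence stands in as subdominant). Clusters with fewer than
#' two correct-length sequences are returned whole as small, with a
#' warning.
#'
#' @inheritParams classify_cluster
#' @param expected_len Expected amplicon length.
#' @return A list of one or two clusters with `status` set.
#' @export
split_ambiguous <- function(cluster, library_size, theta, expected_len) {
  members <- cluster$members  # sorted by decreasing count
  ok_len <- nchar(names(members)) == expected_len
  top <- which(ok_len)
  if (length(top) < 2L) {
    warning("ambiguous cluster ", cluster$label,
            " has fewer than two correct-length sequences; kept whole as small")
    cluster$status <- "small"
    return(list(cluster))
  }
  d_ix <- top[1L]; s_ix <- top[2L]
  d <- unname(members[d_ix]); s <- unname(members[s_ix])
  total <- cluster$size
  size_a <- round(total * d / (d + s))
  size_b <- total - size_a
  mk <- function(ix, size) {
    cl <- .new_cluster(stats::setNames(as.integer(size), names(members)[ix]),
                       cluster$formed_at_gamma)
    cl$status <- if (size / library_size >= theta) "good" else "small"
    cl
  }
  list(mk(d_ix, size_a), mk(s_ix, size_b))
}

#' Run stepwise threshold clustering on one sample library
#'
#' Loops gamma from its starting value (by default the floor of the
#' minimum pairwise similarity) to `gamma_end` in `gamma_step` increments.
#' Each round clusters the pooled not-yet-exempt reads via
#' [modal_clusters()], classifies every cluster, exempts good and small
#' clusters and carries ambiguous reads forward. Residual ambiguous
#' clusters after the last round are resolved with [split_ambiguous()].
#' Fully deterministic for a fixed `params$seed`.
#'
#' @param lib A [sample_library()], normally after [combine_library()].
#' @param params An [stc_params()] object.
#' @param simmat Optional precomputed [similarity_matrix()] over the
#'   library's sequences.
#' @return An object of class `stc_clusterset`: list with `sample_id`,
#'   `good` and `small` (lists of clusters), `logs` (one row per round:
#'   `gamma`, `n_good`, `n_small`, `n_ambiguous`, `reads_left`,
#'   `sequences_left`) and `library_size`.
#' @export
run_stc <- function(lib, params = stc_params(), simmat = NULL) {
  stopifnot(inherits(lib, "stc_library"), inherits(params, "stc_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  counts <- lib$counts
  lib_size <- lib$library_size
  empty_log <- data.frame(gamma = numeric(), n_good = integer(),
                          n_small = integer(), n_ambiguous = integer(),
                          reads_left = integer(), sequences_left = integer())
  res <- structure(list(sample_id = lib$sample_id, good = list(),
                        small = list(), logs = empty_log,
                        library_size = lib_size, params = params),
                   class = "stc_clusterset")
  if (!length(counts)) return(res)

  seqs <- names(counts)
  if (is.null(simmat)) simmat <- similarity_matrix(seqs)
  gs <- if (identical(params$gamma_start, "auto")) {
    gamma_start_auto(lib, params$gamma_end, simmat)
  } else params$gamma_start
  gammas <- seq(gs, params$gamma_end, by = params$gamma_step)
  if (gammas[length(gammas)] < params$gamma_end) {
    gammas <- c(gammas, params$gamma_end)
  }

  active <- counts
  good <- list()
  small <- list()
  logs <- empty_log
  ambiguous <- list()
  for (g in gammas) {
    if (!length(active)) break
    clusters <- modal_clusters(active, g, params$replicates,
                               simmat = simmat, formed_at_gamma = g)
    ambiguous <- list()
    for (cl in clusters) {
      st <- classify_cluster(cl, lib_size, params$theta, params$delta)
      cl$status <- st
      if (st == "good") {
        good <- c(good, list(cl))
      } else if (st == "small") {
        small <- c(small, list(cl))
      } else {
        ambiguous <- c(ambiguous, list(cl))
      }
    }
    exempt <- unlist(lapply(c(good, small), function(cl) names(cl$members)))
    active <- counts[setdiff(names(counts), exempt)]
    logs <- rbind(logs, data.frame(
      gamma = g, n_good = length(good), n_small = length(small),
      n_ambiguous = length(ambiguous), reads_left = sum(active),
      sequences_left = length(active)))
  }
  # resolve residual ambiguous clusters
  for (cl in ambiguous) {
    parts <- split_ambiguous(cl, lib_size, params$theta, params$expected_len)
    for (p in parts) {
      if (p$status == "good") good <- c(good, list(p))
      else small <- c(small, list(p))
    }
  }
  res$good <- good
  res$small <- small
  res$logs <- logs
  res
}

#' @export
print.stc_clusterset <- function(x, ...) {
  cat("Stepwise threshold clustering",
      if (!is.na(x$sample_id)) paste0(" for ", sQuote(x$sample_id)),
      "\n", sep = "")
  cat("  library size: ", x$library_size, " reads\n", sep = "")
  cat("  good clusters: ", length(x$good), ", small clusters: ",
      length(x$small), "\n", sep = "")
  if (nrow(x$logs)) {
    cat("  rounds: gamma ", x$logs$gamma[1L], " -> ",
        x$logs$gamma[nrow(x$logs)], "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.stc_clusterset <- function(object, ...) {
  cl <- c(object$good, object$small)
  data.frame(
    label = vapply(cl, function(c) c$label, character(1L)),
    size = vapply(cl, function(c) c$size, numeric(1L)),
    dominant_count = vapply(cl, function(c) c$dominant_count, numeric(1L)),
    subdominant_count = vapply(cl, function(c)
      as.numeric(c$subdominant_count), numeric(1L)),
    status = vapply(cl, function(c) c$status, character(1L)),
    formed_at_gamma = vapply(cl, function(c)
      as.numeric(c$formed_at_gamma), numeric(1L)),
    stringsAsFactors = FALSE)
}
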