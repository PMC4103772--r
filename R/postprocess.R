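# Phase 4: cross-checking small clusters against common good clusters
# (dropped-allele recovery), chimera screening, genotype assembly and
# amplification-efficiency diagnostics.

.good_labels <- function(cs) {
  vapply(cs$good, function(cl) cl$label, character(1L))
}

#' Promote dropped alleles by cross-checking across samples
#'
#' A small cluster in one sample is promoted to a true (dropped) allele
#' when its label sequence labels good clusters in at least `epsilon`
#' *other* samples and the cluster holds at least `min_dropped_reads`
#' reads. All good-cluster labels plus promotions become the sample's true
#' alleles. Only phase-3 good clusters count toward commonness; promoted
#' alleles do not bootstrap further promotions.
#'
#' @param clustersets A list of `stc_clusterset` objects, one per sample
#'   (named or carrying `sample_id`s).
#' @param epsilon Minimum number of other samples in which a sequence must
#'   label a good cluster to be common (default 3).
#' @param min_dropped_reads Minimum small-cluster size for promotion
#'   (default 3).
#' @return An object of class `stc_genotypes`: a list with `genotypes`
#'   (per sample, data frame `sequence`, `origin` (`"good"`/`"dropped"`),
#'   `cluster_size`) and `catalog` (see [allele_catalog()]).
#' @export
promote_dropped <- function(clustersets, epsilon = 3L, min_dropped_reads = 3L) {
  stopifnot(length(clustersets) >= 1L)
  ids <- vapply(clustersets, function(cs) cs$sample_id, character(1L))
  if (!is.null(names(clustersets))) ids <- names(clustersets)
  names(clustersets) <- ids
  good_by_sample <- lapply(clustersets, .good_labels)
  n_good_samples <- table(unlist(lapply(good_by_sample, unique)))

  genotypes <- lapply(ids, function(s) {
    cs <- clustersets[[s]]
    g <- lapply(cs$good, function(cl)
      data.frame(sequence = cl$label, origin = "good",
                 cluster_size = cl$size, stringsAsFactors = FALSE))
    g <- do.call(rbind, c(g, list(data.frame(sequence = character(),
                                             origin = character(),
                                             cluster_size = numeric()))))
    have <- unique(g$sequence)
    d <- lapply(cs$small, function(cl) {
      if (cl$label %in% have) return(NULL)
      if (cl$size < min_dropped_reads) return(NULL)
      elsewhere <- sum(vapply(ids[ids != s], function(o)
        cl$label %in% good_by_sample[[o]], logical(1L)))
      if (elsewhere < epsilon) return(NULL)
      data.frame(sequence = cl$label, origin = "dropped",
                 cluster_size = cl$size, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(list(g), d))
    out <- out[!duplicated(out$sequence), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(genotypes) <- ids
  res <- structure(list(genotypes = genotypes,
                        library_sizes = stats::setNames(vapply(
                          clustersets, function(cs) cs$library_size,
                          numeric(1L)), ids)),
                   class = "stc_genotypes")
  res$catalog <- allele_catalog(res)
  res
}

#' Per-allele occurrence catalog
#'
#' Counts, for every allele sequence, the samples where it was called as a
#' good cluster, where it entered as a promoted (dropped) allele, and its
#' mean relative cluster size (cluster reads over sample library size),
#' both overall and over good occurrences only.
#'
#' @param genotypes An `stc_genotypes` object.
#' @return A data frame, one row per allele, sorted by decreasing total
#'   occurrences.
#' @export
allele_catalog <- function(genotypes) {
  stopifnot(inherits(genotypes, "stc_genotypes"))
  rows <- lapply(names(genotypes$genotypes), function(s) {
    g <- genotypes$genotypes[[s]]
    if (!nrow(g)) return(NULL)
    data.frame(sequence = g$sequence, origin = g$origin,
               rel_size = g$cluster_size / genotypes$library_sizes[[s]],
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(sequence = character(), n_samples_good = integer(),
                      n_samples_dropped = integer(),
                      n_samples_total = integer(), drop_rate = numeric(),
                      mean_rel_size = numeric(),
                      mean_rel_size_good = numeric()))
  }
  per <- split(all, all$sequence)
  cat <- do.call(rbind, lapply(per, function(g) {
    ng <- sum(g$origin == "good")
    nd <- sum(g$origin == "dropped")
    data.frame(sequence = g$sequence[1L], n_samples_good = ng,
               n_samples_dropped = nd, n_samples_total = ng + nd,
               drop_rate = nd / (ng + nd),
               mean_rel_size = mean(g$rel_size),
               mean_rel_size_good = if (ng)
                 mean(g$rel_size[g$origin == "good"]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  cat <- cat[order(-cat$n_samples_total, cat$sequence), , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

#' @export
print.stc_genotypes <- function(x, ...) {
  n_all <- length(unique(unlist(lapply(x$genotypes, function(g) g$sequence))))
  cat("Genotypes for ", length(x$genotypes), " samples, ", n_all,
      " distinct alleles\n", sep = "")
  counts <- vapply(x$genotypes, nrow, integer(1L))
  cat("  alleles per sample: mean ", round(mean(counts), 2L),
      " (range ", min(counts), "-", max(counts), ")\n", sep = "")
  invisible(x)
}

#' Find single-crossover recombinant candidates among a sample's alleles
#'
#' An allele qualifies as a recombinant daughter of parents (A, B) when
#' some breakpoint splits it so the prefix matches A and the suffix
#' matches B with at most `max_mismatch` total mismatches, and the
#' daughter differs from both parents. Only equal-length alleles are
#' compared positionally.
#'
#' @param alleles Character vector of a sample's allele sequences.
#' @param max_mismatch Total mismatches tolerated across both segments
#'   (default 0, exact matching).
#' @return A data frame `daughter`, `parent_a`, `parent_b`, `breakpoint`
#'   (last position taken from `parent_a`); unordered parent pairs are
#'   reported once each way only if both orders yield a crossover.
#' @export
find_recombinant_candidates <- function(alleles, max_mismatch = 0L) {
  out <- data.frame(daughter = character(), parent_a = character(),
                    parent_b = character(), breakpoint = integer(),
                    stringsAsFactors = FALSE)
  n <- length(alleles)
  if (n < 3L) return(out)
  lens <- nchar(alleles)
  # cumulative mismatch profiles between equal-length pairs
  chars <- lapply(alleles, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  for (d in seq_len(n)) {
    L <- lens[d]
    others <- setdiff(which(lens == L), d)
    if (length(others) < 2L) next
    pref <- lapply(others, function(o) cumsum(chars[[d]] != chars[[o]]))
    names(pref) <- as.character(others)
    for (a in others) for (b in others) {
      if (a == b) next
      pa <- pref[[as.character(a)]]
      pb <- pref[[as.character(b)]]
      tot_b <- pb[L]
      # breakpoint k: positions 1..k from parent a, k+1..L from parent b
      ks <- which((pa + (tot_b - pb))[-L] <= max_mismatch)
      if (length(ks)) {
        out <- rbind(out, data.frame(daughter = alleles[d],
                                     parent_a = alleles[a],
                                     parent_b = alleles[b],
                                     breakpoint = ks[1L],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Screen genotypes for PCR chimeras
#'
#' Every allele that looks like a single-crossover recombinant of two
#' other alleles in at least one sample is evaluated across all samples
#' containing it: if possible parent pairs co-occur in 100% of those
#' samples the allele is classified a chimera and removed from the
#' genotypes. Recombinants that occur without their parents in some sample
#' are assumed to be naturally segregating and kept.
#'
#' @param genotypes An `stc_genotypes` object.
#' @param max_mismatch Passed to [find_recombinant_candidates()].
#' @return A list with `genotypes` (chimeras removed) and `report`, a data
#'   frame mirroring the per-allele chimera table (`allele`,
#'   `n_occurrences`, `n_with_parents`, `percent_with_parents`,
#'   `is_chimera`).
#' @export
classify_chimeras <- function(genotypes, max_mismatch = 0L) {
  stopifnot(inherits(genotypes, "stc_genotypes"))
  ids <- names(genotypes$genotypes)
  allele_sets <- lapply(genotypes$genotypes, function(g) g$sequence)
  # candidate recombinants per sample
  cand_by_sample <- lapply(allele_sets, find_recombinant_candidates,
                           max_mismatch = max_mismatch)
  candidates <- unique(unlist(lapply(cand_by_sample, function(d) d$daughter)))
  report <- data.frame(allele = character(), n_occurrences = integer(),
                       n_with_parents = integer(),
                       percent_with_parents = numeric(),
                       is_chimera = logical(), stringsAsFactors = FALSE)
  for (al in sort(candidates)) {
    with_allele <- ids[vapply(allele_sets, function(s) al %in% s, logical(1L))]
    n_with_parents <- sum(vapply(with_allele, function(s) {
      cc <- cand_by_sample[[s]]
      al %in% cc$daughter
    }, logical(1L)))
    pct <- 100 * n_with_parents / length(with_allele)
    report <- rbind(report, data.frame(
      allele = al, n_occurrences = length(with_allele),
      n_with_parents = n_with_parents, percent_with_parents = pct,
      is_chimera = pct == 100, stringsAsFactors = FALSE))
  }
  chim <- report$allele[report$is_chimera]
  if (length(chim)) {
    genotypes$genotypes <- lapply(genotypes$genotypes, function(g)
      g[!(g$sequence %in% chim), , drop = FALSE])
    genotypes$catalog <- allele_catalog(genotypes)
  }
  list(genotypes = genotypes, report = report)
}

#' Remove alleles of unexpected length
#'
#' A conservative, dataset-specific screen, off by default in the
#' pipeline: alleles whose length differs from the expected amplicon
#' length are removed and reported.
#'
#' @param genotypes An `stc_genotypes` object.
#' @param expected_len Expected amplicon length.
#' @return A list with `genotypes` and `removed` (character vector of
#'   removed allele sequences).
#' @export
length_screen <- function(genotypes, expected_len) {
  stopifnot(inherits(genotypes, "stc_genotypes"))
  all_alleles <- unique(unlist(lapply(genotypes$genotypes,
                                      function(g) g$sequence)))
  bad <- all_alleles[nchar(all_alleles) != expected_len]
  if (length(bad)) {
    genotypes$genotypes <- lapply(genotypes$genotypes, function(g)
      g[!(g$sequence %in% bad), , drop = FALSE])
    genotypes$catalog <- allele_catalog(genotypes)
  }
  list(genotypes = genotypes, removed = bad)
}

#' Amplification-efficiency and library-size diagnostics
#'
#' Computes per-allele drop rates and mean relative cluster sizes, the
#' Pearson correlation between them over alleles dropped at least once
#' (low-efficiency alleles are expected to drop more and form smaller
#' clusters, a negative correlation), and the Pearson correlation between
#' sample library size and allele count, optionally recomputed above
#' increasing minimum library sizes.
#'
#' @param genotypes An `stc_genotypes` object.
#' @param min_sizes Optional numeric vector of minimum library sizes at
#'   which to recompute the size/allele-count correlation.
#' @return A list with `catalog`, `per_sample` (library size and allele
#'   count), `drop_efficiency_cor` (estimate, p, n; `NA` when fewer than 3
#'   informative alleles), `size_allele_cor` and `size_allele_by_min`.
#' @export
stc_diagnostics <- function(genotypes, min_sizes = NULL) {
  stopifnot(inherits(genotypes, "stc_genotypes"))
  cat <- genotypes$catalog
  per_sample <- data.frame(
    sample_id = names(genotypes$genotypes),
    library_size = unname(genotypes$library_sizes[names(genotypes$genotypes)]),
    n_alleles = vapply(genotypes$genotypes, nrow, integer(1L)),
    stringsAsFactors = FALSE)

  cor_or_na <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(list(estimate = NA_real_, p.value = NA_real_, n = length(x)))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    list(estimate = unname(ct$estimate), p.value = ct$p.value, n = length(x))
  }

  dropped <- cat[cat$n_samples_dropped >= 1L, , drop = FALSE]
  drop_cor <- cor_or_na(dropped$drop_rate, dropped$mean_rel_size)
  size_cor <- cor_or_na(per_sample$library_size, per_sample$n_alleles)
  by_min <- NULL
  if (!is.null(min_sizes)) {
    by_min <- do.call(rbind, lapply(min_sizes, function(m) {
      sub <- per_sample[per_sample$library_size >= m, , drop = FALSE]
      cc <- cor_or_na(sub$library_size, sub$n_alleles)
      data.frame(min_size = m, estimate = cc$estimate, p.value = cc$p.value,
                 n = cc$n)
    }))
  }
  list(catalog = cat, per_sample = per_sample,
       drop_efficiency_cor = drop_cor, size_allele_cor = size_cor,
       size_allele_by_min = by_min)
}

#' Assemble the genotype matrix and allele FASTA
#'
#' @param genotypes An `stc_genotypes` object.
#' @param fasta Optional path; when given, alleles are written as FASTA
#'   with stable ids ordered by total occurrence then sequence.
#' @return A list with `matrix` (samples x alleles presence/absence,
#'   columns named `allele_001`, ...) and `alleles` (data frame `id`,
#'   `sequence`, `n_samples`).
#' @export
assemble_outputs <- function(genotypes, fasta = NULL) {
  stopifnot(inherits(genotypes, "stc_genotypes"))
  cat <- genotypes$catalog
  ids <- names(genotypes$genotypes)
  if (!nrow(cat)) {
    m <- matrix(0L, nrow = length(ids), ncol = 0L,
                dimnames = list(ids, NULL))
    alleles <- data.frame(id = character(), sequence = character(),
                          n_samples = integer())
    if (!is.null(fasta)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(), fasta)
    }
    return(list(matrix = m, alleles = alleles))
  }
  alleles <- data.frame(
    id = sprintf("allele_%03d", seq_len(nrow(cat))),
    sequence = cat$sequence, n_samples = cat$n_samples_total,
    stringsAsFactors = FALSE)
  m <- matrix(0L, length(ids), nrow(alleles),
              dimnames = list(ids, alleles$id))
  for (s in ids) {
    m[s, match(genotypes$genotypes[[s]]$sequence, alleles$sequence)] <- 1L
  }
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(alleles$sequence)
    names(x) <- alleles$id
    Biostrings::writeXStringSet(x, fasta)
  }
  list(matrix = m, alleles = alleles)
}
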