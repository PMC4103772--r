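# Synthetic multi-locus amplicon libraries with ground truth.
#
# The generator emulates one pyrosequencing run over barcoded samples:
# each sample carries 2 to 2 x n_loci alleles drawn from a shared pool,
# reads are drawn in proportion to per-allele amplification efficiencies,
# and each read is independently subject to a homopolymer indel (a run of
# identical bases expanded or contracted by one, pyrosequencing's dominant
# error mode), a random substitution, and - at a low rate - single-crossover
# chimera formation between two co-amplified templates. Defaults calibrate
# the per-read error mix so that 82% of reads are error-free.

#' Simulation configuration
#'
#' @param n_samples Number of samples (default 20).
#' @param n_loci Number of co-amplified loci; each sample carries between
#'   2 and `2 * n_loci` distinct alleles (default 6).
#' @param allele_pool_size Number of distinct alleles in the population
#'   pool (default 24).
#' @param allele_length Amplicon length in bp (default 213).
#' @param min_allele_divergence Minimum percent divergence between pool
#'   alleles (pairwise similarity at most `100 - min_allele_divergence`),
#'   except designated similar pairs (default 10).
#' @param n_similar_pairs Number of designated near-identical allele pairs
#'   (2 bp apart) added to the pool to exercise the similar-allele problem
#'   (default 0).
#' @param alleles_per_sample Either `NULL` (uniform between 2 and
#'   `2 * n_loci`) or a fixed integer.
#' @param efficiency_alpha Dirichlet concentration for per-allele relative
#'   amplification efficiencies; larger means more even. `Inf` gives equal
#'   efficiencies (default `Inf`).
#' @param low_efficiency_alleles Number of pool alleles designated
#'   low-efficiency (their weight multiplied by `low_efficiency_factor`),
#'   emulating a divergent weakly-amplifying locus (default 0).
#' @param low_efficiency_factor Multiplier for designated low-efficiency
#'   alleles (default 0.2).
#' @param library_size Integer range (min, max) of reads per sample, drawn
#'   uniformly (default `c(80, 1000)`); a single value fixes the size.
#' @param p_indel Per-read probability of one homopolymer indel (default
#'   0.12).
#' @param p_sub Per-read probability of one substitution; the default is
#'   set so that `(1 - p_indel) * (1 - p_sub) = 0.82`, the expected
#'   error-free read fraction for pyrosequencing.
#' @param chimera_rate Fraction of reads that are single-crossover
#'   chimeras of two co-amplified templates (default 0).
#' @param seed Optional integer seed.
#' @return A list of class `stc_sim_config`.
#' @export
sim_config <- function(n_samples = 20L, n_loci = 6L, allele_pool_size = 24L,
                       allele_length = 213L, min_allele_divergence = 10,
                       n_similar_pairs = 0L, alleles_per_sample = NULL,
                       efficiency_alpha = Inf,
                       low_efficiency_alleles = 0L,
                       low_efficiency_factor = 0.2,
                       library_size = c(80L, 1000L),
                       p_indel = 0.12, p_sub = 1 - 0.82 / (1 - 0.12),
                       chimera_rate = 0, seed = NULL) {
  stopifnot(n_samples >= 1L, n_loci >= 1L, n_loci <= 6L,
            allele_pool_size >= 2L, allele_length >= 20L,
            min_allele_divergence >= 0, min_allele_divergence < 100,
            p_indel >= 0, p_indel <= 1, p_sub >= 0, p_sub <= 1,
            chimera_rate >= 0, chimera_rate < 1,
            low_efficiency_factor > 0)
  if (length(library_size) == 1L) library_size <- rep(library_size, 2L)
  stopifnot(length(library_size) == 2L, library_size[1L] >= 1L,
            library_size[1L] <= library_size[2L])
  if (!is.null(alleles_per_sample)) {
    stopifnot(alleles_per_sample >= 2L, alleles_per_sample <= 2L * n_loci,
              alleles_per_sample <= allele_pool_size)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_loci = as.integer(n_loci),
                 allele_pool_size = as.integer(allele_pool_size),
                 allele_length = as.integer(allele_length),
                 min_allele_divergence = min_allele_divergence,
                 n_similar_pairs = as.integer(n_similar_pairs),
                 alleles_per_sample = alleles_per_sample,
                 efficiency_alpha = efficiency_alpha,
                 low_efficiency_alleles = as.integer(low_efficiency_alleles),
                 low_efficiency_factor = low_efficiency_factor,
                 library_size = as.integer(library_size),
                 p_indel = p_indel, p_sub = p_sub,
                 chimera_rate = chimera_rate, seed = seed),
            class = "stc_sim_config")
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate an allele pool
#'
#' Random alleles satisfying the pairwise divergence constraint, plus
#' optional designated near-identical pairs (2 bp apart) that are exempt
#' from it. Uses the current R random number state (set `cfg$seed` or call
#' `set.seed()` first for reproducibility).
#'
#' @param cfg A [sim_config()].
#' @return Character vector of allele sequences; designated similar pairs
#'   occupy the final positions.
#' @export
make_allele_pool <- function(cfg) {
  stopifnot(inherits(cfg, "stc_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_base <- cfg$allele_pool_size - cfg$n_similar_pairs
  if (n_base < 1L || cfg$n_similar_pairs < 0L) {
    stop("allele_pool_size too small for the requested similar pairs")
  }
  max_sim <- 100 - cfg$min_allele_divergence
  pool <- character(0)
  tries <- 0L
  while (length(pool) < n_base) {
    cand <- .random_seq(cfg$allele_length)
    ok <- !length(pool) ||
      all(vapply(pool, function(p) seq_similarity(cand, p),
                 numeric(1L)) <= max_sim)
    if (ok) pool <- c(pool, cand)
    tries <- tries + 1L
    if (tries > 200L * cfg$allele_pool_size) {
      stop("could not satisfy the divergence constraint; ",
           "reduce allele_pool_size or min_allele_divergence")
    }
  }
  if (cfg$n_similar_pairs > 0L) {
    for (k in seq_len(cfg$n_similar_pairs)) {
      base <- pool[k]
      pos <- sample(cfg$allele_length, 2L)
      ch <- strsplit(base, "", fixed = TRUE)[[1L]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      pool <- c(pool, paste(ch, collapse = ""))
    }
  }
  pool
}

.homopolymer_indel <- function(chars) {
  r <- rle(chars)
  runs <- which(r$lengths >= 2L)
  if (!length(runs)) return(list(chars = chars, applied = FALSE))
  pick <- if (length(runs) == 1L) runs else sample(runs, 1L)
  pos <- sum(r$lengths[seq_len(pick - 1L)]) + 1L
  if (stats::runif(1) < 0.5) {
    chars <- append(chars, chars[pos], after = pos)  # expand run by one
  } else {
    chars <- chars[-pos]                              # contract run by one
  }
  list(chars = chars, applied = TRUE)
}

.mutate_read <- function(seq, p_indel, p_sub) {
  events <- character(0)
  chars <- NULL
  if (p_indel > 0 && stats::runif(1) < p_indel) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    res <- .homopolymer_indel(chars)
    chars <- res$chars
    if (res$applied) events <- c(events, "homopolymer_indel")
  }
  if (p_sub > 0 && stats::runif(1) < p_sub) {
    if (is.null(chars)) chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    pos <- sample(length(chars), 1L)
    chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
    events <- c(events, "substitution")
  }
  list(seq = if (is.null(chars)) seq else paste(chars, collapse = ""),
       events = events)
}

#' Simulate one sample library
#'
#' Draws reads from the sample's true alleles in proportion to their
#' relative amplification efficiencies, then applies the per-read error
#' model and chimera formation. Uses the current R random number state.
#'
#' @param pool Allele pool from [make_allele_pool()].
#' @param allele_idx Indices into `pool` of this sample's true alleles.
#' @param efficiencies Positive relative efficiency weights, parallel to
#'   `pool`.
#' @param size Library size (number of reads).
#' @param cfg A [sim_config()] (error model fields are used).
#' @param sample_id Sample identifier.
#' @return A list with `library` (an [sample_library()]) and `truth`, a
#'   data frame with one provenance row per read (`read`, `source`
#'   (`"allele"` or `"chimera"`), `allele`, `parent_a`, `parent_b`,
#'   `events`).
#' @export
simulate_sample <- function(pool, allele_idx, efficiencies, size, cfg,
                            sample_id = "sim") {
  stopifnot(length(allele_idx) >= 2L, size >= 1L)
  alleles <- pool[allele_idx]
  w <- efficiencies[allele_idx]
  n_chim <- if (cfg$chimera_rate > 0) stats::rbinom(1L, size, cfg$chimera_rate)
            else 0L
  n_norm <- size - n_chim
  src <- sample(seq_along(alleles), n_norm, replace = TRUE, prob = w)
  reads <- character(size)
  truth <- data.frame(read = character(size), source = character(size),
                      allele = NA_character_, parent_a = NA_character_,
                      parent_b = NA_character_, events = character(size),
                      stringsAsFactors = FALSE)
  for (r in seq_len(n_norm)) {
    mut <- .mutate_read(alleles[src[r]], cfg$p_indel, cfg$p_sub)
    reads[r] <- mut$seq
    truth$source[r] <- "allele"
    truth$allele[r] <- alleles[src[r]]
    truth$events[r] <- paste(mut$events, collapse = "+")
  }
  if (n_chim > 0L) {
    for (r in seq_len(n_chim)) {
      par <- sample(seq_along(alleles), 2L, prob = w)
      L <- min(nchar(alleles[par]))
      bp <- sample(L - 1L, 1L)
      chim <- paste0(substr(alleles[par[1L]], 1L, bp),
                     substring(alleles[par[2L]], bp + 1L))
      mut <- .mutate_read(chim, cfg$p_indel, cfg$p_sub)
      i <- n_norm + r
      reads[i] <- mut$seq
      truth$source[i] <- "chimera"
      truth$parent_a[i] <- alleles[par[1L]]
      truth$parent_b[i] <- alleles[par[2L]]
      truth$events[i] <- paste(mut$events, collapse = "+")
    }
  }
  truth$read <- reads
  list(library = sample_library(reads, sample_id = sample_id), truth = truth)
}

#' Simulate a full multi-sample run
#'
#' Builds the allele pool, draws per-allele relative efficiencies (shared
#' across samples, as amplification bias is a property of the allele and
#' primers), assigns each sample a random allele set and library size, and
#' simulates every sample library.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `stc_sim`: list with `pool`,
#'   `efficiencies`, `libraries` (named list of [sample_library()]),
#'   `truth` (per-sample read provenance) and `genotypes` (named list of
#'   true allele sequence sets).
#' @export
simulate_run <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "stc_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pool <- local({
    cfg2 <- cfg; cfg2$seed <- NULL  # already seeded
    make_allele_pool(cfg2)
  })
  np <- length(pool)
  eff <- if (is.finite(cfg$efficiency_alpha)) {
    stats::rgamma(np, shape = cfg$efficiency_alpha)
  } else rep(1, np)
  eff <- eff / sum(eff)
  low <- integer(0)
  if (cfg$low_efficiency_alleles > 0L) {
    low <- seq_len(min(cfg$low_efficiency_alleles, np))
    eff[low] <- eff[low] * cfg$low_efficiency_factor
  }
  ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  libraries <- vector("list", cfg$n_samples)
  truths <- vector("list", cfg$n_samples)
  genotypes <- vector("list", cfg$n_samples)
  for (k in seq_len(cfg$n_samples)) {
    n_all <- if (!is.null(cfg$alleles_per_sample)) cfg$alleles_per_sample
             else sample(2L:min(2L * cfg$n_loci, np), 1L)
    idx <- sort(sample(np, n_all))
    size <- if (cfg$library_size[1L] == cfg$library_size[2L])
      cfg$library_size[1L]
    else sample(cfg$library_size[1L]:cfg$library_size[2L], 1L)
    sim <- simulate_sample(pool, idx, eff, size, cfg, sample_id = ids[k])
    libraries[[k]] <- sim$library
    truths[[k]] <- sim$truth
    genotypes[[k]] <- pool[idx]
  }
  names(libraries) <- names(truths) <- names(genotypes) <- ids
  structure(list(pool = pool, efficiencies = eff,
                 low_efficiency_idx = low, libraries = libraries,
                 truth = truths, genotypes = genotypes, config = cfg),
            class = "stc_sim")
}

#' @export
print.stc_sim <- function(x, ...) {
  sizes <- vapply(x$libraries, function(l) l$library_size, integer(1L))
  cat("Simulated amplicon run: ", length(x$libraries), " samples, pool of ",
      length(x$pool), " alleles\n", sep = "")
  cat("  library sizes ", min(sizes), "-", max(sizes), " reads\n", sep = "")
  invisible(x)
}

#' Score genotype recovery against simulation truth
#'
#' Compares called genotypes with the simulated truth. An allele of a
#' sample counts as recovered when it appears among the sample's called
#' alleles; a true allele with zero reads in the sample library is
#' *missing* (unrecoverable), one with reads but no call is *dropped and
#' lost*. False positives are called alleles absent from the truth.
#'
#' @param sim An `stc_sim` object (or a list with `genotypes` and
#'   `truth`).
#' @param genotypes An `stc_genotypes` object with matching sample ids.
#' @return A list with `per_sample` (data frame: `sample_id`, `n_true`,
#'   `n_recovered`, `n_missing`, `n_dropped_lost`, `n_false_positive`,
#'   `sensitivity`) and overall `sensitivity` and
#'   `false_positives_per_sample`.
#' @export
recovery_report <- function(sim, genotypes) {
  stopifnot(inherits(genotypes, "stc_genotypes"))
  ids <- names(genotypes$genotypes)
  stopifnot(all(ids %in% names(sim$genotypes)))
  rows <- lapply(ids, function(s) {
    true <- sim$genotypes[[s]]
    called <- genotypes$genotypes[[s]]$sequence
    reads_present <- unique(sim$truth[[s]]$allele)
    recovered <- intersect(true, called)
    not_called <- setdiff(true, called)
    missing <- not_called[!(not_called %in% reads_present)]
    dropped_lost <- setdiff(not_called, missing)
    data.frame(sample_id = s, n_true = length(true),
               n_recovered = length(recovered),
               n_missing = length(missing),
               n_dropped_lost = length(dropped_lost),
               n_false_positive = length(setdiff(called, true)),
               sensitivity = length(recovered) / length(true),
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  list(per_sample = per_sample,
       sensitivity = sum(per_sample$n_recovered) / sum(per_sample$n_true),
       false_positives_per_sample = mean(per_sample$n_false_positive))
}
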