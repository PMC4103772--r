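# Orchestration: phases 2-4 over a set of sample libraries, and the full
# run starting from raw reads.

# stable 32-bit hash of a sample id, used to derive per-sample seeds so
# that adding or removing a sample never perturbs the others
.stable_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

.sample_seed <- function(seed, sample_id) {
  as.integer((as.numeric(seed) + .stable_hash(sample_id)) %% 2147483647)
}

#' Genotype a set of sample libraries
#'
#' Runs sequence combination (phase 2), stepwise threshold clustering
#' (phase 3) and post-clustering processing (phase 4) over per-sample
#' libraries. Samples under `min_library_size` reads are reported as not
#' genotyped; libraries over `subsample_cap` reads are subsampled without
#' replacement. One global seed derives per-sample seeds by a stable hash
#' of the sample id, so results per sample are independent of which other
#' samples are present.
#'
#' @param libs Named list of [sample_library()] objects.
#' @param params An [stc_params()] object.
#' @param min_library_size Minimum reads for a sample to be genotyped
#'   (default 80).
#' @param subsample_cap Maximum reads used per sample (default 1000).
#' @param screen_length Apply the conservative [length_screen()] to final
#'   alleles (default `FALSE`).
#' @param combine_conflict Conflict rule for [combine_library()].
#' @param chimera_max_mismatch Passed to [classify_chimeras()].
#' @param verbose Print per-sample progress.
#' @return An object of class `stc_result`: list with `genotypes`
#'   (an `stc_genotypes`), `clustersets`, `combine_records`,
#'   `chimera_report`, `length_removed`, `not_genotyped`, `diagnostics`
#'   and `matrix`.
#' @export
genotype_samples <- function(libs, params = stc_params(),
                             min_library_size = 80L, subsample_cap = 1000L,
                             screen_length = FALSE,
                             combine_conflict = "most_common",
                             chimera_max_mismatch = 0L, verbose = FALSE) {
  stopifnot(length(libs) >= 1L)
  if (is.null(names(libs))) {
    names(libs) <- vapply(libs, function(l) l$sample_id, character(1L))
  }
  sizes <- vapply(libs, function(l) l$library_size, integer(1L))
  not_genotyped <- names(libs)[sizes < min_library_size]
  keep <- filter_min_library(libs, min_library_size)

  clustersets <- list()
  combine_records <- list()
  for (s in names(keep)) {
    lib <- keep[[s]]
    seed_s <- if (!is.null(params$seed)) .sample_seed(params$seed, s)
              else NULL
    lib <- subsample_library(lib, subsample_cap, seed = seed_s)
    comb <- combine_library(lib, params$expected_len,
                            conflict = combine_conflict)
    combine_records[[s]] <- comb$records
    p <- params
    p$seed <- seed_s
    cs <- run_stc(comb$library, p)
    clustersets[[s]] <- cs
    if (verbose) {
      message(sprintf("%s: %d reads, %d good / %d small clusters", s,
                      cs$library_size, length(cs$good), length(cs$small)))
    }
  }
  genotypes <- promote_dropped(clustersets, params$epsilon,
                               params$min_dropped_reads)
  chim <- classify_chimeras(genotypes, max_mismatch = chimera_max_mismatch)
  genotypes <- chim$genotypes
  removed <- character(0)
  if (screen_length) {
    scr <- length_screen(genotypes, params$expected_len)
    genotypes <- scr$genotypes
    removed <- scr$removed
  }
  out <- assemble_outputs(genotypes)
  structure(list(genotypes = genotypes, clustersets = clustersets,
                 combine_records = combine_records,
                 chimera_report = chim$report, length_removed = removed,
                 not_genotyped = not_genotyped,
                 diagnostics = stc_diagnostics(genotypes),
                 matrix = out$matrix, alleles = out$alleles,
                 params = params), class = "stc_result")
}

#' @export
print.stc_result <- function(x, ...) {
  cat("STC genotyping result\n")
  cat("  genotyped samples: ", length(x$genotypes$genotypes),
      if (length(x$not_genotyped)) paste0("  (not genotyped: ",
                                          length(x$not_genotyped), ")"),
      "\n", sep = "")
  cat("  distinct alleles:  ", nrow(x$alleles), "\n", sep = "")
  nchim <- sum(x$chimera_report$is_chimera)
  if (nchim) cat("  chimeras removed:  ", nchim, "\n", sep = "")
  invisible(x)
}

#' Genotype a run from raw reads
#'
#' Full pipeline: parse reads, demultiplex by dual barcodes, trim and
#' length-filter (phase 1), then [genotype_samples()] (phases 2-4).
#'
#' @param reads_file FASTA/FASTQ path of the run library.
#' @param barcode_file Barcode map TSV (see [read_barcode_map()]).
#' @param fwd_primer,rev_primer Primer sequences.
#' @param params An [stc_params()].
#' @param min_length Minimum intra-primer length (default 200).
#' @param max_barcode_mismatch Barcode mismatch tolerance (default 0).
#' @param ... Passed to [genotype_samples()].
#' @return An `stc_result` with the `stc_prep_report` attached as
#'   `$prep_report`.
#' @export
genotype_run <- function(reads_file, barcode_file, fwd_primer, rev_primer,
                         params = stc_params(), min_length = 200L,
                         max_barcode_mismatch = 0L, ...) {
  reads <- read_amplicon_reads(reads_file)
  barcodes <- read_barcode_map(barcode_file)
  dm <- demultiplex(reads, barcodes, fwd_primer, rev_primer,
                    max_barcode_mismatch = max_barcode_mismatch,
                    min_length = min_length)
  res <- genotype_samples(dm$libraries, params = params, ...)
  res$prep_report <- dm$report
  res
}

#' Load a packaged or user-supplied example library
#'
#' `"toy"` loads a small fully synthetic example library shipped with the
#' package. `"sample_x"` loads the published worked-example library (330
#' reads, 101 unique sequences); that table is distributed with the
#' original study's Dryad archive (doi:10.5061/dryad.4fn4g) and is not
#' redistributed here - download it and pass its path (a TSV with columns
#' `sequence` and `count`).
#'
#' @param name `"toy"` or `"sample_x"`.
#' @param path Path to the user-downloaded table (required for
#'   `"sample_x"`).
#' @return A [sample_library()].
#' @export
load_fixture <- function(name = c("toy", "sample_x"), path = NULL) {
  name <- match.arg(name)
  if (name == "toy") {
    path <- system.file("extdata", "synthetic_toy_library.tsv",
                        package = "stclust")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(sample_library(tab$sequence, tab$count, sample_id = "toy"))
  }
  if (is.null(path) || !file.exists(path)) {
    stop("the sample-X library is not redistributed with this package; ",
         "download the per-sequence count table from the original ",
         "study's Dryad archive (doi:10.5061/dryad.4fn4g) and pass its ",
         "path (TSV with columns 'sequence' and 'count')")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "count") %in% names(tab))) {
    stop("expected columns 'sequence' and 'count' in ", path)
  }
  sample_library(tab$sequence, tab$count, sample_id = "sample_x")
}

#' Write result tables
#'
#' Writes the genotype matrix, allele FASTA, allele catalog, chimera
#' report, combination records and per-sample round logs under `dir`.
#'
#' @param result An `stc_result`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_stc_result <- function(result, dir) {
  stopifnot(inherits(result, "stc_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "genotype_matrix.tsv"),
    alleles = file.path(dir, "alleles.fasta"),
    catalog = file.path(dir, "allele_catalog.tsv"),
    chimeras = file.path(dir, "chimera_report.tsv"),
    combines = file.path(dir, "combine_records.tsv"),
    logs = file.path(dir, "round_logs.tsv"))
  utils::write.table(data.frame(sample_id = rownames(result$matrix),
                                result$matrix, check.names = FALSE),
                     paths["matrix"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  assemble_outputs(result$genotypes, fasta = paths["alleles"])
  utils::write.table(result$genotypes$catalog, paths["catalog"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$chimera_report, paths["chimeras"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  combs <- do.call(rbind, lapply(names(result$combine_records), function(s) {
    r <- result$combine_records[[s]]
    if (!nrow(r)) return(NULL)
    cbind(sample_id = s, r)
  }))
  if (is.null(combs)) {
    combs <- data.frame(sample_id = character(), absorbed = character(),
                        target = character(), pair_type = character(),
                        reads_moved = integer())
  }
  utils::write.table(combs, paths["combines"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logs <- do.call(rbind, lapply(names(result$clustersets), function(s) {
    cbind(sample_id = s, result$clustersets[[s]]$logs)
  }))
  utils::write.table(logs, paths["logs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
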