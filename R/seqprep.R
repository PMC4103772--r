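# Phase 1: read parsing, dual-barcode demultiplexing, trimming and
# length filtering into per-sample libraries.

.valid_dna <- function(x) grepl("^[ACGTN]+$", x)

#' Construct a sample library
#'
#' A sample library is the multiset of amplicon sequences observed for one
#' sample, stored as unique sequences with read counts. Sequences are
#' expected to be barcode- and primer-free.
#'
#' @param sequences Character vector of sequences; either one element per
#'   read (possibly duplicated) when `counts` is `NULL`, or unique sequences
#'   matched to `counts`.
#' @param counts Optional positive integer read counts, one per sequence.
#' @param sample_id Sample identifier.
#' @return An object of class `stc_library` with elements `sample_id`,
#'   `counts` (named integer vector, names are the unique sequences) and
#'   `library_size`.
#' @examples
#' lib <- sample_library(c("ACGT", "ACGT", "AGGT"), sample_id = "S1")
#' lib$library_size
#' @export
sample_library <- function(sequences, counts = NULL, sample_id = NA_character_) {
  stopifnot(is.character(sequences))
  if (!length(sequences)) {
    return(structure(list(sample_id = sample_id,
                          counts = stats::setNames(integer(0), character(0)),
                          library_size = 0L), class = "stc_library"))
  }
  sequences <- toupper(sequences)
  bad <- which(!.valid_dna(sequences))
  if (length(bad)) {
    stop("invalid nucleotide sequence (alphabet is ACGTN) at position ",
         bad[1L])
  }
  if (is.null(counts)) {
    tab <- table(sequences)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  } else {
    if (length(counts) != length(sequences)) {
      stop("`counts` must match `sequences` in length")
    }
    counts <- as.integer(counts)
    if (anyNA(counts) || any(counts <= 0L)) {
      stop("read counts must be positive integers")
    }
    if (anyDuplicated(sequences)) {
      counts <- vapply(split(counts, sequences), sum, integer(1L))
    } else {
      names(counts) <- sequences
    }
  }
  counts <- counts[order(names(counts))]
  structure(list(sample_id = sample_id, counts = counts,
                 library_size = sum(counts)),
            class = "stc_library")
}

#' @export
print.stc_library <- function(x, ...) {
  cat("Amplicon sample library", if (!is.na(x$sample_id)) sQuote(x$sample_id),
      "\n  ", x$library_size, " reads, ", length(x$counts),
      " unique sequences\n", sep = "")
  invisible(x)
}

#' Parse amplicon reads from FASTA or FASTQ
#'
#' Reads one run library. FASTQ base qualities are discarded: the method
#' uses no base-quality information. Gzipped files are accepted.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by file extension), `"fasta"` or `"fastq"`.
#' @return A named character vector of reads (names are record ids), in
#'   file order.
#' @export
read_amplicon_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2|xz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  # parse as BString first so alphabet violations can name the record
  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", toupper(format), " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (length(recs) == 0L) {
    warning("no records in ", path)
    return(character())
  }
  reads <- toupper(as.character(recs))
  ids <- sub("\\s.*$", "", names(recs))
  bad <- which(!.valid_dna(reads))
  if (length(bad)) {
    stop("record ", bad[1L], " ('", ids[bad[1L]],
         "') contains characters outside ACGTN")
  }
  stats::setNames(reads, ids)
}

#' Read a barcode map
#'
#' Tab-separated file with header columns `sample_id`, `fwd_barcode`,
#' `rev_barcode`. Each sample is tagged by a unique combination of forward
#' and reverse barcode; all barcodes must share one length.
#'
#' @param path Path to the TSV file.
#' @return A data frame with the three columns, validated.
#' @export
read_barcode_map <- function(path) {
  bc <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_barcode_map(bc)
}

#' @rdname read_barcode_map
#' @param barcodes A data frame to validate in place of a file.
#' @export
validate_barcode_map <- function(barcodes) {
  need <- c("sample_id", "fwd_barcode", "rev_barcode")
  if (!all(need %in% names(barcodes))) {
    stop("barcode map needs columns: ", paste(need, collapse = ", "))
  }
  barcodes <- barcodes[, need]
  barcodes$fwd_barcode <- toupper(barcodes$fwd_barcode)
  barcodes$rev_barcode <- toupper(barcodes$rev_barcode)
  if (any(!.valid_dna(barcodes$fwd_barcode)) ||
      any(!.valid_dna(barcodes$rev_barcode))) {
    stop("barcodes must be ACGTN strings")
  }
  lens <- unique(c(nchar(barcodes$fwd_barcode), nchar(barcodes$rev_barcode)))
  if (length(lens) != 1L) stop("all barcodes must have the same length")
  if (anyDuplicated(paste(barcodes$fwd_barcode, barcodes$rev_barcode))) {
    stop("forward/reverse barcode combinations must be unique")
  }
  if (anyDuplicated(barcodes$sample_id)) {
    stop("sample ids must be unique")
  }
  barcodes
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# hamming distances between equal-length strings and a set of barcodes;
# returns a length(x) x nrow matrix
.hamming_to_set <- function(x, barcodes) {
  n <- length(x)
  k <- length(barcodes)
  if (n == 0L) return(matrix(integer(), 0L, k))
  xm <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  d <- matrix(0L, n, k)
  for (b in seq_len(k)) {
    bm <- strsplit(barcodes[b], "", fixed = TRUE)[[1L]]
    d[, b] <- as.integer(rowSums(xm != matrix(bm, n, length(bm), byrow = TRUE)))
  }
  d
}

#' Demultiplex dual-barcoded amplicon reads
#'
#' Reads carry, in forward orientation, the forward barcode and forward
#' primer at the 5' end and the reverse complements of the reverse primer
#' and reverse barcode at the 3' end. A read is assigned to the sample
#' whose barcode pair matches both ends within `max_barcode_mismatch`;
#' reads matching no sample, or two samples equally well, are discarded as
#' unassignable (never mis-assigned). Surviving reads are stripped of
#' barcodes and primers and the intra-primer sequence is length-filtered.
#'
#' @param reads Character vector of reads (e.g. from
#'   [read_amplicon_reads()]).
#' @param barcodes Barcode map data frame (see [read_barcode_map()]).
#' @param fwd_primer,rev_primer Primer sequences, written 5' to 3' on their
#'   own strands.
#' @param max_barcode_mismatch Maximum mismatches tolerated per barcode
#'   (default 0, exact matching).
#' @param min_length Minimum intra-primer sequence length to keep a read
#'   (default 200).
#' @return A list with `libraries` (named list of [sample_library()]
#'   objects, samples with zero reads omitted) and `report`, a
#'   `stc_prep_report` with counts `n_input_reads`, `n_failed_barcode`,
#'   `n_failed_length`, `n_assigned` and `per_sample_sizes`.
#' @export
demultiplex <- function(reads, barcodes, fwd_primer, rev_primer,
                        max_barcode_mismatch = 0L, min_length = 200L) {
  stopifnot(min_length >= 1L, max_barcode_mismatch >= 0L)
  barcodes <- validate_barcode_map(barcodes)
  fwd_primer <- toupper(fwd_primer)
  rev_primer <- toupper(rev_primer)
  bc_len <- nchar(barcodes$fwd_barcode[1L])
  fp_len <- nchar(fwd_primer)
  rp_len <- nchar(rev_primer)
  n <- length(reads)
  lens <- nchar(reads)

  assigned <- rep(NA_integer_, n)
  long_enough_for_bc <- lens >= 2L * bc_len
  idx <- which(long_enough_for_bc)
  if (length(idx)) {
    pre <- substr(reads[idx], 1L, bc_len)
    suf <- .revcomp(substring(reads[idx], lens[idx] - bc_len + 1L))
    fwd_set <- unique(barcodes$fwd_barcode)
    rev_set <- unique(barcodes$rev_barcode)
    df <- .hamming_to_set(pre, fwd_set)
    dr <- .hamming_to_set(suf, rev_set)
    fcol <- match(barcodes$fwd_barcode, fwd_set)
    rcol <- match(barcodes$rev_barcode, rev_set)
    # per read, total distance to each sample's barcode pair
    for (r in seq_along(idx)) {
      okf <- df[r, fcol] <= max_barcode_mismatch
      okr <- dr[r, rcol] <= max_barcode_mismatch
      cand <- which(okf & okr)
      if (!length(cand)) next
      tot <- df[r, fcol[cand]] + dr[r, rcol[cand]]
      best <- cand[tot == min(tot)]
      if (length(best) == 1L) assigned[idx[r]] <- best
    }
  }

  failed_bc <- is.na(assigned)
  inserts <- rep(NA_character_, n)
  ok <- !failed_bc
  if (any(ok)) {
    start <- bc_len + fp_len + 1L
    end <- lens[ok] - bc_len - rp_len
    ins <- substr(reads[ok], start, pmax(end, 0L))
    inserts[ok] <- ins
  }
  failed_len <- ok & (is.na(inserts) | nchar(inserts) < min_length)
  keep <- ok & !failed_len

  libs <- list()
  per_sample <- stats::setNames(integer(nrow(barcodes)), barcodes$sample_id)
  if (any(keep)) {
    by_sample <- split(inserts[keep], barcodes$sample_id[assigned[keep]])
    libs <- lapply(names(by_sample), function(s) {
      sample_library(by_sample[[s]], sample_id = s)
    })
    names(libs) <- names(by_sample)
    per_sample[names(by_sample)] <- vapply(libs, function(l) l$library_size,
                                           integer(1L))
  }
  report <- structure(list(
    n_input_reads = n,
    n_failed_barcode = sum(failed_bc),
    n_failed_length = sum(failed_len),
    n_assigned = sum(keep),
    per_sample_sizes = per_sample), class = "stc_prep_report")
  list(libraries = libs, report = report)
}

#' @export
print.stc_prep_report <- function(x, ...) {
  cat("Read preparation report\n")
  cat("  input reads:     ", x$n_input_reads, "\n", sep = "")
  cat("  failed barcode:  ", x$n_failed_barcode, "\n", sep = "")
  cat("  failed length:   ", x$n_failed_length, "\n", sep = "")
  cat("  assigned:        ", x$n_assigned, " across ",
      sum(x$per_sample_sizes > 0L), " samples\n", sep = "")
  invisible(x)
}

#' Subsample a library without replacement
#'
#' Draws at most `cap` reads from the library, multiset-style over read
#' instances (not unique sequences). Libraries at or under the cap are
#' returned unchanged.
#'
#' @param lib A [sample_library()].
#' @param cap Maximum number of reads to keep.
#' @param seed Optional integer seed for reproducibility.
#' @return A `stc_library` with `library_size == min(cap, library_size)`.
#' @export
subsample_library <- function(lib, cap, seed = NULL) {
  stopifnot(inherits(lib, "stc_library"), cap >= 1L)
  if (lib$library_size <= cap) return(lib)
  if (!is.null(seed)) set.seed(seed)
  pool <- rep(names(lib$counts), lib$counts)
  kept <- sample(pool, cap, replace = FALSE)
  sample_library(kept, sample_id = lib$sample_id)
}

#' Drop samples with too few reads
#'
#' @param libs Named list of [sample_library()] objects.
#' @param min_reads Minimum library size to retain a sample (default 80).
#' @return The retained subset of `libs`; removals are reported via
#'   `message()`.
#' @export
filter_min_library <- function(libs, min_reads = 80L) {
  stopifnot(min_reads >= 1L)
  sizes <- vapply(libs, function(l) l$library_size, integer(1L))
  drop <- sizes < min_reads
  if (any(drop)) {
    message("not genotyped (fewer than ", min_reads, " reads): ",
            paste(names(libs)[drop], collapse = ", "))
  }
  libs[!drop]
}

#' Write per-sample FASTA of trimmed reads
#'
#' Unique sequences are written once each with a `;size=NN` annotation in
#' the header carrying the read count.
#'
#' @param libs Named list of [sample_library()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_sample_fasta <- function(libs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in names(libs)) {
    lib <- libs[[s]]
    x <- Biostrings::DNAStringSet(names(lib$counts))
    names(x) <- sprintf("%s_seq%04d;size=%d", s, seq_along(lib$counts),
                        unname(lib$counts))
    p <- file.path(dir, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
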