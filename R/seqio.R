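#' Construct a table of sequencing read records
#'
#' A read-record table is the package's in-memory representation of a set of
#' reads: one row per read, with the SAM flag retained so that unmapped-read
#' extraction can be replayed without the original aligner output.
#'
#' @param read_id character vector of read names.
#' @param sequence character vector of DNA sequences over `A,C,G,T,N`
#'   (case-insensitive; stored upper-case).
#' @param quality optional character vector of Phred+33-encoded base
#'   qualities (same string length as `sequence`), or `NA` when absent
#'   (e.g. FASTA input).
#' @param flag optional integer vector of SAM bitwise flags (`NA` when the
#'   reads did not come from an alignment). Must be non-negative integers.
#' @param mate_role one of `"first"`, `"second"`, `"unpaired"` per read.
#'   Defaults to a value derived from the flag bits 0x40/0x80 when flags are
#'   present, else `"unpaired"`.
#' @return a `data.frame` of class `tmi_reads` with columns `read_id`,
#'   `sequence`, `quality`, `flag`, `mate_role`.
#' @examples
#' read_records("r1", "ACGT", "IIII", flag = 4L)
#' @export
read_records <- function(read_id, sequence, quality = NA_character_,
                         flag = NA_integer_, mate_role = NULL) {
  n <- length(read_id)
  sequence <- toupper(as.character(sequence))
  quality <- rep_len(as.character(quality), n)
  if (!is.numeric(flag) && !all(is.na(flag))) {
    stop("malformed record: SAM flag must be numeric")
  }
  flag <- rep_len(suppressWarnings(as.integer(flag)), n)
  if (any(!is.na(flag) & flag < 0L)) {
    stop("malformed record: negative SAM flag")
  }
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("invalid sequence character in read(s): ",
         paste(utils::head(read_id[bad], 3L), collapse = ", "))
  }
  qlen_ok <- is.na(quality) | nchar(quality) == nchar(sequence)
  if (!all(qlen_ok)) {
    stop("quality string length differs from sequence length for read(s): ",
         paste(utils::head(read_id[!qlen_ok], 3L), collapse = ", "))
  }
  if (is.null(mate_role)) {
    mate_role <- ifelse(is.na(flag) | bitwAnd(flag, 1L) == 0L, "unpaired",
                        ifelse(bitwAnd(flag, 64L) != 0L, "first", "second"))
  } else {
    mate_role <- rep_len(match.arg(mate_role, c("first", "second", "unpaired"),
                                   several.ok = TRUE), n)
  }
  out <- data.frame(read_id = as.character(read_id), sequence = sequence,
                    quality = quality, flag = flag, mate_role = mate_role,
                    stringsAsFactors = FALSE)
  class(out) <- c("tmi_reads", "data.frame")
  out
}

empty_reads <- function() {
  read_records(character(0), character(0), character(0), integer(0))
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality character vector of Phred+33 strings.
#' @return list of integer vectors (one per read); `NULL` entries for `NA`.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) {
    if (is.na(q)) return(NULL)
    as.integer(utf8ToInt(q)) - 33L
  })
}

#' Parse alignments from a SAM text file or BAM file
#'
#' Only the fields needed downstream are retained: read name, flag, sequence
#' and base qualities. Coordinates are deliberately ignored (the extraction
#' logic is purely flag-driven). BAM input requires the `Rsamtools` package.
#'
#' @param path path to a SAM (text) or BAM file; format is chosen by the
#'   `.bam` extension unless `format` is given.
#' @param format `"auto"`, `"sam"` or `"bam"`.
#' @return a `tmi_reads` table.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "sam"
  }
  if (format == "bam") {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM input requires the Rsamtools package")
    }
    p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "seq", "qual"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    return(read_records(b$qname, as.character(b$seq),
                        as.character(b$qual), as.integer(b$flag)))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(empty_reads())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 11L
  if (any(short)) stop("malformed SAM record: fewer than 11 fields")
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- vapply(fields, `[[`, "", 2L)
  if (any(!grepl("^[0-9]+$", flag))) {
    stop("malformed record: non-integer SAM flag")
  }
  seqs <- toupper(vapply(fields, `[[`, "", 10L))
  qual <- vapply(fields, `[[`, "", 11L)
  seqs[seqs == "*"] <- ""
  qual[qual == "*"] <- NA_character_
  read_records(qname, seqs, qual, as.integer(flag))
}

# samtools-style flag predicate: all bits of `f` set, no bit of `F` set
flag_match <- function(flag, f, F) {
  if (any(is.na(flag))) stop("malformed record: missing SAM flag")
  bitwAnd(flag, f) == f & bitwAnd(flag, F) == 0L
}

#' Extract single-end unmapped reads (read unmapped, mate mapped)
#'
#' Reproduces `samtools view -f 4 -F 264`: keeps records whose own segment is
#' unmapped (bit 4) while the mate is mapped (bit 8 unset) and which are not
#' secondary alignments (bit 256 unset). These are the one-end-anchored
#' "foreign" read candidates.
#'
#' @param reads a `tmi_reads` table with valid flags.
#' @return the kept subset, same class.
#' @export
extract_unmapped_single <- function(reads) {
  keep <- flag_match(reads$flag, 4L, 264L)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract read pairs with both ends unmapped
#'
#' Reproduces `samtools view -f 12 -F 256`: keeps primary records with both
#' bit 4 (read unmapped) and bit 8 (mate unmapped) set, then groups them into
#' mate pairs by read name. Templates for which only one end survives the
#' filter are demoted to a singleton stream with a warning rather than
#' erroring (mirrors truncated real-world BAMs).
#'
#' @param reads a `tmi_reads` table with valid flags.
#' @return list with elements `pairs` (a `tmi_reads` table ordered
#'   first/second within template) and `orphans` (a `tmi_reads` table).
#' @export
extract_unmapped_pairs <- function(reads) {
  keep <- flag_match(reads$flag, 12L, 256L)
  hit <- reads[keep, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(list(pairs = empty_reads(), orphans = empty_reads()))
  }
  counts <- table(hit$read_id)
  paired_ids <- names(counts)[counts == 2L]
  orphan <- !(hit$read_id %in% paired_ids)
  if (any(orphan)) {
    warning(sum(orphan), " orphaned mate(s) routed to singleton stream")
  }
  pairs <- hit[!orphan, , drop = FALSE]
  ord <- order(match(pairs$read_id, paired_ids),
               match(pairs$mate_role, c("first", "second")))
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  orphans <- hit[orphan, , drop = FALSE]
  rownames(orphans) <- NULL
  list(pairs = pairs, orphans = orphans)
}

#' Quality-control policy for foreign reads
#'
#' Defaults encode the filtering stage applied before microbial remapping:
#' drop a read when its length is below 36 bp, when it carries more than 5
#' ambiguous `N` bases, or when more than 40% of its bases fall below Q15.
#'
#' @param phred_threshold bases below this Phred score count as low quality.
#' @param max_low_quality_fraction maximum tolerated fraction of low-quality
#'   bases, in `[0, 1]`.
#' @param max_n_count maximum tolerated number of `N` bases.
#' @param min_length minimum read length in bp (>= 1).
#' @return a `qc_policy` list.
#' @export
qc_policy <- function(phred_threshold = 15L, max_low_quality_fraction = 0.40,
                      max_n_count = 5L, min_length = 36L) {
  stopifnot(max_low_quality_fraction >= 0, max_low_quality_fraction <= 1,
            min_length >= 1, max_n_count >= 0, phred_threshold >= 0)
  structure(list(phred_threshold = as.integer(phred_threshold),
                 max_low_quality_fraction = max_low_quality_fraction,
                 max_n_count = as.integer(max_n_count),
                 min_length = as.integer(min_length)),
            class = "qc_policy")
}

#' Filter reads by length, N content and base quality
#'
#' A read survives when `length >= min_length`, `count(N) <= max_n_count`,
#' and the fraction of bases with Phred score below `phred_threshold` is at
#' most `max_low_quality_fraction`. Reads without quality strings skip the
#' quality criterion. Drop reasons are counted in priority order
#' length > N-count > quality (each read is charged to one reason).
#'
#' @param reads a `tmi_reads` table.
#' @param policy a [qc_policy()].
#' @return list with `reads` (survivors) and `report` (named counts:
#'   `input`, `kept`, `drop_length`, `drop_n`, `drop_quality`).
#' @export
qc_filter <- function(reads, policy = qc_policy()) {
  n <- nrow(reads)
  report <- c(input = n, kept = 0L, drop_length = 0L, drop_n = 0L,
              drop_quality = 0L)
  if (n == 0L) return(list(reads = reads, report = report))
  len <- nchar(reads$sequence)
  n_count <- nchar(reads$sequence) - nchar(gsub("N", "", reads$sequence,
                                               fixed = TRUE))
  lowfrac <- vapply(seq_len(n), function(i) {
    q <- reads$quality[i]
    if (is.na(q)) return(0)
    s <- utf8ToInt(q) - 33L
    mean(s < policy$phred_threshold)
  }, 0)
  fail_len <- len < policy$min_length
  fail_n <- !fail_len & n_count > policy$max_n_count
  fail_q <- !fail_len & !fail_n & lowfrac > policy$max_low_quality_fraction
  keep <- !(fail_len | fail_n | fail_q)
  report["drop_length"] <- sum(fail_len)
  report["drop_n"] <- sum(fail_n)
  report["drop_quality"] <- sum(fail_q)
  report["kept"] <- sum(keep)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, report = report)
}

#' Reverse complement of a DNA sequence
#'
#' @param s character vector over `A,C,G,T,N`.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  bad <- grepl("[^ACGTN]", toupper(s))
  if (any(bad)) stop("invalid sequence: non-ACGTN character")
  vapply(toupper(s), function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' Pair singleton reads with synthetic reverse-complement mates
#'
#' Single-end unmapped survivors are given an artificial second mate whose
#' sequence is the reverse complement of the read, so that singleton and
#' genuine pairs can be remapped through one paired-end path. The synthetic
#' mate reuses the read's quality string reversed (base-wise qualities follow
#' their bases) and carries `mate_role = "second"`.
#'
#' @param reads a `tmi_reads` table of unpaired reads.
#' @return a `tmi_reads` table with two rows per input read (first, second).
#' @export
pair_singleton_with_revcomp <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  if (any(reads$mate_role != "unpaired")) {
    stop("pair_singleton_with_revcomp expects unpaired reads")
  }
  rc <- reverse_complement(reads$sequence)
  rq <- vapply(reads$quality, function(q) {
    if (is.na(q)) NA_character_
    else paste(rev(strsplit(q, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  first <- reads
  first$mate_role <- "first"
  second <- read_records(reads$read_id, rc, rq, reads$flag,
                         mate_role = rep("second", nrow(reads)))
  out <- rbind(first, second)
  ord <- order(match(out$read_id, reads$read_id),
               match(out$mate_role, c("first", "second")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tmi_reads", "data.frame")
  out
}

dedup_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  warning("duplicate read ids disambiguated with numeric suffixes")
  make.unique(ids, sep = ".")
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a `tmi_reads` table; reads lacking qualities are written
#'   with constant Q30 (`?`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- dedup_ids(reads$read_id)
  qual <- reads$quality
  miss <- is.na(qual)
  qual[miss] <- vapply(nchar(reads$sequence[miss]),
                       function(n) strrep("?", n), "")
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file path.
#' @return a `tmi_reads` table (flags `NA`, `mate_role` `"unpaired"`).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  if (length(x) == 0L) return(empty_reads())
  read_records(names(x), as.character(x),
               as.character(S4Vectors_mcols(x)$qualities))
}

# small shim so Biostrings metadata access works without importing S4Vectors
S4Vectors_mcols <- function(x) {
  getFromNamespace("mcols", "S4Vectors")(x)
}

#' Write reads to FASTA (qualities discarded)
#'
#' @param reads a `tmi_reads` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- dedup_ids(reads$read_id)
  Biostrings::writeXStringSet(dna, path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file into a read table
#'
#' @param path FASTA file path.
#' @return a `tmi_reads` table with `NA` qualities.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0L) return(empty_reads())
  read_records(names(x), as.character(x))
}
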