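#' Build an alignment-candidate set
#'
#' Candidates are the multimap of foreign reads onto microbial reference
#' genomes: one entry per (read, genome) pair with the best (smallest)
#' mismatch count observed for that pair. Secondary alignments are kept on
#' purpose — they carry the ambiguity signal the EM resolves.
#'
#' @param read_id,genome_id,mismatches parallel vectors describing candidate
#'   alignments; `mismatches` are non-negative integers.
#' @param genome_lengths named numeric vector, genome id -> length in bp.
#'   Every genome appearing in `genome_id` must be present.
#' @return an `alignment_candidates` object: list with `entries`
#'   (data.frame `read_id`, `genome_id`, `mismatches`) and `genome_lengths`.
#' @export
alignment_candidates <- function(read_id, genome_id, mismatches,
                                 genome_lengths) {
  stopifnot(length(read_id) == length(genome_id))
  if (length(read_id) == 0L) stop("no candidates")
  mismatches <- rep_len(mismatches, length(read_id))
  mismatches <- as.numeric(mismatches)
  if (any(mismatches < 0)) stop("mismatch_count must be >= 0")
  missing_g <- setdiff(unique(genome_id), names(genome_lengths))
  if (length(missing_g) > 0L) {
    stop("genome(s) absent from length table: ",
         paste(missing_g, collapse = ", "))
  }
  df <- data.frame(read_id = as.character(read_id),
                   genome_id = as.character(genome_id),
                   mismatches = mismatches, stringsAsFactors = FALSE)
  # dedupe (read, genome) keeping the best alignment
  df <- df[order(df$read_id, df$genome_id, df$mismatches), , drop = FALSE]
  df <- df[!duplicated(df[, c("read_id", "genome_id")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(entries = df,
                 genome_lengths = genome_lengths[sort(names(genome_lengths))]),
            class = "alignment_candidates")
}

#' Parse alignment candidates from SAM or tabular input
#'
#' Accepts either a SAM text file of read-to-genome alignments (reference
#' name = genome id, NM tag = mismatches, secondary alignments retained) or
#' a 3-column tab-separated file `read_id  genome_id  mismatches` with no
#' header.
#'
#' @param path candidate file (SAM or TSV; SAM is detected by an `@` header
#'   or a `.sam` extension).
#' @param genome_lengths named numeric vector of genome lengths, or path to
#'   a 2-column TSV `genome_id  length`, or path to a FASTA of genomes.
#' @return an `alignment_candidates` object.
#' @export
parse_alignment_candidates <- function(path, genome_lengths) {
  if (is.character(genome_lengths) && length(genome_lengths) == 1L) {
    genome_lengths <- read_genome_lengths(genome_lengths)
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("no candidates in ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE) ||
    any(startsWith(lines, "@")) ||
    length(strsplit(body[[1]], "\t", fixed = TRUE)[[1]]) >= 11L
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (is_sam) {
    mapped <- vapply(fields, function(f) {
      bitwAnd(as.integer(f[[2]]), 4L) == 0L
    }, NA)
    fields <- fields[mapped]
    if (length(fields) == 0L) stop("no candidates (all records unmapped)")
    rid <- vapply(fields, `[[`, "", 1L)
    gid <- vapply(fields, `[[`, "", 3L)
    nm <- vapply(fields, function(f) {
      tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
      if (length(tag) == 0L) 0 else as.numeric(sub("^NM:i:", "", tag[[1]]))
    }, 0)
  } else {
    ncol_ok <- vapply(fields, length, 0L) >= 3L
    if (!all(ncol_ok)) stop("tabular candidates need 3 columns")
    rid <- vapply(fields, `[[`, "", 1L)
    gid <- vapply(fields, `[[`, "", 2L)
    nm <- as.numeric(vapply(fields, `[[`, "", 3L))
  }
  alignment_candidates(rid, gid, nm, genome_lengths)
}

#' Read genome lengths from a 2-column TSV or a FASTA file
#' @param path TSV (`genome_id\tlength`, no header) or FASTA of genomes.
#' @return named numeric vector.
#' @export
read_genome_lengths <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    x <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.numeric(Biostrings::width(x)),
                           sub("\\s.*$", "", names(x))))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("genome_id", "length"),
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$length), tab$genome_id)
}

#' Estimate genome relative abundance by EM over ambiguous mappings
#'
#' Models the foreign reads as draws from a mixture over reference genomes.
#' The per-genome read likelihood uses a per-base substitution-error model
#' with genome-length normalization,
#' `p(r | j) proportional to (1 / length_j) * eps^m * (1 - eps)^(L - m)`,
#' where `m` is the mismatch count of candidate alignment (r, j); terms not
#' depending on `j` cancel in the responsibilities. The E-step computes read
#' responsibilities under the current mixture weights `pi`; the M-step sets
#' each `pi_j` to the mean responsibility. Iteration stops when the
#' log-likelihood gain drops below `tol`. The reported abundance is the
#' genome-length-corrected mixture weight, `a_j = (pi_j / length_j)` after
#' renormalization — the relative abundance of genomes, not of reads.
#'
#' @param cands an `alignment_candidates` object.
#' @param error_rate per-base error probability in (0, 1); default 0.01.
#' @param tol stop when the log-likelihood improves by less than this.
#' @param max_iter maximum EM iterations.
#' @return an `abundance_profile`: list with `abundances` (named, sums to 1),
#'   `read_mixture` (uncorrected `pi`), `n_reads_used`, `n_reads_dropped`,
#'   `loglik_trace` and `n_iter`.
#' @export
em_abundance <- function(cands, error_rate = 0.01, tol = 1e-8,
                         max_iter = 1000L) {
  stopifnot(inherits(cands, "alignment_candidates"),
            error_rate > 0, error_rate < 1)
  e <- cands$entries
  genomes <- names(cands$genome_lengths)
  glen <- as.numeric(cands$genome_lengths)
  k <- length(genomes)
  if (nrow(e) == 0L) stop("no candidates: need >= 1 read with a candidate")
  rid <- factor(e$read_id)
  gidx <- match(e$genome_id, genomes)
  # log candidate likelihood up to a per-read constant
  llr <- -log(glen[gidx]) + e$mismatches * (log(error_rate) -
                                              log1p(-error_rate))
  n_reads <- nlevels(rid)
  ridx <- as.integer(rid)
  pi <- rep(1 / k, k)
  trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    lw <- log(pi[gidx]) + llr
    # per-read log-sum-exp
    mx <- tapply(lw, ridx, max)
    lse <- mx + log(as.numeric(
      tapply(exp(lw - mx[ridx]), ridx, sum)))
    ll <- sum(lse)
    if (!is.finite(ll)) stop("numerical underflow in EM log-likelihood")
    trace <- c(trace, ll)
    resp <- exp(lw - lse[ridx])
    pi_new <- as.numeric(tapply(resp, factor(gidx, levels = seq_len(k)),
                                sum, default = 0)) / n_reads
    converged <- (ll - ll_old) < tol && it > 1L
    pi <- pi_new
    if (converged || it >= max_iter) break
    ll_old <- ll
  }
  ab <- (pi / glen)
  ab <- ab / sum(ab)
  structure(list(abundances = stats::setNames(ab, genomes),
                 read_mixture = stats::setNames(pi, genomes),
                 n_reads_used = n_reads,
                 n_reads_dropped = 0L,
                 loglik_trace = trace, n_iter = it),
            class = "abundance_profile")
}

#' Shannon diversity of an abundance profile (natural log)
#'
#' `H = -sum(p_i * log(p_i))` with the convention that zero-abundance terms
#' contribute zero.
#'
#' @param profile an `abundance_profile` or a numeric vector of proportions
#'   summing to 1.
#' @return diversity in nats.
#' @export
shannon_diversity <- function(profile) {
  p <- if (inherits(profile, "abundance_profile")) profile$abundances
       else as.numeric(profile)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("profile must be non-negative and sum to 1")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("Abundance profile over", length(x$abundances), "genomes,",
      x$n_reads_used, "reads,", x$n_iter, "EM iterations\n")
  print(round(sort(x$abundances, decreasing = TRUE), 4))
  invisible(x)
}
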