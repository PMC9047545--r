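#' Specification for the synthetic-data generators
#'
#' One container of knobs for every simulated stage. Defaults describe the
#' "stated world" the validation suite runs in: 200 marker-structured genes
#' over 5 cell types and 20 bulk samples for deconvolution; 3 equal-length
#' toy genomes of 10 kb with 10,000 reads of 75 bp at a 1% per-base error
#' rate and 20% ambiguous mappings for abundance estimation; and a 49-pair
#' tumor/normal cohort mirroring the paired-biopsy design, with planted
#' fold changes on selected features.
#'
#' @param seed integer RNG seed; every generator is a pure function of its
#'   spec (identical output for identical spec).
#' @param n_genes,m_cell_types,L_samples deconvolution problem dimensions.
#' @param noise_sd Gaussian noise standard deviation, as a fraction of the
#'   mean mixture signal (0 = noiseless).
#' @param marker_fold expression elevation of each cell type's marker-gene
#'   block over baseline.
#' @param n_genomes,genome_length,n_reads,read_length,error_rate microbial
#'   read-set dimensions; `error_rate` is the per-base substitution rate.
#' @param ambiguous_fraction fraction of reads drawn from a region shared
#'   between all genomes (hence mapping to every genome).
#' @param genome_props true genome proportions (recycled/normalized to
#'   `n_genomes`).
#' @param n_pairs number of tumor/normal sample pairs in the cohort.
#' @param n_bact_features,n_cell_features cohort feature-block widths.
#' @param planted_bacteria,planted_cells named numeric vectors of fold
#'   changes applied to the tumor arm (names = feature indices as
#'   characters, values = fold change).
#' @param cohort_noise_sd log-scale biological noise in the cohort blocks.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L, n_genes = 200L, m_cell_types = 5L,
                       L_samples = 20L, noise_sd = 0.05, marker_fold = 5,
                       n_genomes = 3L, genome_length = 10000L,
                       n_reads = 10000L, read_length = 75L,
                       error_rate = 0.01, ambiguous_fraction = 0.2,
                       genome_props = c(0.5, 0.3, 0.2),
                       n_pairs = 49L, n_bact_features = 8L,
                       n_cell_features = 5L,
                       planted_bacteria = c("1" = 2),
                       planted_cells = c("1" = 2),
                       cohort_noise_sd = 0.4) {
  stopifnot(n_genes >= 1, m_cell_types >= 1, L_samples >= 1, n_genomes >= 1,
            noise_sd >= 0, ambiguous_fraction >= 0, ambiguous_fraction <= 1,
            error_rate >= 0, error_rate < 1, n_pairs >= 1)
  genome_props <- rep_len(genome_props, n_genomes)
  genome_props <- genome_props / sum(genome_props)
  structure(as.list(environment()), class = "synth_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Generate a marker-structured signature matrix
#'
#' Each cell type receives a contiguous block of marker genes whose
#' expression is `marker_fold` times a lognormal baseline; off-block
#' entries stay at baseline. This yields a well-conditioned, non-negative
#' basis reminiscent of a curated immune signature.
#'
#' @param spec a [synth_spec()].
#' @return genes x cell-types matrix with gene/cell-type dimnames.
#' @export
make_signature <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_genes; m <- spec$m_cell_types
    base <- matrix(stats::rlnorm(n * m, meanlog = 1, sdlog = 0.3), n, m)
    block <- split(seq_len(n), cut(seq_len(n), m, labels = FALSE))
    for (j in seq_len(m)) base[block[[j]], j] <- base[block[[j]], j] *
        spec$marker_fold
    dimnames(base) <- list(paste0("gene_", seq_len(n)),
                           paste0("cell_", seq_len(m)))
    base
  })
}

#' Generate noisy bulk mixtures with known cell fractions
#'
#' Fractions are drawn per sample from a flat Dirichlet (independent
#' standard exponentials renormalized); the mixture is `X = S f` plus
#' Gaussian noise with standard deviation `noise_sd * mean(S f)`,
#' truncated at zero.
#'
#' @param S signature matrix from [make_signature()].
#' @param spec a [synth_spec()].
#' @return list with `X` (genes x samples) and `fractions`
#'   (samples x cell types; rows sum to 1).
#' @export
make_mixtures <- function(S, spec) {
  with_seed(spec$seed + 1L, {
    m <- ncol(S); L <- spec$L_samples
    f <- matrix(stats::rexp(L * m), L, m)
    f <- f / rowSums(f)
    dimnames(f) <- list(paste0("sample_", seq_len(L)), colnames(S))
    X <- S %*% t(f)
    if (spec$noise_sd > 0) {
      X <- X + stats::rnorm(length(X), sd = spec$noise_sd * mean(X))
      X[X < 0] <- 0
    }
    colnames(X) <- rownames(f)
    list(X = X, fractions = f)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, error_rate) {
  if (error_rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < error_rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate toy genomes, reads and their alignment-candidate multimap
#'
#' Builds `n_genomes` equal-length genomes sharing a common prefix of
#' length `ambiguous_fraction * genome_length`; reads are sampled from
#' genomes at `genome_props` with per-base substitution errors. Reads drawn
#' entirely from the shared prefix receive a candidate on every genome
#' (mismatch count = its errors for the source genome, the same shared
#' sequence elsewhere), all other reads a single candidate. Since genome
#' lengths are equal, the true genome abundances equal the read
#' proportions.
#'
#' @param spec a [synth_spec()].
#' @return list with `reads` (a `tmi_reads` table), `genomes` (named
#'   character vector), `genome_lengths`, `truth` (true abundance vector),
#'   `cands` (an `alignment_candidates` object).
#' @export
make_read_set <- function(spec) {
  with_seed(spec$seed + 2L, {
    k <- spec$n_genomes
    gl <- spec$genome_length
    rl <- spec$read_length
    stopifnot(rl < gl)
    shared_len <- floor(spec$ambiguous_fraction * gl)
    shared <- if (shared_len > 0) random_dna(shared_len) else ""
    genomes <- vapply(seq_len(k), function(j) {
      paste0(shared, random_dna(gl - shared_len))
    }, "")
    names(genomes) <- paste0("genome_", seq_len(k))
    glen <- stats::setNames(rep(gl, k), names(genomes))
    src <- sample.int(k, spec$n_reads, replace = TRUE,
                      prob = spec$genome_props)
    # read start positions uniform over valid starts
    pos <- sample.int(gl - rl + 1L, spec$n_reads, replace = TRUE)
    ambiguous <- pos + rl - 1L <= shared_len
    seqs <- character(spec$n_reads)
    n_mm <- integer(spec$n_reads)
    for (i in seq_len(spec$n_reads)) {
      raw <- substr(genomes[[src[i]]], pos[i], pos[i] + rl - 1L)
      mut <- mutate_seq(raw, spec$error_rate)
      n_mm[i] <- sum(strsplit(raw, "")[[1]] != strsplit(mut, "")[[1]])
      seqs[i] <- mut
    }
    ids <- sprintf("read_%05d", seq_len(spec$n_reads))
    qual <- strrep("I", rl)   # Q40; read errors are in the bases, not flagged
    reads <- read_records(ids, seqs, rep(qual, spec$n_reads))
    rid <- rep(ids, times = ifelse(ambiguous, k, 1L))
    gid <- unlist(lapply(seq_len(spec$n_reads), function(i) {
      if (ambiguous[i]) names(genomes) else names(genomes)[src[i]]
    }), use.names = FALSE)
    mm <- unlist(lapply(seq_len(spec$n_reads), function(i) {
      if (ambiguous[i]) rep(n_mm[i], k) else n_mm[i]
    }), use.names = FALSE)
    cands <- alignment_candidates(rid, gid, mm, glen)
    truth <- stats::setNames(spec$genome_props, names(genomes))
    list(reads = reads, genomes = genomes, genome_lengths = glen,
         truth = truth, cands = cands)
  })
}

#' Generate a paired tumor/normal cohort with planted effects
#'
#' Simulates `n_pairs` patients, each contributing one normal and one tumor
#' sample. Each feature block starts from lognormal baselines with a shared
#' per-pair random effect (paired design); the fold changes in
#' `planted_bacteria` / `planted_cells` multiply the tumor arm of the named
#' features. Both blocks are closed compositionally (rows renormalized to
#' sum to 1 after planting), as abundances and fractions are.
#'
#' @param spec a [synth_spec()].
#' @return list with `bacteria` (samples x features), `cells`
#'   (samples x features), `labels` (0 normal / 1 tumor), `pair_id`.
#' @export
make_cohort <- function(spec) {
  with_seed(spec$seed + 3L, {
    np <- spec$n_pairs
    gen_block <- function(p, planted, prefix) {
      basel <- stats::rlnorm(p, meanlog = 0, sdlog = 0.5)   # feature scale
      pair_eff <- matrix(stats::rnorm(np * p, sd = 0.2), np, p)
      draw <- function() {
        exp(log(basel)[col(pair_eff)] + pair_eff +
              stats::rnorm(np * p, sd = spec$cohort_noise_sd))
      }
      normal <- draw()
      tumor <- draw()
      for (f in names(planted)) {
        j <- as.integer(f)
        tumor[, j] <- tumor[, j] * planted[[f]]
      }
      x <- rbind(normal, tumor)
      x <- x / rowSums(x)
      colnames(x) <- paste0(prefix, "_", seq_len(p))
      x
    }
    bact <- gen_block(spec$n_bact_features, spec$planted_bacteria, "bact")
    cell <- gen_block(spec$n_cell_features, spec$planted_cells, "cell")
    labels <- rep(c(0L, 1L), each = np)
    pair_id <- rep(seq_len(np), times = 2L)
    rn <- paste0(ifelse(labels == 0L, "normal_", "tumor_"), pair_id)
    rownames(bact) <- rn
    rownames(cell) <- rn
    list(bacteria = bact, cells = cell, labels = labels, pair_id = pair_id)
  })
}
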