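# run expr with a temporarily seeded RNG, restoring any prior state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic precursor and expression generator
#'
#' The generator emulates the canonical proneuropeptide architecture: an
#' N-terminal signal peptide, then peptide copies (optionally interleaved
#' with inactive spacers) flanked by basic cleavage sites, with amidation
#' (glycine-extended copies), N-terminal pyroglutamate (leading Gln) and
#' Cys-rich signatures at configurable rates; plus stage count matrices
#' with clustered bump-shaped expression profiles and Poisson count noise.
#'
#' @param n_precursors Number of precursors (also the number of expression
#'   genes).
#' @param copies_range Peptide copies per precursor (default 1-16, the
#'   range observed across real precursors up to the highly repetitive
#'   ones).
#' @param peptide_length_range Mature peptide length in residues (default
#'   4-18).
#' @param sp_length_range Signal-peptide length (default 15-30).
#' @param amidation_rate,pyroglu_rate,cys_rich_rate Per-precursor
#'   probabilities of the corresponding peptide signature.
#' @param wamide_rate Probability that a precursor's peptides carry the
#'   two-tryptophan Wamide/MIP pattern (gives family ground truth).
#' @param monobasic_rate Probability that an individual cleavage site is
#'   monobasic rather than dibasic.
#' @param multibasic_rate Probability of a length-3 multibasic site.
#' @param spacer_rate Probability of an inactive spacer (with its own
#'   flanking site) after a peptide copy.
#' @param dibasic_pairs Dibasic pairs to sample sites from.
#' @param spacer_length_range Spacer length (default 2-12).
#' @param n_stages Number of developmental stages (default 13).
#' @param n_expression_clusters Number of expression clusters (default 3).
#' @param library_size_range Per-stage library sizes (reads).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_precursors = 200L,
                             copies_range = c(1L, 16L),
                             peptide_length_range = c(4L, 18L),
                             sp_length_range = c(15L, 30L),
                             amidation_rate = 0.5,
                             pyroglu_rate = 0.2,
                             cys_rich_rate = 0.1,
                             wamide_rate = 0.1,
                             monobasic_rate = 0.1,
                             multibasic_rate = 0.1,
                             spacer_rate = 0.3,
                             dibasic_pairs = c("KR", "RR", "KK", "RK"),
                             spacer_length_range = c(2L, 12L),
                             n_stages = 13L,
                             n_expression_clusters = 3L,
                             library_size_range = c(2e5, 2e6),
                             seed = 1L) {
  cfg <- list(n_precursors = as.integer(n_precursors),
              copies_range = as.integer(copies_range),
              peptide_length_range = as.integer(peptide_length_range),
              sp_length_range = as.integer(sp_length_range),
              amidation_rate = amidation_rate, pyroglu_rate = pyroglu_rate,
              cys_rich_rate = cys_rich_rate, wamide_rate = wamide_rate,
              monobasic_rate = monobasic_rate,
              multibasic_rate = multibasic_rate,
              spacer_rate = spacer_rate,
              dibasic_pairs = dibasic_pairs,
              spacer_length_range = as.integer(spacer_length_range),
              n_stages = as.integer(n_stages),
              n_expression_clusters = as.integer(n_expression_clusters),
              library_size_range = as.numeric(library_size_range),
              seed = as.integer(seed))
  rates <- c(cfg$amidation_rate, cfg$pyroglu_rate, cfg$cys_rich_rate,
             cfg$wamide_rate, cfg$monobasic_rate, cfg$multibasic_rate,
             cfg$spacer_rate)
  stopifnot(cfg$n_precursors >= 1,
            all(rates >= 0 & rates <= 1),
            cfg$copies_range[1] >= 1,
            diff(cfg$copies_range) >= 0,
            cfg$peptide_length_range[1] >= 3,
            diff(cfg$peptide_length_range) >= 0,
            cfg$sp_length_range[1] >= 13, diff(cfg$sp_length_range) >= 0,
            diff(cfg$spacer_length_range) >= 0,
            cfg$n_stages >= 2, cfg$n_expression_clusters >= 1,
            all(cfg$library_size_range > 0))
  structure(cfg, class = "generator_config")
}

# residue pools: peptides and spacers avoid K/R so cleavage boundaries are
# exactly the inserted basic runs and the ground truth stays exact
PEPTIDE_POOL <- setdiff(AA20, c("K", "R"))
SPACER_POOL <- c("A", "S", "T", "N", "D", "E", "P", "H", "Y", "G")
SP_CORE_POOL <- c("L", "V", "I", "F", "A", "M")
# C-region tails terminating the hydrophobic core and presenting a
# small/neutral (-3,-1) cleavage pattern exactly at the last SP residue
SP_TAILS <- c("QHSHA", "QNSNA", "PHTHA", "QHGHA")

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

gen_signal_peptide <- function(len) {
  core_len <- len - 7L  # M + charged + core + 5-residue tail
  core <- paste(sample(SP_CORE_POOL, core_len, replace = TRUE),
                collapse = "")
  paste0("M", sample(c("K", "R", "N"), 1L), core,
         sample(SP_TAILS, 1L))
}

gen_basic_run <- function(cfg) {
  u <- stats::runif(1)
  if (u < cfg$monobasic_rate) {
    sample(c("K", "R"), 1L)
  } else if (u < cfg$monobasic_rate + cfg$multibasic_rate) {
    paste0(sample(cfg$dibasic_pairs, 1L), sample(c("K", "R"), 1L))
  } else {
    sample(cfg$dibasic_pairs, 1L)
  }
}

gen_peptide <- function(len, pyroglu, cys_rich, wamide,
                        wamide_spacer = sample(6:7, 1L)) {
  if (wamide) {
    # xWx{6,7}W[GIL] with a non-G terminus so the trailing residue is
    # never mistaken for an amidation glycine
    first <- sample(setdiff(PEPTIDE_POOL, c("Q", "W")), 1L)
    if (pyroglu) first <- "Q"
    return(paste0(first, "W",
                  paste(sample(setdiff(PEPTIDE_POOL, "W"), wamide_spacer,
                               replace = TRUE), collapse = ""),
                  "W", sample(c("I", "L"), 1L)))
  }
  chars <- sample(PEPTIDE_POOL, len, replace = TRUE)
  chars[1L] <- if (pyroglu) "Q" else sample(setdiff(PEPTIDE_POOL, "Q"), 1L)
  chars[len] <- sample(setdiff(PEPTIDE_POOL, "G"), 1L)
  if (cys_rich && len >= 4L) {
    pos <- sample(2:(len - 1L), 2L)
    chars[pos] <- "C"
  }
  paste(chars, collapse = "")
}

# vary up to two interior positions of a peptide copy, keeping the first
# and last residues (and the Wamide tryptophans) fixed
vary_copy <- function(base, wamide) {
  chars <- seq_chars(base)
  n <- length(chars)
  if (n < 5L) return(base)
  candidates <- 2:(n - 1L)
  if (wamide) candidates <- setdiff(candidates, c(2L, n - 1L))
  candidates <- candidates[chars[candidates] != "C"]
  if (length(candidates) < 1L) return(base)
  k <- sample(0:min(2L, length(candidates)), 1L)
  if (k == 0L) return(base)
  pos <- sample(candidates, k)
  chars[pos] <- sample(setdiff(PEPTIDE_POOL, c("W", "C")), k, replace = TRUE)
  paste(chars, collapse = "")
}

gen_spacer <- function(len) {
  chars <- sample(SPACER_POOL, len, replace = TRUE)
  chars[1L] <- sample(setdiff(SPACER_POOL, "Q"), 1L)
  chars[len] <- sample(setdiff(SPACER_POOL, "G"), 1L)
  paste(chars, collapse = "")
}

#' Generate a synthetic precursor set with ground truth
#'
#' Each protein is a signal peptide (constructed so the built-in heuristic
#' recovers its exact end) followed by peptide copies, optional spacers and
#' basic cleavage runs; amidated copies carry a glycine before the
#' following run, pyroglutaminated copies start with Gln, Cys-rich copies
#' contain two cysteines. Transcripts are seeded reverse-translations with
#' an ATG start and a stop codon and no internal stops. The ground truth
#' records every segment correct processing should liberate (designated
#' peptides plus spacer/tail segments at or above the minimum peptide
#' length), so end-to-end recovery is exact. Fully deterministic given the
#' config seed.
#'
#' @param config A [generator_config()].
#' @return List with `transcripts` (nucleotide [seq_record]s), `proteins`
#'   (protein [seq_record]s) and `truth`, itself a list with `sp`
#'   (id, sp_end), `segments` (all expected liberated segments with spans,
#'   flags and `role` in peptide/spacer/tail, plus segments dropped for
#'   length with `role = "dropped"`), `sites`, and `precursors`
#'   (copies, family, repetitive flag).
#' @export
generate_precursor_set <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_precursor_set_impl(config))
}

generate_precursor_set_impl <- function(cfg) {
  min_pep <- 3L  # default processing_config() minimum used for the truth
  proteins <- vector("list", cfg$n_precursors)
  transcripts <- vector("list", cfg$n_precursors)
  sp_rows <- vector("list", cfg$n_precursors)
  seg_rows <- list()
  site_rows <- list()
  prec_rows <- vector("list", cfg$n_precursors)

  for (i in seq_len(cfg$n_precursors)) {
    id <- sprintf("pnp%04d", i)
    sp_len <- sample_range(cfg$sp_length_range)
    sp <- gen_signal_peptide(sp_len)
    copies <- sample_range(cfg$copies_range)
    amidated <- stats::runif(1) < cfg$amidation_rate
    pyroglu <- stats::runif(1) < cfg$pyroglu_rate
    cys_rich <- stats::runif(1) < cfg$cys_rich_rate
    wamide <- stats::runif(1) < cfg$wamide_rate
    len <- sample_range(cfg$peptide_length_range)
    # a multi-copy precursor with no modification signature must expose
    # its repetitive structure to the x(3-10)-K[K/R] scanner: keep its
    # peptides within the spacer window and its sites K-initiated
    has_signature <- amidated || pyroglu ||
      (cys_rich && !wamide && len >= 4L)
    needs_scan <- copies >= 2L && !has_signature
    wamide_spacer <- if (needs_scan) 6L else sample(6:7, 1L)
    if (needs_scan) len <- min(len, 10L)
    base <- gen_peptide(len, pyroglu, cys_rich, wamide, wamide_spacer)
    k_pairs <- intersect(c("KR", "KK"), cfg$dibasic_pairs)
    scan_run <- function() {
      if (length(k_pairs)) sample(k_pairs, 1L) else "KKR"
    }

    parts <- sp
    pos <- sp_len
    add_segment <- function(seqstr, role, ami) {
      chars <- seq_chars(seqstr)
      seg_rows[[length(seg_rows) + 1L]] <<- data.frame(
        precursor_id = id, role = role,
        start = pos + 1L, end = pos + nchar(seqstr),
        sequence = seqstr, amidated = ami,
        pyroglutaminated = chars[1L] == "Q",
        cys_count = sum(chars == "C"), stringsAsFactors = FALSE)
    }
    add_run <- function(run) {
      kind <- c("monobasic", "dibasic", "multibasic")[
        min(nchar(run), 3L)]
      site_rows[[length(site_rows) + 1L]] <<- data.frame(
        precursor_id = id, start = pos + 1L, end = pos + nchar(run),
        kind = kind, stringsAsFactors = FALSE)
      parts <<- c(parts, run)
      pos <<- pos + nchar(run)
    }

    # without a basic residue between the SP and the first copy, the
    # first copy's K/R-free run reaches back through the SP and escapes
    # the repeat scanner's spacer window; scanner-dependent precursors
    # get a cleavage site directly after the SP
    if (needs_scan) add_run(scan_run())

    for (k in seq_len(copies)) {
      copy <- vary_copy(base, wamide)
      add_segment(copy, "peptide", amidated)
      emitted <- if (amidated) paste0(copy, "G") else copy
      parts <- c(parts, emitted)
      pos <- pos + nchar(emitted)
      add_run(if (needs_scan) scan_run() else gen_basic_run(cfg))
      if (k < copies && stats::runif(1) < cfg$spacer_rate) {
        spacer <- gen_spacer(sample_range(cfg$spacer_length_range))
        add_segment(spacer, if (nchar(spacer) >= min_pep) "spacer"
                    else "dropped", FALSE)
        parts <- c(parts, spacer)
        pos <- pos + nchar(spacer)
        add_run(if (needs_scan) scan_run() else gen_basic_run(cfg))
      }
    }
    if (stats::runif(1) < 0.5) {
      tail_seq <- gen_spacer(sample_range(cfg$spacer_length_range))
      add_segment(tail_seq, if (nchar(tail_seq) >= min_pep) "tail"
                  else "dropped", FALSE)
      parts <- c(parts, tail_seq)
      pos <- pos + nchar(tail_seq)
    }

    protein <- paste(parts, collapse = "")
    proteins[[i]] <- seq_record(id, protein, "protein",
                                desc = "synthetic precursor")
    nt <- paste0(reverse_translate_impl(protein),
                 sample(c("TAA", "TAG", "TGA"), 1L))
    transcripts[[i]] <- seq_record(id, nt, "nucleotide",
                                   desc = "synthetic transcript")
    sp_rows[[i]] <- data.frame(precursor_id = id, sp_end = sp_len,
                               stringsAsFactors = FALSE)
    prec_rows[[i]] <- data.frame(
      precursor_id = id, copies = copies,
      family = if (wamide) "Wamide/MIP" else "unassigned",
      amidated = amidated, pyroglu = pyroglu, cys_rich = cys_rich,
      repetitive = copies >= 2L, length = nchar(protein),
      stringsAsFactors = FALSE)
  }
  list(transcripts = transcripts, proteins = proteins,
       truth = list(sp = do.call(rbind, sp_rows),
                    segments = do.call(rbind, seg_rows),
                    sites = do.call(rbind, site_rows),
                    precursors = do.call(rbind, prec_rows)))
}

# codon choices per amino acid, stops excluded
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA20]
}

#' Reverse-translate a protein with seeded synonymous codon choice
#'
#' Each residue maps to a uniformly sampled synonymous codon; translating
#' the result in frame +1 returns the input, and no internal stop codons
#' can occur by construction.
#'
#' @param protein Amino-acid string without stop symbols.
#' @param seed Integer seed.
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, seed = 1L) {
  with_seed(seed, reverse_translate_impl(protein))
}

reverse_translate_impl <- function(protein) {
  protein <- toupper(protein)
  if (grepl("\\*", protein)) stop("protein contains a stop symbol")
  chars <- seq_chars(protein)
  tab <- codon_table()
  codons <- vapply(chars, function(a) {
    choices <- tab[[a]]
    if (is.null(choices)) stop("cannot reverse-translate residue ",
                               sQuote(a))
    choices[sample.int(length(choices), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Generate a synthetic stage count matrix with clustered profiles
#'
#' Genes are partitioned into expression clusters; each cluster has a
#' smooth bump-shaped stage-mean profile centred on a cluster-specific
#' stage, genes scale it by a log-normal baseline, and counts are drawn
#' from a Poisson law around `mean_rpm * library_size / 1e6`. Library
#' sizes are sampled within the configured range. Deterministic given the
#' config seed.
#'
#' @param config A [generator_config()].
#' @return List with `m` (a raw [count_matrix()] with library sizes and
#'   gene lengths) and `truth` (cluster labels and noiseless rpm means).
#' @export
generate_expression_matrix <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n_genes <- config$n_precursors
    n_stages <- config$n_stages
    K <- config$n_expression_clusters
    stages <- seq_len(n_stages)
    centers <- seq(2, n_stages - 1, length.out = K)
    labels <- sort(rep_len(seq_len(K), n_genes))
    base <- exp(stats::rnorm(n_genes, mean = log(40), sd = 0.6))
    means <- matrix(0, n_genes, n_stages,
                    dimnames = list(sprintf("pnp%04d", seq_len(n_genes)),
                                    paste0("stage", stages)))
    for (g in seq_len(n_genes)) {
      profile <- exp(-(stages - centers[labels[g]])^2 / (2 * 1.2^2))
      means[g, ] <- base[g] * (0.02 + profile)
    }
    libs <- stats::runif(n_stages, config$library_size_range[1],
                         config$library_size_range[2])
    counts <- matrix(stats::rpois(n_genes * n_stages,
                                  lambda = sweep(means, 2L, libs / 1e6,
                                                 `*`)),
                     n_genes, n_stages, dimnames = dimnames(means))
    lengths <- sample(500:3000, n_genes, replace = TRUE)
    m <- count_matrix(counts, library_sizes = libs, lengths = lengths,
                      normalization = "raw")
    list(m = m, truth = list(cluster = stats::setNames(labels,
                                                       rownames(means)),
                             means = means))
  })
}
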