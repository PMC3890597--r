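#' Processing configuration for precursor cleavage and peptide liberation
#'
#' Collects the tunable rules of prohormone-convertase style processing:
#' which ordered dibasic pairs are accepted, whether single basic residues
#' cleave, the minimum length of a reported mature peptide, the spacer
#' window of the repeat motif `x(3-10)-K[K/R]`, the copy number at which a
#' precursor counts as repetitive, and the cysteine count regarded as
#' Cys-rich.
#'
#' @param dibasic_pairs Ordered pairs accepted as dibasic sites, subset of
#'   `KR`, `RR`, `KK`, `RK` (default all four).
#' @param monobasic_enabled Report single `K`/`R` residues as monobasic
#'   sites (default `TRUE`); peptides flanked by a monobasic site carry a
#'   provenance flag because monobasic processing is used selectively.
#' @param min_peptide_length Minimum processed-peptide length (default 3).
#' @param repeat_spacer_min,repeat_spacer_max Spacer window of the repeat
#'   motif (defaults 3 and 10).
#' @param repeat_min_copies Matches needed to call a precursor repetitive
#'   (default 2).
#' @param cys_rich_min Cysteine count that flags a peptide as Cys-rich
#'   (default 2).
#' @return A list of class `processing_config`.
#' @export
processing_config <- function(dibasic_pairs = c("KR", "RR", "KK", "RK"),
                              monobasic_enabled = TRUE,
                              min_peptide_length = 3L,
                              repeat_spacer_min = 3L,
                              repeat_spacer_max = 10L,
                              repeat_min_copies = 2L,
                              cys_rich_min = 2L) {
  dibasic_pairs <- match.arg(dibasic_pairs, several.ok = TRUE)
  stopifnot(min_peptide_length >= 1, repeat_min_copies >= 1,
            cys_rich_min >= 1,
            repeat_spacer_min <= repeat_spacer_max)
  structure(list(dibasic_pairs = dibasic_pairs,
                 monobasic_enabled = isTRUE(monobasic_enabled),
                 min_peptide_length = as.integer(min_peptide_length),
                 repeat_spacer_min = as.integer(repeat_spacer_min),
                 repeat_spacer_max = as.integer(repeat_spacer_max),
                 repeat_min_copies = as.integer(repeat_min_copies),
                 cys_rich_min = as.integer(cys_rich_min)),
            class = "processing_config")
}

#' Detect basic cleavage sites on a precursor
#'
#' Maximal runs of `K`/`R` are treated as single cleavage events: a run of
#' length 1 is monobasic (reported only when enabled), length 2 is dibasic
#' (reported only when its ordered pair is accepted), length 3 or more is
#' multibasic and always reported.
#'
#' @param protein Amino-acid string or protein [seq_record].
#' @param config A [processing_config()].
#' @return Data frame with columns `start`, `end` (1-based inclusive span
#'   of the basic run) and `kind`, sorted by `start`.
#' @export
detect_cleavage_sites <- function(protein, config = processing_config()) {
  seq <- if (inherits(protein, "seq_record")) protein$seq else
    toupper(protein)
  chars <- seq_chars(seq)
  basic <- chars %in% c("K", "R")
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = integer(0), end = integer(0),
                    kind = character(0), stringsAsFactors = FALSE)
  for (i in which(r$values)) {
    len <- r$lengths[i]
    if (len == 1L) {
      if (!config$monobasic_enabled) next
      kind <- "monobasic"
    } else if (len == 2L) {
      pair <- substr(seq, starts[i], ends[i])
      if (!pair %in% config$dibasic_pairs) next
      kind <- "dibasic"
    } else {
      kind <- "multibasic"
    }
    out <- rbind(out, data.frame(start = starts[i], end = ends[i],
                                 kind = kind, stringsAsFactors = FALSE))
  }
  out[order(out$start), , drop = FALSE]
}

#' Liberate mature peptides from a precursor
#'
#' Candidate segments are the substrings strictly between the signal
#' peptide (or position 1 when absent), the basic-run spans, and the
#' precursor C-terminus. Within each segment a trailing glycine that
#' immediately precedes a basic run is removed and the peptide flagged
#' amidated (the glycine-extended intermediate of C-terminal
#' alpha-amidation); a glycine at the precursor terminus is not an
#' amidation signature. A leading glutamine flags N-terminal
#' pyroglutamination; the Q is retained in the reported sequence so
#' peptides stay matchable against MS lists. Segments shorter than
#' `min_peptide_length` after processing are dropped. Cleavage sites lying
#' within the signal peptide are ignored for segmentation.
#'
#' @param protein Protein [seq_record].
#' @param sp `sp_annotation` for the protein, or `NULL`.
#' @param sites Data frame from [detect_cleavage_sites()] on the same
#'   protein.
#' @param config A [processing_config()].
#' @return Data frame of mature peptides, N- to C-terminal, with columns
#'   `precursor_id`, `start`, `end` (full-precursor span of the processed
#'   peptide), `post_sp_start`, `post_sp_end` (same span in post-SP
#'   coordinates), `sequence`, `amidated`, `pyroglutaminated`, `cys_count`,
#'   `monobasic_flanked` and `ms_evidence` (initialised to `"none"`).
#' @export
liberate_peptides <- function(protein, sp = NULL, sites = NULL,
                              config = processing_config()) {
  stopifnot(inherits(protein, "seq_record"))
  seq <- protein$seq
  n <- nchar(seq)
  if (is.null(sites)) sites <- detect_cleavage_sites(seq, config)
  sp_end <- if (is.null(sp)) 0L else as.integer(sp$sp_end)

  if (nrow(sites)) {
    if (any(sites$start < 1L | sites$end > n | sites$start > sites$end)) {
      stop("cleavage-site span out of bounds for ", sQuote(protein$id))
    }
    o <- order(sites$start)
    sites <- sites[o, , drop = FALSE]
    if (nrow(sites) > 1L &&
        any(sites$start[-1L] <= sites$end[-nrow(sites)])) {
      stop("overlapping cleavage-site spans for ", sQuote(protein$id))
    }
  }
  post <- sites[sites$start > sp_end, , drop = FALSE]

  seg_start <- c(sp_end + 1L, post$end + 1L)
  seg_end <- c(post$start - 1L, n)
  followed_by_site <- c(rep(TRUE, nrow(post)), FALSE)
  preceded_kind <- c(NA_character_, post$kind)
  followed_kind <- c(post$kind, NA_character_)

  rows <- list()
  for (i in seq_along(seg_start)) {
    s <- seg_start[i]; e <- seg_end[i]
    if (e < s || s > n) next
    raw <- substr(seq, s, e)
    amidated <- FALSE
    pe <- e
    if (followed_by_site[i] && substr(raw, nchar(raw), nchar(raw)) == "G") {
      raw <- substr(raw, 1L, nchar(raw) - 1L)
      amidated <- TRUE
      pe <- e - 1L
    }
    if (nchar(raw) < config$min_peptide_length) next
    chars <- seq_chars(raw)
    rows[[length(rows) + 1L]] <- data.frame(
      precursor_id = protein$id, start = s, end = pe,
      post_sp_start = s - sp_end, post_sp_end = pe - sp_end,
      sequence = raw, amidated = amidated,
      pyroglutaminated = chars[1L] == "Q",
      cys_count = sum(chars == "C"),
      monobasic_flanked = isTRUE(preceded_kind[i] == "monobasic") ||
        isTRUE(followed_kind[i] == "monobasic"),
      ms_evidence = "none", stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(precursor_id = character(0), start = integer(0),
                      end = integer(0), post_sp_start = integer(0),
                      post_sp_end = integer(0), sequence = character(0),
                      amidated = logical(0), pyroglutaminated = logical(0),
                      cys_count = integer(0), monobasic_flanked = logical(0),
                      ms_evidence = character(0)))
  }
  do.call(rbind, rows)
}

#' Scan for the repeat motif x(3-10)-K[K/R]
#'
#' A match is a maximal K/R-free run whose length lies in the spacer
#' window, immediately followed by `K` and then `K` or `R`. Matches are
#' reported left to right and are non-overlapping by construction. The
#' spacer window is taken literally; longer peptides are still recovered by
#' [liberate_peptides()], so the scanner is a discovery heuristic, not a
#' processing rule.
#'
#' @param protein Amino-acid string or protein [seq_record].
#' @param config A [processing_config()].
#' @return List with `matches` (data frame of `start`, `end` spans covering
#'   spacer plus the two basic residues) and `repetitive` (`TRUE` when the
#'   match count reaches `repeat_min_copies`).
#' @export
scan_repeat_motif <- function(protein, config = processing_config()) {
  seq <- if (inherits(protein, "seq_record")) protein$seq else
    toupper(protein)
  chars <- seq_chars(seq)
  n <- length(chars)
  basic <- chars %in% c("K", "R")
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ms <- integer(0); me <- integer(0)
  for (i in which(!r$values)) {
    len <- r$lengths[i]
    if (len < config$repeat_spacer_min || len > config$repeat_spacer_max) next
    e <- ends[i]
    if (e + 2L > n) next
    if (chars[e + 1L] == "K" && chars[e + 2L] %in% c("K", "R")) {
      ms <- c(ms, starts[i]); me <- c(me, e + 2L)
    }
  }
  matches <- data.frame(start = ms, end = me)
  list(matches = matches,
       repetitive = nrow(matches) >= config$repeat_min_copies)
}

#' Build a C-terminally anchored position frequency matrix
#'
#' Peptides are aligned by right-justification with no internal gaps, the
#' alignment used for logos of repetitive peptide families whose conserved
#' residues sit at the C-terminus. Column `-k` is computed over the
#' peptides of length at least `k`; no pseudocounts are added.
#'
#' @param peptides Character vector of at least two amino-acid strings.
#' @return Object of class `pnp_pfm`: a list with `freq` (20-row matrix,
#'   one column per position, rightmost column is position `-1`) and
#'   `support` (contributing peptide count per column).
#' @export
build_pfm <- function(peptides) {
  peptides <- toupper(as.character(peptides))
  if (length(peptides) < 2L) stop("at least 2 peptides required for a PFM")
  lens <- nchar(peptides)
  W <- max(lens)
  freq <- matrix(0, nrow = length(AA20), ncol = W,
                 dimnames = list(AA20, paste0(-(W:1))))
  support <- integer(W)
  char_list <- strsplit(peptides, "", fixed = TRUE)
  for (k in seq_len(W)) {
    contrib <- which(lens >= k)
    support[k] <- length(contrib)
    res <- vapply(char_list[contrib],
                  function(ch) ch[length(ch) - k + 1L], character(1))
    tab <- table(factor(res, levels = AA20))
    freq[, W - k + 1L] <- as.numeric(tab) / length(contrib)
  }
  structure(list(freq = freq, support = rev(support)), class = "pnp_pfm")
}

#' @export
print.pnp_pfm <- function(x, ...) {
  W <- ncol(x$freq)
  cat("<pnp_pfm> ", W, " columns (C-terminally anchored), support ",
      x$support[W], " at -1\n", sep = "")
  consensus <- apply(x$freq, 2L, function(col) rownames(x$freq)[which.max(col)])
  cat("  consensus: ", paste(consensus, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Match observed MS peptides against predicted peptides
#'
#' A predicted peptide receives full evidence when an observed sequence is
#' identical and the observed modification flags do not contradict the
#' prediction (an observed modification requires the predicted flag; an
#' unmodified observation is compatible with either). Evidence is partial
#' when an observed sequence of length at least 5 is a substring of the
#' predicted sequence.
#'
#' @param peptides Data frame from [liberate_peptides()].
#' @param observed Data frame with columns `sequence`, `amidated`,
#'   `pyroglu` (0/1), as read by [read_table()] with kind `"ms_peptide"`.
#' @return A copy of `peptides` with `ms_evidence` set to `"full"`,
#'   `"partial"` or `"none"`.
#' @export
match_ms_evidence <- function(peptides, observed) {
  out <- peptides
  if (!nrow(peptides) || is.null(observed) || !nrow(observed)) return(out)
  obs_seq <- toupper(observed$sequence)
  obs_ami <- if ("amidated" %in% names(observed)) observed$amidated == 1 else
    rep(FALSE, nrow(observed))
  obs_pyr <- if ("pyroglu" %in% names(observed)) observed$pyroglu == 1 else
    rep(FALSE, nrow(observed))
  long_obs <- obs_seq[nchar(obs_seq) >= 5L]
  for (i in seq_len(nrow(out))) {
    pred <- out$sequence[i]
    hit <- which(obs_seq == pred &
                   !(obs_ami & !out$amidated[i]) &
                   !(obs_pyr & !out$pyroglutaminated[i]))
    if (length(hit)) {
      out$ms_evidence[i] <- "full"
    } else if (any(vapply(long_obs, grepl, logical(1), x = pred,
                          fixed = TRUE))) {
      out$ms_evidence[i] <- "partial"
    } else {
      out$ms_evidence[i] <- "none"
    }
  }
  out
}

#' Annotate a precursor end to end
#'
#' Convenience wrapper running cleavage-site detection, peptide liberation
#' and repeat scanning, returning a single annotation object that
#' [qualify_precursor()] can complete.
#'
#' @param protein Protein [seq_record].
#' @param sp `sp_annotation` or `NULL`.
#' @param config A [processing_config()].
#' @param evidence Character vector of externally supplied evidence flags,
#'   subset of `homology`, `expression`, `ms`, `conservation`,
#'   `structural`.
#' @return Object of class `precursor_annotation`.
#' @export
annotate_precursor <- function(protein, sp = NULL,
                               config = processing_config(),
                               evidence = character(0)) {
  sites <- detect_cleavage_sites(protein$seq, config)
  peptides <- liberate_peptides(protein, sp, sites, config)
  rep_scan <- scan_repeat_motif(protein$seq, config)
  structure(list(protein = protein, sp = sp, sites = sites,
                 peptides = peptides, repetitive = rep_scan$repetitive,
                 repeat_matches = rep_scan$matches,
                 evidence = unique(evidence), qualified = NA,
                 rejection_reasons = character(0), config = config),
            class = "precursor_annotation")
}

#' Apply the bona fide prohormone qualification rule
#'
#' Structural evidence is added automatically when the precursor is
#' repetitive, or any liberated peptide is amidated or pyroglutaminated or
#' Cys-rich. A precursor qualifies when it has a signal peptide, at least
#' one cleavage site, no conflicting (non-neuropeptide) protein-domain hit,
#' and at least one line of evidence; every failed conjunct is listed in
#' `rejection_reasons`.
#'
#' @param annotation A `precursor_annotation` from [annotate_precursor()].
#' @param domain_hits Optional data frame of imported domain hits
#'   (`protein_id`, `domain_name`, ...); any row for this protein counts as
#'   a conflict.
#' @return The annotation with `evidence`, `qualified` and
#'   `rejection_reasons` filled in.
#' @export
qualify_precursor <- function(annotation, domain_hits = NULL) {
  stopifnot(inherits(annotation, "precursor_annotation"))
  a <- annotation
  cfg <- a$config
  pep <- a$peptides
  structural <- isTRUE(a$repetitive) ||
    (nrow(pep) > 0 && any(pep$amidated | pep$pyroglutaminated |
                            pep$cys_count >= cfg$cys_rich_min))
  if (structural) a$evidence <- unique(c(a$evidence, "structural"))

  reasons <- character(0)
  if (is.null(a$sp)) reasons <- c(reasons, "no signal peptide")
  if (nrow(a$sites) == 0L) reasons <- c(reasons, "no cleavage site")
  if (!is.null(domain_hits) && nrow(domain_hits) &&
      a$protein$id %in% domain_hits$protein_id) {
    reasons <- c(reasons, "conflicting protein domain")
  }
  if (length(a$evidence) == 0L) reasons <- c(reasons, "no supporting evidence")
  a$qualified <- length(reasons) == 0L
  a$rejection_reasons <- reasons
  a
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("<precursor_annotation> ", x$protein$id, " (",
      nchar(x$protein$seq), " aa)\n", sep = "")
  cat("  SP: ", if (is.null(x$sp)) "none" else paste0("1-", x$sp$sp_end),
      "; sites: ", nrow(x$sites), "; peptides: ", nrow(x$peptides),
      "; repetitive: ", x$repetitive, "\n", sep = "")
  cat("  evidence: ",
      if (length(x$evidence)) paste(x$evidence, collapse = ", ") else "none",
      "; qualified: ", x$qualified, "\n", sep = "")
  if (length(x$rejection_reasons)) {
    cat("  rejected: ", paste(x$rejection_reasons, collapse = "; "), "\n",
        sep = "")
  }
  invisible(x)
}
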