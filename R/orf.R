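#' Translate one reading frame of a nucleotide sequence
#'
#' Standard genetic code via [Biostrings::translate()]. Negative frames
#' translate the reverse complement; the frame's absolute value gives the
#' 1-based offset on the reading strand. A trailing partial codon is
#' dropped, stop codons are rendered `*`, and any codon containing `N`
#' renders `X`.
#'
#' @param nt Nucleotide string (may contain `N`).
#' @param frame Integer in `{+1,+2,+3,-1,-2,-3}`.
#' @return Amino-acid string (possibly empty).
#' @export
translate_frame <- function(nt, frame) {
  stopifnot(length(frame) == 1L, abs(frame) %in% 1:3)
  nt <- toupper(as.character(nt))
  if (!nzchar(nt)) return("")
  d <- Biostrings::DNAString(nt)
  if (frame < 0) d <- Biostrings::reverseComplement(d)
  off <- abs(frame) - 1L
  n <- length(d) - off
  n <- n - n %% 3L
  if (n < 3L) return("")
  d <- Biostrings::subseq(d, start = off + 1L, width = n)
  # plain codon-table semantics: no initiator-codon special-casing, and
  # the fuzzy-codon path only when N is present (it is expensive)
  if (Biostrings::countPattern("N", d) == 0L) {
    as.character(Biostrings::translate(d, no.init.codon = TRUE))
  } else {
    as.character(Biostrings::translate(d, no.init.codon = TRUE,
                                       if.fuzzy.codon = "X"))
  }
}

#' Reverse complement of a nucleotide string
#' @param nt Nucleotide string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Find the longest open reading frame in a transcript
#'
#' Searches all six frames. ATG-initiated ORFs (ATG to the next in-frame
#' stop, or to the sequence end) are preferred; when no ATG-initiated ORF
#' reaches `min_protein_length`, the longest stop-free translated stretch is
#' returned instead (initiator `"open_end"`), reflecting the 5'-truncation
#' common in EST assemblies. Ties are broken by frame order
#' `+1,+2,+3,-1,-2,-3`, then by the smallest forward-strand start.
#'
#' @param transcript A nucleotide-mode [seq_record].
#' @param min_protein_length Minimum protein length in residues to report
#'   (default 120, the proteome cutoff used for EST-derived protein sets).
#' @param allow_open_ended Permit the stop-free fallback (default `TRUE`).
#' @return An object of class `orf` with fields `transcript_id`, `frame`,
#'   `nt_start`, `nt_end` (1-based inclusive, forward strand, including the
#'   stop codon when present), `protein` and `initiator`; or `NULL` when no
#'   ORF reaches `min_protein_length`.
#' @export
find_longest_orf <- function(transcript, min_protein_length = 120L,
                             allow_open_ended = TRUE) {
  stopifnot(inherits(transcript, "seq_record"),
            transcript$alphabet == "nucleotide",
            min_protein_length >= 1)
  L <- nchar(transcript$seq)
  if (L < 3L) return(NULL)

  cand <- list()
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- translate_frame(transcript$seq, f)
    n <- nchar(aa)
    if (n == 0L) next
    chars <- seq_chars(aa)
    stops <- which(chars == "*")
    bounds <- c(0L, stops, n + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      a <- bounds[k] + 1L
      b <- bounds[k + 1L] - 1L
      if (b < a) next
      has_stop <- bounds[k + 1L] <= n
      # open-ended candidate: the whole stop-free stretch
      cand[[length(cand) + 1L]] <- orf_candidate(
        transcript, f, a, b, has_stop, chars, initiator = "open_end")
      # ATG candidate: from the first Met in the stretch
      m <- which(chars[a:b] == "M")
      if (length(m)) {
        cand[[length(cand) + 1L]] <- orf_candidate(
          transcript, f, a + m[1L] - 1L, b, has_stop, chars,
          initiator = "ATG")
      }
    }
  }
  if (!length(cand)) return(NULL)

  pick_best <- function(cands) {
    if (!length(cands)) return(NULL)
    len <- vapply(cands, function(o) nchar(o$protein), integer(1))
    ord <- vapply(cands, `[[`, integer(1), "frame_order")
    st <- vapply(cands, `[[`, integer(1), "nt_start")
    cands[[order(-len, ord, st)[1L]]]
  }
  atg <- Filter(function(o) o$initiator == "ATG" &&
                  nchar(o$protein) >= min_protein_length, cand)
  best <- pick_best(atg)
  if (is.null(best) && allow_open_ended) {
    open <- Filter(function(o) o$initiator == "open_end" &&
                     nchar(o$protein) >= min_protein_length, cand)
    best <- pick_best(open)
  }
  if (is.null(best)) return(NULL)
  best$frame_order <- NULL
  structure(best, class = "orf")
}

# build one ORF candidate from codon indices [a, b] on the reading frame;
# the span includes the terminal stop codon when present.
orf_candidate <- function(transcript, f, a, b, has_stop, chars, initiator) {
  L <- nchar(transcript$seq)
  off <- abs(f) - 1L
  last_codon <- if (has_stop) b + 1L else b
  rs <- off + 3L * (a - 1L) + 1L
  re <- off + 3L * last_codon
  if (f > 0) {
    nt_start <- rs; nt_end <- re
  } else {
    nt_start <- L - re + 1L; nt_end <- L - rs + 1L
  }
  frame_order <- match(f, c(1L, 2L, 3L, -1L, -2L, -3L))
  list(transcript_id = transcript$id, frame = f,
       nt_start = nt_start, nt_end = nt_end,
       protein = paste(chars[a:b], collapse = ""),
       initiator = initiator, frame_order = frame_order)
}

#' @export
print.orf <- function(x, ...) {
  cat("<orf> ", x$transcript_id, " frame ", sprintf("%+d", x$frame),
      " nt ", x$nt_start, "-", x$nt_end, " (", x$initiator, ", ",
      nchar(x$protein), " aa)\n", sep = "")
  invisible(x)
}

#' Derive the predicted proteome from transcripts
#'
#' Applies [find_longest_orf()] to every transcript and keeps proteins at or
#' above the length cutoff.
#'
#' @param transcripts List of nucleotide [seq_record]s.
#' @inheritParams find_longest_orf
#' @return List with `proteins` (protein [seq_record]s named as their
#'   transcripts) and `orfs` (a data frame of ORF coordinates).
#' @export
predict_proteome <- function(transcripts, min_protein_length = 120L,
                             allow_open_ended = TRUE) {
  orfs <- lapply(transcripts, find_longest_orf,
                 min_protein_length = min_protein_length,
                 allow_open_ended = allow_open_ended)
  keep <- !vapply(orfs, is.null, logical(1))
  orfs <- orfs[keep]
  proteins <- lapply(orfs, function(o) {
    seq_record(o$transcript_id, o$protein, "protein",
               desc = sprintf("frame %+d nt %d-%d %s", o$frame, o$nt_start,
                              o$nt_end, o$initiator))
  })
  tab <- if (length(orfs)) {
    data.frame(
      transcript_id = vapply(orfs, `[[`, character(1), "transcript_id"),
      frame = vapply(orfs, `[[`, integer(1), "frame"),
      nt_start = vapply(orfs, `[[`, integer(1), "nt_start"),
      nt_end = vapply(orfs, `[[`, integer(1), "nt_end"),
      initiator = vapply(orfs, `[[`, character(1), "initiator"),
      protein_length = vapply(orfs, function(o) nchar(o$protein), integer(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = character(0), frame = integer(0),
               nt_start = integer(0), nt_end = integer(0),
               initiator = character(0), protein_length = integer(0))
  }
  list(proteins = proteins, orfs = tab)
}
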