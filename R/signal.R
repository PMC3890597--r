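# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

# residues with Kyte-Doolittle hydropathy > 1.6; a maximal run of these is
# the candidate hydrophobic core (h-region) of a signal peptide
SP_CORE_RESIDUES <- c("A", "C", "F", "I", "L", "M", "V")
# small/neutral residues tolerated at the -1 and -3 positions of a signal
# peptidase cleavage site (the (-3,-1) rule)
SP_CLEAVAGE_RESIDUES <- c("A", "G", "S", "C", "T", "V")

#' Predict an N-terminal signal peptide
#'
#' When an imported annotation (e.g. from an external predictor) is
#' supplied, it is returned verbatim with `source = "imported"`. Otherwise a
#' built-in heuristic is applied within residues 1-45: it requires a
#' hydrophobic core of at least 6 consecutive residues with mean
#' Kyte-Doolittle hydropathy above 1.6 (the longest maximal run of
#' hydropathy > 1.6 residues is taken as the core, leftmost on ties), a
#' non-negative net charge over residues 1-5, and picks as cleavage point
#' the first position after the core whose residues at -1 and -3 relative
#' to cleavage are small/neutral (`A,G,S,C,T,V`). The score maps the core's
#' mean hydropathy into `[0,1]` as `min(1, (mean - 1.6) / 2.9)`.
#'
#' @param protein A protein-mode [seq_record].
#' @param imported Optional list with `sp_end` (and optionally `score`) from
#'   an external predictor.
#' @return A list of class `sp_annotation` with `protein_id`, `sp_end`
#'   (1-based position of the last signal-peptide residue), `score` and
#'   `source`; or `NULL` when no signal peptide is found.
#' @export
predict_signal_peptide <- function(protein, imported = NULL) {
  stopifnot(inherits(protein, "seq_record"), protein$alphabet == "protein")
  n <- nchar(protein$seq)
  if (!is.null(imported)) {
    sp_end <- as.integer(imported$sp_end)
    if (sp_end < 5L || sp_end > 45L || sp_end >= n) {
      stop("imported sp_end ", sp_end, " invalid for protein ",
           sQuote(protein$id), " of length ", n)
    }
    score <- if (!is.null(imported$score)) as.numeric(imported$score) else 1
    return(structure(list(protein_id = protein$id, sp_end = sp_end,
                          score = score, source = "imported"),
                     class = "sp_annotation"))
  }
  chars <- seq_chars(protein$seq)
  window <- chars[seq_len(min(45L, n))]

  hyd <- window %in% SP_CORE_RESIDUES
  r <- rle(hyd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  core_idx <- which(r$values & r$lengths >= 6L)
  if (!length(core_idx)) return(NULL)
  core_idx <- core_idx[which.max(r$lengths[core_idx])]
  core_start <- starts[core_idx]
  core_end <- ends[core_idx]

  kd <- KYTE_DOOLITTLE[window[core_start:core_end]]
  if (mean(kd) <= 1.6) return(NULL)

  charge <- sum(chars[seq_len(min(5L, n))] %in% c("K", "R")) -
    sum(chars[seq_len(min(5L, n))] %in% c("D", "E"))
  if (charge < 0) return(NULL)

  p_max <- min(45L, n - 1L)
  if (core_end + 1L > p_max) return(NULL)
  sp_end <- NA_integer_
  for (p in seq(core_end + 1L, p_max)) {
    if (p < 5L || p - 2L < 1L) next
    if (chars[p] %in% SP_CLEAVAGE_RESIDUES &&
        chars[p - 2L] %in% SP_CLEAVAGE_RESIDUES) {
      sp_end <- p
      break
    }
  }
  if (is.na(sp_end)) return(NULL)
  structure(list(protein_id = protein$id, sp_end = sp_end,
                 score = min(1, (mean(kd) - 1.6) / 2.9),
                 source = "heuristic"),
            class = "sp_annotation")
}

#' @export
print.sp_annotation <- function(x, ...) {
  cat("<sp_annotation> ", x$protein_id, " sp_end=", x$sp_end,
      " score=", round(x$score, 3), " (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Remove a signal peptide in silico
#'
#' Returns the mature chain (residues after `sp_end`) as a new record with
#' the identifier preserved, the form used to build a secretome database
#' for peptide-evidence matching.
#'
#' @param protein A protein-mode [seq_record].
#' @param sp An `sp_annotation` for that protein.
#' @return A protein [seq_record] with the signal peptide removed.
#' @export
make_secretome_record <- function(protein, sp) {
  stopifnot(inherits(protein, "seq_record"), inherits(sp, "sp_annotation"))
  if (!identical(sp$protein_id, protein$id)) {
    stop("signal-peptide annotation is for ", sQuote(sp$protein_id),
         ", not ", sQuote(protein$id))
  }
  n <- nchar(protein$seq)
  if (sp$sp_end >= n) {
    stop("sp_end ", sp$sp_end, " leaves no mature chain for protein ",
         sQuote(protein$id), " of length ", n)
  }
  seq_record(protein$id, substr(protein$seq, sp$sp_end + 1L, n), "protein",
             desc = paste0("SP 1-", sp$sp_end, " removed"))
}

#' Derive the secretome from a predicted proteome
#'
#' Gates proteins on the presence of a signal peptide (imported calls win
#' over the heuristic) and removes the signal peptide in silico.
#'
#' @param proteins List of protein [seq_record]s.
#' @param imported Optional data frame of imported calls
#'   (`protein_id`, `sp_end`, optionally `score`), as read by
#'   [read_table()] with kind `"signal_peptide"`.
#' @return List with `secretome` (mature-chain records), `sp` (a data frame
#'   of the retained signal-peptide calls) and `annotations` (named list of
#'   `sp_annotation`s).
#' @export
predict_secretome <- function(proteins, imported = NULL) {
  imp <- list()
  if (!is.null(imported) && nrow(imported)) {
    for (i in seq_len(nrow(imported))) {
      imp[[imported$protein_id[i]]] <-
        list(sp_end = imported$sp_end[i],
             score = if ("score" %in% names(imported)) imported$score[i]
                     else NULL)
    }
  }
  anns <- list()
  secretome <- list()
  for (p in proteins) {
    sp <- predict_signal_peptide(p, imported = imp[[p$id]])
    if (is.null(sp)) next
    anns[[p$id]] <- sp
    secretome[[length(secretome) + 1L]] <- make_secretome_record(p, sp)
  }
  tab <- if (length(anns)) {
    data.frame(protein_id = vapply(anns, `[[`, character(1), "protein_id"),
               sp_end = vapply(anns, `[[`, integer(1), "sp_end"),
               score = vapply(anns, `[[`, numeric(1), "score"),
               source = vapply(anns, `[[`, character(1), "source"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(protein_id = character(0), sp_end = integer(0),
               score = numeric(0), source = character(0))
  }
  list(secretome = secretome, sp = tab, annotations = anns)
}
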