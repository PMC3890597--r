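NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PROT_ALPHABET <- c(AA20, "X")

#' Create a sequence record
#'
#' The basic unit handled by the pipeline: a named nucleotide or amino-acid
#' sequence. Sequences are stored upper-case and validated against the
#' declared alphabet (`A/C/G/T/N` for nucleotides, the 20 amino acids plus
#' `X` for proteins).
#'
#' @param id Identifier, a non-empty string without whitespace.
#' @param seq Sequence string; case-insensitive on input.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param desc Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `seq`,
#'   `alphabet` and `desc`.
#' @export
seq_record <- function(id, seq, alphabet = c("protein", "nucleotide"),
                       desc = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("sequence identifier must be a non-empty string")
  }
  if (grepl("[[:space:]]", id)) {
    stop("sequence identifier must not contain whitespace: ", sQuote(id))
  }
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq)) {
    stop("sequence must be non-empty (record ", sQuote(id), ")")
  }
  validate_alphabet(seq, alphabet, id)
  structure(list(id = id, seq = seq, alphabet = alphabet,
                 desc = as.character(desc)),
            class = "seq_record")
}

alphabet_chars <- function(alphabet) {
  switch(alphabet,
         nucleotide = NUC_ALPHABET,
         protein = PROT_ALPHABET,
         stop("unknown alphabet: ", alphabet))
}

validate_alphabet <- function(seq, alphabet, id = "?") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet_chars(alphabet))
  if (length(bad)) {
    stop("record ", sQuote(id), ": character ", sQuote(chars[bad[1L]]),
         " at position ", bad[1L], " is outside the ", alphabet, " alphabet")
  }
  invisible(TRUE)
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$id, " (", x$alphabet, ", ", nchar(x$seq), " ",
      if (x$alphabet == "protein") "aa" else "nt", ")\n", sep = "")
  s <- x$seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  ", s, "\n", sep = "")
  invisible(x)
}

# split a sequence into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
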