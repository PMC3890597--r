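# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths (and Biostrings) wherever the point is to
# cross-check an implementation.

# literal standard codon table
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "")[[1]]), collapse = "")
}

oracle_translate <- function(nt, frame) {
  s <- if (frame < 0) oracle_revcomp(nt) else nt
  off <- abs(frame) - 1L
  s <- substr(s, off + 1L, nchar(s))
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return("")
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    codon <- substr(s, 3L * i - 2L, 3L * i)
    out[i] <- if (grepl("N", codon)) "X" else unname(ORACLE_CODONS[codon])
  }
  paste(out, collapse = "")
}

# exhaustive six-frame ORF enumeration: every ATG...stop(or end) candidate
# and every stop-free stretch, selected by the documented rules
oracle_longest_orf <- function(rec, min_len, allow_open = TRUE) {
  L <- nchar(rec$seq)
  cands <- list()
  frame_seq <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (fi in seq_along(frame_seq)) {
    f <- frame_seq[fi]
    aa <- oracle_translate(rec$seq, f)
    if (!nzchar(aa)) next
    ch <- strsplit(aa, "")[[1]]
    n <- length(ch)
    bounds <- c(0L, which(ch == "*"), n + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      a <- bounds[k] + 1L
      b <- bounds[k + 1L] - 1L
      if (b < a) next
      has_stop <- bounds[k + 1L] <= n
      starts <- c(a, a - 1L + which(ch[a:b] == "M"))
      inits <- c("open_end", rep("ATG", length(starts) - 1L))
      for (t in seq_along(starts)) {
        sc <- starts[t]
        last <- if (has_stop) b + 1L else b
        off <- abs(f) - 1L
        rs <- off + 3L * (sc - 1L) + 1L
        re <- off + 3L * last
        cands[[length(cands) + 1L]] <- list(
          frame = f, fi = fi,
          nt_start = if (f > 0) rs else L - re + 1L,
          nt_end = if (f > 0) re else L - rs + 1L,
          protein = paste(ch[sc:b], collapse = ""),
          initiator = inits[t])
      }
    }
  }
  sel <- function(want) {
    keep <- Filter(function(x) x$initiator == want &&
                     nchar(x$protein) >= min_len, cands)
    if (!length(keep)) return(NULL)
    len <- vapply(keep, function(x) nchar(x$protein), integer(1))
    fi <- vapply(keep, function(x) x$fi, integer(1))
    st <- vapply(keep, function(x) x$nt_start, integer(1))
    keep[[order(-len, fi, st)[1L]]]
  }
  best <- sel("ATG")
  if (is.null(best) && allow_open) best <- sel("open_end")
  best
}

# run-length spans of K/R runs over the indicator string
oracle_basic_runs <- function(seq) {
  basic <- strsplit(seq, "")[[1]] %in% c("K", "R")
  r <- rle(basic)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  data.frame(start = s[r$values], end = e[r$values],
             len = r$lengths[r$values])
}

# literal regular-expression oracle for the repeat motif x(3-10)-K[K/R]
oracle_repeat_matches <- function(seq, lo = 3, hi = 10) {
  pat <- sprintf("(?:^|(?<=[KR]))[^KR]{%d,%d}K[KR]", lo, hi)
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# per-column counting oracle for the C-anchored PFM
oracle_pfm <- function(peptides) {
  lens <- nchar(peptides)
  W <- max(lens)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  freq <- matrix(0, 20, W, dimnames = list(aa, paste0(-(W:1))))
  support <- integer(W)
  for (k in seq_len(W)) {
    cnt <- setNames(numeric(20), aa)
    nk <- 0L
    for (p in peptides) {
      if (nchar(p) < k) next
      res <- substr(p, nchar(p) - k + 1L, nchar(p) - k + 1L)
      cnt[res] <- cnt[res] + 1
      nk <- nk + 1L
    }
    freq[, W - k + 1L] <- cnt / nk
    support[W - k + 1L] <- nk
  }
  list(freq = freq, support = support)
}

# union-find connected components
oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# canonical form of a partition for comparison
partition_canon <- function(groups) {
  groups <- lapply(groups, sort)
  keys <- vapply(groups, paste, character(1), collapse = ",")
  sort(unname(keys))
}

# naive O(n^3) agglomerative clustering on a distance matrix; returns the
# sorted sequence of merge heights
oracle_agglomerate <- function(d, linkage = "average") {
  active <- seq_len(nrow(d))
  size <- rep(1, nrow(d))
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bh) { bh <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bh)
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- switch(linkage,
        average = (size[i] * d[i, k] + size[j] * d[j, k]) /
          (size[i] + size[j]),
        complete = max(d[i, k], d[j, k]),
        single = min(d[i, k], d[j, k]))
      d[k, i] <- d[i, k]
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# adjusted Rand index between two labelings (contingency-table form)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# random sequence helpers
random_nt <- function(n, with_n = FALSE) {
  pool <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}
random_aa <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
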