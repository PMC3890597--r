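# One-off deterministic generation of the plain-text fixtures shipped in
# inst/extdata. Run from the repository root.
suppressPackageStartupMessages(library(pnpkit))

set.seed(4242)

## --- synthetic DH44-like precursors (13 and 16 amidated copies) ---------
# SP: M + charged + hydrophobic core + C-region tail ending at the SP end
sp1 <- "MKFLVLLALVILAVQHSHA"   # 19 aa
sp2 <- "MRVLLFAVLLIVAFAQNSNA"  # 20 aa
base <- "ISAMHNLPDALSQELAA"    # ELH/DH44-like core peptide, K/R-free
vary <- function(base, k) {
  ch <- strsplit(base, "")[[1]]
  pos <- sample(3:(length(ch) - 2), k)
  ch[pos] <- sample(setdiff(strsplit("ASTNDEQHGPILVFMY", "")[[1]], "W"),
                    k, replace = TRUE)
  paste(ch, collapse = "")
}
mk_precursor <- function(sp, n_copies) {
  copies <- vapply(seq_len(n_copies), function(i) vary(base, sample(1:3, 1)),
                   character(1))
  paste0(sp, paste(vapply(copies, function(p) paste0(p, "G", "KR"),
                          character(1)), collapse = ""), "DE")
}
p1 <- mk_precursor(sp1, 13)
p2 <- mk_precursor(sp2, 16)
recs <- list(
  seq_record("DH44-1_synthetic", p1, "protein",
             desc = "synthetic stand-in, 13 amidated peptide copies"),
  seq_record("DH44-2_synthetic", p2, "protein",
             desc = "synthetic stand-in, 16 amidated peptide copies"))
write_fasta(recs, "inst/extdata/synthetic_dh44_precursors.fasta")

# sanity: exact copy counts under default processing
for (r in recs) {
  sp <- predict_signal_peptide(r)
  pep <- liberate_peptides(r, sp)
  cat(r$id, "sp_end", sp$sp_end, "peptides", nrow(pep),
      "all amidated", all(pep$amidated), "\n")
}

## --- synthetic 98 x 13 count table --------------------------------------
stages <- c("egg", "hpf24", "hpf36", "hpf48", "hpf72", "dpf4", "dpf10",
            "dpf15", "mo1pre", "mo1post", "mo3", "male", "female")
libs <- round(runif(13, 8e5, 2.5e6))
names(libs) <- stages
genes <- sprintf("pnp%03d", 1:98)

# 79 expressed genes: bump profiles peaking at different stages, overall
# mass rising through development and peaking at dpf15
peak_weight <- c(0.2, 0.4, 0.5, 0.7, 0.9, 1.1, 1.6, 2.2, 1.4, 1.2, 0.9,
                 1.0, 0.6)
counts <- matrix(0L, 98, 13, dimnames = list(genes, stages))
for (i in 1:79) {
  center <- sample(1:13, 1, prob = peak_weight)
  level <- exp(rnorm(1, log(25), 0.9))          # peak rpm
  prof <- exp(-((1:13) - center)^2 / (2 * 1.8^2))
  rpm <- level * (0.05 + prof)
  counts[i, ] <- rpois(13, rpm * libs / 1e6)
}
# gene 1: boundary case, maximum exactly 2.0 rpm
libs["dpf15"] <- 1.5e6
counts[1, ] <- 0L
counts[1, "dpf15"] <- 3L                         # 3 / 1.5e6 * 1e6 = 2.0 rpm
# genes 80..98: below the filter everywhere (max rpm < 2)
for (i in 80:98) {
  rpm <- runif(13, 0, 1.6)
  counts[i, ] <- pmin(rpois(13, rpm * libs / 1e6),
                      floor(1.9 * libs / 1e6))
}
# enforce the filter outcome exactly: 1..79 pass, 80..98 fail
rpm_mat <- sweep(counts, 2, libs, "/") * 1e6
for (i in 2:79) {
  if (max(rpm_mat[i, ]) < 2) {
    j <- which.max(rpm_mat[i, ])
    counts[i, j] <- as.integer(ceiling(2 * libs[j] / 1e6))
  }
}
rpm_mat <- sweep(counts, 2, libs, "/") * 1e6
stopifnot(sum(apply(rpm_mat, 1, max) >= 2) == 79)

write_tsv(data.frame(gene_id = genes, counts, check.names = FALSE),
          "inst/extdata/synthetic_pnp_counts.tsv")
write_tsv(data.frame(stage = stages, total_reads = as.numeric(libs)),
          "inst/extdata/synthetic_library_sizes.tsv")
write_tsv(data.frame(gene_id = genes,
                     length = sample(600:3000, 98, replace = TRUE)),
          "inst/extdata/synthetic_pnp_lengths.tsv")
cat("retained:", sum(apply(rpm_mat, 1, max) >= 2), "of 98\n")
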