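make_sp <- function(id, sp_end) {
  structure(list(protein_id = id, sp_end = as.integer(sp_end), score = 1,
                 source = "imported"), class = "sp_annotation")
}

test_that("cleavage sites are maximal basic runs classified by length", {
  cfg <- processing_config()
  s <- detect_cleavage_sites("AAAKRAAA", cfg)
  expect_equal(s$start, 4L)
  expect_equal(s$end, 5L)
  expect_equal(s$kind, "dibasic")

  # greedy maximal run: RKRR is one multibasic event, not nested pairs
  s2 <- detect_cleavage_sites("AAARKRRA", cfg)
  expect_equal(nrow(s2), 1L)
  expect_equal(c(s2$start, s2$end), c(4L, 7L))
  expect_equal(s2$kind, "multibasic")

  no_mono <- processing_config(monobasic_enabled = FALSE)
  expect_equal(nrow(detect_cleavage_sites("AAARAAA", no_mono)), 0L)
  expect_equal(detect_cleavage_sites("AAARAAA", cfg)$kind, "monobasic")

  # a dibasic pair outside the accepted set is not a site
  only_kr <- processing_config(dibasic_pairs = "KR",
                               monobasic_enabled = FALSE)
  expect_equal(nrow(detect_cleavage_sites("AAARKAAA", only_kr)), 0L)
})

test_that("cleavage spans equal a run-length oracle on random sequences", {
  set.seed(99)
  cfg <- processing_config()  # monobasic on, all pairs: every run reported
  for (rep in 1:500) {
    seq <- random_aa(sample(10:120, 1))
    got <- detect_cleavage_sites(seq, cfg)
    want <- oracle_basic_runs(seq)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$kind,
                 c("monobasic", "dibasic", "multibasic")[pmin(want$len, 3)])
  }
})

test_that("peptide liberation strips amidation glycines and flags pyroglutamate", {
  cfg <- processing_config(monobasic_enabled = FALSE)
  p <- seq_record("fmrf", paste0(strrep("A", 5), "FMRFGKRAAPAFMRFGKK"),
                  "protein")
  pep <- liberate_peptides(p, make_sp("fmrf", 5), config = cfg)
  expect_equal(pep$sequence, c("FMRF", "AAPAFMRF"))
  expect_true(all(pep$amidated))
  expect_false(any(pep$pyroglutaminated))
  # spans exclude the stripped glycine and come in N-to-C order
  expect_equal(pep$start, c(6L, 13L))
  expect_equal(pep$end, c(9L, 20L))
  expect_equal(pep$post_sp_start, c(1L, 8L))

  q <- seq_record("q1", paste0(strrep("A", 5), "QSGFLGKR"), "protein")
  qpep <- liberate_peptides(q, make_sp("q1", 5))
  expect_equal(qpep$sequence, "QSGFL")
  expect_true(qpep$amidated)
  expect_true(qpep$pyroglutaminated)

  # terminal glycine with no following site is not an amidation signature
  t <- seq_record("t1", paste0(strrep("A", 5), "KRPEPG"), "protein")
  tpep <- liberate_peptides(t, make_sp("t1", 5))
  expect_equal(tpep$sequence, "PEPG")
  expect_false(tpep$amidated)
})

test_that("liberation drops short segments, counts cysteines, flags monobasic flanks", {
  p <- seq_record("x", "MMMMMKRAGKRCACAKVVVV", "protein")
  pep <- liberate_peptides(p, make_sp("x", 5))
  # "AG" before KR strips to "A" (dropped); "CACA" kept; "VVVV" kept
  expect_equal(pep$sequence, c("CACA", "VVVV"))
  expect_equal(pep$cys_count, c(2L, 0L))
  expect_equal(pep$monobasic_flanked, c(TRUE, TRUE))

  bad_sites <- data.frame(start = c(6L, 7L), end = c(7L, 8L),
                          kind = "dibasic")
  expect_error(liberate_peptides(p, make_sp("x", 5), sites = bad_sites),
               "overlap")
  oob <- data.frame(start = 19L, end = 25L, kind = "dibasic")
  expect_error(liberate_peptides(p, make_sp("x", 5), sites = oob),
               "out of bounds")
})

test_that("residues are conserved: SP + runs + peptides + glycines + dropped = precursor", {
  gen <- generate_precursor_set(generator_config(n_precursors = 40,
                                                 seed = 17))
  cfg <- processing_config()
  for (i in seq_along(gen$proteins)) {
    p <- gen$proteins[[i]]
    sp_end <- gen$truth$sp$sp_end[i]
    sites <- detect_cleavage_sites(p$seq, cfg)
    pep <- liberate_peptides(p, make_sp(p$id, sp_end), sites, cfg)
    covered <- rep(FALSE, nchar(p$seq))
    covered[seq_len(sp_end)] <- TRUE
    for (j in seq_len(nrow(sites))) {
      covered[sites$start[j]:sites$end[j]] <- TRUE
    }
    if (nrow(pep)) for (j in seq_len(nrow(pep))) {
      expect_false(any(covered[pep$start[j]:pep$end[j]]))  # disjoint spans
      covered[pep$start[j]:pep$end[j]] <- TRUE
      if (pep$amidated[j]) covered[pep$end[j] + 1L] <- TRUE
    }
    # whatever is left must be a dropped short segment between boundaries
    gaps <- rle(covered)
    gap_lens <- gaps$lengths[!gaps$values]
    expect_true(all(gap_lens < cfg$min_peptide_length))
  }
})

test_that("repeat scanner obeys the literal spacer window", {
  cfg <- processing_config()
  res <- scan_repeat_motif("AAAKKGGGGKRCCCCKK", cfg)
  expect_equal(nrow(res$matches), 3L)
  expect_true(res$repetitive)
  expect_equal(res$matches$start, c(1L, 6L, 12L))

  expect_equal(nrow(scan_repeat_motif("AAKK", cfg)$matches), 0L)
  # an 11-residue spacer misses the 3-10 window
  expect_equal(nrow(scan_repeat_motif(paste0(strrep("A", 11), "KR"),
                                      cfg)$matches), 0L)
  expect_equal(nrow(scan_repeat_motif(paste0(strrep("A", 10), "KR"),
                                      cfg)$matches), 1L)
  # K[K/R] required: RR after the spacer does not count
  expect_equal(nrow(scan_repeat_motif("AAAARR", cfg)$matches), 0L)
  expect_false(scan_repeat_motif("GGGGKK", cfg)$repetitive)
})

test_that("repeat matches equal the regular-expression oracle", {
  set.seed(5)
  cfg <- processing_config()
  for (rep in 1:1000) {
    seq <- paste(sample(c("A", "G", "C", "S", "K", "R"),
                        sample(5:60, 1), replace = TRUE,
                        prob = c(2, 2, 1, 1, 2, 2)), collapse = "")
    got <- scan_repeat_motif(seq, cfg)$matches
    want <- oracle_repeat_matches(seq)
    expect_equal(got$start, want$start, info = seq)
    expect_equal(got$end, want$end, info = seq)
  }
})

test_that("repeat scan is invariant under spacer substitutions among non-basic residues", {
  set.seed(6)
  cfg <- processing_config()
  for (rep in 1:50) {
    seq <- paste(sample(c("A", "G", "K", "R"), 40, replace = TRUE),
                 collapse = "")
    chars <- strsplit(seq, "")[[1]]
    non_basic <- which(!chars %in% c("K", "R"))
    chars[non_basic] <- sample(c("S", "T", "P", "Y"),
                               length(non_basic), replace = TRUE)
    perturbed <- paste(chars, collapse = "")
    expect_equal(scan_repeat_motif(seq, cfg)$matches,
                 scan_repeat_motif(perturbed, cfg)$matches)
  }
})

test_that("PFMs are right-anchored with per-column support", {
  pfm <- build_pfm(c("FMRF", "FMRF"))
  expect_equal(unname(pfm$freq["F", "-1"]), 1)
  expect_equal(unname(pfm$freq["M", "-3"]), 1)
  expect_equal(pfm$support, c(2L, 2L, 2L, 2L))

  ragged <- build_pfm(c("ARF", "RF"))
  expect_equal(unname(ragged$freq["F", "-1"]), 1)
  expect_equal(unname(ragged$freq["R", "-2"]), 1)
  expect_equal(unname(ragged$freq["A", "-3"]), 1)
  expect_equal(ragged$support, c(1L, 2L, 2L))

  expect_error(build_pfm("FMRF"), "at least 2")
})

test_that("PFM frequencies equal a counting oracle and columns sum to one", {
  set.seed(30)
  peptides <- vapply(1:30, function(i) random_aa(sample(4:12, 1)),
                     character(1))
  pfm <- build_pfm(peptides)
  want <- oracle_pfm(peptides)
  expect_equal(pfm$freq, want$freq)
  expect_equal(pfm$support, want$support)
  expect_equal(unname(colSums(pfm$freq)), rep(1, ncol(pfm$freq)),
               tolerance = 1e-9)
  # support never increases toward the N-terminus
  expect_true(all(diff(pfm$support) >= 0))
})

test_that("MS evidence matching distinguishes full, partial and none", {
  pep <- data.frame(precursor_id = "p", start = 1L, end = 10L,
                    post_sp_start = 1L, post_sp_end = 10L,
                    sequence = c("FMRF", "QSGFLRESAM", "AAAA"),
                    amidated = c(TRUE, FALSE, FALSE),
                    pyroglutaminated = c(FALSE, TRUE, FALSE),
                    cys_count = 0L, monobasic_flanked = FALSE,
                    ms_evidence = "none", stringsAsFactors = FALSE)
  obs <- data.frame(sequence = c("FMRF", "GFLRE"),
                    amidated = c(1, 0), pyroglu = c(0, 0))
  out <- match_ms_evidence(pep, obs)
  expect_equal(out$ms_evidence, c("full", "partial", "none"))
  # an observed modification must not contradict the prediction
  obs2 <- data.frame(sequence = "AAAA", amidated = 1, pyroglu = 0)
  out2 <- match_ms_evidence(pep, obs2)
  expect_equal(out2$ms_evidence[3], "none")
  # observed substrings shorter than 5 residues never give partial evidence
  obs3 <- data.frame(sequence = "GFLR", amidated = 0, pyroglu = 0)
  expect_equal(match_ms_evidence(pep, obs3)$ms_evidence,
               rep("none", 3))
  # empty observation list leaves everything at none
  expect_equal(match_ms_evidence(pep, obs[0, ])$ms_evidence,
               rep("none", 3))
  # input is untouched
  expect_equal(pep$ms_evidence, rep("none", 3))
})

test_that("qualification requires SP, a cleavage site, no domain, and evidence", {
  p <- seq_record("good", paste0("MKLLVLLLLLAVQHSHA",
                                 strrep("AWAPAWIGKR", 3), "DE"), "protein")
  ann <- annotate_precursor(p, make_sp("good", 17))
  ann <- qualify_precursor(ann)
  expect_true(ann$qualified)
  expect_true("structural" %in% ann$evidence)
  expect_equal(ann$rejection_reasons, character(0))

  # same precursor without an SP is rejected for exactly that reason
  ann2 <- qualify_precursor(annotate_precursor(p, NULL))
  expect_false(ann2$qualified)
  expect_equal(ann2$rejection_reasons, "no signal peptide")

  # a domain hit disqualifies
  hits <- data.frame(protein_id = "good", domain_name = "Trypsin",
                     start = 1, end = 50)
  ann3 <- qualify_precursor(annotate_precursor(p, make_sp("good", 17)),
                            domain_hits = hits)
  expect_false(ann3$qualified)
  expect_equal(ann3$rejection_reasons, "conflicting protein domain")

  # SP + one site but no evidence of any kind: rejected
  plain <- seq_record("plain", paste0("MKLLVLLLLLAVQHSHA", "ADSTNE", "KR",
                                      "TSDNAH"), "protein")
  ann4 <- qualify_precursor(annotate_precursor(plain, make_sp("plain", 17)))
  expect_false(ann4$qualified)
  expect_equal(ann4$rejection_reasons, "no supporting evidence")
  # externally supplied evidence rescues it
  ann5 <- qualify_precursor(annotate_precursor(plain, make_sp("plain", 17),
                                               evidence = "ms"))
  expect_true(ann5$qualified)
})
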