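toy_matrix <- function(values, libs = NULL, lengths = NULL) {
  count_matrix(values, library_sizes = libs, lengths = lengths,
               normalization = "raw")
}

test_that("rpm and RPKM normalization follow the definitions", {
  v <- matrix(c(2, 10), 1, 2, dimnames = list("g1", c("s1", "s2")))
  m <- toy_matrix(v, libs = c(1e6, 2e6), lengths = 500)
  rpm <- normalize_counts(m, "rpm")
  expect_equal(unname(rpm$values[1, ]), c(2, 5))
  rpkm <- normalize_counts(m, "rpkm")
  expect_equal(unname(rpkm$values[1, ]), c(4, 10))  # rpm * 1e3 / 500

  expect_error(normalize_counts(toy_matrix(v, libs = c(1e6, 2e6)), "rpkm"),
               "lengths")
  expect_error(normalize_counts(rpm, "rpm"), "raw")
  m0 <- toy_matrix(v, libs = c(1e6, 2e6))
  m0$library_sizes[1] <- 0
  expect_error(normalize_counts(m0, "rpm"), "zero library")
})

test_that("normalization equals a per-cell arithmetic oracle", {
  set.seed(50)
  v <- matrix(rpois(50 * 13, 20), 50, 13)
  libs <- runif(13, 5e5, 5e6)
  lens <- sample(300:3000, 50)
  m <- toy_matrix(v, libs = libs, lengths = lens)
  rpm <- normalize_counts(m, "rpm")$values
  rpkm <- normalize_counts(m, "rpkm")$values
  for (g in c(1, 17, 50)) for (s in c(1, 7, 13)) {
    expect_equal(rpm[g, s], v[g, s] / libs[s] * 1e6)
    expect_equal(rpkm[g, s], v[g, s] / libs[s] * 1e6 * 1e3 / lens[g])
  }
  expect_equal(unname(colSums(rpm)), unname(colSums(v) / libs * 1e6))
})

test_that("the expression filter keeps genes at the inclusive boundary", {
  v <- matrix(c(1.9, 0.5,   # below everywhere -> dropped
                2.0, 0.1,   # exactly at the boundary -> kept
                0.0, 0.0,   # all zero -> dropped
                9.0, 0.0),  # above -> kept
              4, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  rpm <- count_matrix(v, library_sizes = c(1e6, 1e6),
                      normalization = "rpm")
  kept <- filter_min_expression(rpm, 2)
  expect_equal(rownames(kept$values), c("g2", "g4"))

  all_zero <- count_matrix(matrix(0, 3, 2, dimnames = list(paste0("g", 1:3),
                                                           c("a", "b"))),
                           library_sizes = c(1, 1), normalization = "rpm")
  expect_equal(nrow(filter_min_expression(all_zero, 2)$values), 0L)

  # monotonicity: raising the threshold never adds genes
  set.seed(51)
  rv <- matrix(runif(40 * 13, 0, 6), 40, 13)
  rm_ <- count_matrix(rv, library_sizes = rep(1e6, 13),
                      normalization = "rpm")
  kept2 <- rownames(filter_min_expression(rm_, 2)$values)
  kept4 <- rownames(filter_min_expression(rm_, 4)$values)
  expect_true(all(kept4 %in% kept2))
  expect_error(filter_min_expression(toy_matrix(rv)), "rpm")
})

test_that("profile clustering uses 1 - Pearson distance with documented degeneracies", {
  v <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1))
  m <- count_matrix(v, normalization = "raw")
  cl <- cluster_profiles(m)
  hc <- cl$hclust
  # identical (proportional) profiles merge at height 0
  expect_equal(min(hc$height), 0)
  # anti-correlated profiles sit at distance 2
  d <- pnpkit:::pearson_distance(v)
  expect_equal(unname(d["g1", "g3"]), 2)
  expect_equal(unname(d["g1", "g2"]), 0)
  # zero-variance rows at distance 1 to everything
  v2 <- rbind(v, g4 = c(5, 5, 5))
  d2 <- pnpkit:::pearson_distance(v2)
  expect_equal(unname(d2["g4", c("g1", "g2", "g3")]), rep(1, 3))

  expect_error(cluster_profiles(count_matrix(v[1, , drop = FALSE],
                                             normalization = "raw")),
               "at least two genes")
})

test_that("merge heights equal a naive agglomeration oracle for every linkage", {
  set.seed(40)
  v <- matrix(rnorm(40 * 13), 40, 13,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  m <- count_matrix(abs(v), normalization = "raw")
  d <- pnpkit:::pearson_distance(abs(v))
  for (linkage in c("average", "complete", "single")) {
    cl <- cluster_profiles(m, linkage)
    expect_equal(sort(cl$hclust$height), oracle_agglomerate(d, linkage),
                 tolerance = 1e-9, info = linkage)
  }
})

test_that("clustering is invariant under gene-order permutation", {
  set.seed(41)
  v <- matrix(rpois(20 * 13, 30), 20, 13,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  m1 <- count_matrix(v, normalization = "raw")
  m2 <- count_matrix(v[sample(20), ], normalization = "raw")
  c1 <- cluster_profiles(m1)
  c2 <- cluster_profiles(m2)
  expect_equal(c1$hclust$height, c2$hclust$height)
  expect_equal(c1$labels, c2$labels)
  expect_equal(cut_profiles(c1, 4), cut_profiles(c2, 4))
})

test_that("stage totals are column sums over the requested subset", {
  v <- matrix(1, 98, 13, dimnames = list(sprintf("g%02d", 1:98),
                                         paste0("s", 1:13)))
  m <- count_matrix(v, library_sizes = rep(1e6, 13), normalization = "rpm")
  expect_equal(unname(stage_totals(m)), rep(98, 13))
  expect_equal(unname(stage_totals(m, "g01")), rep(1, 13))
  expect_error(stage_totals(m, c("g01", "nope")), "unknown gene")

  set.seed(52)
  rv <- matrix(runif(30 * 13, 0, 50), 30, 13,
               dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:13)))
  rm_ <- count_matrix(rv, library_sizes = rep(1e6, 13),
                      normalization = "rpm")
  subset <- sample(rownames(rv), 10)
  expect_equal(stage_totals(rm_, subset), colSums(rv[subset, ]))
})

test_that("fraction transform normalizes rows, keeps zeros, and is idempotent", {
  v <- rbind(g1 = c(1, 1, 2), g2 = c(0, 0, 0), g3 = c(4, 0, 0))
  m <- count_matrix(v, normalization = "raw")
  f <- fraction_transform(m)
  expect_equal(unname(f$values["g1", ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(f$values["g2", ]), c(0, 0, 0))
  expect_equal(f$normalization, "fraction")
  # idempotence
  f2 <- fraction_transform(f)
  expect_equal(f2$values, f$values)
  # row-max variant
  fm <- fraction_transform(m, by = "max")
  expect_equal(unname(fm$values["g1", ]), c(0.5, 0.5, 1))

  set.seed(53)
  rv <- matrix(runif(25 * 13), 25, 13)
  fr <- fraction_transform(count_matrix(rv, normalization = "raw"))
  expect_equal(unname(rowSums(fr$values)), rep(1, 25), tolerance = 1e-9)
})

test_that("count matrices read back from TSV with matched library sizes", {
  counts <- system.file("extdata", "synthetic_pnp_counts.tsv",
                        package = "pnpkit")
  libs <- system.file("extdata", "synthetic_library_sizes.tsv",
                      package = "pnpkit")
  lens <- system.file("extdata", "synthetic_pnp_lengths.tsv",
                      package = "pnpkit")
  m <- read_count_matrix(counts, libs, lens)
  expect_equal(dim(m), c(98L, 13L))
  expect_equal(m$normalization, "raw")
  expect_equal(length(m$library_sizes), 13L)
  expect_equal(names(m$library_sizes), colnames(m$values))
  expect_equal(length(m$lengths), 98L)
})
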