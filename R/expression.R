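#' Construct a gene-by-stage count matrix
#'
#' Container for pNP expression data: a non-negative gene x stage value
#' matrix with per-stage library sizes, optional per-gene transcript
#' lengths, and a normalization state (`raw`, `rpm`, `rpkm` or
#' `fraction`).
#'
#' @param values Numeric matrix with gene row names and stage column names.
#' @param library_sizes Per-stage positive totals (named or in column
#'   order); required for any normalization other than `raw`.
#' @param lengths Optional per-gene transcript length in bases.
#' @param normalization Normalization state of `values`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(values, library_sizes = NULL, lengths = NULL,
                         normalization = c("raw", "rpm", "rpkm",
                                           "fraction")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0L) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(colnames(values)) && ncol(values) > 0L) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (any(values < 0)) stop("count values must be non-negative")
  if (!is.null(library_sizes)) {
    if (length(library_sizes) != ncol(values)) {
      stop("library_sizes length must equal the number of stages")
    }
    if (any(library_sizes <= 0)) stop("library sizes must be positive")
    library_sizes <- stats::setNames(as.numeric(library_sizes),
                                     colnames(values))
  } else if (normalization %in% c("rpm", "rpkm")) {
    stop("library_sizes required for ", normalization, " matrices")
  }
  if (!is.null(lengths)) {
    if (length(lengths) != nrow(values)) {
      stop("lengths must have one entry per gene")
    }
    lengths <- stats::setNames(as.numeric(lengths), rownames(values))
  }
  structure(list(values = values, library_sizes = library_sizes,
                 lengths = lengths, normalization = normalization),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " stages (", x$normalization, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a count matrix and its library sizes from TSV files
#'
#' @param counts_path Counts table (first column gene ids, one numeric
#'   column per stage).
#' @param libsize_path Two-column stage / total-reads table; matched to
#'   count columns by stage name when names agree, else by order.
#' @param lengths_path Optional two-column gene / length table.
#' @return A raw [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, libsize_path,
                              lengths_path = NULL) {
  tab <- read_table(counts_path, "counts")
  if (!nrow(tab)) stop("counts table is empty: ", counts_path)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  libs <- read_table(libsize_path, "library_size")
  sizes <- stats::setNames(libs$total_reads, libs$stage)
  if (all(colnames(values) %in% names(sizes))) {
    sizes <- sizes[colnames(values)]
  } else if (length(sizes) == ncol(values)) {
    names(sizes) <- colnames(values)
  } else {
    stop("library sizes do not match count columns")
  }
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- read_table(lengths_path, "library_size")
    lv <- stats::setNames(lt[[2L]], lt[[1L]])
    if (!all(rownames(values) %in% names(lv))) {
      stop("lengths table missing entries for some genes")
    }
    lengths <- lv[rownames(values)]
  }
  count_matrix(values, library_sizes = sizes, lengths = lengths,
               normalization = "raw")
}

#' Normalize counts to rpm or RPKM
#'
#' Reads per million: `rpm = raw / library_size * 1e6`, correcting for
#' sequencing depth. RPKM additionally divides by transcript length in
#' kilobases: `rpkm = rpm * 1e3 / length`.
#'
#' @param m Raw [count_matrix()].
#' @param mode `"rpm"` or `"rpkm"` (the latter requires `lengths`).
#' @return Normalized [count_matrix()].
#' @export
normalize_counts <- function(m, mode = c("rpm", "rpkm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalization != "raw") {
    stop("normalize_counts expects a raw matrix, got ", m$normalization)
  }
  if (is.null(m$library_sizes)) stop("library_sizes required")
  if (any(m$library_sizes == 0)) stop("zero library size")
  v <- sweep(m$values, 2L, m$library_sizes, `/`) * 1e6
  if (mode == "rpkm") {
    if (is.null(m$lengths)) stop("gene lengths required for rpkm")
    v <- sweep(v, 1L, m$lengths / 1e3, `/`)
  }
  count_matrix(v, library_sizes = m$library_sizes, lengths = m$lengths,
               normalization = mode)
}

#' Filter genes on minimum expression
#'
#' Retains genes with at least `min_rpm` in at least one stage (inclusive
#' boundary), the standard low-expression filter applied before profile
#' clustering. Gene order is preserved.
#'
#' @param m An rpm-normalized [count_matrix()].
#' @param min_rpm Minimum rpm (default 2).
#' @return Filtered [count_matrix()].
#' @export
filter_min_expression <- function(m, min_rpm = 2) {
  stopifnot(inherits(m, "count_matrix"), min_rpm >= 0)
  if (m$normalization != "rpm") {
    stop("filter_min_expression expects an rpm matrix, got ",
         m$normalization)
  }
  keep <- apply(m$values, 1L, max) >= min_rpm
  count_matrix(m$values[keep, , drop = FALSE],
               library_sizes = m$library_sizes,
               lengths = if (!is.null(m$lengths)) m$lengths[keep],
               normalization = "rpm")
}

#' Hierarchically cluster stage-expression profiles
#'
#' Pairwise distance between genes is one minus the Pearson correlation of
#' their stage profiles; agglomeration uses [stats::hclust()] under the
#' chosen linkage (average by default). Genes are ordered
#' lexicographically before clustering so the result does not depend on
#' input order; zero-variance profiles are assigned the maximal distance 1
#' to all others rather than raising an error, so constant low-expressors
#' cluster together.
#'
#' @param m A [count_matrix()] with at least two genes and two stages.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return Object of class `profile_clust` wrapping the `hclust` result,
#'   with `distance_metric = "pearson"`.
#' @export
cluster_profiles <- function(m, linkage = c("average", "complete",
                                            "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(m, "count_matrix"))
  v <- m$values
  if (nrow(v) < 2L) stop("at least two genes required for clustering")
  if (ncol(v) < 2L) stop("at least two stages required for clustering")
  v <- v[order(rownames(v)), , drop = FALSE]
  d <- pearson_distance(v)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(hclust = hc, distance_metric = "pearson",
                 linkage = linkage, labels = rownames(v)),
            class = "profile_clust")
}

# 1 - Pearson correlation between rows; zero-variance rows at distance 1
pearson_distance <- function(v) {
  sds <- apply(v, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[is.na(cc)] <- 0
  d <- 1 - cc
  zero <- which(sds == 0)
  if (length(zero)) {
    d[zero, ] <- 1
    d[, zero] <- 1
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(v), rownames(v))
  d
}

#' @export
print.profile_clust <- function(x, ...) {
  cat("<profile_clust> ", length(x$labels), " genes, 1 - Pearson distance, ",
      x$linkage, " linkage\n", sep = "")
  invisible(x)
}

#' @export
as.hclust.profile_clust <- function(x, ...) x$hclust

#' @export
plot.profile_clust <- function(x, ...) plot(x$hclust, ...)

#' Cut a profile clustering into k groups
#' @param clust A `profile_clust`.
#' @param k Number of groups.
#' @return Named integer vector of group labels.
#' @export
cut_profiles <- function(clust, k) {
  stats::cutree(clust$hclust, k = k)
}

#' Per-stage expression totals
#'
#' Sums rpm values over a gene subset per stage, the quantity plotted as a
#' stage-specific expression overview.
#'
#' @param m An rpm-normalized [count_matrix()].
#' @param gene_subset Gene identifiers to sum over (default all genes).
#' @return Named numeric vector of per-stage totals.
#' @export
stage_totals <- function(m, gene_subset = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalization != "rpm") {
    stop("stage_totals expects an rpm matrix, got ", m$normalization)
  }
  if (is.null(gene_subset)) gene_subset <- rownames(m$values)
  missing <- setdiff(gene_subset, rownames(m$values))
  if (length(missing)) {
    stop("unknown gene id in subset: ", sQuote(missing[1L]))
  }
  colSums(m$values[gene_subset, , drop = FALSE])
}

#' Transform each profile to a fraction of one
#'
#' Divides each gene row by its row sum so profiles become comparable in
#' shape regardless of absolute level; all-zero rows stay all-zero. Row-max
#' scaling is offered as an alternative reading of "transformed to 1".
#'
#' @param m A [count_matrix()] with non-negative values.
#' @param by `"sum"` (default) or `"max"`.
#' @return A [count_matrix()] with `normalization = "fraction"`.
#' @export
fraction_transform <- function(m, by = c("sum", "max")) {
  by <- match.arg(by)
  stopifnot(inherits(m, "count_matrix"))
  v <- m$values
  denom <- if (by == "sum") rowSums(v) else apply(v, 1L, max)
  denom[denom == 0] <- 1  # all-zero rows stay all-zero
  v <- sweep(v, 1L, denom, `/`)
  count_matrix(v, library_sizes = m$library_sizes, lengths = m$lengths,
               normalization = "fraction")
}
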