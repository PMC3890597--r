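#' Build a similarity cluster map from pairwise hits
#'
#' Takes imported pairwise similarity hits (BLAST tabular dialect), keeps
#' the minimum e-value per unordered pair, retains edges with
#' `evalue < threshold` (strict inequality, matching map legends of the
#' form "connections of P value < 1e-10"), and extracts connected
#' components. Unconnected sequences can optionally be dropped, as
#' published maps remove nodes without connections.
#'
#' @param hits Data frame with at least `query_id`, `subject_id` and
#'   `evalue` columns, as read by [read_table()] with kind
#'   `"similarity_hit"`. Self-hits are ignored.
#' @param threshold Positive e-value threshold; edges survive when their
#'   best e-value is strictly below it.
#' @param drop_singletons Remove single-node components (default `FALSE`).
#' @return Object of class `cluster_map`: `nodes`, `edges` (data frame
#'   `a`, `b`, `evalue`), `threshold`, `membership` (named integer vector),
#'   `components` (list of identifier vectors, largest first) and
#'   `singletons_removed`.
#' @export
build_cluster_map <- function(hits, threshold, drop_singletons = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive number")
  }
  q <- as.character(hits$query_id)
  s <- as.character(hits$subject_id)
  ev <- as.numeric(hits$evalue)
  keep <- q != s
  q <- q[keep]; s <- s[keep]; ev <- ev[keep]
  nodes <- sort(unique(c(q, s)))

  if (length(q)) {
    a <- pmin(q, s)
    b <- pmax(q, s)
    key <- paste(a, b, sep = "\r")
    best <- tapply(ev, key, min)
    pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
    edges <- data.frame(a = pairs[, 1L], b = pairs[, 2L],
                        evalue = as.numeric(best),
                        stringsAsFactors = FALSE, row.names = NULL)
    edges <- edges[edges$evalue < threshold, , drop = FALSE]
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    row.names(edges) <- NULL
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        evalue = numeric(0))
  }

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$a, nodes),
                                    match(edges$b, nodes)))
  }
  comp <- igraph::components(g)
  membership <- stats::setNames(as.integer(comp$membership), nodes)

  if (drop_singletons) {
    sizes <- table(membership)
    keep_comp <- as.integer(names(sizes)[sizes >= 2L])
    keep_nodes <- names(membership)[membership %in% keep_comp]
    nodes <- nodes[nodes %in% keep_nodes]
    membership <- membership[nodes]
    # renumber components compactly
    membership <- stats::setNames(as.integer(factor(membership)), nodes)
  }
  components <- split(names(membership), membership)
  components <- components[order(-lengths(components))]
  names(components) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 membership = membership, components = components,
                 singletons_removed = isTRUE(drop_singletons)),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("<cluster_map> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges at e-value < ", format(x$threshold), "\n", sep = "")
  sizes <- lengths(x$components)
  cat("  ", length(sizes), " components; sizes: ",
      paste(utils::head(sizes, 10L), collapse = ", "),
      if (length(sizes) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Curated peptide-family motifs
#'
#' The default motif table covering classical family-defining patterns:
#' the Wamide/MIP two-tryptophan pattern `xWx{6,7}W[GIL]` at the
#' C-terminus, and the C-terminally amidated RFamide (`R[FY]`), FVamide,
#' RGWamide and FVRIamide families. Users can extend the table with
#' additional rows or load one from YAML via [read_family_motifs()].
#'
#' Motif grammar (deliberately smaller than full regular expressions so
#' motifs stay auditable): fixed residues (`W`), bracketed residue classes
#' (`[GIL]`), `x` for any residue, `x{m,n}` / `x{m}` ranged spacers, and an
#' optional `$` anchoring the match at the C-terminus.
#'
#' @return Data frame with columns `family_name`, `pattern`,
#'   `requires_amidation`.
#' @export
default_family_motifs <- function() {
  data.frame(
    family_name = c("Wamide/MIP", "FVRIamide", "RGWamide", "FVamide",
                    "RFamide"),
    pattern = c("xWx{6,7}W[GIL]$", "FVRI$", "RGW$", "FV$", "R[FY]$"),
    requires_amidation = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Read a family motif table from YAML
#'
#' Expects a list of entries with `family_name`, `pattern` and optionally
#' `requires_amidation` (default `FALSE`). Patterns are validated at load
#' time.
#'
#' @param path Path to a YAML file.
#' @return Data frame as [default_family_motifs()].
#' @export
read_family_motifs <- function(path) {
  entries <- yaml::read_yaml(path)
  df <- data.frame(
    family_name = vapply(entries, `[[`, character(1), "family_name"),
    pattern = vapply(entries, `[[`, character(1), "pattern"),
    requires_amidation = vapply(entries, function(e)
      isTRUE(e$requires_amidation), logical(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$family_name)) stop("duplicate family_name in ", path)
  for (p in df$pattern) motif_to_regex(p)
  df
}

#' Compile a family motif to a regular expression
#'
#' @param pattern Motif in the grammar of [default_family_motifs()].
#' @return A regular expression string.
#' @export
motif_to_regex <- function(pattern) {
  rest <- pattern
  out <- character(0)
  while (nzchar(rest)) {
    if (grepl("^x\\{[0-9]+(,[0-9]+)?\\}", rest)) {
      m <- regmatches(rest, regexpr("^x\\{[0-9]+(,[0-9]+)?\\}", rest))
      out <- c(out, sub("^x", "[A-Z]", m))
      rest <- substr(rest, nchar(m) + 1L, nchar(rest))
    } else if (grepl("^x", rest)) {
      out <- c(out, "[A-Z]")
      rest <- substr(rest, 2L, nchar(rest))
    } else if (grepl("^\\[[A-Z]+\\]", rest)) {
      m <- regmatches(rest, regexpr("^\\[[A-Z]+\\]", rest))
      out <- c(out, m)
      rest <- substr(rest, nchar(m) + 1L, nchar(rest))
    } else if (grepl("^[A-Z]", rest)) {
      out <- c(out, substr(rest, 1L, 1L))
      rest <- substr(rest, 2L, nchar(rest))
    } else if (rest == "$") {
      out <- c(out, "$")
      rest <- ""
    } else {
      stop("unparseable motif pattern: ", sQuote(pattern))
    }
  }
  paste(out, collapse = "")
}

#' Assign peptides to named families by motif
#'
#' The first matching motif in table order wins per peptide; peptides
#' matching nothing are `"unassigned"`. Motifs requiring amidation only
#' match amidated peptides.
#'
#' @param peptides Data frame from [liberate_peptides()] (needs `sequence`
#'   and `amidated`), or a character vector of sequences (then treated as
#'   non-amidated unless `amidated` is given).
#' @param motifs Motif table, default [default_family_motifs()].
#' @param amidated Optional logical vector when `peptides` is a character
#'   vector.
#' @return Character vector of family names, one per peptide.
#' @export
assign_family <- function(peptides, motifs = default_family_motifs(),
                          amidated = NULL) {
  if (is.character(peptides)) {
    seqs <- toupper(peptides)
    ami <- if (is.null(amidated)) rep(FALSE, length(seqs)) else amidated
  } else {
    seqs <- peptides$sequence
    ami <- peptides$amidated
  }
  regexes <- vapply(motifs$pattern, motif_to_regex, character(1))
  fam <- rep("unassigned", length(seqs))
  for (i in seq_along(seqs)) {
    for (j in seq_len(nrow(motifs))) {
      if (motifs$requires_amidation[j] && !ami[i]) next
      if (grepl(regexes[j], seqs[i])) {
        fam[i] <- motifs$family_name[j]
        break
      }
    }
  }
  fam
}

#' Assign precursors to families by majority over their peptides
#'
#' The precursor-level family is the modal family among its assigned
#' peptides; precursors with no assigned peptide, or with a tie for the
#' mode, are `"unassigned"`.
#'
#' @param peptides Data frame from [liberate_peptides()] covering one or
#'   more precursors.
#' @param motifs Motif table, default [default_family_motifs()].
#' @return Data frame with `precursor_id` and `family`.
#' @export
assign_precursor_family <- function(peptides,
                                    motifs = default_family_motifs()) {
  fam <- assign_family(peptides, motifs)
  ids <- unique(peptides$precursor_id)
  out <- vapply(ids, function(id) {
    f <- fam[peptides$precursor_id == id]
    f <- f[f != "unassigned"]
    if (!length(f)) return("unassigned")
    tab <- sort(table(f), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) return("unassigned")
    names(tab)[1L]
  }, character(1))
  data.frame(precursor_id = ids, family = unname(out),
             stringsAsFactors = FALSE)
}
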