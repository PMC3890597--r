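#' Default pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param transcripts,proteins Paths to the input FASTA (supply one; when
#'   both are given, `proteins` is used directly and ORF calling is
#'   skipped).
#' @param sp,ms,domains,hits,counts,library_sizes,lengths Optional paths to
#'   imported annotation tables (see [read_table()] for the formats).
#' @param min_protein_length Proteome length cutoff in residues (default
#'   120).
#' @param allow_open_ended Allow stop-free ORF fallback (default `TRUE`).
#' @param processing A [processing_config()] or a list of its arguments.
#' @param motifs Family motif table (data frame) or path to a YAML table.
#' @param cluster_threshold E-value threshold for the similarity map
#'   (default `1e-10`).
#' @param drop_singletons Drop unconnected nodes from the map.
#' @param min_rpm Expression filter threshold (default 2).
#' @param linkage Profile-clustering linkage (default `"average"`).
#' @param cluster_on `"rpkm"` (default, used when gene lengths are
#'   available) or `"rpm"`.
#' @param fraction_by `"sum"` or `"max"` for the fraction transform.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            transcripts = NULL, proteins = NULL,
                            sp = NULL, ms = NULL, domains = NULL,
                            hits = NULL, counts = NULL,
                            library_sizes = NULL, lengths = NULL,
                            min_protein_length = 120L,
                            allow_open_ended = TRUE,
                            processing = processing_config(),
                            motifs = NULL,
                            cluster_threshold = 1e-10,
                            drop_singletons = FALSE,
                            min_rpm = 2,
                            linkage = "average",
                            cluster_on = c("rpkm", "rpm"),
                            fraction_by = c("sum", "max"),
                            seed = 1L) {
  if (is.list(processing) && !inherits(processing, "processing_config")) {
    processing <- do.call(processing_config, processing)
  }
  structure(list(out_dir = out_dir, transcripts = transcripts,
                 proteins = proteins, sp = sp, ms = ms, domains = domains,
                 hits = hits, counts = counts,
                 library_sizes = library_sizes, lengths = lengths,
                 min_protein_length = as.integer(min_protein_length),
                 allow_open_ended = isTRUE(allow_open_ended),
                 processing = processing, motifs = motifs,
                 cluster_threshold = cluster_threshold,
                 drop_singletons = isTRUE(drop_singletons),
                 min_rpm = min_rpm, linkage = linkage,
                 cluster_on = match.arg(cluster_on),
                 fraction_by = match.arg(fraction_by),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [pipeline_config()]; the `processing`
#' key may hold a mapping of [processing_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full discovery pipeline
#'
#' Executes, in order: ORF calling on transcripts (skipped when a protein
#' FASTA is supplied), secretome gating with in-silico SP removal,
#' precursor processing (cleavage sites, peptide liberation, repeat scan,
#' MS matching, qualification), family assignment, similarity-map
#' clustering when pairwise hits are supplied, and expression profiling
#' when a count table is supplied. All tabular outputs are TSV with a
#' header line; a JSON manifest lists every output file with its row count
#' and a hash of the configuration, so identical configurations produce
#' identical manifests. On a stage failure, files already written by the
#' failing stage are renamed with a `.partial` suffix before the error
#' propagates.
#'
#' @param config A `pipeline_config` (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (field in c("transcripts", "proteins", "sp", "ms", "domains",
                  "hits", "counts", "library_sizes", "lengths")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input path for ", sQuote(field), " does not exist: ", p)
    }
  }
  if (is.null(config$transcripts) && is.null(config$proteins)) {
    stop("either transcripts or proteins input is required")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(files = list(), config_hash = config_hash(config),
                   seed = config$seed, stages = character(0))
  written <- character(0)
  emit <- function(name, df) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    written <<- c(written, path)
    manifest$files[[name]] <<- list(path = path, rows = nrow(df))
  }
  run_stage <- function(name, expr) {
    written <<- character(0)
    tryCatch(expr, error = function(e) {
      for (p in written) file.rename(p, paste0(p, ".partial"))
      stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
  }

  # --- orfs ---------------------------------------------------------------
  proteins <- NULL
  run_stage("orfs", {
    if (!is.null(config$proteins)) {
      proteins <- read_fasta(config$proteins, "protein")
    } else {
      transcripts <- read_fasta(config$transcripts, "nucleotide")
      res <- predict_proteome(transcripts, config$min_protein_length,
                              config$allow_open_ended)
      proteins <- res$proteins
      emit("orfs.tsv", res$orfs)
      fa <- file.path(config$out_dir, "proteome.fasta")
      write_fasta(res$proteins, fa)
      written <- c(written, fa)
      manifest$files[["proteome.fasta"]] <-
        list(path = fa, rows = length(res$proteins))
    }
  })

  # --- secretome ----------------------------------------------------------
  sec <- NULL
  run_stage("secretome", {
    imported <- if (!is.null(config$sp))
      read_table(config$sp, "signal_peptide")
    sec <- predict_secretome(proteins, imported)
    emit("signal_peptides.tsv", sec$sp)
    fa <- file.path(config$out_dir, "secretome.fasta")
    write_fasta(sec$secretome, fa)
    written <- c(written, fa)
    manifest$files[["secretome.fasta"]] <-
      list(path = fa, rows = length(sec$secretome))
  })

  # --- process ------------------------------------------------------------
  peptides <- NULL
  run_stage("process", {
    ms <- if (!is.null(config$ms)) read_table(config$ms, "ms_peptide")
    domains <- if (!is.null(config$domains))
      read_table(config$domains, "domain_hit")
    pep_list <- list()
    sum_rows <- list()
    for (p in proteins) {
      ann <- annotate_precursor(p, sec$annotations[[p$id]],
                                config$processing)
      ann <- qualify_precursor(ann, domains)
      pep <- ann$peptides
      if (!is.null(ms) && nrow(pep)) pep <- match_ms_evidence(pep, ms)
      pep_list[[p$id]] <- pep
      sum_rows[[p$id]] <- data.frame(
        precursor_id = p$id, length = nchar(p$seq),
        sp_end = if (is.null(ann$sp)) NA_integer_ else ann$sp$sp_end,
        n_sites = nrow(ann$sites), n_peptides = nrow(pep),
        repetitive = ann$repetitive,
        evidence = paste(ann$evidence, collapse = ","),
        qualified = ann$qualified,
        rejection_reasons = paste(ann$rejection_reasons, collapse = "; "),
        stringsAsFactors = FALSE)
    }
    peptides <- do.call(rbind, c(pep_list, list(make.row.names = FALSE)))
    if (is.null(peptides)) peptides <- liberate_peptides(
      seq_record("empty", "AAA", "protein"))[0, ]
    emit("peptides.tsv", peptides)
    emit("precursors.tsv",
         do.call(rbind, c(sum_rows, list(make.row.names = FALSE))))
  })

  # --- families -----------------------------------------------------------
  run_stage("families", {
    motifs <- config$motifs
    if (is.null(motifs)) motifs <- default_family_motifs()
    else if (is.character(motifs)) motifs <- read_family_motifs(motifs)
    pf <- peptides
    pf$family <- assign_family(peptides, motifs)
    emit("peptide_families.tsv",
         pf[, c("precursor_id", "sequence", "amidated", "family")])
    emit("precursor_families.tsv", assign_precursor_family(peptides, motifs))
  })

  # --- cluster ------------------------------------------------------------
  if (!is.null(config$hits)) {
    run_stage("cluster", {
      hits <- read_table(config$hits, "similarity_hit")
      map <- build_cluster_map(hits, config$cluster_threshold,
                               config$drop_singletons)
      emit("cluster_components.tsv",
           data.frame(id = names(map$membership),
                      component = as.integer(map$membership)))
      emit("cluster_edges.tsv", map$edges)
    })
  }

  # --- profile ------------------------------------------------------------
  if (!is.null(config$counts)) {
    run_stage("profile", {
      if (is.null(config$library_sizes)) {
        stop("library_sizes input is required with counts")
      }
      m <- read_count_matrix(config$counts, config$library_sizes,
                             config$lengths)
      rpm <- normalize_counts(m, "rpm")
      kept <- filter_min_expression(rpm, config$min_rpm)
      emit("stage_totals.tsv",
           data.frame(stage = colnames(rpm$values),
                      total_rpm = as.numeric(stage_totals(rpm))))
      emit("retained_genes.tsv",
           data.frame(gene_id = rownames(kept$values)))
      use <- if (config$cluster_on == "rpkm" && !is.null(m$lengths)) {
        raw_kept <- count_matrix(
          m$values[rownames(kept$values), , drop = FALSE],
          library_sizes = m$library_sizes,
          lengths = m$lengths[rownames(kept$values)],
          normalization = "raw")
        normalize_counts(raw_kept, "rpkm")
      } else kept
      cl <- cluster_profiles(use, config$linkage)
      hc <- cl$hclust
      emit("merge_tree.tsv",
           data.frame(step = seq_len(nrow(hc$merge)),
                      left = hc$merge[, 1], right = hc$merge[, 2],
                      height = hc$height))
      frac <- fraction_transform(use, config$fraction_by)
      emit("fraction_matrix.tsv",
           data.frame(gene_id = rownames(frac$values), frac$values,
                      check.names = FALSE))
      emit("rpm_matrix.tsv",
           data.frame(gene_id = rownames(kept$values), kept$values,
                      check.names = FALSE))
    })
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# stable hash of the configuration: canonical JSON, md5 via tools::md5sum
config_hash <- function(config) {
  x <- unclass(config)
  x$processing <- unclass(x$processing)
  x <- x[order(names(x))]
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}
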