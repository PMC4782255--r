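#' Aligned barcode sequences
#'
#' Container for a gap-free alignment of equal-length DNA barcode sequences
#' (the data model is a pruned mitochondrial COI fragment, typically 644 bp).
#' Sequences are stored uppercased, in input order, named by sample id.
#'
#' @param ids character vector of unique sample ids.
#' @param seqs character vector of sequences over \{A,C,G,T\}, same length as
#'   `ids`, all of one common length.
#' @param allow_ambiguous if `TRUE`, IUPAC ambiguity codes are accepted and
#'   later treated as mismatches in all distance computations; by default any
#'   non-ACGT character is an error.
#' @return an object of class `aligned_seqs`: a list with elements `ids`,
#'   `seq` (named character vector) and `L` (alignment length).
#' @export
aligned_seqs <- function(ids, seqs, allow_ambiguous = FALSE) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (length(seqs) == 0L)
    stop("empty alignment")
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  L <- lens[[1L]]
  if (L == 0L) stop("alignment error: zero-length sequences")
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("gap error: alignment contains '-' characters; input must be gap-free")
  allowed <- if (allow_ambiguous) "[^ACGTRYSWKMBDHVN]" else "[^ACGT]"
  bad <- grepl(allowed, seqs)
  if (any(bad))
    stop(if (allow_ambiguous) "invalid character in sequence(s): "
         else "non-ACGT character in sequence(s) (use allow_ambiguous = TRUE for IUPAC codes): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  structure(list(ids = ids, seq = setNames(seqs, ids), L = L),
            class = "aligned_seqs")
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("Aligned sequences:", length(x$ids), "samples x", x$L, "bp\n")
  invisible(x)
}

#' Read a gap-free FASTA alignment
#'
#' @param path path to a FASTA file of pre-aligned, equal-length sequences.
#' @inheritParams aligned_seqs
#' @return an [aligned_seqs] object, records in file order.
#' @export
read_alignment <- function(path, allow_ambiguous = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty alignment: ", path)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  aligned_seqs(names(dna), seqs, allow_ambiguous = allow_ambiguous)
}

#' Write an alignment to FASTA
#'
#' @param alignment an [aligned_seqs] object.
#' @param path output path.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", alignment$ids, "\n", unname(alignment$seq)), con)
  invisible(path)
}

.meta_cols <- c("sample_id", "species", "site_id", "site_type",
                "latitude", "longitude", "mat_side", "zoogeo_category")
.island_cols <- c("site_id", "area", "latitude", "longitude", "mat_side")

#' Read the per-sample metadata table
#'
#' Tab-separated, one row per sample, with header columns `sample_id`,
#' `species`, `site_id`, `site_type` (island/mainland), `latitude`,
#' `longitude`, `mat_side` (W/E of the trench) and `zoogeo_category`
#' (Balkan / Anatolian / Wide / COL). Cross-referenced against the alignment:
#' every sequenced sample must have a metadata row; metadata rows without a
#' sequence are dropped with a warning.
#'
#' @param path path to the TSV file.
#' @param alignment optional [aligned_seqs] to cross-reference against.
#' @return a data.frame of validated sample records.
#' @export
read_metadata <- function(path, alignment = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df, alignment)
}

#' Validate an in-memory sample metadata table
#'
#' @param df data.frame with the columns documented in [read_metadata()].
#' @param alignment optional [aligned_seqs] to cross-reference against.
#' @return the validated (possibly subset) data.frame.
#' @export
validate_metadata <- function(df, alignment = NULL) {
  miss <- setdiff(.meta_cols, names(df))
  if (length(miss))
    stop("schema error: metadata lacks column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- trimws(as.character(df$sample_id))
  df$site_id <- trimws(as.character(df$site_id))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  if (!all(df$site_type %in% c("island", "mainland")))
    stop("schema error: site_type must be 'island' or 'mainland'")
  if (any(is.na(df$mat_side)) || !all(df$mat_side %in% c("W", "E")))
    stop("schema error: mat_side must be 'W' or 'E' for every sample")
  if (!all(df$zoogeo_category %in% c("Balkan", "Anatolian", "Wide", "COL")))
    stop("schema error: unknown zoogeo_category value(s)")
  if (!is.null(alignment)) {
    absent <- setdiff(alignment$ids, df$sample_id)
    if (length(absent))
      stop("cross-reference error: sample(s) in alignment missing from metadata: ",
           paste(utils::head(absent, 5L), collapse = ", "))
    extra <- setdiff(df$sample_id, alignment$ids)
    if (length(extra)) {
      warning(length(extra), " metadata row(s) without sequence dropped")
      df <- df[df$sample_id %in% alignment$ids, , drop = FALSE]
    }
    df <- df[match(alignment$ids, df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read the island attribute table
#'
#' Tab-separated with header columns `site_id`, `area` (km^2), `latitude`,
#' `longitude`, `mat_side`. Areas must be positive.
#'
#' @param path path to the TSV file.
#' @return a validated data.frame of island attributes.
#' @export
read_islands <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_islands(read.delim(path, stringsAsFactors = FALSE))
}

#' Validate an in-memory island attribute table
#'
#' @param df data.frame with the columns documented in [read_islands()].
#' @return the validated data.frame.
#' @export
validate_islands <- function(df) {
  miss <- setdiff(.island_cols, names(df))
  if (length(miss))
    stop("schema error: island table lacks column(s): ", paste(miss, collapse = ", "))
  df$site_id <- trimws(as.character(df$site_id))
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in island table")
  if (any(!is.finite(df$area)) || any(df$area <= 0))
    stop("schema error: island area must be > 0")
  if (!all(df$mat_side %in% c("W", "E")))
    stop("schema error: mat_side must be 'W' or 'E'")
  df
}

#' Write a parsimony network to GraphML and TSV edge/node lists
#'
#' @param net a `parsimony_network` object from [build_network()].
#' @param prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv` and `<prefix>_nodes.tsv`.
#' @export
write_network <- function(net, prefix) {
  g <- net$graph
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  nd <- igraph::as_data_frame(g, what = "vertices")
  write.table(el, paste0(prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(nd, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read back a GraphML network written by [write_network()]
#'
#' @param path path to the `.graphml` file.
#' @return an igraph graph.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write a tree in Newick format (bootstrap support as node labels)
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write all pipeline results to a directory
#'
#' Emits, for each component present in `results`: per-species haplotype
#' tables and networks, the combined tree (Newick), beta-diversity pair table
#' and matrices, the Mantel/partitioning report, the congruence report, and a
#' JSON run manifest holding the seed and parameters.
#'
#' @param results a result bundle from [run_all()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  written <- character()
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  mat_tsv <- function(m, name) {
    p <- file.path(out_dir, name)
    write.table(data.frame(site_id = rownames(m), m, check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  for (sp in names(results$species)) {
    r <- results$species[[sp]]
    tsv(haplotype_table(r$haplotypes), paste0(sp, "_haplotypes.tsv"))
    if (!is.null(r$network)) {
      write_network(r$network, file.path(out_dir, paste0(sp, "_network")))
      written <- c(written, file.path(out_dir, paste0(sp, "_network.graphml")))
    }
  }
  if (!is.null(results$congruence)) tsv(results$congruence, "congruence.tsv")
  if (!is.null(results$tree)) {
    write_tree_newick(results$tree, file.path(out_dir, "combined_nj.nwk"))
    written <- c(written, file.path(out_dir, "combined_nj.nwk"))
  }
  if (!is.null(results$beta)) {
    tsv(results$beta$pairs, "beta_pairs.tsv")
    mat_tsv(results$beta$total, "beta_total.tsv")
    mat_tsv(results$beta$repl, "beta_repl.tsv")
    mat_tsv(results$beta$rich, "beta_rich.tsv")
  }
  if (!is.null(results$barrier_tests)) tsv(results$barrier_tests, "barrier_tests.tsv")
  manifest <- list(seed = results$config$seed,
                   parameters = results$config[setdiff(names(results$config), "seed")],
                   r_version = as.character(getRversion()))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(written, mp))
}
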