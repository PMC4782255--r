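#' Pipeline configuration
#'
#' Defaults equal the study-stated parameters: 95% parsimony connection
#' confidence, 10,000 Mantel permutations, 1,000 bootstrap replicates, a
#' 2.3%/My clock, islands-only beta analyses.
#'
#' @param mode `"per-species"`, `"combined"`, or `"both"`.
#' @param confidence parsimony connection confidence.
#' @param n_perm Mantel permutations.
#' @param bootstrap NJ bootstrap replicates for the combined tree (0 = off;
#'   off by default because support values feed no downstream statistic).
#' @param clock_rate percent divergence per million years.
#' @param islands_only restrict beta/Mantel analyses to island sites.
#' @param max_steps optional manual connection-limit override.
#' @param seed RNG seed recorded in the manifest and driving all
#'   permutation and bootstrap streams.
#' @param out_dir optional output directory for [write_outputs()].
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("both", "per-species", "combined"),
                       confidence = 0.95, n_perm = 10000, bootstrap = 0,
                       clock_rate = 2.3, islands_only = TRUE,
                       max_steps = NULL, seed = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (confidence <= 0 || confidence >= 1) stop("domain error: confidence in (0,1)")
  if (n_perm < 1 || bootstrap < 0 || clock_rate <= 0)
    stop("domain error: invalid numeric parameter")
  structure(list(mode = mode, confidence = confidence, n_perm = n_perm,
                 bootstrap = bootstrap, clock_rate = clock_rate,
                 islands_only = islands_only, max_steps = max_steps,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' @param path JSON file with any subset of [run_config()]'s fields.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full phylogeographic analysis
#'
#' Per species: haplotype collapse, statistical-parsimony network, outgroup
#' probabilities, ancestral-locality call and zoogeographic congruence.
#' Combined: all species' haplotypes pooled (haplotypes stay species-scoped;
#' ids are prefixed, never merged across species), K2P Neighbor-Joining
#' tree, midpoint rooting, island x haplotype incidence, the three
#' phylogenetic beta-diversity matrices, and the barrier-test report
#' (Mantel / partial Mantel / hierarchical partitioning against distance,
#' trench and area). Species present on fewer than two islands are skipped
#' by the beta stage with a logged reason; the combined beta/Mantel stage
#' requires at least four islands.
#'
#' @param alignment an [aligned_seqs] object (or a `sim_dataset`, in which
#'   case metadata and islands are taken from it).
#' @param metadata validated sample metadata.
#' @param islands validated island attribute table.
#' @param config a [run_config()].
#' @return result bundle: list with `species` (per-species haplotypes,
#'   network, ancestral call), `congruence`, `haplotypes` (pooled set),
#'   `tree`, `incidence`, `beta`, `predictors`, `barrier_tests`, `log`,
#'   `config`.
#' @export
run_all <- function(alignment, metadata = NULL, islands = NULL,
                    config = run_config()) {
  if (inherits(alignment, "sim_dataset")) {
    metadata <- alignment$metadata
    islands <- alignment$islands
    alignment <- alignment$alignment
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  metadata <- .stage("metadata", validate_metadata(metadata, alignment))
  islands <- .stage("islands", validate_islands(islands))
  logline <- character()
  say <- function(...) logline <<- c(logline, paste0(...))

  species <- unique(metadata$species)
  per_sp <- list()
  cong <- list()
  if (config$mode %in% c("per-species", "both")) {
    for (sp in species) {
      md <- metadata[metadata$species == sp, , drop = FALSE]
      aln <- aligned_seqs(md$sample_id, alignment$seq[md$sample_id])
      haps <- .stage(paste0("collapse:", sp), collapse_haplotypes(aln, md))
      jmax <- connection_limit(aln$L, config$confidence, config$max_steps)
      net <- .stage(paste0("network:", sp),
                    build_network(haps, j_max = jmax,
                                  confidence = config$confidence))
      call <- .stage(paste0("ancestral:", sp),
                     ancestral_localities(net, haps, md))
      per_sp[[sp]] <- list(haplotypes = haps, network = net,
                           ancestral = call)
      cong[[sp]] <- data.frame(
        species = sp, category = call$category,
        ancestral_haps = paste(call$hap_ids, collapse = ","),
        localities = paste(call$localities, collapse = ","),
        sides = paste(call$sides, collapse = ","),
        verdict = call$verdict, stringsAsFactors = FALSE)
      say("species ", sp, ": ", nrow(md), " samples -> ",
          nrow(haps$table), " haplotypes, j_max=", net$j_max,
          ", ancestral=", paste(call$hap_ids, collapse = "/"),
          " (", call$verdict, ")")
    }
  }

  res <- list(species = per_sp,
              congruence = if (length(cong)) do.call(rbind, cong) else NULL)
  rownames(res$congruence) <- NULL

  if (config$mode %in% c("combined", "both")) {
    # pooled haplotype set: collapse within species, prefix ids by species
    pooled_seq <- character(); pooled_id <- character()
    site_freq_list <- list()
    for (sp in species) {
      md <- metadata[metadata$species == sp, , drop = FALSE]
      aln <- aligned_seqs(md$sample_id, alignment$seq[md$sample_id])
      haps <- collapse_haplotypes(aln, md)
      pid <- paste0(sp, ".", haps$table$hap_id)
      pooled_id <- c(pooled_id, pid)
      pooled_seq <- c(pooled_seq, haps$table$sequence)
      sf <- haps$site_freq
      colnames(sf) <- pid
      site_freq_list[[sp]] <- sf
    }
    names(pooled_seq) <- pooled_id
    say("combined: ", length(pooled_id), " haplotypes across ",
        length(species), " species")
    tree <- .stage("nj", if (config$bootstrap > 0)
      nj_bootstrap(pooled_seq, reps = config$bootstrap, seed = config$seed)
      else k2p_nj(pooled_seq))
    rooted <- phangorn::midpoint(tree)
    all_sites <- sort(unique(unlist(lapply(site_freq_list, rownames))))
    inc_full <- matrix(0L, length(all_sites), length(pooled_id),
                       dimnames = list(all_sites, pooled_id))
    for (sf in site_freq_list)
      inc_full[rownames(sf), colnames(sf)] <-
        inc_full[rownames(sf), colnames(sf)] + (sf > 0)
    if (config$islands_only) {
      type <- metadata$site_type[match(rownames(inc_full), metadata$site_id)]
      inc_full <- inc_full[!is.na(type) & type == "island", , drop = FALSE]
    }
    inc <- (inc_full > 0) * 1L
    inc <- inc[rowSums(inc) > 0, , drop = FALSE]
    res$haplotypes <- pooled_seq
    res$tree <- tree
    res$incidence <- inc
    if (nrow(inc) >= 2L) {
      res$beta <- .stage("beta", beta_matrices(rooted, inc))
      say("beta: ", nrow(inc), " islands, ", nrow(res$beta$pairs), " pairs")
      isl_used <- islands[match(rownames(inc), islands$site_id), , drop = FALSE]
      if (nrow(inc) >= 4L) {
        res$predictors <- .stage("predictors", predictor_matrices(isl_used))
        res$barrier_tests <- .stage("mantel",
          barrier_tests(res$beta, res$predictors,
                        n_perm = config$n_perm, seed = config$seed))
        say("barrier tests: ", config$n_perm, " permutations")
      } else say("barrier tests skipped: fewer than 4 islands")
    } else say("beta stage skipped: fewer than 2 islands with haplotypes")
  }
  res$log <- logline
  res$config <- config
  if (!is.null(config$out_dir)) write_outputs(res, config$out_dir)
  res
}

#' Per-species congruence report
#'
#' One row per species: zoogeographic category, ancestral haplotype(s),
#' ancestral localities and the congruence verdict -- the tabular analogue
#' of marking ancestral-haplotype localities on a distribution table.
#'
#' @param results a bundle from [run_all()] (per-species mode).
#' @return data.frame.
#' @export
congruence_report <- function(results) {
  if (is.null(results$congruence))
    stop("no per-species results in bundle (run with mode 'per-species' or 'both')")
  results$congruence
}
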