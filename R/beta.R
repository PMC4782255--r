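#' Island x haplotype incidence matrix
#'
#' Presence/absence of each haplotype on each site, from the per-site
#' frequencies of a haplotype set. By default restricted to island sites
#' (the between-island analyses model interisland barriers; mainland sites
#' can be kept with `islands_only = FALSE`). Sites with no haplotype are
#' dropped.
#'
#' @param haps a `haplotype_set` collapsed with metadata.
#' @param metadata validated sample metadata (supplies `site_type`).
#' @param islands_only drop mainland sites (default TRUE).
#' @return binary matrix, sites in rows, haplotypes in columns.
#' @export
incidence_matrix <- function(haps, metadata, islands_only = TRUE) {
  if (is.null(haps$site_freq))
    stop("haplotype set lacks per-site frequencies; collapse with metadata")
  inc <- (haps$site_freq > 0) * 1L
  if (islands_only) {
    type <- metadata$site_type[match(rownames(inc), metadata$site_id)]
    inc <- inc[!is.na(type) & type == "island", , drop = FALSE]
  }
  inc <- inc[rowSums(inc) > 0, , drop = FALSE]
  inc
}

.edge_paths <- function(tree) {
  # parent edge index of every node (NA for the root)
  nn <- ape::Ntip(tree) + tree$Nnode
  pe <- match(seq_len(nn), tree$edge[, 2L])
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # edge set on the root path of each tip
  paths <- vector("list", ape::Ntip(tree))
  for (tip in seq_len(ape::Ntip(tree))) {
    e <- integer()
    node <- tip
    while (!is.na(pe[node])) {
      e <- c(e, pe[node])
      node <- parent[node]
    }
    paths[[tip]] <- e
  }
  names(paths) <- tree$tip.label
  paths
}

#' Shared and exclusive branch-length components for an island pair
#'
#' On a rooted tree, a branch belongs to an island when it lies on the
#' root-to-tip path of some haplotype present there (root paths included, so
#' single-haplotype islands carry positive phylogenetic diversity). Returns
#' `a` = branch length shared by both islands (common evolutionary history),
#' `b`/`c` = branch length exclusive to each island.
#'
#' @param tree a rooted `ape::phylo` with branch lengths (use
#'   [phangorn::midpoint()] on an unrooted NJ tree).
#' @param tips1,tips2 non-empty character vectors of tip labels present on
#'   each island.
#' @param paths optional precomputed root-path edge list from the internal
#'   cache (used by [beta_matrices()]).
#' @return list with `a`, `b`, `c`, `pd1` = a+b, `pd2` = a+c.
#' @export
pd_components <- function(tree, tips1, tips2, paths = NULL) {
  if (is.null(paths)) {
    if (!ape::is.rooted(tree)) stop("tree must be rooted (e.g. midpoint)")
    paths <- .edge_paths(tree)
  }
  if (length(tips1) == 0L || length(tips2) == 0L)
    stop("input error: empty tip set")
  bad <- setdiff(c(tips1, tips2), names(paths))
  if (length(bad))
    stop("reference error: tip(s) not in tree: ", paste(bad, collapse = ", "))
  e1 <- unique(unlist(paths[tips1], use.names = FALSE))
  e2 <- unique(unlist(paths[tips2], use.names = FALSE))
  len <- tree$edge.length
  shared <- intersect(e1, e2)
  a <- sum(len[shared])
  b <- sum(len[setdiff(e1, shared)])
  c_ <- sum(len[setdiff(e2, shared)])
  list(a = a, b = b, c = c_, pd1 = a + b, pd2 = a + c_)
}

#' Partition pairwise phylogenetic beta diversity
#'
#' From the shared (`a`) and exclusive (`b`, `c`) branch lengths of an
#' island pair: total = (b + c)/(a + b + c), replacement =
#' 2 min(b, c)/(a + b + c), richness difference = |b - c|/(a + b + c).
#' Total = replacement + richness difference exactly, and all three lie in
#' [0, 1]. A pair with a + b + c = 0 is defined as all-zero.
#'
#' @param comp a list with elements `a`, `b`, `c` (from [pd_components()]),
#'   or the value of `a` when `b` and `c` are given.
#' @param b,c exclusive branch lengths when `comp` is the scalar `a`.
#' @return named numeric vector `c(total =, repl =, rich =)`.
#' @export
beta_partition <- function(comp, b = NULL, c = NULL) {
  if (is.list(comp)) {
    a <- comp$a; b <- comp$b; c <- comp$c
  } else a <- comp
  if (any(c(a, b, c) < 0)) stop("domain error: negative branch-length component")
  tot <- a + b + c
  if (tot == 0) return(c(total = 0, repl = 0, rich = 0))
  c(total = (b + c) / tot,
    repl = 2 * min(b, c) / tot,
    rich = abs(b - c) / tot)
}

#' Pairwise beta-diversity matrices over all islands
#'
#' @param tree rooted `ape::phylo` over haplotype tips.
#' @param incidence binary island x haplotype matrix ([incidence_matrix()]);
#'   every column must be a tree tip.
#' @return list of class `beta_matrices`: symmetric zero-diagonal matrices
#'   `total`, `repl`, `rich`, plus `pairs`, a long-format data.frame with
#'   the a/b/c components and the three measures per island pair.
#' @export
beta_matrices <- function(tree, incidence) {
  if (nrow(incidence) < 2L) stop("input error: need >= 2 islands")
  if (any(rowSums(incidence) == 0))
    stop("reference error: island with no haplotypes")
  bad <- setdiff(colnames(incidence), tree$tip.label)
  if (length(bad))
    stop("reference error: haplotype(s) not in tree: ", paste(bad, collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted (e.g. midpoint)")
  paths <- .edge_paths(tree)
  isl <- rownames(incidence)
  n <- length(isl)
  total <- repl <- rich <- matrix(0, n, n, dimnames = list(isl, isl))
  rows <- list()
  tipsets <- lapply(seq_len(n), function(i)
    colnames(incidence)[incidence[i, ] > 0])
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- pd_components(tree, tipsets[[i]], tipsets[[j]], paths = paths)
    bp <- beta_partition(comp)
    total[i, j] <- total[j, i] <- bp[["total"]]
    repl[i, j] <- repl[j, i] <- bp[["repl"]]
    rich[i, j] <- rich[j, i] <- bp[["rich"]]
    rows[[length(rows) + 1L]] <- data.frame(
      island_i = isl[i], island_j = isl[j],
      a = comp$a, b = comp$b, c = comp$c,
      total = bp[["total"]], repl = bp[["repl"]], rich = bp[["rich"]],
      stringsAsFactors = FALSE)
  }
  structure(list(total = total, repl = repl, rich = rich,
                 pairs = do.call(rbind, rows)),
            class = "beta_matrices")
}

#' @export
print.beta_matrices <- function(x, ...) {
  cat("Phylogenetic beta diversity over", nrow(x$total), "islands;",
      nrow(x$pairs), "pairs\n  mean total =", signif(mean(x$pairs$total), 3),
      " repl =", signif(mean(x$pairs$repl), 3),
      " rich =", signif(mean(x$pairs$rich), 3), "\n")
  invisible(x)
}
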