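#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape's implementation, which is exact on
#' additive matrices). Negative estimated branch lengths are clamped to zero
#' with a warning, as is conventional for distance trees fed into diversity
#' computations.
#'
#' @param d symmetric numeric distance matrix with dimnames (n >= 2 tips;
#'   n = 2 returns the trivial two-tip tree).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("input error: distance matrix needs dimnames")
  if (any(!is.finite(d))) stop("input error: non-finite distances")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("input error: matrix not symmetric")
  n <- nrow(d)
  if (n < 2L) stop("input error: need >= 2 tips")
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' K2P Neighbor-Joining tree over a haplotype set
#'
#' @param haps a `haplotype_set` or named character vector of aligned
#'   sequences.
#' @return an unrooted `ape::phylo` tree with haplotype tips.
#' @export
k2p_nj <- function(haps) {
  nj_tree(k2p_matrix(haps))
}

#' Nonparametric bootstrap support for a K2P Neighbor-Joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P distance
#' matrix and NJ tree per replicate, and reports for each internal branch of
#' the reference tree the percentage of replicates containing the same
#' bipartition (zero-length branches count topologically). Replicates in
#' which the K2P distance saturates are dropped with a warning and the
#' denominator adjusted. Fully seeded and reproducible.
#'
#' @param seqs named character vector of aligned sequences (one per tip;
#'   typically haplotype sequences), or a `haplotype_set`.
#' @param reps number of bootstrap replicates (0 = no support annotation).
#' @param seed optional RNG seed.
#' @return the reference NJ tree with `node.label` holding support
#'   percentages (NA for the root node) and attribute `reps_used`.
#' @export
nj_bootstrap <- function(seqs, reps = 1000, seed = NULL) {
  if (inherits(seqs, "haplotype_set"))
    seqs <- setNames(seqs$table$sequence, seqs$table$hap_id)
  if (reps < 0) stop("domain error: reps must be >= 0")
  ref <- k2p_nj(seqs)
  if (reps == 0) return(ref)
  if (!is.null(seed)) set.seed(seed)
  chars <- .seq_char_matrix(tolower(seqs))
  rownames(chars) <- names(seqs)
  L <- ncol(chars)
  boots <- vector("list", reps)
  dropped <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    tr <- tryCatch({
      dna <- ape::as.DNAbin(chars[, idx, drop = FALSE])
      dd <- ape::dist.dna(dna, model = "K80", pairwise.deletion = FALSE)
      if (any(!is.finite(dd))) stop("saturation")
      nj_tree(as.matrix(dd))
    }, error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else boots[[r]] <- tr
  }
  boots <- boots[!vapply(boots, is.null, TRUE)]
  if (dropped > 0L)
    warning(dropped, " bootstrap replicate(s) dropped (K2P saturation)")
  if (length(boots) == 0L) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(boots)
  support[1L] <- NA_real_  # root node of the unrooted representation
  ref$node.label <- support
  attr(ref, "reps_used") <- length(boots)
  ref
}

#' Check that each species' haplotypes form a connected cluster on a tree
#'
#' Reported as a screen (not enforced): a species is "monophyletic" here
#' when its tips form a clade on the midpoint-rooted combined tree.
#'
#' @param tree an `ape::phylo` over haplotype tips.
#' @param species named character vector: tip label -> species.
#' @return named logical vector, one entry per species.
#' @export
monophyly_check <- function(tree, species) {
  rooted <- phangorn::midpoint(tree)
  sp <- unique(species)
  setNames(vapply(sp, function(s) {
    tips <- names(species)[species == s]
    if (length(tips) <= 1L) return(TRUE)
    ape::is.monophyletic(rooted, tips)
  }, TRUE), sp)
}
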