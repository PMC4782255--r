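# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by routes different from the
# package implementation.

# all permutations of 1..n, one per row (recursive insertion; independent
# of the package's internal generator)
perms_oracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_oracle(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# pairwise step distance along a simulated genealogy (parent pointers),
# by explicit path-to-root walks and LCA
genealogy_steps <- function(genealogy) {
  ids <- genealogy$true_hap
  parent <- setNames(genealogy$parent, ids)
  steps <- setNames(genealogy$steps, ids)
  path_to_root <- function(h) {
    p <- character()
    while (!is.na(h)) {
      p <- c(p, h)
      h <- parent[[h]]
    }
    p
  }
  paths <- lapply(ids, path_to_root)
  names(paths) <- ids
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    anc <- intersect(paths[[i]], paths[[j]])[1L]  # nearest common ancestor
    climb <- function(h) {
      s <- 0
      while (h != anc) {
        s <- s + steps[[h]]
        h <- parent[[h]]
      }
      s
    }
    d[i, j] <- climb(ids[i]) + climb(ids[j])
  }
  d
}

# per-branch brute-force a/b/c oracle: an edge belongs to an island iff any
# of the island's tips descends from it
pd_components_bruteforce <- function(tree, tips1, tips2) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
  tip_sets <- lapply(desc, function(idx) tree$tip.label[idx])
  in1 <- vapply(tip_sets, function(ts) any(ts %in% tips1), TRUE)
  in2 <- vapply(tip_sets, function(ts) any(ts %in% tips2), TRUE)
  len <- tree$edge.length
  list(a = sum(len[in1 & in2]),
       b = sum(len[in1 & !in2]),
       c = sum(len[!in1 & in2]))
}

# random additive distance matrix from a random tree with known path lengths
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# tiny gap-free alignment written to a temp FASTA
write_tmp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# random ACGT sequences with given pairwise tweaks applied
random_seqs <- function(n, L, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
}
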