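.rooted_fixture <- function() {
  ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1):0;")
}

test_that("PD components split shared and exclusive branch length", {
  tr <- .rooted_fixture()
  # identical tip sets: all shared
  c0 <- pd_components(tr, c("t1", "t2"), c("t1", "t2"))
  expect_equal(c(c0$b, c0$c), c(0, 0))
  expect_equal(c0$a, c0$pd1)
  # disjoint cherries on a balanced 4-tip tree: a = 0, b = c = 3
  c1 <- pd_components(tr, c("t1", "t2"), c("t3", "t4"))
  expect_equal(c(c1$a, c1$b, c1$c), c(0, 3, 3))
  # nested subset: no exclusive branch for the subset island
  c2 <- pd_components(tr, c("t1", "t2", "t3"), c("t1", "t2"))
  expect_equal(c2$c, 0)
  expect_error(pd_components(tr, "t1", "t9"), "reference")
  # root-path inclusion: a single-haplotype island has positive PD
  c3 <- pd_components(tr, "t1", "t3")
  expect_equal(c3$pd1, 2)
})

test_that("beta partition follows the replacement/richness decomposition", {
  expect_equal(beta_partition(list(a = 1, b = 1, c = 1)),
               c(total = 2 / 3, repl = 2 / 3, rich = 0))
  # pure richness difference
  bp <- beta_partition(list(a = 2, b = 0, c = 3))
  expect_equal(bp[["repl"]], 0)
  expect_equal(bp[["rich"]], bp[["total"]])
  # pure replacement
  bp2 <- beta_partition(list(a = 0, b = 2, c = 2))
  expect_equal(unname(bp2), c(1, 1, 0))
  # degenerate all-empty pair
  expect_equal(unname(beta_partition(list(a = 0, b = 0, c = 0))), c(0, 0, 0))
  expect_error(beta_partition(list(a = -1, b = 0, c = 0)), "domain")
})

test_that("beta matrices are symmetric, additive, and match the per-branch oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n_tip <- sample(5:20, 1)
    n_isl <- sample(2:6, 1)
    tr <- phangorn::midpoint(ape::rtree(n_tip, br = function(k) runif(k, 0.05, 1)))
    inc <- matrix(rbinom(n_isl * n_tip, 1, 0.45), n_isl, n_tip,
                  dimnames = list(paste0("I", seq_len(n_isl)), tr$tip.label))
    inc[rowSums(inc) == 0, sample(n_tip, 1)] <- 1
    bm <- beta_matrices(tr, inc)
    # additivity and range
    expect_equal(bm$total, bm$repl + bm$rich, tolerance = 1e-12)
    expect_true(all(bm$total >= 0 & bm$total <= 1))
    expect_true(all(bm$repl >= 0 & bm$rich >= 0))
    expect_true(isSymmetric(bm$total) && isSymmetric(bm$rich))
    expect_equal(diag(bm$total), setNames(rep(0, n_isl), rownames(inc)))
    # per-branch brute-force oracle on every pair
    for (r in seq_len(nrow(bm$pairs))) {
      p <- bm$pairs[r, ]
      tips1 <- colnames(inc)[inc[p$island_i, ] > 0]
      tips2 <- colnames(inc)[inc[p$island_j, ] > 0]
      bf <- pd_components_bruteforce(tr, tips1, tips2)
      expect_equal(c(p$a, p$b, p$c), c(bf$a, bf$b, bf$c), tolerance = 1e-9)
    }
  }
})

test_that("duplicate island rows give zero beta and swapping islands swaps b/c", {
  tr <- phangorn::midpoint(ape::rtree(10, br = function(k) runif(k, 0.1, 1)))
  inc <- matrix(0, 3, 10, dimnames = list(c("I1", "I2", "I3"), tr$tip.label))
  inc[1, 1:4] <- 1; inc[2, 1:4] <- 1; inc[3, 5:9] <- 1
  bm <- beta_matrices(tr, inc)
  expect_equal(bm$total["I1", "I2"], 0)
  cab <- pd_components(tr, tr$tip.label[1:4], tr$tip.label[5:9])
  cba <- pd_components(tr, tr$tip.label[5:9], tr$tip.label[1:4])
  expect_equal(cab$b, cba$c)
  expect_equal(beta_partition(cab), beta_partition(cba))
})

test_that("incidence matrices restrict to islands and drop empty sites", {
  aln <- aligned_seqs(paste0("s", 1:4), c("AAAA", "AAAA", "AAAT", "AATT"))
  md <- data.frame(sample_id = paste0("s", 1:4), species = "sp",
                   site_id = c("I1", "M1", "I2", "I2"),
                   site_type = c("island", "mainland", "island", "island"),
                   latitude = 0, longitude = 0, mat_side = "W",
                   zoogeo_category = "Wide", stringsAsFactors = FALSE)
  h <- collapse_haplotypes(aln, md)
  inc <- incidence_matrix(h, md)
  expect_setequal(rownames(inc), c("I1", "I2"))
  inc_all <- incidence_matrix(h, md, islands_only = FALSE)
  expect_true("M1" %in% rownames(inc_all))
})
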