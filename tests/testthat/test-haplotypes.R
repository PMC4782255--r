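test_that("collapse groups identical sequences and conserves frequencies", {
  aln <- aligned_seqs(paste0("s", 1:4), rep("ACGTACGT", 4))
  h <- collapse_haplotypes(aln)
  expect_equal(nrow(h$table), 1L)
  expect_equal(h$table$frequency, 4L)

  aln2 <- aligned_seqs(c("a", "b"), c("ACGTACGT", "ACGTACGA"))
  h2 <- collapse_haplotypes(aln2)
  expect_equal(nrow(h2$table), 2L)
  expect_equal(h2$table$frequency, c(1L, 1L))
  expect_equal(h2$table$hap_id, c("H001", "H002"))

  # conservation: sum of frequencies = sample count, across random collapses
  for (seed in 1:5) {
    set.seed(seed)
    pool <- random_seqs(4, 20, seed)
    seqs <- sample(pool, 30, replace = TRUE)
    h <- collapse_haplotypes(aligned_seqs(sprintf("x%02d", 1:30), seqs))
    expect_equal(sum(h$table$frequency), 30L)
    expect_equal(sort(unlist(h$members, use.names = FALSE)),
                 sort(sprintf("x%02d", 1:30)))
  }
  expect_error(collapse_haplotypes(structure(list(), class = "aligned_seqs")),
               "empty")
})

test_that("per-site frequencies tabulate by locality", {
  aln <- aligned_seqs(c("a", "b", "c"), c("AAAA", "AAAA", "AAAT"))
  md <- data.frame(sample_id = c("a", "b", "c"), species = "sp",
                   site_id = c("I1", "I2", "I1"), site_type = "island",
                   latitude = 0, longitude = 0, mat_side = "W",
                   zoogeo_category = "Wide", stringsAsFactors = FALSE)
  h <- collapse_haplotypes(aln, md)
  expect_equal(h$site_freq["I1", "H001"], 1L)
  expect_equal(h$site_freq["I2", "H001"], 1L)
  expect_equal(h$site_freq["I1", "H002"], 1L)
  expect_equal(sum(h$site_freq), 3L)
})

test_that("step matrix counts differing positions and matches a recount", {
  expect_equal(step_matrix(c("ACGT", "ACGT"))[1, 2], 0L)
  expect_equal(step_matrix(c("ACGT", "AGGT"))[1, 2], 1L)

  seqs <- random_seqs(10, 60, seed = 7)
  sm <- step_matrix(seqs)
  expect_true(isSymmetric(sm))
  expect_equal(diag(sm), setNames(rep(0L, 10), rownames(sm)))
  # brute-force position-by-position recount
  for (i in 1:9) for (j in (i + 1):10) {
    a <- substring(seqs[i], 1:60, 1:60)
    b <- substring(seqs[j], 1:60, 1:60)
    expect_equal(sm[i, j], sum(a != b))
  }

  # invariance under record permutation (up to relabeling)
  aln <- aligned_seqs(paste0("s", 1:10), seqs)
  set.seed(3)
  perm <- sample(10)
  aln2 <- aligned_seqs(aln$ids[perm], unname(aln$seq[perm]))
  s1 <- step_matrix(collapse_haplotypes(aln))
  s2 <- step_matrix(collapse_haplotypes(aln2))
  expect_equal(sort(s1[upper.tri(s1)]), sort(s2[upper.tri(s2)]))
})

test_that("K2P distance follows the closed form and flags saturation", {
  z <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(c(z$P, z$Q, z$d), c(0, 0, 0))

  z <- k2p_distance("AAAA", "GAAA")  # one transition over L = 4
  expect_equal(z$P, 0.25)
  expect_equal(z$Q, 0)
  expect_equal(z$d, -0.5 * log(0.5), tolerance = 1e-12)

  expect_error(k2p_distance("AAGG", "GGAA"), "saturation")  # P = 0.5, Q = 0

  # matrix route (ape K80) agrees with the per-pair closed form
  # (related sequences: a base haplotype with <= 8 substitutions each)
  set.seed(11)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  seqs <- vapply(1:6, function(i) {
    s <- base
    for (p in sample(200, sample(0:8, 1)))
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    paste(s, collapse = "")
  }, "")
  m <- k2p_matrix(setNames(seqs, paste0("h", 1:6)))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(m[i, j], k2p_distance(seqs[i], seqs[j])$d, tolerance = 1e-10)

  # inflation ordering: K2P d >= p-distance on every valid pair
  for (i in 1:5) for (j in (i + 1):6) {
    p <- p_distance(seqs[i], seqs[j])
    expect_gte(m[i, j], p - 1e-12)
  }
})

test_that("molecular-clock conversion scales divergence into years", {
  expect_equal(divergence_to_age(0.006, 2.3), 260869.5652, tolerance = 1e-8)
  expect_equal(divergence_to_age(0.006, 2.3, sigfig = 2), 260000)
  expect_equal(divergence_to_age(0, 2.3), 0)
  for (p in c(0.001, 0.004, 0.01))
    expect_equal(divergence_to_age(p, 4.6), divergence_to_age(p, 2.3) / 2)
  expect_error(divergence_to_age(-0.1), "domain")
  expect_error(divergence_to_age(0.01, rate = 0), "domain")
})
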