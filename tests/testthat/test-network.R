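test_that("connection limit matches an independent closed-form evaluation", {
  expect_equal(connection_limit(644, max_steps = 5), 5L)
  expect_gte(connection_limit(1288, 0.95), connection_limit(644, 0.95))
  expect_error(connection_limit(644, confidence = 1.2), "domain")
  expect_error(connection_limit(0), "domain")

  # oracle: no-repeated-site probability via the log-gamma closed form
  # P(j; L) = L! / ((L - j)! L^j)
  oracle <- function(L, conf) {
    j <- 1L
    while (j < L) {
      p_next <- exp(lfactorial(L) - lfactorial(L - (j + 1L)) -
                    (j + 1L) * log(L))
      if (p_next < conf - 1e-9) break  # float slack at exact boundaries
      j <- j + 1L
    }
    j
  }
  for (L in c(100L, 300L, 644L, 1288L))
    for (cf in c(0.90, 0.95, 0.99))
      expect_equal(connection_limit(L, cf), oracle(L, cf),
                   info = sprintf("L=%d conf=%.2f", L, cf))
  expect_identical(parsimony_probability(0, 644), 1)
  expect_identical(parsimony_probability(1, 644), 1)
})

test_that("network construction inserts chains, respects the limit, and matches MST on a ladder", {
  # one step apart: single edge, no intermediates
  h2 <- collapse_haplotypes(aligned_seqs(c("a", "b"), c("AAAA", "AAAT")))
  n2 <- build_network(h2, j_max = 5)
  expect_equal(igraph::vcount(n2$graph), 2L)
  expect_equal(igraph::ecount(n2$graph), 1L)

  # three steps apart: chain with exactly 2 inferred nodes
  h3 <- collapse_haplotypes(aligned_seqs(c("a", "b"), c("AAAA", "TTTA")))
  n3 <- build_network(h3, j_max = 5)
  expect_equal(sum(!igraph::V(n3$graph)$sampled), 2L)
  expect_equal(igraph::ecount(n3$graph), 3L)
  expect_equal(length(unique(n3$membership)), 1L)

  # beyond the limit: two components
  n3b <- build_network(h3, j_max = 2)
  expect_equal(length(unique(n3b$membership)), 2L)
  expect_equal(igraph::ecount(n3b$graph), 0L)

  # nested-prefix ladder with all-distinct distances: skeleton is the MST
  base <- strsplit(paste(rep("A", 20), collapse = ""), "")[[1]]
  cuts <- c(0, 1, 3, 7, 12)
  seqs <- vapply(cuts, function(k) {
    s <- base
    if (k > 0) s[seq_len(k)] <- "T"
    paste(s, collapse = "")
  }, "")
  h <- collapse_haplotypes(aligned_seqs(paste0("s", 1:5), seqs))
  net <- build_network(h, j_max = 20)
  expect_equal(length(unique(net$membership)), 1L)
  # MST weight of the chain = 1 + 2 + 4 + 5 = 12 unit-step edges
  expect_equal(igraph::ecount(net$graph), 12L)
  dg <- igraph::distances(net$graph, v = "H001", to = "H005")
  expect_equal(unname(dg[1, 1]), 12)
})

test_that("component membership equals threshold-graph components (property)", {
  for (seed in 1:8) {
    sim <- simulate_species(make_archipelago(5, seed = seed), seed = seed,
                            params = sim_params(haplotypes_per_species = c(8, 14)))
    h <- collapse_haplotypes(sim$alignment, sim$metadata)
    sm <- step_matrix(h)
    jm <- 3L
    net <- build_network(h, steps = sm, j_max = jm)
    adj <- (sm > 0 & sm <= jm) * 1
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp_oracle <- igraph::components(g)$membership
    # same partition up to label permutation
    expect_equal(length(unique(net$membership)),
                 length(unique(comp_oracle)))
    tab <- table(net$membership, comp_oracle)
    expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))

    # within a component, graph distance >= Hamming steps between sampled nodes
    dg <- igraph::distances(net$graph)
    ids <- h$table$hap_id
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j && is.finite(dg[ids[i], ids[j]]))
        expect_gte(dg[ids[i], ids[j]], sm[i, j])
    }
  }
})

test_that("outgroup probabilities weight frequency plus one-step neighbours", {
  # star: hub sampled 5x, three leaves 1x each
  seqs <- c(rep("AAAAA", 5), "TAAAA", "ATAAA", "AATAA")
  h <- collapse_haplotypes(aligned_seqs(paste0("s", 1:8), seqs))
  net <- build_network(h, j_max = 5)
  op <- outgroup_probabilities(net, h)
  expect_equal(op$weight, c(8, 6, 6, 6))
  expect_equal(op$outgroup_p[1], 8 / 26, tolerance = 1e-12)
  expect_equal(sum(op$outgroup_p), 1)
  expect_equal(op$hap_id[op$ancestral], "H001")

  # symmetric pair: tie reported on both
  hs <- collapse_haplotypes(aligned_seqs(c("x", "y"), c("AAAA", "AAAT")))
  ops <- outgroup_probabilities(build_network(hs, j_max = 5), hs)
  expect_equal(ops$outgroup_p, c(0.5, 0.5))
  expect_true(all(ops$ancestral))

  # single-haplotype component
  h1 <- collapse_haplotypes(aligned_seqs("z", "ACGT"))
  op1 <- outgroup_probabilities(build_network(h1), h1)
  expect_equal(op1$outgroup_p, 1)

  # sums to one within every component on a simulated species
  sim <- simulate_species(make_archipelago(5, seed = 2), seed = 2)
  h <- collapse_haplotypes(sim$alignment, sim$metadata)
  net <- build_network(h, j_max = 2)
  op <- outgroup_probabilities(net, h)
  sums <- tapply(op$outgroup_p, op$component, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)

  # frequency strategy: weights are the frequencies themselves
  opf <- outgroup_probabilities(net, h, strategy = "frequency")
  expect_equal(opf$weight, opf$frequency)
})

.anc_fixture <- function(category, c_site = "Eisl") {
  seqs <- c(rep("AAAA", 3), "AAAT", "AATA")
  md <- data.frame(
    sample_id = paste0("s", 1:5), species = "sp",
    site_id = c("Wisl", "Wisl", "Wisl", "Wisl2", c_site),
    site_type = "island", latitude = 37, longitude = 25,
    mat_side = c("W", "W", "W", "W", if (c_site == "Eisl") "E" else "W"),
    zoogeo_category = category, stringsAsFactors = FALSE)
  aln <- aligned_seqs(md$sample_id, seqs)
  h <- collapse_haplotypes(aln, md)
  net <- build_network(h, j_max = 5)
  list(net = net, haps = h, md = md)
}

test_that("ancestral calls score zoogeographic congruence by trench side", {
  f <- .anc_fixture("Balkan")
  call <- ancestral_localities(f$net, f$haps, f$md)
  expect_equal(call$hap_ids, "H001")
  expect_equal(call$localities, "Wisl")
  expect_equal(call$verdict, "congruent")

  expect_equal(ancestral_localities(f$net, f$haps, f$md,
                                    category = "Wide")$verdict, "congruent")
  # the ancestral haplotype sits on the W side: incongruent for an Anatolian
  expect_equal(ancestral_localities(f$net, f$haps, f$md,
                                    category = "Anatolian")$verdict,
               "incongruent")
  # COL resolves when ancestral localities fall on one side
  expect_equal(ancestral_localities(f$net, f$haps, f$md,
                                    category = "COL")$verdict, "congruent")

  # ancestral haplotype spanning both sides: incongruent for side-restricted
  g <- .anc_fixture("Balkan")
  g$md$site_id[2] <- "Eisl"; g$md$mat_side[2] <- "E"
  h2 <- collapse_haplotypes(aligned_seqs(g$md$sample_id,
                                         c(rep("AAAA", 3), "AAAT", "AATA")), g$md)
  n2 <- build_network(h2, j_max = 5)
  expect_equal(ancestral_localities(n2, h2, g$md)$verdict, "incongruent")
  expect_equal(ancestral_localities(n2, h2, g$md, category = "COL")$verdict,
               "incongruent")
})
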