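#' Probability of a parsimonious (non-multiply-hit) connection
#'
#' Probability that a path of `j` mutational steps over an alignment of `L`
#' positions involves no position struck more than once, under uniform
#' placement of mutations: P(j; L) = prod_{i=0}^{j-1} (1 - i/L). Parsimony
#' in the statistical-parsimony sense holds exactly when no site is multiply
#' hit, so this is the confidence attached to connecting two haplotypes `j`
#' steps apart.
#'
#' @param j number of mutational steps (scalar or vector).
#' @param L alignment length in positions.
#' @return probability in (0, 1].
#' @export
parsimony_probability <- function(j, L) {
  if (L < 1) stop("domain error: L must be >= 1")
  vapply(j, function(jj) {
    if (jj < 0) stop("domain error: j must be >= 0")
    if (jj > L) return(0)
    prod(1 - (seq_len(jj) - 1) / L)
  }, 0)
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` at which two haplotypes may be
#' connected such that the probability of the connection being parsimonious
#' (no multiply-hit site) is at least `confidence`. A `max_steps` override
#' bypasses the computation entirely, for reproducibility against published
#' networks.
#'
#' @param L alignment length in positions (e.g. 644).
#' @param confidence required parsimony probability, default 0.95.
#' @param max_steps optional manual override; returned as-is when given.
#' @return integer number of steps, >= 1.
#' @export
connection_limit <- function(L, confidence = 0.95, max_steps = NULL) {
  if (!is.null(max_steps)) {
    if (max_steps < 1) stop("domain error: max_steps must be >= 1")
    return(as.integer(max_steps))
  }
  if (confidence <= 0 || confidence >= 1)
    stop("domain error: confidence must be in (0, 1)")
  if (L < 1) stop("domain error: L must be >= 1")
  j <- 1L
  p <- 1
  repeat {
    p_next <- p * (1 - j / L)  # P(j + 1; L)
    if (p_next < confidence || j >= L) break
    p <- p_next
    j <- j + 1L
  }
  j
}

.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build a statistical-parsimony haplotype network
#'
#' Agglomerative construction in the statistical-parsimony style: sampled
#' haplotype pairs are processed in increasing step distance; at each
#' distance level d <= `j_max`, every pair of components that were distinct
#' at the end of level d-1 and contain a haplotype pair at distance d is
#' connected by a chain of d-1 inferred (unsampled) intermediate nodes. All
#' equally short between-component connections at a level are retained, so
#' alternative connections (loops) survive; no random tie-breaking occurs.
#' Pairs beyond `j_max` remain in separate subnetworks.
#'
#' @param haps a `haplotype_set`.
#' @param steps optional precomputed [step_matrix()]; computed when NULL.
#' @param j_max connection limit in steps; computed from the alignment
#'   length via [connection_limit()] when NULL.
#' @param confidence parsimony confidence for the connection limit.
#' @return object of class `parsimony_network`: list with `graph` (igraph,
#'   node attributes `sampled`, `frequency`, `sites`), `j_max`,
#'   `confidence`, and `membership` (component id per sampled haplotype).
#' @export
build_network <- function(haps, steps = NULL, j_max = NULL, confidence = 0.95) {
  if (!inherits(haps, "haplotype_set")) stop("input error: need a haplotype_set")
  n <- nrow(haps$table)
  if (n == 0L) stop("input error: empty haplotype set")
  if (is.null(steps)) steps <- step_matrix(haps)
  if (is.null(j_max)) j_max <- connection_limit(haps$L, confidence)
  ids <- haps$table$hap_id

  edges_from <- character(); edges_to <- character(); edge_steps <- integer()
  inferred <- character()
  parent <- seq_len(n)
  if (n > 1L) {
    dists <- sort(unique(steps[upper.tri(steps)]))
    dists <- dists[dists >= 1L & dists <= j_max]
    for (d in dists) {
      # component partition frozen at the end of the previous level
      comp <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
      merges <- list()
      for (i in 1:(n - 1L)) for (k in (i + 1L):n) {
        if (steps[i, k] != d || comp[i] == comp[k]) next
        if (d == 1L) {
          edges_from <- c(edges_from, ids[i]); edges_to <- c(edges_to, ids[k])
          edge_steps <- c(edge_steps, 1L)
        } else {
          mids <- sprintf("%s-%s.m%d", ids[i], ids[k], seq_len(d - 1L))
          inferred <- c(inferred, mids)
          chain <- c(ids[i], mids, ids[k])
          edges_from <- c(edges_from, chain[-length(chain)])
          edges_to <- c(edges_to, chain[-1L])
          edge_steps <- c(edge_steps, rep(1L, d))
        }
        merges[[length(merges) + 1L]] <- c(i, k)
      }
      for (mk in merges) {
        ra <- .uf_find(parent, mk[1L]); rb <- .uf_find(parent, mk[2L])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  membership <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
  membership <- setNames(match(membership, unique(membership)), ids)

  sites <- if (is.null(haps$site_freq)) rep("", n) else
    apply(haps$site_freq > 0, 2L, function(z)
      paste(rownames(haps$site_freq)[z], collapse = ","))
  verts <- data.frame(
    name = c(ids, inferred),
    sampled = c(rep(TRUE, n), rep(FALSE, length(inferred))),
    frequency = c(haps$table$frequency, rep(0L, length(inferred))),
    sites = c(unname(sites), rep("", length(inferred))),
    stringsAsFactors = FALSE)
  eds <- data.frame(from = edges_from, to = edges_to, steps = edge_steps,
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(eds, directed = FALSE, vertices = verts)
  structure(list(graph = g, j_max = as.integer(j_max),
                 confidence = confidence, membership = membership),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  ns <- sum(igraph::V(x$graph)$sampled)
  cat("Parsimony network:", ns, "sampled +",
      igraph::vcount(x$graph) - ns, "inferred nodes,",
      igraph::ecount(x$graph), "edges, j_max =", x$j_max,
      "(", length(unique(x$membership)), "subnetwork(s) )\n")
  invisible(x)
}

#' Haplotype outgroup (ancestral) probabilities
#'
#' Two documented weighting strategies, normalised within each connected
#' component:
#'
#' * `"freq_neighbors"` (default): each sampled haplotype's own frequency
#'   plus the summed frequencies of its directly connected (one-step)
#'   sampled neighbours -- a monotone proxy for the
#'   frequency-and-connectedness criterion of statistical-parsimony
#'   software.
#' * `"frequency"`: the haplotype frequency alone. Under neutral coalescent
#'   theory the probability that a haplotype is the oldest in the sample is
#'   proportional to its frequency, so this is the estimator with the
#'   cleanest theoretical warrant; the network then only delimits the
#'   component within which the call is made.
#'
#' The two agree on star-shaped networks with a dominant centre; they can
#' differ on chain-like genealogies, where the neighbour-sum weight cannot
#' separate the root from its first descendant.
#'
#' @param net a `parsimony_network`.
#' @param haps the `haplotype_set` the network was built from.
#' @param strategy weighting strategy, see above.
#' @return data.frame with `hap_id`, `component`, `frequency`, `weight`,
#'   `outgroup_p` (sums to 1 within each component) and `ancestral`
#'   (TRUE for every maximiser within its component; ties all flagged).
#' @export
outgroup_probabilities <- function(net, haps,
                                   strategy = c("freq_neighbors", "frequency")) {
  strategy <- match.arg(strategy)
  g <- net$graph
  ids <- haps$table$hap_id
  f <- setNames(haps$table$frequency, ids)
  w <- if (strategy == "frequency") f else vapply(ids, function(h) {
    nb <- igraph::neighbors(g, h)$name
    nb <- nb[nb %in% ids]  # sampled one-step neighbours only
    f[[h]] + sum(f[nb])
  }, 0)
  comp <- net$membership[ids]
  p <- unname(w)
  for (cc in unique(comp)) {
    sel <- comp == cc
    p[sel] <- w[sel] / sum(w[sel])
  }
  anc <- logical(length(ids))
  for (cc in unique(comp)) {
    sel <- which(comp == cc)
    anc[sel] <- abs(p[sel] - max(p[sel])) < 1e-12
  }
  data.frame(hap_id = ids, component = unname(comp),
             frequency = unname(f), weight = unname(w),
             outgroup_p = p, ancestral = anc,
             stringsAsFactors = FALSE)
}

.side_of_sites <- function(sites, metadata) {
  side <- metadata$mat_side[match(sites, metadata$site_id)]
  unique(side[!is.na(side)])
}

#' Ancestral haplotype call and zoogeographic congruence
#'
#' Identifies the ancestral haplotype(s) of the main (largest-sample)
#' subnetwork as the outgroup-probability maximisers, collects the
#' localities where they were sampled, and scores congruence against the
#' species' zoogeographic category: Balkan requires all ancestral localities
#' on the W side of the trench, Anatolian all on the E side, Wide admits
#' any, and COL (continental/large-island) is congruent when the ancestral
#' localities resolve to a single side. Tied ancestral haplotypes whose
#' localities straddle both sides give an indeterminate verdict for
#' side-restricted categories.
#'
#' @param net a `parsimony_network`.
#' @param haps the underlying `haplotype_set` (with site frequencies).
#' @param metadata validated sample metadata for this species.
#' @param category zoogeographic category, one of Balkan, Anatolian, Wide,
#'   COL; taken from the metadata when NULL.
#' @param strategy outgroup-probability strategy, see
#'   [outgroup_probabilities()].
#' @return list of class `ancestral_call`: `hap_ids`, `localities`,
#'   `sides`, `category`, `verdict` (congruent / incongruent /
#'   indeterminate) and the outgroup-probability table.
#' @export
ancestral_localities <- function(net, haps, metadata, category = NULL,
                                 strategy = "freq_neighbors") {
  if (is.null(haps$site_freq))
    stop("haplotype set lacks per-site frequencies; collapse with metadata")
  if (is.null(category)) {
    category <- unique(metadata$zoogeo_category)
    if (length(category) != 1L)
      stop("metadata spans multiple zoogeo categories; pass `category`")
  }
  op <- outgroup_probabilities(net, haps, strategy = strategy)
  # main subnetwork = the component carrying the most samples
  comp_n <- tapply(op$frequency, op$component, sum)
  main <- as.integer(names(comp_n)[which.max(comp_n)])
  cand <- op$hap_id[op$ancestral & op$component == main]
  loc <- sort(unique(unlist(lapply(cand, function(h)
    rownames(haps$site_freq)[haps$site_freq[, h] > 0]))))
  if (length(loc) == 0L) stop("ancestral haplotype has no sampled localities")
  sides <- .side_of_sites(loc, metadata)
  verdict <- switch(category,
    Wide = "congruent",
    Balkan = if (identical(sides, "W")) "congruent"
             else if (length(cand) > 1L && length(sides) > 1L) "indeterminate"
             else "incongruent",
    Anatolian = if (identical(sides, "E")) "congruent"
                else if (length(cand) > 1L && length(sides) > 1L) "indeterminate"
                else "incongruent",
    COL = if (length(sides) == 1L) "congruent"
          else if (length(cand) > 1L) "indeterminate"
          else "incongruent",
    stop("unknown category: ", category))
  structure(list(hap_ids = cand, localities = loc, sides = sides,
                 category = category, verdict = verdict, outgroup = op),
            class = "ancestral_call")
}

#' @export
print.ancestral_call <- function(x, ...) {
  cat("Ancestral haplotype(s):", paste(x$hap_ids, collapse = ", "),
      "\n  localities:", paste(x$localities, collapse = ", "),
      "\n  category:", x$category, "->", x$verdict, "\n")
  invisible(x)
}
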