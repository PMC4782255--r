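#' Collapse aligned sequences into haplotypes
#'
#' Exact string identity defines a haplotype. Haplotype ids `H001`, `H002`,
#' ... are assigned in first-occurrence order so repeated runs on the same
#' input produce identical labels. When metadata is supplied, per-site
#' haplotype counts are tabulated as well.
#'
#' @param alignment an [aligned_seqs] object.
#' @param metadata optional validated sample metadata (see [read_metadata()]);
#'   needed for per-site frequencies and all downstream geography.
#' @return an object of class `haplotype_set`: list with `table` (data.frame
#'   `hap_id`, `sequence`, `frequency`), `members` (named list hap_id ->
#'   sample ids), `site_freq` (site x haplotype count matrix, or NULL) and
#'   `L` (alignment length).
#' @export
collapse_haplotypes <- function(alignment, metadata = NULL) {
  if (!inherits(alignment, "aligned_seqs")) stop("alignment must be aligned_seqs")
  seqs <- alignment$seq
  if (length(seqs) == 0L) stop("input error: empty alignment")
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  hap_of <- match(seqs, uniq)
  hap_id <- sprintf("H%03d", seq_along(uniq))
  members <- split(alignment$ids, hap_id[hap_of])
  members <- members[hap_id]  # first-occurrence order, not alphabetical
  tab <- data.frame(hap_id = hap_id,
                    sequence = unname(uniq),
                    frequency = as.integer(lengths(members)),
                    stringsAsFactors = FALSE)
  site_freq <- NULL
  if (!is.null(metadata)) {
    md <- metadata[match(alignment$ids, metadata$sample_id), , drop = FALSE]
    if (anyNA(md$sample_id))
      stop("cross-reference error: metadata lacks sample(s) present in alignment")
    site_freq <- table(factor(md$site_id, levels = unique(md$site_id)),
                       factor(hap_id[hap_of], levels = hap_id))
    site_freq <- unclass(site_freq)  # plain matrix, sites x haplotypes
  }
  structure(list(table = tab, members = members, site_freq = site_freq,
                 L = alignment$L),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", nrow(x$table), "haplotypes from",
      sum(x$table$frequency), "samples (", x$L, "bp )\n")
  invisible(x)
}

#' Flat haplotype table for export
#'
#' @param haps a `haplotype_set`.
#' @return data.frame with hap_id, frequency, member sample ids
#'   (comma-separated), sites (comma-separated), and the sequence.
#' @export
haplotype_table <- function(haps) {
  sites <- if (is.null(haps$site_freq)) rep("", nrow(haps$table)) else
    apply(haps$site_freq > 0, 2L, function(z)
      paste(rownames(haps$site_freq)[z], collapse = ","))
  data.frame(hap_id = haps$table$hap_id,
             frequency = haps$table$frequency,
             members = vapply(haps$members, paste, "", collapse = ","),
             sites = unname(sites),
             sequence = haps$table$sequence,
             stringsAsFactors = FALSE)
}

.seq_char_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Mutational-step (Hamming) matrix between haplotypes
#'
#' `steps[i, j]` is the count of alignment positions at which haplotypes i
#' and j carry different bases; each unit corresponds to one mutational step
#' on a network edge.
#'
#' @param haps a `haplotype_set` (or character vector of equal-length
#'   sequences).
#' @return symmetric integer matrix with zero diagonal, dimnames = hap ids.
#' @export
step_matrix <- function(haps) {
  if (inherits(haps, "haplotype_set")) {
    seqs <- haps$table$sequence
    ids <- haps$table$hap_id
  } else {
    ids <- if (is.null(names(haps))) sprintf("H%03d", seq_along(haps)) else names(haps)
    seqs <- unname(as.character(haps))
  }
  if (length(seqs) < 1L) stop("input error: no haplotypes")
  m <- .seq_char_matrix(seqs)
  n <- nrow(m)
  steps <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- sum(m[i, ] != m[j, ])
        steps[i, j] <- steps[j, i] <- as.integer(d)
      }
    }
  }
  steps
}

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Separates transition (A<->G, C<->T) and transversion changes. With
#' transition proportion P and transversion proportion Q, the distance is
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q) substitutions per site.
#' Differences involving an ambiguity code (only possible when the alignment
#' was read with `allow_ambiguous`) are counted conservatively as
#' transversions.
#'
#' @param seq_a,seq_b equal-length sequence strings.
#' @return list of class `k2p` with elements `P`, `Q`, `d`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences of unequal length")
  L <- length(a)
  diff <- a != b
  ts <- diff & !is.na(.TRANSITIONS[a]) & .TRANSITIONS[a] == b
  P <- sum(ts) / L
  Q <- (sum(diff) - sum(ts)) / L
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    stop("saturation error: K2P distance undefined (P = ", signif(P, 4),
         ", Q = ", signif(Q, 4), ")")
  d <- -0.5 * log(arg1) - 0.25 * log(arg2)
  structure(list(P = P, Q = Q, d = d), class = "k2p")
}

#' Pairwise K2P distance matrix over haplotypes
#'
#' Matrix-scale computation is delegated to `ape::dist.dna(model = "K80")`;
#' the per-pair closed form in [k2p_distance()] defines the quantity and the
#' two routes are required to agree.
#'
#' @param haps a `haplotype_set` or named character vector of sequences.
#' @return symmetric numeric matrix of K2P distances (substitutions/site).
#' @export
k2p_matrix <- function(haps) {
  if (inherits(haps, "haplotype_set")) {
    seqs <- setNames(haps$table$sequence, haps$table$hap_id)
  } else {
    nm <- names(haps)
    seqs <- as.character(haps)
    names(seqs) <- if (is.null(nm)) sprintf("H%03d", seq_along(seqs)) else nm
  }
  dna <- ape::as.DNAbin(.seq_char_matrix(tolower(seqs)))
  rownames(dna) <- names(seqs)
  d <- as.matrix(ape::dist.dna(dna, model = "K80", pairwise.deletion = FALSE))
  if (any(!is.finite(d)))
    stop("saturation error: K2P distance undefined for at least one pair")
  d
}

#' Uncorrected p-distance between two aligned sequences
#'
#' @inheritParams k2p_distance
#' @return proportion of differing positions.
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences of unequal length")
  mean(a != b)
}

#' Convert a divergence proportion to an age under a molecular clock
#'
#' Uses the standard invertebrate mitochondrial clock of 2.3% sequence
#' divergence per million years by default: age (years) =
#' divergence / (rate/100) * 1e6.
#'
#' @param p_distance divergence as a proportion (e.g. 0.006 for 0.6%).
#' @param rate clock rate in percent divergence per million years.
#' @param sigfig optional number of significant figures to round the result
#'   to (the field convention is 2).
#' @return age in years.
#' @export
divergence_to_age <- function(p_distance, rate = 2.3, sigfig = NULL) {
  if (any(p_distance < 0)) stop("domain error: negative divergence")
  if (rate <= 0) stop("domain error: rate must be > 0")
  age <- p_distance / (rate / 100) * 1e6
  if (!is.null(sigfig)) age <- signif(age, sigfig)
  age
}
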