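#' Great-circle distance in kilometres (haversine)
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84);
#'   vectorised.
#' @return distance in km (Earth radius 6371 km).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  h <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(h)))
}

#' Predictor matrices for barrier analyses
#'
#' Builds, over a set of islands: `D`, great-circle interisland distance
#' (km) between island reference coordinates; `MAT`, a binary indicator
#' coded 1 when two islands lie on opposite sides of the trench and 0 when
#' on the same side; and `A`, area dissimilarity
#' |log10(area_i) - log10(area_j)|.
#'
#' @param islands validated island attribute table ([read_islands()]).
#' @return list of class `predictor_matrices` with symmetric zero-diagonal
#'   matrices `D`, `MAT`, `A`.
#' @export
predictor_matrices <- function(islands) {
  islands <- validate_islands(islands)
  need <- c("latitude", "longitude", "area", "mat_side")
  if (any(vapply(islands[need], anyNA, TRUE)))
    stop("schema error: missing island attribute(s)")
  n <- nrow(islands)
  ids <- islands$site_id
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(islands$latitude[i], islands$longitude[i],
                 islands$latitude[j], islands$longitude[j]))
  MAT <- outer(islands$mat_side, islands$mat_side, "!=") * 1
  la <- log10(islands$area)
  A <- abs(outer(la, la, "-"))
  diag(D) <- diag(MAT) <- diag(A) <- 0
  dimnames(D) <- dimnames(MAT) <- dimnames(A) <- list(ids, ids)
  structure(list(D = D, MAT = MAT, A = A), class = "predictor_matrices")
}

#' Strictly-lower-triangle vectorisation of a square matrix
#'
#' The shared unfolding used by every matrix statistic in the package, so
#' all vectors align pair-for-pair.
#'
#' @param m square matrix.
#' @return numeric vector of the n(n-1)/2 below-diagonal entries,
#'   column-major.
#' @export
lower_triangle <- function(m) {
  m <- as.matrix(m)
  m[lower.tri(m)]
}

.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

.check_mantel_input <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("input error: matrices differ in dimension")
  n <- nrow(X)
  if (n < 4L) stop("input error: need >= 4 islands")
  for (m in list(X, Y)) {
    if (any(!is.finite(m))) stop("input error: non-finite matrix entries")
    if (!isSymmetric(unname(m), tol = 1e-8)) stop("input error: matrix not symmetric")
  }
  if (sd(lower_triangle(X)) == 0 || sd(lower_triangle(Y)) == 0)
    stop("degenerate-input error: zero-variance distance matrix")
  list(X = X, Y = Y, n = n)
}

#' Mantel permutation test
#'
#' Pearson correlation of the strictly-lower triangles of two distance
#' matrices; the null distribution permutes rows and columns of `Y`
#' simultaneously. The p-value uses the +1 correction,
#' p = (#\{r_perm >= r_obs\} + 1)/(n_perm + 1), one-tailed (positive) by
#' default, matching a directional barrier hypothesis. With
#' `exhaustive = TRUE` (n <= 7) all n! permutations are enumerated and the
#' p-value is exact.
#'
#' @param X,Y symmetric matrices over the same islands in the same order.
#' @param n_perm number of random permutations (default 10000).
#' @param seed optional RNG seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `alternative`,
#'   `exhaustive`, `seed`.
#' @export
mantel <- function(X, Y, n_perm = 10000, seed = NULL,
                   alternative = c("greater", "two.sided"),
                   exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  chk <- .check_mantel_input(X, Y)
  X <- chk$X; Y <- chk$Y; n <- chk$n
  lt <- lower.tri(X)
  vx <- X[lt]
  r_obs <- cor(vx, Y[lt])
  stat <- function(r) if (alternative == "greater") r else abs(r)
  if (exhaustive) {
    if (n > 7L) stop("exhaustive enumeration limited to n <= 7")
    perms <- .all_perms(n)
    r_all <- apply(perms, 1L, function(p) cor(vx, Y[p, p][lt]))
    p_val <- mean(stat(r_all) >= stat(r_obs) - 1e-12)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (stat(cor(vx, Y[p, p][lt])) >= stat(r_obs) - 1e-12) hits <- hits + 1L
    }
    p_val <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p_val, n_perm = n_used,
                 alternative = alternative, exhaustive = exhaustive,
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(if (!is.null(x$partial) && x$partial) "Partial Mantel" else "Mantel",
      "r =", signif(x$r, 4), ", p =", signif(x$p, 4),
      "(", x$n_perm, if (x$exhaustive) "exhaustive" else "random",
      "permutations,", x$alternative, ")\n")
  invisible(x)
}

.residualize <- function(v, Z) {
  fit <- lm.fit(cbind(1, Z), v)
  fit$residuals
}

#' Partial Mantel permutation test
#'
#' Correlation between two distance matrices after removing, by ordinary
#' least squares on the vectorised lower triangles, the effect of one or
#' more conditioning matrices. Significance permutes rows/columns of `X`
#' and recomputes the partial correlation (residuals of the permuted `X`
#' against the same conditioners) per permutation.
#'
#' @param X,Y symmetric matrices over the same islands.
#' @param conditioners a matrix or list of matrices to condition on.
#' @inheritParams mantel
#' @return a `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel <- function(X, Y, conditioners, n_perm = 10000, seed = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.matrix(conditioners)) conditioners <- list(conditioners)
  if (length(conditioners) < 1L) stop("input error: need >= 1 conditioner")
  chk <- .check_mantel_input(X, Y)
  X <- chk$X; Y <- chk$Y; n <- chk$n
  lt <- lower.tri(X)
  Z <- vapply(conditioners, function(m) as.matrix(m)[lt], X[lt])
  qz <- qr(cbind(1, Z))
  if (qz$rank < ncol(Z) + 1L)
    warning("conditioning warning: collinear conditioners; least-squares fit is rank-deficient")
  ry <- .residualize(Y[lt], Z)
  rx <- .residualize(X[lt], Z)
  # conditioning away all of X (e.g. conditioning on X itself) leaves only
  # numerical noise: the partial correlation is 0 by definition
  if (sd(rx) < 1e-10 * sd(X[lt]) || sd(ry) < 1e-10 * sd(Y[lt]))
    return(structure(list(r = 0, p = 1, n_perm = n_perm,
                          alternative = alternative, exhaustive = FALSE,
                          seed = seed, partial = TRUE),
                     class = "mantel_result"))
  r_obs <- cor(rx, ry)
  stat <- function(r) if (alternative == "greater") r else abs(r)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    rxp <- .residualize(X[p, p][lt], Z)
    if (sd(rxp) == 0) next
    if (stat(cor(rxp, ry)) >= stat(r_obs) - 1e-12) hits <- hits + 1L
  }
  res <- structure(list(r = r_obs, p = (hits + 1) / (n_perm + 1),
                        n_perm = n_perm, alternative = alternative,
                        exhaustive = FALSE, seed = seed, partial = TRUE),
                   class = "mantel_result")
  res
}

.r2 <- function(y, Xcols) {
  if (length(Xcols) == 0L) return(0)
  fit <- lm.fit(cbind(1, Xcols), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Hierarchical partitioning of explained variation
#'
#' Fits ordinary least squares for all 2^k subsets of the predictors and
#' averages, over all orderings of entry, the increase in R^2 contributed by
#' each predictor when it enters the model (lmg averaging). Contributions
#' are reported on the absolute R^2 scale and sum exactly to the full-model
#' R^2.
#'
#' @param y numeric response vector (here a vectorised beta-diversity
#'   lower triangle).
#' @param X numeric matrix of predictors, one column each (k <= 10).
#' @return list of class `hier_part`: `contributions` (named, absolute R^2
#'   scale), `full_r2`.
#' @export
hierarchical_partitioning <- function(y, X) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 1L || k > 10L) stop("input error: need 1..10 predictors")
  if (nrow(X) <= k) stop("input error: need more observations than predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  if (qr(cbind(1, X))$rank < k + 1L)
    warning("conditioning warning: rank-deficient full model; ",
            "aliased predictors share their joint contribution")
  subsets <- 0:(2^k - 1L)
  in_set <- function(s) which(bitwAnd(s, bitwShiftL(1L, 0:(k - 1L))) != 0L)
  r2s <- vapply(subsets, function(s) .r2(y, X[, in_set(s), drop = FALSE]), 0)
  names(r2s) <- as.character(subsets)
  fact <- factorial(0:k)
  contrib <- setNames(numeric(k), colnames(X))
  for (v in seq_len(k)) {
    bit <- bitwShiftL(1L, v - 1L)
    without <- subsets[bitwAnd(subsets, bit) == 0L]
    sizes <- vapply(without, function(s) length(in_set(s)), 0L)
    w <- fact[sizes + 1L] * fact[k - sizes] / fact[k + 1L]
    gain <- r2s[as.character(without + bit)] - r2s[as.character(without)]
    contrib[v] <- sum(w * gain)
  }
  structure(list(contributions = contrib,
                 full_r2 = r2s[[as.character(2^k - 1L)]]),
            class = "hier_part")
}

#' @export
print.hier_part <- function(x, ...) {
  cat("Hierarchical partitioning (full R^2 =", signif(x$full_r2, 4), "):\n")
  print(signif(x$contributions, 4))
  invisible(x)
}

#' Barrier-test report: Mantel, partial Mantel and variance partitioning
#'
#' For each beta-diversity measure (total, replacement, richness difference)
#' against each predictor (distance, trench indicator, area dissimilarity):
#' the Mantel correlation with permutation p-value, the partial Mantel
#' statistic conditioning on the other two predictors, and the predictor's
#' independent contribution to the R^2 of the three-predictor regression on
#' the vectorised pairs (hierarchical partitioning, absolute scale).
#'
#' @param beta a `beta_matrices` object.
#' @param predictors a `predictor_matrices` object over the same islands
#'   (rows are aligned by island id).
#' @param n_perm permutations per test (default 10000).
#' @param seed RNG seed; each test uses a seed derived from it.
#' @param alternative tail for the Mantel tests.
#' @return data.frame with columns measure, predictor, r_m, p, partial_r,
#'   partial_p, variation, full_r2.
#' @export
barrier_tests <- function(beta, predictors, n_perm = 10000, seed = NULL,
                          alternative = "greater") {
  isl <- rownames(beta$total)
  if (!all(isl %in% rownames(predictors$D)))
    stop("reference error: islands missing from predictor matrices")
  P <- lapply(predictors[c("D", "MAT", "A")], function(m) m[isl, isl])
  names(P) <- c("distance", "MAT", "area")
  measures <- list(total = beta$total, repl = beta$repl, rich = beta$rich)
  lt <- lower.tri(beta$total)
  Xmat <- vapply(P, function(m) m[lt], P[[1]][lt])
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(measures) * 2L * length(P))
  si <- 0L
  rows <- list()
  for (mn in names(measures)) {
    hp <- hierarchical_partitioning(measures[[mn]][lt], Xmat)
    for (pn in names(P)) {
      si <- si + 1L
      mt <- mantel(P[[pn]], measures[[mn]], n_perm = n_perm,
                   seed = seeds[si], alternative = alternative)
      si <- si + 1L
      pm <- partial_mantel(P[[pn]], measures[[mn]],
                           P[setdiff(names(P), pn)], n_perm = n_perm,
                           seed = seeds[si], alternative = alternative)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = mn, predictor = pn,
        r_m = mt$r, p = mt$p,
        partial_r = pm$r, partial_p = pm$p,
        variation = unname(hp$contributions[pn]),
        full_r2 = hp$full_r2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
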