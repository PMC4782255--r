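.rand_dist <- function(n, seed) {
  set.seed(seed)
  xy <- matrix(rnorm(2 * n), n)
  m <- as.matrix(dist(xy))
  dimnames(m) <- list(paste0("I", 1:n), paste0("I", 1:n))
  m
}

test_that("predictor matrices encode distance, trench side, and log-area", {
  isl <- data.frame(site_id = c("A", "B", "C"),
                    area = c(100, 100, 1000),
                    latitude = c(37, 38, 37), longitude = c(25, 25, 26),
                    mat_side = c("W", "W", "E"), stringsAsFactors = FALSE)
  pm <- predictor_matrices(isl)
  expect_equal(diag(pm$D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(diag(pm$MAT), rep(0, 3), ignore_attr = TRUE)
  expect_equal(pm$MAT["A", "B"], 0)
  expect_equal(pm$MAT["A", "C"], 1)
  expect_equal(pm$A["A", "B"], 0)
  expect_equal(pm$A["A", "C"], 1)
  # one degree of latitude is ~111.2 km on the great circle
  expect_equal(pm$D["A", "B"], 111.19, tolerance = 1e-3)
  expect_error(predictor_matrices(transform(isl, area = c(1, -1, 1))), "area")
})

test_that("Mantel statistic and permutation p behave per contract", {
  X <- .rand_dist(8, 1)
  r <- mantel(X, X, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 100)

  Y0 <- X; Y0[] <- 1; diag(Y0) <- 0
  expect_error(mantel(X, Y0), "degenerate")
  expect_error(mantel(X[1:3, 1:3], X[1:3, 1:3]), ">= 4")

  # invariance under a common reordering of island labels
  Y <- .rand_dist(8, 2)
  p <- sample(8)
  expect_equal(mantel(X, Y, n_perm = 0 + 9, seed = 5)$r,
               mantel(X[p, p], Y[p, p], n_perm = 9, seed = 5)$r,
               tolerance = 1e-12)

  # statistic agrees with vegan's implementation
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(X), as.dist(Y), permutations = 0)
  expect_equal(mantel(X, Y, n_perm = 9, seed = 1)$r, unname(vg$statistic),
               tolerance = 1e-10)
})

test_that("exhaustive n = 4 Mantel p equals full 24-permutation enumeration", {
  for (seed in c(3, 9, 27)) {
    X <- .rand_dist(4, seed)
    Y <- .rand_dist(4, seed + 100)
    got <- mantel(X, Y, exhaustive = TRUE)
    # oracle: enumerate with an independently generated permutation set
    lt <- lower.tri(X)
    r_obs <- cor(X[lt], Y[lt])
    pm <- perms_oracle(4L)
    r_all <- apply(pm, 1, function(p) cor(X[lt], Y[p, p][lt]))
    expect_equal(got$p, mean(r_all >= r_obs - 1e-12), tolerance = 1e-12)
    expect_equal(got$n_perm, 24L)
  }
})

test_that("partial Mantel conditions by least-squares residuals", {
  X <- .rand_dist(9, 4)
  Y <- .rand_dist(9, 5)
  # conditioning on X itself annihilates the partial correlation
  pm <- partial_mantel(X, Y, X, n_perm = 49, seed = 2)
  expect_equal(pm$r, 0)
  expect_equal(pm$p, 1)

  # conditioner orthogonal to both triangles leaves the simple r unchanged
  n <- 9
  lt <- lower.tri(X)
  vx <- X[lt]; vy <- Y[lt]
  set.seed(8)
  raw <- rnorm(length(vx))
  Q <- qr.Q(qr(cbind(1, vx, vy)))
  vz <- raw - Q %*% crossprod(Q, raw)        # orthogonal to 1, vx, vy
  Z <- matrix(0, n, n); Z[lt] <- vz; Z <- Z + t(Z)
  dimnames(Z) <- dimnames(X)
  pm2 <- partial_mantel(X, Y, Z, n_perm = 9, seed = 2)
  expect_equal(pm2$r, cor(vx, vy), tolerance = 1e-9)

  # determinism under seed
  a <- partial_mantel(X, Y, Z, n_perm = 99, seed = 7)
  b <- partial_mantel(X, Y, Z, n_perm = 99, seed = 7)
  expect_identical(a$p, b$p)
  expect_warning(partial_mantel(X, Y, list(Z, Z), n_perm = 9, seed = 1),
                 "collinear")
})

test_that("hierarchical partitioning averages R2 gains over orderings", {
  set.seed(10)
  n <- 60
  # single predictor: contribution is its R2
  x <- rnorm(n); y <- x + rnorm(n)
  hp1 <- hierarchical_partitioning(y, cbind(x = x))
  expect_equal(unname(hp1$contributions["x"]), summary(lm(y ~ x))$r.squared,
               tolerance = 1e-10)

  # orthogonal predictors: contributions equal univariate R2 and sum to full R2
  # (columns orthogonal to each other AND to the intercept)
  Xo <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  colnames(Xo) <- c("a", "b", "c")
  y2 <- 2 * Xo[, 1] + 1 * Xo[, 2] + rnorm(n, sd = 0.3)
  hp <- hierarchical_partitioning(y2, Xo)
  uni <- vapply(1:3, function(j) summary(lm(y2 ~ Xo[, j]))$r.squared, 0)
  expect_equal(unname(hp$contributions), uni, tolerance = 1e-6)
  expect_equal(sum(hp$contributions), hp$full_r2, tolerance = 1e-10)

  # lmg identity on correlated random designs
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(2:4, 1)
    Xr <- matrix(rnorm(n * k), n) %*% matrix(rnorm(k * k), k)
    yr <- Xr %*% rnorm(k) + rnorm(n)
    hpr <- hierarchical_partitioning(drop(yr), Xr)
    expect_equal(sum(hpr$contributions), hpr$full_r2, tolerance = 1e-10)
    expect_true(all(hpr$contributions > -1e-10))
  }

  # duplicated predictor: equal contributions by symmetry (with a
  # rank-deficiency warning)
  expect_warning(
    hp2 <- hierarchical_partitioning(y2, cbind(p = Xo[, 1], q = Xo[, 1])),
    "conditioning")
  expect_equal(unname(hp2$contributions["p"]), unname(hp2$contributions["q"]),
               tolerance = 1e-12)
  expect_equal(sum(hp2$contributions), hp2$full_r2, tolerance = 1e-10)
})

test_that("barrier report covers all measure x predictor cells coherently", {
  sim <- simulate_dataset(params = sim_params(n_species = 3), seed = 33,
                          n_islands = 8)
  res <- suppressWarnings(run_all(sim, config = run_config(
    mode = "combined", n_perm = 99, seed = 33)))
  bt <- res$barrier_tests
  expect_equal(nrow(bt), 9L)
  expect_setequal(unique(bt$measure), c("total", "repl", "rich"))
  expect_setequal(unique(bt$predictor), c("distance", "MAT", "area"))
  expect_true(all(bt$p > 0 & bt$p <= 1))
  expect_true(all(abs(bt$r_m) <= 1))
  # variation cells within a measure sum to that measure's full R2
  for (mn in unique(bt$measure)) {
    sel <- bt$measure == mn
    expect_equal(sum(bt$variation[sel]), bt$full_r2[sel][1], tolerance = 1e-10)
  }
})
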