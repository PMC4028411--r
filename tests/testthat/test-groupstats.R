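make_contrast_map <- function(coords, contrast) {
  tibble::tibble(voxel = seq_len(nrow(coords)), x = coords[, 1],
                 y = coords[, 2], z = coords[, 3], contrast = contrast)
}

test_that("select_seed maximizes contrast within the radius only", {
  coords <- toy_coords(c(5, 5, 1))
  ct <- rep(0, nrow(coords))
  centre <- which(coords[, 1] == 0 & coords[, 2] == 0)
  near <- which(coords[, 1] == 10 & coords[, 2] == 0)    # 10 mm away
  far <- which(coords[, 1] == 20 & coords[, 2] == 10)    # ~22 mm away
  ct[near] <- 1; ct[far] <- 5
  cm <- make_contrast_map(coords, ct)
  expect_equal(select_seed(cm, coords[centre, ], radius = 20), near)
  # when the global max is inside the radius it wins
  ct2 <- ct; ct2[centre] <- 10
  expect_equal(select_seed(make_contrast_map(coords, ct2), coords[centre, ],
                           radius = 20), centre)
  expect_error(select_seed(cm, c(500, 500, 500), radius = 20),
               "no voxel within")
})

test_that("seed-search neighbourhood matches brute-force distance enumeration", {
  coords <- toy_coords(c(5, 5, 5))
  centre <- coords[which(rowSums(abs(coords)) == 0), ]
  inside_brute <- which(apply(coords, 1, function(p)
    sqrt(sum((p - centre)^2)) <= 20))
  # every inside voxel can be returned as the seed when it holds the max
  for (v in sample(inside_brute, 5)) {
    ct <- rep(0, nrow(coords)); ct[v] <- 1
    expect_equal(select_seed(make_contrast_map(coords, ct), centre, 20), v)
  }
  # an outside voxel never wins even with a huge value
  outside <- setdiff(seq_len(nrow(coords)), inside_brute)
  ct <- rep(0, nrow(coords)); ct[outside[1]] <- 100; ct[inside_brute[1]] <- 1
  expect_equal(select_seed(make_contrast_map(coords, ct), centre, 20),
               inside_brute[1])
})

test_that("select_seed breaks ties by distance then index", {
  coords <- toy_coords(c(3, 1, 1))  # x = -10, 0, 10
  ct <- c(1, 1, 1)
  expect_equal(select_seed(make_contrast_map(coords, ct), c(10, 0, 0), 20), 3)
  expect_equal(select_seed(make_contrast_map(coords, ct), c(0, 0, 0), 20), 2)
})

test_that("one_sample_t_map matches the textbook formula", {
  set.seed(61)
  maps <- matrix(rnorm(17 * 30), 17)
  sm <- one_sample_t_map(maps)
  expect_equal(sm$df, 16L)
  for (v in c(1, 7, 30)) {
    expect_equal(sm$table$t[v], t_brute(maps[, v]), tolerance = 1e-10)
  }
  # frozen fixture: 17 values, t computed independently below
  x <- c(0.12, -0.05, 0.31, 0.08, 0.22, -0.11, 0.05, 0.18, 0.02, 0.09,
         0.27, -0.02, 0.14, 0.07, 0.19, 0.03, 0.1)
  smx <- one_sample_t_map(matrix(x, 17, 1))
  expect_equal(smx$table$t[1], t_brute(x), tolerance = 1e-10)
  # Z matches the upper-tail probability of the t
  expect_equal(pnorm(smx$table$z[1], lower.tail = FALSE),
               pt(smx$table$t[1], 16, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("t of near-constant maps matches the closed form and Z is clipped", {
  n <- 10; cval <- 5; s <- 0.01
  set.seed(62)
  jit <- rnorm(n, sd = s)
  jit <- (jit - mean(jit)) / sd(jit) * s  # exact mean 0, sd s
  maps <- matrix(cval + jit, n, 1)
  sm <- one_sample_t_map(maps)
  expect_equal(sm$table$t[1], cval * sqrt(n) / s, tolerance = 1e-6)
  expect_equal(sm$table$z[1], 8)  # clipped
  expect_warning(one_sample_t_map(matrix(rep(1, 5 * 2), 5)), "zero-variance")
})

test_that("type-I rate of the voxel threshold is nominal on null maps", {
  set.seed(63)
  nv <- 20000
  maps <- matrix(rnorm(17 * nv), 17)
  sm <- one_sample_t_map(maps)
  rate <- mean(sm$table$p < 0.001)
  se <- sqrt(0.001 * 0.999 / nv)
  expect_lt(abs(rate - 0.001), 4 * se)
})

test_that("cluster extent and 6-connectivity rules are enforced", {
  coords <- toy_coords(c(6, 6, 2))
  nvox <- nrow(coords)
  n <- 17
  base <- matrix(rnorm(n * nvox, sd = 0.1), n)
  # a 12-voxel connected blob (3 x 2 x 2 block)
  blob <- which(coords[, 1] %in% c(-25, -15, -5) & coords[, 2] %in% c(-25, -15))
  expect_length(blob, 12L)
  maps <- base; maps[, blob] <- maps[, blob] + 5
  sm <- cluster_threshold(one_sample_t_map(maps, coords), coords)
  expect_equal(nrow(sm$clusters), 1L)
  expect_equal(sm$clusters$extent, 12L)
  # a 9-voxel blob is discarded under min_extent = 10
  blob9 <- blob[1:9]
  maps9 <- base; maps9[, blob9] <- maps9[, blob9] + 5
  sm9 <- cluster_threshold(one_sample_t_map(maps9, coords), coords)
  expect_true(is.null(sm9$clusters) || nrow(sm9$clusters) == 0L)
  # two blobs touching only diagonally form 2 clusters (faces-only)
  b1 <- which(coords[, 1] %in% c(-25, -15) & coords[, 2] %in% c(-25, -15))
  b2 <- which(coords[, 1] %in% c(-5, 5) & coords[, 2] %in% c(-5, 5))
  mapsd <- base; mapsd[, c(b1, b2)] <- mapsd[, c(b1, b2)] + 5
  smd <- cluster_threshold(one_sample_t_map(mapsd, coords), coords,
                           min_extent = 4)
  expect_equal(nrow(smd$clusters), 2L)
})

test_that("an extreme cluster attains the minimum permutation p-value", {
  set.seed(64)
  coords <- toy_coords(c(4, 4, 2))
  n <- 20
  maps <- matrix(rnorm(n * nrow(coords), sd = 0.05), n)
  blob <- which(coords[, 1] < 0 & coords[, 2] < 0)  # 2x2x2 x2 = 8... take all
  maps[, blob] <- maps[, blob] + 10
  res <- suppressWarnings(
    cluster_fwe_permutation(maps, coords, min_extent = 5, n_perm = 199))
  expect_equal(min(res$clusters$p_fwe), 1 / 200)
  expect_warning(cluster_fwe_permutation(maps, coords, min_extent = 5,
                                         n_perm = 50), "coarse")
})

test_that("permutation FWE p-values are valid under the null", {
  set.seed(65)
  coords <- toy_coords(c(4, 4, 3))
  alpha_hits <- replicate(60, {
    maps <- matrix(rnorm(12 * nrow(coords)), 12)
    res <- cluster_fwe_permutation(maps, coords, p_voxel = 0.05,
                                   min_extent = 1, n_perm = 99)
    if (!is.null(res$clusters) && nrow(res$clusters)) {
      min(res$clusters$p_fwe) <= 0.05
    } else {
      FALSE
    }
  })
  # P(any FWE-significant cluster) <= ~0.05 under the null
  expect_lte(mean(alpha_hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})
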