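test_that("Spearman rho matches its closed forms and rank-formula oracle", {
  expect_equal(spearman_rho(1:6, c(2, 4, 6, 8, 10, 12))$rho, 1)
  expect_equal(spearman_rho(1:5, -(1:5))$rho, -1)
  s <- spearman_rho(1:5, c(3, 1, 4, 2, 5))
  expect_equal(s$rho, spearman_d2_oracle(1:5, c(3, 1, 4, 2, 5)))
  # random tie-free vectors against the 1 - 6*sum(d^2)/(n(n^2-1)) formula
  set.seed(11)
  for (r in 1:50) {
    n <- sample(4:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(spearman_rho(x, y)$rho, spearman_d2_oracle(x, y),
                 tolerance = 1e-12)
    # and against R's own implementation (ties handled the same way)
    expect_equal(spearman_rho(x, y)$rho,
                 unname(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
  # constant input is flagged, not guessed
  cs <- spearman_rho(rep(1, 6), rnorm(6))
  expect_true(cs$flag && is.na(cs$rho))
  expect_error(spearman_rho(1:3, 3:1), "at least 4")
})

test_that("correlation map respects subject alignment and missingness", {
  set.seed(12)
  n <- 8
  z <- rnorm(n)
  diffs <- stats::setNames(z, paste0("s", 1:n))
  # noiseless linear maps -> rho = 1 in every cell
  maps <- array(0, c(n, 3, 4), dimnames = list(names(diffs), NULL, NULL))
  for (i in 1:3) for (j in 1:4) maps[, i, j] <- 2 * z + i + j
  cm <- correlation_map(diffs, maps)
  expect_true(all(cm$rho == 1))
  expect_true(all(cm$p == 0))
  # constant maps across subjects -> undefined everywhere, flagged
  maps0 <- array(1, c(n, 3, 4), dimnames = list(names(diffs), NULL, NULL))
  cm0 <- correlation_map(diffs, maps0)
  expect_true(all(cm0$flagged))
  # misaligned subject identifiers are an error, not a silent mismatch
  shuffled <- maps
  dimnames(shuffled)[[1]] <- rev(names(diffs))
  expect_error(correlation_map(diffs, shuffled), "disagree")
  # subjects with missing cells are dropped; too few left is an error
  maps[1:5, 1, 1] <- NA
  expect_error(correlation_map(diffs, maps), "fewer than 4")
})

test_that("cluster formation obeys adjacency, sign separation and the oracle", {
  # L-shaped positive region in a 3x3 grid
  p <- matrix(1, 3, 3); rho <- matrix(0.5, 3, 3)
  p[cbind(c(1, 2, 2), c(1, 1, 2))] <- 0.01
  cl <- form_clusters(p, rho)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$cells), 3)
  expect_equal(cl[[1]]$mass, 3 * 0.5)
  expect_equal(cl[[1]]$sign, "positive")
  # diagonal contact does not join clusters
  p2 <- matrix(1, 3, 3)
  p2[1, 1] <- 0.01; p2[2, 2] <- 0.01
  cl2 <- form_clusters(p2, rho)
  expect_length(cl2, 2)
  # opposite signs split an orthogonally connected region
  p3 <- matrix(1, 3, 3); rho3 <- matrix(0, 3, 3)
  p3[1, 1] <- 0.01; rho3[1, 1] <- 0.6
  p3[2, 1] <- 0.01; rho3[2, 1] <- -0.6
  cl3 <- form_clusters(p3, rho3)
  expect_length(cl3, 2)
  expect_setequal(vapply(cl3, `[[`, character(1), "sign"),
                  c("positive", "negative"))
  # no supra-threshold cells -> empty list
  expect_length(form_clusters(matrix(1, 2, 2), matrix(0.2, 2, 2)), 0)
  # random grids against an independent recursive flood fill
  set.seed(13)
  for (r in 1:200) {
    rr <- matrix(runif(36, -1, 1), 6, 6)
    pp <- matrix(runif(36), 6, 6)
    got <- canon_clusters(form_clusters(pp, rr, alpha = 0.3), 6)
    want <- floodfill_oracle(pp < 0.3 & rr != 0, rr)
    want_cells <- lapply(want, `[[`, "cells")
    ord <- order(vapply(want_cells, min, numeric(1)))
    expect_identical(got$cells, want_cells[ord])
    expect_equal(got$mass, vapply(want, `[[`, numeric(1), "mass")[ord],
                 tolerance = 1e-12)
  }
})

test_that("|rho| thresholding in the null loop equals p-value thresholding", {
  set.seed(14)
  for (n in c(6, 10, 20)) {
    rho <- runif(500, -1, 1)
    p <- imcoh:::spearman_p(rho, n)
    rc <- imcoh:::rho_crit(n, 0.05)
    expect_identical(p < 0.05, abs(rho) > rc)
  }
})

test_that("permutation test is seed-reproducible and reports valid p-values", {
  set.seed(15)
  n <- 12
  z <- rnorm(n)
  diffs <- stats::setNames(z, paste0("s", 1:n))
  maps <- array(rnorm(n * 8 * 9), c(n, 8, 9),
                dimnames = list(names(diffs), NULL, NULL))
  maps[, 3:5, 2:6] <- maps[, 3:5, 2:6] + array(1.2 * z, c(n, 3, 5))
  r1 <- permutation_test(diffs, maps, n_perm = 200, seed = 7)
  r2 <- permutation_test(diffs, maps, n_perm = 200, seed = 7)
  expect_identical(r1$null, r2$null)
  expect_identical(summary(r1), summary(r2))
  r3 <- permutation_test(diffs, maps, n_perm = 200, seed = 8)
  expect_false(identical(r1$null, r3$null))
  # permutation p = (1 + #{null >= mass}) / (1 + n_perm)
  for (cl in r1$clusters) {
    expect_equal(cl$p_perm,
                 (1 + sum(r1$null >= cl$mass)) / (1 + length(r1$null)))
    expect_identical(cl$significant, cl$mass > r1$threshold)
  }
  expect_true(all(r1$null >= 0))
  expect_error(permutation_test(diffs, maps, n_perm = 50), "at least 100")
})

test_that("small samples fall back to complete enumeration of permutations", {
  set.seed(16)
  n <- 5
  diffs <- stats::setNames(rnorm(n), paste0("s", 1:n))
  maps <- array(rnorm(n * 4 * 4), c(n, 4, 4),
                dimnames = list(names(diffs), NULL, NULL))
  r <- permutation_test(diffs, maps, n_perm = 150, seed = 1)
  expect_equal(r$n_perm, factorial(5))
})

test_that("the enumerated null is invariant to relabeling subjects", {
  # with full enumeration the max-mass null is a fixed multiset under any
  # joint relabeling of (diffs, maps) -- exchangeability under the null
  set.seed(17)
  n <- 5
  diffs <- stats::setNames(rnorm(n), paste0("s", 1:n))
  maps <- array(rnorm(n * 4 * 4), c(n, 4, 4),
                dimnames = list(names(diffs), NULL, NULL))
  r1 <- permutation_test(diffs, maps, n_perm = 150, seed = 1)
  pp <- c(3, 1, 5, 2, 4)
  r2 <- permutation_test(diffs[pp], maps[pp, , , drop = FALSE],
                         n_perm = 150, seed = 99)
  expect_equal(r1$n_perm, factorial(n))
  expect_equal(sort(r1$null), sort(r2$null), tolerance = 1e-12)
})
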