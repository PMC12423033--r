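test_that("fc_matrix handles perfect, anti- and null correlation", {
  t <- (0:199) * TR
  a <- sin(2 * pi * 0.05 * t)
  m <- rbind(a, a, -a)
  r <- suppressWarnings(fc_matrix(m))
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_true(isSymmetric(r))
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)

  set.seed(5)
  big <- matrix(rnorm(10 * 10000), 10)
  r2 <- fc_matrix(big)
  expect_lt(max(abs(r2[upper.tri(r2)])), 0.05)

  expect_error(fc_matrix(matrix(1:4, 2, 2)), "3 time points")
  expect_warning(rc <- fc_matrix(rbind(a, rep(1, 200))), "constant")
  expect_equal(rc[1, 2], 0)
})

test_that("fisher_z is atanh with clipping at |r| = 1", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
  expect_error(fisher_z(1.5), "\\[-1, 1\\]")
})

test_that("shuffled-mode null destroys planted correlation and is seeded", {
  set.seed(3)
  n <- 1200
  shared <- rnorm(n)
  m <- rbind(shared + 0.5 * rnorm(n), shared + 0.5 * rnorm(n),
             shared + 0.5 * rnorm(n))
  expect_gt(min(fc_matrix(m)[upper.tri(diag(3))]), 0.7) # planted r ~ 0.8
  nulls <- build_null(m, n_perm = 200, seed = 9)
  offdiag <- apply(nulls, 1, function(z) z[upper.tri(z)])
  expect_lt(mean(abs(offdiag)), 0.05)
  expect_identical(nulls, build_null(m, n_perm = 200, seed = 9))
  expect_warning(build_null(m, n_perm = 10, seed = 1), "small")
  expect_error(build_null(m, n_perm = 0), "positive")
})

test_that("small-sample null variance matches brute-force enumeration", {
  # C = 2, T = 4: enumerate all (4!)^2 per-channel permutation pairs
  m <- rbind(c(0.3, -1.2, 0.8, 2.1), c(-0.5, 1.4, 0.2, -1.1))
  allp <- matrix(unlist(all_permutations(4)), ncol = 4, byrow = TRUE)
  zs <- c()
  for (i in seq_len(nrow(allp))) {
    for (j in seq_len(nrow(allp))) {
      r <- cor(m[1, allp[i, ]], m[2, allp[j, ]])
      zs <- c(zs, atanh(min(max(r, -1 + 1e-7), 1 - 1e-7)))
    }
  }
  exact_var <- var(zs)
  nulls <- build_null(m, n_perm = 2000, seed = 2)
  emp_var <- var(nulls[, 1, 2])
  expect_lt(abs(emp_var - exact_var) / exact_var, 0.25)
})

test_that("average_fc equals the per-entry mean", {
  set.seed(8)
  stack <- array(rnorm(5 * 4 * 4), c(5, 4, 4))
  avg <- average_fc(stack)
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) brute[i, j] <- mean(stack[, i, j])
  expect_equal(avg, brute, tolerance = 1e-12)
  one <- stack[1, , ]
  expect_equal(average_fc(array(rep(one, each = 3), c(3, 4, 4))), one)
})

test_that("module ordering reorders and inverts exactly", {
  labs <- paste0("R", 1:6)
  ord <- module_ordering(labs[c(1, 4, 2, 5, 3, 6)],
                         c("A", "B", "A", "B", "A", "B"))
  set.seed(2)
  m <- matrix(rnorm(36), 6, 6)
  m <- m + t(m)
  dimnames(m) <- list(labs, labs)
  om <- order_by_module(m, ord)
  # modules contiguous
  expect_equal(attr(om, "module"), c("A", "A", "A", "B", "B", "B"),
               ignore_attr = TRUE)
  # invert: reorder back by original labels
  inv <- om[labs, labs]
  expect_equal(inv, m, ignore_attr = TRUE)
  expect_error(module_ordering(c("a", "a"), c("A", "B")), "duplicate")
})

test_that("module ordering restores planted blocks", {
  # block-diagonal truth scrambled, then reordered: block mass is restored
  C <- 12
  mods <- rep(c("m1", "m2", "m3"), each = 4)
  labs <- paste0("R", 1:C)
  truth <- outer(mods, mods, "==") * 0.8 + diag(C) * 0.2
  dimnames(truth) <- list(labs, labs)
  scramble <- sample(C)
  scr <- truth[scramble, scramble]
  ord <- module_ordering(labs[scramble], mods[scramble])
  restored <- order_by_module(scr, ord)
  block_mass <- function(m, groups) {
    sum(m[outer(groups, groups, "==")])
  }
  expect_equal(block_mass(restored, attr(restored, "module")),
               block_mass(truth, mods))
  expect_true(all(diff(match(attr(restored, "module"),
                             unique(attr(restored, "module")))) >= 0))
})

test_that("group significance controls errors and validates input", {
  set.seed(1)
  obs <- array(rnorm(5 * 4 * 4, sd = 0.03), c(5, 4, 4))
  nulls <- array(rnorm(5 * 50 * 4 * 4, sd = 0.03), c(5, 50, 4, 4))
  mask <- group_significance(obs, nulls, q = 0.05, n_stat_perm = 200, seed = 3)
  expect_true(isSymmetric(mask))
  expect_false(any(diag(mask)))
  expect_error(group_significance(obs[1, , , drop = FALSE], nulls), "2 participants")
  expect_error(group_significance(obs, nulls, q = 1.5), "q")
  # determinism
  mask2 <- group_significance(obs, nulls, q = 0.05, n_stat_perm = 200, seed = 3)
  expect_identical(mask, mask2)
})

test_that("a strong common edge is detected against the shuffled null", {
  # one edge with true r ~ 0.75 in all participants, C = 4, T = 600
  set.seed(7)
  N <- 8
  C <- 4
  n <- 600
  obs <- array(NA_real_, c(N, C, C))
  nulls <- array(NA_real_, c(N, 100, C, C))
  for (p in seq_len(N)) {
    base <- rnorm(n)
    m <- rbind(base + 0.6 * rnorm(n), base + 0.6 * rnorm(n),
               rnorm(n), rnorm(n))
    obs[p, , ] <- fisher_z(fc_matrix(m))
    nulls[p, , , ] <- build_null(m, n_perm = 100, seed = 100 + p)
  }
  mask <- group_significance(obs, nulls, q = 0.01, n_stat_perm = 2000, seed = 5)
  expect_true(mask[1, 2])
  expect_false(any(mask[3, 4]))
})

test_that("fc_analysis wires participants, nulls and tidiers together", {
  fitlist <- lapply(1:3, function(p) {
    set.seed(p)
    m <- tone_matrix(c(0.02, 0.10), 4, n = 400) +
      matrix(rnorm(4 * 400, sd = 0.3), 4)
    mvmd(t(m), dt = TR, k = 2, tau = 0)
  })
  res <- fc_analysis(fitlist, mode_index = 2, n_perm = 100,
                     n_stat_perm = 200, seed = 4)
  expect_s3_class(res, "fc_result")
  expect_equal(dim(res$per_participant_z), c(3, 4, 4))
  expect_true(isSymmetric(res$group_mean_z))
  td <- tidy(res)
  expect_equal(nrow(td), 6)
  expect_true(all(c("roi_i", "roi_j", "mean_z", "significant") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_edges, 6)
})
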