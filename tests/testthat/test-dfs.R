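test_that("a single-site spectrum is stratified by hand-checkable values", {
  counts <- array(0, dim = c(3, 3, 3))
  counts[1, 2, 3] <- 1  # derived counts (0, 1, 2) with n = 2 everywhere
  res <- dfs(joint_sfs(counts))
  tbl <- tidy(res)
  # c_abba = 1 * 0.5 * 1 = 0.5, c_baba = 0; all mass in bin k = 1
  expect_equal(tbl$d_k, c(1, NA))
  expect_equal(tbl$w_k, c(1, 0))
  expect_equal(res$d_overall, 1)
  expect_equal(res$abba_total, 0.5)
  expect_equal(res$baba_total, 0)
})

test_that("spectra symmetric in P1 and P2 have zero D everywhere", {
  set.seed(42)
  for (rep in 1:5) {
    s <- random_sfs(n = 4L)
    sym <- unclass(s) + aperm(unclass(s), c(2, 1, 3))
    res <- dfs(joint_sfs(sym))
    expect_equal(res$d_overall, 0, tolerance = 1e-12)
    expect_true(all(abs(res$tbl$d_k) < 1e-12, na.rm = TRUE))
  }
})

test_that("the SFS path agrees exactly with per-site brute-force enumeration", {
  set.seed(7)
  for (rep in 1:20) {
    s <- random_sfs(n = 5L, n3 = sample(2:6, 1))
    res <- dfs(s)
    ref <- brute_force_dfs(unclass(s))
    expect_equal(res$tbl$d_k, ref$d_k)
    expect_equal(res$tbl$w_k, ref$w_k)
    expect_equal(res$d_overall, ref$d_overall)
    expect_equal(res$abba_total, ref$abba_total)
    expect_equal(res$baba_total, ref$baba_total)
  }
})

test_that("weights normalise and the weighted bins reconstruct overall D", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_sfs(n = sample(2:8, 1))
    res <- dfs(s)
    expect_equal(sum(res$tbl$w_k), 1, tolerance = 1e-12)
    ok <- !is.na(res$tbl$d_k)
    expect_equal(sum(res$tbl$w_k[ok] * res$tbl$d_k[ok]), res$d_overall,
                 tolerance = 1e-12)
    expect_true(all(res$tbl$w_k[!ok] == 0))
    expect_true(all(abs(res$tbl$d_k[ok]) <= 1 + 1e-12))
    expect_true(all(res$tbl$w_k >= 0 & res$tbl$w_k <= 1))
    expect_true(abs(res$d_overall) <= 1 + 1e-12)
  }
})

test_that("swapping P1 and P2 negates every bin and preserves weights", {
  set.seed(13)
  for (rep in 1:10) {
    s <- random_sfs(n = sample(2:6, 1))
    a <- dfs(s)
    b <- dfs(swap_p1_p2(s))
    expect_equal(b$tbl$d_k, -a$tbl$d_k)
    expect_equal(b$tbl$w_k, a$tbl$w_k, tolerance = 1e-12)
    expect_equal(b$d_overall, -a$d_overall, tolerance = 1e-12)
  }
  # swap specifics: a symmetric spectrum maps to itself, a cell transposes
  s <- random_sfs(n = 3L)
  sym <- joint_sfs(unclass(s) + aperm(unclass(s), c(2, 1, 3)))
  expect_equal(unclass(swap_p1_p2(sym)), unclass(sym))
  one <- array(0, dim = c(3, 3, 3)); one[1, 2, 3] <- 1
  expect_equal(which(unclass(swap_p1_p2(joint_sfs(one))) == 1, arr.ind = TRUE),
               matrix(c(2L, 1L, 3L), 1, dimnames = list(NULL, c("dim1", "dim2", "dim3"))))
})

test_that("fractional (projected) mass is handled natively", {
  set.seed(17)
  s <- random_sfs(n = 6L)
  p <- project_sfs(s, c(4, 4, 4))
  res <- dfs(p)
  expect_equal(sum(res$tbl$w_k), 1, tolerance = 1e-12)
  ref <- brute_force_dfs(unclass(p))
  expect_equal(res$tbl$d_k, ref$d_k)
})

test_that("unequal focal sample sizes are projected to the smaller size", {
  set.seed(19)
  counts <- array(rpois(7 * 5 * 4, 2), dim = c(7, 5, 4))
  s <- joint_sfs(counts)
  expect_message(res <- dfs(s), "projecting")
  expect_equal(res$n, 4L)
  direct <- dfs(project_sfs(s, c(4, 4, 3)))
  expect_equal(res$tbl, direct$tbl)
})

test_that("degenerate inputs are signalled, not silently computed", {
  z <- array(0, dim = c(3, 3, 3))
  expect_error(dfs(joint_sfs(z)), "zero total mass")
  # mass only where both patterns vanish (p3 = 0): undefined D
  m <- z; m[2, 2, 1] <- 5
  res <- dfs(joint_sfs(m))
  expect_true(is.na(res$d_overall))
  expect_true(all(is.na(res$tbl$d_k)))
  unpol <- joint_sfs(array(1, dim = c(2, 2, 2)), polarized = FALSE)
  expect_error(dfs(unpol), "polarized")
})

test_that("bootstrap errors shrink with site count and cover the truth", {
  set.seed(23)
  s <- random_sfs(n = 4L, max_count = 200L)
  b <- dfs_bootstrap(s, n_boot = 60)
  expect_equal(b$bins$d_k, dfs(s)$tbl$d_k)
  expect_true(all(b$bins$se >= 0, na.rm = TRUE))
  big <- joint_sfs(unclass(s) * 100, sample_sizes = sfs_sample_sizes(s))
  b_big <- dfs_bootstrap(big, n_boot = 60)
  expect_lt(b_big$d_overall_se, b$d_overall_se)
})
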