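test_that("pairwise coalescence times match the classical expectations", {
  # two lineages in one population of relative size nu coalesce after nu
  # units of 2N generations on average
  m1 <- demographic_model(npop = 1)
  t1 <- simulate_tmrca(m1, samples = c(2L), n_rep = 5e4, seed = 2)
  se1 <- sd(t1) / sqrt(length(t1))
  expect_lt(abs(mean(t1) - 1), 3 * se1)

  m_half <- demographic_model(npop = 1,
                              sizes = tibble::tibble(pop = 1, start = 0, nu = 0.5))
  t2 <- simulate_tmrca(m_half, samples = c(2L), n_rep = 5e4, seed = 3)
  expect_lt(abs(mean(t2) - 0.5), 3 * sd(t2) / sqrt(length(t2)))
})

test_that("lineages in unmerged pools cannot coalesce before the split", {
  m <- demographic_model(npop = 2,
                         merges = tibble::tibble(time = 1, from = 1, to = 2))
  t <- simulate_tmrca(m, samples = c(1L, 1L), n_rep = 2000, seed = 4)
  expect_true(all(t >= 1))
  # and a model whose pools never merge is refused, not spun forever
  m_bad <- demographic_model(npop = 2)
  expect_error(simulate_tmrca(m_bad, samples = c(1L, 1L), n_rep = 10, seed = 5),
               "never merge")
})

test_that("a genealogy is a single rooted binary tree with ordered times", {
  g <- simulate_genealogy(presets("fig2a_recent_geneflow"),
                          samples = c(4L, 4L, 4L), seed = 6)
  expect_equal(nrow(g), 2 * 12 - 1)
  expect_equal(sum(g$parent == 0), 1L)   # one root
  internal <- g$node[g$time > 0]
  expect_equal(length(internal), 11L)
  # every coalescence is strictly older than both children
  kids <- g[g$parent != 0, ]
  expect_true(all(g$time[kids$parent] > kids$time - 1e-12))
  # leaf bookkeeping: the root subtends the full sample
  root <- g[g$parent == 0, ]
  expect_equal(c(root$leaves_p1, root$leaves_p2, root$leaves_p3), c(4, 4, 4))
})

test_that("simulated spectra are seed-deterministic", {
  m <- presets("fig2a_recent_geneflow")
  a <- simulate_joint_sfs(m, samples = c(4L, 4L, 4L), n_sites = 500, seed = 77)
  b <- simulate_joint_sfs(m, samples = c(4L, 4L, 4L), n_sites = 500, seed = 77)
  c <- simulate_joint_sfs(m, samples = c(4L, 4L, 4L), n_sites = 500, seed = 78)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(c)))
  expect_equal(sum(unclass(a)), 500)
})

test_that("the mutation window restricts placement to old branches", {
  # two lineages in one population with mutations allowed only above t = 0.5:
  # every genealogy with TMRCA <= 0.5 must be redrawn, at expected odds
  # (1 - p) / p with p = P(TMRCA > 0.5) = exp(-0.5), and every site is a
  # singleton placed on one of the two root branches
  m <- demographic_model(npop = 1, mutation_window = c(0.5, Inf))
  n_sites <- 4000
  s <- simulate_joint_sfs(m, samples = c(2L, 0L, 0L), n_sites = n_sites, seed = 9)
  expect_equal(sum(unclass(s)[2, 1, 1]), n_sites)
  p <- exp(-0.5)
  odds <- (1 - p) / p
  se <- sqrt(n_sites * odds * (1 + odds))  # geometric-failure count spread
  expect_lt(abs(attr(s, "resampled") - n_sites * odds), 4 * se)
})

test_that("restricting mutations to the pre-split era depletes young variants", {
  m_all <- presets("fig2a_recent_geneflow")
  m_anc <- presets("s3_ancient_mutations_only")
  n_sites <- 6000
  s_all <- simulate_joint_sfs(m_all, samples = c(4L, 4L, 4L), n_sites = n_sites, seed = 9)
  s_anc <- simulate_joint_sfs(m_anc, samples = c(4L, 4L, 4L), n_sites = n_sites, seed = 9)
  # variants private to P3 arise disproportionately on branches younger than
  # the deepest split, so the ancient-only window must carry fewer of them
  priv_p3 <- function(s) sum(unclass(s)[1, 1, -1])
  test <- prop.test(c(priv_p3(s_anc), priv_p3(s_all)), c(n_sites, n_sites),
                    alternative = "less")
  expect_lt(test$p.value, 0.001)
})

test_that("the grid runner is deterministic and reduces to single runs", {
  grid <- tibble::tibble(M = c(0, 2))
  g1 <- dfs_grid("fig2a_recent_geneflow", grid, samples = c(4L, 4L, 4L),
                 n_sites = 2000, seed = 10)
  g2 <- dfs_grid("fig2a_recent_geneflow", grid, samples = c(4L, 4L, 4L),
                 n_sites = 2000, seed = 10)
  expect_equal(g1, g2)
  expect_equal(nrow(g1), 2L)
  expect_true(all(is.na(g1$error)))
  expect_gt(g1$d_overall[g1$M == 2], g1$d_overall[g1$M == 0])
  # a single-row grid equals the direct simulate + stratify path
  one <- dfs_grid("no_geneflow", NULL, samples = c(4L, 4L, 4L),
                  n_sites = 1000, seed = 10)
  expect_equal(nrow(one), 1L)
  # failures are recorded per combination without aborting the run
  bad <- dfs_grid("fig2a_recent_geneflow",
                  tibble::tibble(M = c(2, -1)), samples = c(4L, 4L, 4L),
                  n_sites = 500, seed = 10)
  expect_true(is.na(bad$error[1]) && !is.na(bad$error[2]))
})

test_that("migration events move lineages: gene flow leaves a D signal", {
  s0 <- simulate_joint_sfs(presets("no_geneflow"), n_sites = 3e4, seed = 12)
  s2 <- simulate_joint_sfs(presets("fig2a_recent_geneflow", M = 2),
                           n_sites = 3e4, seed = 12)
  d0 <- dfs(s0); d2 <- dfs(s2)
  b0 <- dfs_bootstrap(s0, 50); b2 <- dfs_bootstrap(s2, 50)
  expect_gt(d2$d_overall - d0$d_overall,
            3 * sqrt(b0$d_overall_se^2 + b2$d_overall_se^2))
})
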