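# Independent brute-force reference for the stratified statistic: expand an
# SFS into individual sites and accumulate the per-site pattern contributions
# bin by bin with plain loops. Deliberately shares no code with the package's
# array-based implementation.
brute_force_dfs <- function(counts, n3 = dim(counts)[3] - 1L) {
  n <- dim(counts)[1] - 1L
  stopifnot(dim(counts)[2] - 1L == n)
  A_k <- numeric(n)
  B_k <- numeric(n)
  abba_tot <- 0
  baba_tot <- 0
  for (i1 in 0:n) {
    for (i2 in 0:n) {
      for (i3 in 0:n3) {
        m <- counts[i1 + 1L, i2 + 1L, i3 + 1L]
        if (m == 0) next
        p1 <- i1 / n; p2 <- i2 / n; p3 <- i3 / n3
        cab <- (1 - p1) * p2 * p3
        cba <- p1 * (1 - p2) * p3
        abba_tot <- abba_tot + m * cab
        baba_tot <- baba_tot + m * cba
        if (i2 >= 1L) A_k[i2] <- A_k[i2] + m * cab
        if (i1 >= 1L) B_k[i1] <- B_k[i1] + m * cba
      }
    }
  }
  tot <- abba_tot + baba_tot
  d_k <- ifelse(A_k + B_k > 0, (A_k - B_k) / (A_k + B_k), NA_real_)
  list(
    d_k = d_k,
    w_k = if (tot > 0) (A_k + B_k) / tot else rep(0, n),
    d_overall = if (tot > 0) (abba_tot - baba_tot) / tot else NA_real_,
    abba_total = abba_tot,
    baba_total = baba_tot
  )
}

# random integer joint SFS for property tests
random_sfs <- function(n = 5L, n3 = n, max_count = 20L) {
  counts <- array(sample(0:max_count, (n + 1L)^2 * (n3 + 1L), replace = TRUE),
                  dim = c(n + 1L, n + 1L, n3 + 1L))
  joint_sfs(counts, sample_sizes = c(n, n, n3), polarized = TRUE)
}
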