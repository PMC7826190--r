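#' Per-site ABBA and BABA pattern contributions
#'
#' For a biallelic site with derived-allele frequencies `p1`, `p2`, `p3` in
#' the three focal populations (the outgroup assumed fixed ancestral), the
#' site's contribution to the ABBA class is `(1 - p1) * p2 * p3` and to the
#' BABA class `p1 * (1 - p2) * p3`. With single haploid sequences these
#' reduce to the classical 0/1 pattern indicators.
#'
#' @param p1,p2,p3 Numeric vectors of derived-allele frequencies in `[0, 1]`
#'   (recycled to a common length).
#' @return A tibble with columns `c_abba` and `c_baba`.
#' @export
#' @examples
#' pattern_weights(0, 1, 1)        # a pure ABBA site
#' pattern_weights(0.2, 0.4, 0.5)
pattern_weights <- function(p1, p2, p3) {
  if (anyNA(c(p1, p2, p3)) ||
      any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1) || any(p3 < 0 | p3 > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    c_abba = (1 - p1) * p2 * p3,
    c_baba = p1 * (1 - p2) * p3
  )
}

#' The D-statistic from summed pattern contributions
#'
#' `(abba - baba) / (abba + baba)`. When both sums are zero the statistic is
#' undefined and `NA` is returned (never 0: a zero denominator carries no
#' information about balance).
#'
#' @param abba_sum,baba_sum Non-negative sums of ABBA and BABA contributions
#'   (vectorised).
#' @return Numeric vector in `[-1, 1]`, `NA` where both sums are zero.
#' @export
d_statistic <- function(abba_sum, baba_sum) {
  if (any(abba_sum < 0, na.rm = TRUE) || any(baba_sum < 0, na.rm = TRUE)) {
    stop("pattern sums must be non-negative", call. = FALSE)
  }
  tot <- abba_sum + baba_sum
  ifelse(tot > 0, (abba_sum - baba_sum) / tot, NA_real_)
}

#' The D frequency spectrum from a polarized joint SFS
#'
#' Partitions the ABBA-BABA D-statistic by derived-allele frequency. For each
#' bin `k` in `1..n` (with `n` the common haploid sample size of P1 and P2),
#' the bin's ABBA mass sums site contributions `(1 - p1) * p2 * p3` over
#' sites where the derived allele occurs exactly `k` times in P2, and its
#' BABA mass sums `p1 * (1 - p2) * p3` over sites where the derived allele
#' occurs `k` times in P1. The stratified value is
#' `D_k = (A_k - B_k) / (A_k + B_k)` and the bin weight
#' `w_k = (A_k + B_k) / (sum A + sum B)` is its share of the total pattern
#' mass, so that `sum_k w_k * D_k` equals the overall D exactly.
#'
#' Bin `k = 0` is structurally empty (both contributions vanish there) and is
#' omitted. Bins with zero mass have `D_k = NA` and `w_k = 0`.
#'
#' If P1 and P2 sample sizes differ, both focal axes are first projected down
#' to the smaller size by exact hypergeometric downsampling (with a message).
#'
#' @param sfs A polarized `joint_sfs`.
#' @return An object of class `dfs_result`; see [tidy.dfs_result()] and
#'   [glance.dfs_result()] for tabular views and [autoplot.dfs_result()] for
#'   the standard bar figure.
#' @export
#' @examples
#' counts <- array(0, dim = c(3, 3, 3))
#' counts[1, 2, 3] <- 1
#' res <- dfs(joint_sfs(counts))
#' tidy(res)
#' glance(res)
dfs <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  if (!attr(sfs, "polarized")) {
    stop("D_FS requires a polarized (unfolded) joint SFS; see polarize_sfs()",
         call. = FALSE)
  }
  sz <- attr(sfs, "sample_sizes")
  if (sz[1] != sz[2]) {
    n <- min(sz[1:2])
    message(sprintf(
      "P1 and P2 sample sizes differ (%d, %d); projecting both to n = %d",
      sz[1], sz[2], n))
    sfs <- project_sfs(sfs, c(n, n, sz[3]))
    sz <- attr(sfs, "sample_sizes")
  }
  n <- sz[1]
  n3 <- sz[3]
  x <- unclass(sfs)
  if (sum(x) <= 0) stop("SFS has zero total mass", call. = FALSE)

  p1 <- (0:n) / n
  p2 <- (0:n) / n
  p3 <- (0:n3) / n3
  abba <- x * outer(outer(1 - p1, p2), p3)     # (1-p1) p2 p3 per cell
  baba <- x * outer(outer(p1, 1 - p2), p3)     # p1 (1-p2) p3 per cell

  # A_k: ABBA mass in cells with derived count k in P2; B_k: BABA with k in P1
  A <- apply(abba, 2L, sum)[-1L]               # drop k = 0 (identically zero)
  B <- apply(baba, 1L, sum)[-1L]
  abba_total <- sum(abba)
  baba_total <- sum(baba)
  total <- abba_total + baba_total

  d_k <- d_statistic(A, B)
  w_k <- if (total > 0) (A + B) / total else rep(0, n)

  structure(
    list(
      n = n,
      tbl = tibble::tibble(
        k = seq_len(n),
        freq = seq_len(n) / n,
        d_k = d_k,
        w_k = w_k,
        abba_k = A,
        baba_k = B
      ),
      d_overall = d_statistic(abba_total, baba_total),
      abba_total = abba_total,
      baba_total = baba_total
    ),
    class = "dfs_result"
  )
}

#' @export
print.dfs_result <- function(x, ...) {
  cat(sprintf("D frequency spectrum (n = %d bins)\n", x$n))
  cat(sprintf("  overall D = %s  (ABBA = %.6g, BABA = %.6g)\n",
              format(x$d_overall, digits = 4), x$abba_total, x$baba_total))
  print(x$tbl[, c("k", "freq", "d_k", "w_k")], n = min(x$n, 12L))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-bin table of a D frequency spectrum
#'
#' @param x A `dfs_result`.
#' @param ... Unused.
#' @return A tibble with one row per frequency bin: `k`, `freq` (= k/n),
#'   `d_k` (`NA` where the bin carries no pattern mass), `w_k`, and the raw
#'   bin masses `abba_k`, `baba_k`.
#' @export
tidy.dfs_result <- function(x, ...) x$tbl

#' One-row summary of a D frequency spectrum
#'
#' @param x A `dfs_result`.
#' @param ... Unused.
#' @return A tibble with `n`, `d_overall`, `abba_total`, `baba_total` and
#'   `n_defined_bins`.
#' @export
glance.dfs_result <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    d_overall = x$d_overall,
    abba_total = x$abba_total,
    baba_total = x$baba_total,
    n_defined_bins = sum(!is.na(x$tbl$d_k))
  )
}

#' Bootstrap standard errors for the D frequency spectrum
#'
#' Resamples sites by drawing multinomially over the SFS cells (holding the
#' total site count fixed) and recomputes the spectrum, giving a site-level
#' bootstrap distribution for the overall D and every stratified `D_k`. The
#' SFS must carry (approximately) integer total mass for the multinomial
#' resample to be meaningful; fractional per-cell mass from projection is
#' handled by using the cell masses as resampling probabilities.
#'
#' @param sfs A polarized `joint_sfs`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @return A list with `d_overall_se`, and a tibble `bins` with columns `k`,
#'   `d_k`, `se`, `z` (`d_k / se`). Bins undefined in any replicate use the
#'   standard deviation over the replicates where they were defined.
#' @export
dfs_bootstrap <- function(sfs, n_boot = 100) {
  stopifnot(inherits(sfs, "joint_sfs"))
  sz <- attr(sfs, "sample_sizes")
  x <- unclass(sfs)
  total <- sum(x)
  if (total <= 0) stop("SFS has zero total mass", call. = FALSE)
  size <- max(1L, round(total))
  prob <- as.vector(x) / total
  base <- dfs(sfs)

  draws <- stats::rmultinom(n_boot, size = size, prob = prob)
  reps <- apply(draws, 2L, function(v) {
    r <- dfs(joint_sfs(array(v, dim = dim(x)),
                       sample_sizes = sz, polarized = TRUE))
    c(r$d_overall, r$tbl$d_k)
  })
  ses <- apply(reps, 1L, stats::sd, na.rm = TRUE)
  list(
    d_overall = base$d_overall,
    d_overall_se = ses[1L],
    bins = tibble::tibble(
      k = base$tbl$k,
      d_k = base$tbl$d_k,
      se = ses[-1L],
      z = base$tbl$d_k / ses[-1L]
    )
  )
}

#' Export a D frequency spectrum as a tab-separated table
#'
#' Writes one row per bin with columns `k`, `freq`, `D_k` (empty for
#' undefined bins) and `w_k`, preceded by a comment header carrying the
#' overall D and the total ABBA/BABA masses.
#'
#' @param x A `dfs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dfs <- function(x, path) {
  stopifnot(inherits(x, "dfs_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# d_overall=%.15g abba_total=%.15g baba_total=%.15g n=%d",
                     x$d_overall, x$abba_total, x$baba_total, x$n), con)
  writeLines("k\tfreq\tD_k\tw_k", con)
  dk <- ifelse(is.na(x$tbl$d_k), "", sprintf("%.15g", x$tbl$d_k))
  writeLines(sprintf("%d\t%.15g\t%s\t%.15g", x$tbl$k, x$tbl$freq, dk, x$tbl$w_k),
             con)
  invisible(path)
}

#' Read a D frequency spectrum table written by [write_dfs()]
#'
#' @param path Path to the TSV file.
#' @return A `dfs_result` (bin masses `abba_k`/`baba_k` are not recoverable
#'   from the table and are reported as `NA`).
#' @export
read_dfs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)][1L]
  get <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  tbl <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  structure(
    list(
      n = as.integer(get("n")),
      tbl = tibble::tibble(
        k = as.integer(tbl$k), freq = tbl$freq,
        d_k = as.numeric(tbl$D_k), w_k = tbl$w_k,
        abba_k = NA_real_, baba_k = NA_real_
      ),
      d_overall = get("d_overall"),
      abba_total = get("abba_total"),
      baba_total = get("baba_total")
    ),
    class = "dfs_result"
  )
}
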