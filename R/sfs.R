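#' Construct a joint site frequency spectrum
#'
#' A joint SFS is a three-dimensional tensor of site counts indexed by the
#' derived-allele count in each of three populations (P1, P2, P3). Axis `j`
#' runs over counts `0..n_j`, where `n_j` is the haploid sample size of
#' population `j`. Entries may be fractional: exact hypergeometric projection
#' (see [project_sfs()]) redistributes integer site counts into real-valued
#' mass, and all downstream computations sum over real masses.
#'
#' @param counts Numeric array of dimension `(n1+1, n2+1, n3+1)` with
#'   non-negative entries, or anything coercible to one via [array()] when
#'   `sample_sizes` is given.
#' @param sample_sizes Integer vector `(n1, n2, n3)` of haploid sample sizes.
#'   Defaults to `dim(counts) - 1`.
#' @param polarized Logical; `TRUE` (the only value accepted by the D_FS
#'   computation) declares that axis indices are derived-allele counts, i.e.
#'   the spectrum is unfolded.
#'
#' @return An object of class `joint_sfs`: the counts array with attributes
#'   `sample_sizes` and `polarized`.
#' @seealso [dfs()], [project_sfs()], [polarize_sfs()], [read_sfs()]
#' @export
#' @examples
#' counts <- array(0, dim = c(3, 3, 3))
#' counts[1, 2, 3] <- 1  # one site: derived counts (0, 1, 2) with n = (2, 2, 2)
#' sfs <- joint_sfs(counts)
#' dfs(sfs)
joint_sfs <- function(counts, sample_sizes = NULL, polarized = TRUE) {
  if (is.null(sample_sizes)) {
    if (length(dim(counts)) != 3L) {
      stop("`counts` must be a 3-dimensional array (P1 x P2 x P3)", call. = FALSE)
    }
    sample_sizes <- dim(counts) - 1L
  } else {
    sample_sizes <- as.integer(sample_sizes)
    if (length(sample_sizes) != 3L) {
      stop("`sample_sizes` must have length 3", call. = FALSE)
    }
    counts <- array(as.numeric(counts), dim = sample_sizes + 1L)
  }
  if (!identical(dim(counts), as.integer(sample_sizes + 1L))) {
    stop("counts array dimensions must equal sample_sizes + 1", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("SFS entries must be non-negative and non-missing", call. = FALSE)
  }
  structure(
    array(as.numeric(counts), dim = sample_sizes + 1L),
    sample_sizes = as.integer(sample_sizes),
    polarized = isTRUE(polarized),
    class = "joint_sfs"
  )
}

#' @export
print.joint_sfs <- function(x, ...) {
  n <- attr(x, "sample_sizes")
  cat(sprintf(
    "Joint SFS: %s haploid samples (%s), total mass %.6g over %d cells\n",
    paste(n, collapse = " x "),
    if (attr(x, "polarized")) "polarized" else "unpolarized",
    sum(x), length(x)
  ))
  invisible(x)
}

#' Sample sizes of a joint SFS
#' @param sfs A `joint_sfs` object.
#' @return Integer vector `(n1, n2, n3)`.
#' @export
sfs_sample_sizes <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  attr(sfs, "sample_sizes")
}

#' Swap the P1 and P2 axes of a joint SFS
#'
#' Exchanges the roles of the two focal populations. Because the ABBA and
#' BABA site contributions swap under exchange of P1 and P2, the D_FS of the
#' swapped spectrum has every stratified value negated while the bin weights
#' are unchanged — a useful internal consistency check.
#'
#' @param sfs A `joint_sfs` object.
#' @return A `joint_sfs` with the first two axes transposed.
#' @export
swap_p1_p2 <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  n <- attr(sfs, "sample_sizes")
  joint_sfs(aperm(unclass(sfs), c(2L, 1L, 3L)),
            sample_sizes = n[c(2L, 1L, 3L)],
            polarized = attr(sfs, "polarized"))
}

# Hypergeometric projection matrix: entry [i+1, c+1] is the probability that
# a subsample of m haploids contains c derived alleles given i derived among n.
projection_matrix <- function(n, m) {
  outer(0:n, 0:m, function(i, c) stats::dhyper(c, i, n - i, m))
}

#' Project a joint SFS to smaller sample sizes
#'
#' Exact hypergeometric downsampling: the mass at derived count `i` out of
#' `n` haploids is redistributed over counts `c` out of `m` with weight
#' `choose(i, c) * choose(n - i, m - c) / choose(n, m)`. Total mass is
#' conserved exactly. Projection is the standard device for making spectra
#' with unequal (or missing-data-reduced) sample sizes conform to the common
#' size required by the stratified statistic.
#'
#' @param sfs A `joint_sfs`.
#' @param target_sizes Integer vector `(m1, m2, m3)` with `1 <= m_j <= n_j`.
#' @return A `joint_sfs` with sample sizes `target_sizes`.
#' @export
#' @examples
#' counts <- array(0, dim = c(5, 5, 5))
#' counts[2, 1, 1] <- 1  # one derived copy among n = 4 in P1
#' project_sfs(joint_sfs(counts), c(2, 4, 4))
project_sfs <- function(sfs, target_sizes) {
  stopifnot(inherits(sfs, "joint_sfs"))
  n <- attr(sfs, "sample_sizes")
  m <- as.integer(target_sizes)
  if (length(m) != 3L) stop("`target_sizes` must have length 3", call. = FALSE)
  if (any(m < 1L) || any(m > n)) {
    stop(sprintf(
      "target sizes must satisfy 1 <= m_j <= n_j; got (%s) for sizes (%s)",
      paste(m, collapse = ", "), paste(n, collapse = ", ")
    ), call. = FALSE)
  }
  x <- unclass(sfs)
  # apply the projection matrix along each axis in turn
  for (ax in 1:3) {
    if (m[ax] == n[ax]) next
    P <- projection_matrix(n[ax], m[ax])
    perm <- c(ax, setdiff(1:3, ax))
    mat <- matrix(aperm(x, perm), nrow = dim(x)[ax])
    newdim <- dim(x)
    newdim[ax] <- m[ax] + 1L
    x <- aperm(array(crossprod(P, mat), dim = newdim[perm]), order(perm))
  }
  joint_sfs(x, sample_sizes = m, polarized = attr(sfs, "polarized"))
}

#' Polarize a 4D joint SFS using the outgroup axis
#'
#' The statistic assumes the outgroup is fixed for the ancestral state. Given
#' a 4D spectrum whose fourth axis indexes the outgroup's count of the same
#' allele that indexes the three ingroup axes, cells where the outgroup
#' carries none of that allele keep their orientation (the indexed allele is
#' derived); cells where the outgroup is fixed for it are flipped (each
#' ingroup axis index `i_j` becomes `n_j - i_j`, so the other allele is
#' derived); cells where the outgroup is polymorphic are discarded.
#'
#' @param sfs4d Numeric 4D array with dimensions
#'   `(n1+1, n2+1, n3+1, n_o+1)`.
#' @return A polarized `joint_sfs` over the three ingroup populations. The
#'   discarded (outgroup-polymorphic) mass is recorded in the attribute
#'   `discarded_mass`.
#' @export
polarize_sfs <- function(sfs4d) {
  d <- dim(sfs4d)
  if (length(d) != 4L) {
    stop("`sfs4d` must be a 4-dimensional array with the outgroup on axis 4",
         call. = FALSE)
  }
  if (anyNA(sfs4d) || any(sfs4d < 0)) {
    stop("SFS entries must be non-negative and non-missing", call. = FALSE)
  }
  n <- d[1:3] - 1L
  no <- d[4L] - 1L
  keep <- sfs4d[, , , 1L, drop = TRUE]
  flip <- sfs4d[, , , no + 1L, drop = TRUE]
  # reverse every ingroup axis of the fixed-for-indexed-allele slice
  flip <- flip[(n[1] + 1L):1L, (n[2] + 1L):1L, (n[3] + 1L):1L, drop = FALSE]
  dim(keep) <- dim(flip) <- n + 1L
  out <- joint_sfs(keep + flip, sample_sizes = n, polarized = TRUE)
  attr(out, "discarded_mass") <- sum(sfs4d) - sum(out)
  out
}

#' Read a joint SFS from a dadi-style text file
#'
#' The format is the plain-text array format used by dadi and moments: a
#' header line with the shape of the array followed by `"unfolded"` or
#' `"folded"`, a line of whitespace-separated counts in row-major (last axis
#' fastest) order, and an optional mask line of 0/1 flags. Masked entries are
#' set to zero. Only unfolded (polarized) spectra are accepted.
#'
#' @param path Path to the text file.
#' @return A `joint_sfs` (3D) or, for 4-dimensional input, a plain 4D array
#'   suitable for [polarize_sfs()].
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("SFS file must have a header and a data line", call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  fold_tok <- grep("folded", header, value = TRUE)
  if (length(fold_tok) && any(fold_tok == "folded")) {
    stop("folded spectra are not supported; provide an unfolded (polarized) SFS",
         call. = FALSE)
  }
  shape <- suppressWarnings(as.integer(header[!is.na(suppressWarnings(as.integer(header)))]))
  shape <- shape[!is.na(shape)]
  if (!length(shape) %in% c(3L, 4L)) {
    stop("SFS header must give 3 or 4 axis lengths", call. = FALSE)
  }
  vals <- as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  if (length(vals) != prod(shape)) {
    stop(sprintf("expected %d entries, found %d", prod(shape), length(vals)),
         call. = FALSE)
  }
  if (length(lines) >= 3L) {
    mask <- as.integer(strsplit(trimws(lines[3L]), "\\s+")[[1L]])
    if (length(mask) == length(vals)) vals[mask == 1L] <- 0
  }
  # dadi flattens row-major (C order); R arrays are column-major
  arr <- aperm(array(vals, dim = rev(shape)), length(shape):1L)
  if (length(shape) == 3L) {
    joint_sfs(arr, sample_sizes = shape - 1L, polarized = TRUE)
  } else {
    arr
  }
}

#' Write a joint SFS to a dadi-style text file
#'
#' @param sfs A `joint_sfs` object (or plain 3D/4D array).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path) {
  arr <- unclass(sfs)
  shape <- dim(arr)
  header <- paste(c(shape, "unfolded"), collapse = " ")
  flat <- as.vector(aperm(arr, length(shape):1L))  # C order
  writeLines(c(header,
               paste(format(flat, scientific = FALSE, trim = TRUE), collapse = " ")),
             path)
  invisible(path)
}
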