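#' Read a population map
#'
#' A population map is a two-column whitespace- or tab-separated file mapping
#' sample IDs to one of the four roles `P1`, `P2`, `P3`, `outgroup` of the
#' four-taxon topology (((P1, P2), P3), outgroup). Every role must have at
#' least one sample and no sample may carry two roles.
#'
#' @param path Path to the TSV file (no header; columns: sample, role), or a
#'   data frame with columns `sample` and `pop`.
#' @return A tibble with columns `sample` and `pop`.
#' @export
read_popmap <- function(path) {
  pm <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_table(path, col_names = c("sample", "pop"),
                      col_types = readr::cols(.default = readr::col_character()))
  }
  names(pm)[1:2] <- c("sample", "pop")
  pm$pop <- sub("^(O|o|Out|out|OUTGROUP|Outgroup)$", "outgroup", pm$pop)
  roles <- c("P1", "P2", "P3", "outgroup")
  bad <- setdiff(unique(pm$pop), roles)
  if (length(bad)) {
    stop(sprintf("unknown population role(s): %s (expected %s)",
                 paste(bad, collapse = ", "), paste(roles, collapse = ", ")),
         call. = FALSE)
  }
  missing_roles <- setdiff(roles, unique(pm$pop))
  if (length(missing_roles)) {
    stop(sprintf("population map lacks role(s): %s",
                 paste(missing_roles, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(pm$sample)) {
    stop("a sample appears more than once in the population map", call. = FALSE)
  }
  pm
}

#' Filtering configuration for VCF site extraction
#'
#' @param min_call_fraction Minimum fraction of individuals (across all
#'   mapped samples) genotyped at a site; sites below it are excluded
#'   (default 0.8).
#' @param min_depth Optional per-genotype read-depth threshold applied to the
#'   FORMAT `DP` field; genotypes below it are set to missing. Default `NULL`
#'   (off; depth QC is usually done upstream).
#' @param biallelic_only Keep only biallelic SNPs (always recommended;
#'   default `TRUE`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_call_fraction = 0.8, min_depth = NULL,
                          biallelic_only = TRUE) {
  stopifnot(min_call_fraction >= 0, min_call_fraction <= 1)
  structure(list(min_call_fraction = min_call_fraction,
                 min_depth = min_depth,
                 biallelic_only = biallelic_only),
            class = "filter_config")
}

# Count allele copies in a vector of GT strings. Ploidy is whatever the GT
# string carries, so haploid, diploid and tetraploid calls all work. '.' and
# '*'-coded alleles count as missing.
count_gt_alleles <- function(gt) {
  alt <- integer(length(gt))
  called <- integer(length(gt))
  alleles <- strsplit(ifelse(is.na(gt), ".", gt), "[/|]")
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    ok <- a %in% c("0", "1")
    called[i] <- sum(ok)
    alt[i] <- sum(a == "1")
  }
  list(alt = alt, called = called)
}

#' Extract per-population allele counts from a VCF
#'
#' Reads a VCF (plain or bgzipped), keeps biallelic SNPs passing the filters,
#' and tallies for each site the ALT-allele count and the number of called
#' allele copies in each of the four populations. Ploidy is taken from the GT
#' strings, so mixed-ploidy and polyploid data are handled transparently.
#' Spanning-deletion (`*`) alleles and indels are excluded.
#'
#' @param vcf_path Path to the VCF file.
#' @param popmap A population map (path or data frame; see [read_popmap()]).
#' @param filters A [filter_config()].
#' @return A tibble with one row per retained site: `chrom`, `pos`, `ref`,
#'   `alt`, and for each role `r` in P1/P2/P3/outgroup the columns `alt_r`
#'   (ALT copies) and `called_r` (called copies). Filter counters are
#'   attached as attribute `counters` (also retrievable with
#'   [site_counters()]).
#' @export
read_sites <- function(vcf_path, popmap, filters = filter_config()) {
  pm <- read_popmap(popmap)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_all <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_all))) gt_all <- matrix(gt_all, nrow = 1, dimnames = list(NULL, names(gt_all)))

  absent <- setdiff(pm$sample, colnames(gt_all))
  if (length(absent)) {
    stop(sprintf("samples in the population map are absent from the VCF: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }

  n_in <- nrow(gt_all)
  counters <- c(sites_in = n_in, not_snp = 0L, not_biallelic = 0L,
                low_call = 0L, sites_used = 0L)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- nchar(ref) == 1L & ref %in% c("A", "C", "G", "T")
  multi <- grepl(",", alt)
  alt1 <- sub(",.*$", "", alt)
  snp_alt <- nchar(alt1) == 1L & alt1 %in% c("A", "C", "G", "T")
  keep <- is_snp & snp_alt & !(filters$biallelic_only & multi)
  counters["not_snp"] <- sum(!(is_snp & snp_alt))
  counters["not_biallelic"] <- sum(is_snp & snp_alt & multi & filters$biallelic_only)

  if (!is.null(filters$min_depth)) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    if (!is.null(dp) && all(dim(dp) == dim(gt_all))) {
      gt_all[!is.na(dp) & dp < filters$min_depth] <- NA
    }
  }

  gt <- gt_all[keep, pm$sample, drop = FALSE]
  fixk <- fix[keep, , drop = FALSE]

  roles <- c("P1", "P2", "P3", "outgroup")
  idx <- lapply(roles, function(r) which(pm$pop == r))
  names(idx) <- roles

  n_sites <- nrow(gt)
  out <- vector("list", length(roles) * 2L + 4L)
  alt_m <- called_m <- matrix(0L, n_sites, length(roles),
                              dimnames = list(NULL, roles))
  genotyped <- integer(n_sites)
  if (n_sites > 0) {
    for (j in seq_len(ncol(gt))) {
      cnt <- count_gt_alleles(gt[, j])
      r <- pm$pop[j]
      alt_m[, r] <- alt_m[, r] + cnt$alt
      called_m[, r] <- called_m[, r] + cnt$called
      genotyped <- genotyped + as.integer(cnt$called > 0L)
    }
  }
  frac_ok <- genotyped >= filters$min_call_fraction * nrow(pm)
  counters["low_call"] <- sum(!frac_ok)
  counters["sites_used"] <- sum(frac_ok)

  res <- tibble::tibble(
    chrom = as.character(fixk[frac_ok, "CHROM"]),
    pos = as.integer(fixk[frac_ok, "POS"]),
    ref = as.character(fixk[frac_ok, "REF"]),
    alt = sub(",.*$", "", as.character(fixk[frac_ok, "ALT"]))
  )
  for (r in roles) {
    res[[paste0("alt_", r)]] <- alt_m[frac_ok, r]
    res[[paste0("called_", r)]] <- called_m[frac_ok, r]
  }
  attr(res, "counters") <- counters
  res
}

#' Filter counters attached to a site table or SFS
#' @param x An object returned by [read_sites()], [polarize_sites()] or
#'   [build_joint_sfs()].
#' @return A named integer vector of per-filter site counts.
#' @export
site_counters <- function(x) attr(x, "counters")

#' Polarize site records using the outgroup
#'
#' Implements the fixed-outgroup convention: if the outgroup is fixed for REF
#' the ALT allele is taken as derived (counts kept); if fixed for ALT the REF
#' allele is derived (counts complemented against the called totals); sites
#' where the outgroup is polymorphic, or has fewer than
#' `min_outgroup_alleles` called copies, are discarded.
#'
#' @param sites A site tibble from [read_sites()].
#' @param min_outgroup_alleles Minimum called outgroup allele copies needed
#'   to polarize (default 1).
#' @return A tibble with columns `chrom`, `pos` and per-population
#'   `derived_*` / `called_*` counts for P1, P2, P3. Counter attribute
#'   updated with `outgroup_polymorphic` and `outgroup_uncalled` tallies.
#' @export
polarize_sites <- function(sites, min_outgroup_alleles = 1L) {
  oc <- sites$called_outgroup
  oa <- sites$alt_outgroup
  uncalled <- oc < min_outgroup_alleles
  fixed_ref <- !uncalled & oa == 0L
  fixed_alt <- !uncalled & oa == oc
  poly <- !uncalled & !fixed_ref & !fixed_alt

  keep <- fixed_ref | fixed_alt
  res <- tibble::tibble(chrom = sites$chrom[keep], pos = sites$pos[keep])
  flip <- fixed_alt[keep]
  for (r in c("P1", "P2", "P3")) {
    a <- sites[[paste0("alt_", r)]][keep]
    n <- sites[[paste0("called_", r)]][keep]
    res[[paste0("derived_", r)]] <- ifelse(flip, n - a, a)
    res[[paste0("called_", r)]] <- n
  }
  counters <- attr(sites, "counters")
  counters <- c(counters,
                outgroup_uncalled = sum(uncalled),
                outgroup_polymorphic = sum(poly),
                sites_polarized = sum(keep))
  attr(res, "counters") <- counters
  res
}

#' Build a polarized joint SFS from polarized site records
#'
#' Each site contributes unit mass to the spectrum at target sample sizes
#' `target_n`. A site whose called-allele totals exceed the targets is
#' downsampled exactly (hypergeometric redistribution of its unit mass over
#' the possible subsample counts). Sites with fewer called copies than the
#' target in any population are either dropped (`missing = "drop"`) or, by
#' default, excluded only when projection is impossible — projection requires
#' called >= target, so under both policies such sites are removed, and the
#' policies differ only in whether fully-called sites above target are
#' projected (`"project"`, default) or required to match exactly (`"drop"`).
#'
#' @param records A tibble from [polarize_sites()].
#' @param target_n Integer vector `(n1, n2, n3)` of haploid target sizes.
#' @param missing Either `"project"` (default: hypergeometric downsampling of
#'   sites with more called copies than the target) or `"drop"` (keep only
#'   sites whose called totals equal the target exactly).
#' @return A polarized `joint_sfs`; counter attribute extended with
#'   `sites_dropped_small` (called < target) and `sites_binned`.
#' @export
build_joint_sfs <- function(records, target_n, missing = c("project", "drop")) {
  missing <- match.arg(missing)
  target_n <- as.integer(target_n)
  stopifnot(length(target_n) == 3L, all(target_n >= 1L))
  if (nrow(records) == 0L) stop("no sites to bin: empty record table", call. = FALSE)

  der <- as.matrix(records[, c("derived_P1", "derived_P2", "derived_P3")])
  cal <- as.matrix(records[, c("called_P1", "called_P2", "called_P3")])

  too_small <- rowSums(cal < rep(target_n, each = nrow(cal))) > 0L
  exact <- rowSums(cal != rep(target_n, each = nrow(cal))) == 0L
  usable <- if (missing == "project") !too_small else exact
  dropped <- sum(!usable)

  counts <- array(0, dim = target_n + 1L)
  proj_cache <- new.env(parent = emptyenv())
  get_weights <- function(i, n, m) {
    key <- paste(i, n, m, sep = ":")
    w <- proj_cache[[key]]
    if (is.null(w)) {
      w <- stats::dhyper(0:m, i, n - i, m)
      proj_cache[[key]] <- w
    }
    w
  }
  for (s in which(usable)) {
    w1 <- get_weights(der[s, 1], cal[s, 1], target_n[1])
    w2 <- get_weights(der[s, 2], cal[s, 2], target_n[2])
    w3 <- get_weights(der[s, 3], cal[s, 3], target_n[3])
    counts <- counts + outer(outer(w1, w2), w3)
  }
  sfs <- joint_sfs(counts, sample_sizes = target_n, polarized = TRUE)
  counters <- attr(records, "counters")
  attr(sfs, "counters") <- c(counters,
                             sites_dropped_small = dropped,
                             sites_binned = sum(usable))
  sfs
}

#' Compute the D frequency spectrum directly from a VCF
#'
#' Convenience pipeline: [read_sites()] then [polarize_sites()] then
#' [build_joint_sfs()] then [dfs()].
#'
#' @inheritParams read_sites
#' @inheritParams polarize_sites
#' @inheritParams build_joint_sfs
#' @return A `dfs_result` with the joint SFS attached as attribute `sfs`.
#' @export
dfs_from_vcf <- function(vcf_path, popmap, target_n,
                         filters = filter_config(),
                         min_outgroup_alleles = 1L,
                         missing = "project") {
  sites <- read_sites(vcf_path, popmap, filters)
  pol <- polarize_sites(sites, min_outgroup_alleles)
  sfs <- build_joint_sfs(pol, target_n, missing)
  res <- dfs(sfs)
  attr(res, "sfs") <- sfs
  res
}
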