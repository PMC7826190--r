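test_that("fixture generation is deterministic and self-describing", {
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  f1 <- make_fixture_vcf(n_sites = 40, seed = 99, path = p1)
  f2 <- make_fixture_vcf(n_sites = 40, seed = 99, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(unclass(f1$truth), unclass(f2$truth))
  f3 <- make_fixture_vcf(n_sites = 40, seed = 100, path = p2)
  expect_false(identical(readLines(p1), readLines(p2)))
  expect_equal(sum(unclass(f1$truth)), 40)
})

test_that("the VCF pipeline reproduces the fixture's true joint SFS exactly", {
  set.seed(1)
  fx <- make_fixture_vcf(n_per_pop = c(2L, 2L, 3L, 1L), n_sites = 150, seed = 7)
  sites <- read_sites(fx$path, fx$popmap)
  expect_equal(nrow(sites), 150)
  pol <- polarize_sites(sites)
  sfs <- build_joint_sfs(pol, sfs_sample_sizes(fx$truth))
  expect_equal(sfs_array(sfs), sfs_array(fx$truth))
  cnt <- site_counters(sfs)
  # mass accounting: every input site is classified exactly once
  expect_equal(unname(cnt["sites_in"]),
               unname(cnt["sites_used"] + cnt["not_snp"] +
                      cnt["not_biallelic"] + cnt["low_call"]))
  expect_equal(unname(cnt["sites_binned"]), 150)
})

test_that("allele copies are counted from GT strings across ploidies", {
  # diploid 0/0 + 0/1 in a 2-individual population
  cnt <- dfspectrum:::count_gt_alleles(c("0/0", "0/1"))
  expect_equal(cnt$called, c(2L, 2L))
  expect_equal(sum(cnt$alt), 1L)
  # haploid, tetraploid, phased, missing and spanning-deletion codes
  cnt2 <- dfspectrum:::count_gt_alleles(c("1", "0/1/1/1", "0|1", "./.", "1/*"))
  expect_equal(cnt2$called, c(1L, 4L, 2L, 0L, 1L))
  expect_equal(cnt2$alt, c(1L, 3L, 1L, 0L, 1L))
})

test_that("non-SNP, multiallelic and under-called sites are filtered", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="G">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("s", 1:8)), collapse = "\t"))
  gts_ok <- paste(rep("0/1", 8), collapse = "\t")
  gts_low <- paste(c("0/1", "0/0", rep("./.", 6)), collapse = "\t")
  rows <- c(
    paste("chr1", 1, ".", "A", "T", ".", ".", ".", "GT", gts_ok, sep = "\t"),
    paste("chr1", 2, ".", "A", "T,G", ".", ".", ".", "GT", gts_ok, sep = "\t"),
    paste("chr1", 3, ".", "AT", "A", ".", ".", ".", "GT", gts_ok, sep = "\t"),
    paste("chr1", 4, ".", "A", "T", ".", ".", ".", "GT", gts_low, sep = "\t")
  )
  writeLines(c(header, rows), vcf)
  pm <- tibble::tibble(sample = paste0("s", 1:8),
                       pop = rep(c("P1", "P2", "P3", "outgroup"), each = 2))
  sites <- read_sites(vcf, pm, filter_config(min_call_fraction = 0.8))
  expect_equal(sites$pos, 1L)
  cnt <- site_counters(sites)
  expect_equal(unname(cnt["not_biallelic"]), 1L)
  expect_equal(unname(cnt["not_snp"]), 1L)
  expect_equal(unname(cnt["low_call"]), 1L)
  # a sample missing from the VCF header is a configuration error
  pm_bad <- rbind(pm, tibble::tibble(sample = "ghost", pop = "P1"))
  expect_error(read_sites(vcf, pm_bad, filter_config()), "ghost")
})

test_that("polarization follows the fixed-outgroup rule", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
    alt_P1 = c(1L, 1L, 1L, 1L), called_P1 = 4L,
    alt_P2 = c(2L, 2L, 2L, 2L), called_P2 = 4L,
    alt_P3 = c(3L, 3L, 3L, 3L), called_P3 = 4L,
    alt_outgroup = c(0L, 2L, 1L, 0L), called_outgroup = c(2L, 2L, 2L, 0L)
  )
  attr(sites, "counters") <- c(sites_in = 4L)
  pol <- polarize_sites(sites, min_outgroup_alleles = 1L)
  expect_equal(nrow(pol), 2L)
  # outgroup fixed REF: ALT is derived, counts unchanged
  expect_equal(pol$derived_P1[pol$pos == 1], 1L)
  # outgroup fixed ALT: REF is derived, counts complemented
  expect_equal(pol$derived_P1[pol$pos == 2], 3L)
  expect_equal(pol$derived_P2[pol$pos == 2], 2L)
  expect_equal(pol$derived_P3[pol$pos == 2], 1L)
  cnt <- site_counters(pol)
  expect_equal(unname(cnt["outgroup_polymorphic"]), 1L)
  expect_equal(unname(cnt["outgroup_uncalled"]), 1L)
  # complementing twice returns the original counts (involution)
  twice <- sites
  twice$alt_P1 <- sites$called_P1 - sites$alt_P1
  twice$alt_P2 <- sites$called_P2 - sites$alt_P2
  twice$alt_P3 <- sites$called_P3 - sites$alt_P3
  attr(twice, "counters") <- c(sites_in = 4L)
  pol_twice <- polarize_sites(twice)
  expect_equal(pol_twice$derived_P1[pol_twice$pos == 2], sites$alt_P1[2])
})

test_that("outgroup-polymorphic fixture sites are all discarded", {
  fx <- make_fixture_vcf(n_per_pop = c(2L, 2L, 2L, 2L), n_sites = 30,
                         n_outgroup_poly = 10, seed = 3)
  sites <- read_sites(fx$path, fx$popmap)
  pol <- polarize_sites(sites)
  expect_equal(nrow(pol), 30)
  expect_equal(unname(site_counters(pol)["outgroup_polymorphic"]), 10L)
})

test_that("missing data is dropped or projected per policy", {
  # a site with 3 of 4 copies called in P2, target 4: dropped under "drop",
  # spread hypergeometrically under "project" only if called >= target, so
  # both policies drop it; called = 4 with target 3 projects fractionally
  rec <- tibble::tibble(
    chrom = "chr1", pos = 1:2,
    derived_P1 = c(1L, 1L), called_P1 = c(4L, 4L),
    derived_P2 = c(1L, 1L), called_P2 = c(3L, 4L),
    derived_P3 = c(2L, 2L), called_P3 = c(4L, 4L)
  )
  attr(rec, "counters") <- c(sites_in = 2L)
  s_drop <- build_joint_sfs(rec, c(4L, 4L, 4L), missing = "drop")
  expect_equal(unname(site_counters(s_drop)["sites_binned"]), 1L)
  s_proj <- build_joint_sfs(rec, c(4L, 3L, 4L), missing = "project")
  expect_equal(unname(site_counters(s_proj)["sites_binned"]), 2L)
  expect_equal(sum(unclass(s_proj)), 2)
  # site 1: P2 has 1 derived of 3 called, already at target -> unit weight;
  # site 2: 1 of 4 projected to 3 -> weights dhyper(0:3, 1, 3, 3)
  marg2 <- apply(unclass(s_proj), 2, sum)
  expect_equal(marg2, c(0, 1, 0, 0) + dhyper(0:3, 1, 3, 3))
  expect_error(build_joint_sfs(rec[0, ], c(4L, 4L, 4L)), "empty")
})

test_that("missingness in the fixture flows through the project policy", {
  fx <- make_fixture_vcf(n_per_pop = c(3L, 3L, 3L, 1L), n_sites = 120,
                         missing_rate = 0.2, seed = 13)
  res <- dfs_from_vcf(fx$path, fx$popmap, target_n = c(4L, 4L, 4L),
                      filters = filter_config(min_call_fraction = 0.5))
  expect_s3_class(res, "dfs_result")
  sfs <- attr(res, "sfs")
  cnt <- site_counters(sfs)
  expect_true(cnt["sites_binned"] > 0)
  expect_equal(unname(cnt["sites_binned"] + cnt["sites_dropped_small"]),
               unname(cnt["sites_polarized"]))
})
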