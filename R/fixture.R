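#' Generate a synthetic VCF fixture with a known joint SFS
#'
#' Writes a minimal but valid VCF containing biallelic SNPs whose true
#' polarized joint SFS is known by construction, for round-trip testing of
#' the genotype pipeline. Derived-allele counts per site are drawn from a
#' frequency profile over SFS cells; genotypes are assigned by randomly
#' distributing the derived copies among allele slots within each
#' population. Optionally, some sites are written with the REF/ALT labels
#' swapped (outgroup fixed for ALT), exercising the polarization complement
#' path, and sites with a polymorphic outgroup or with missing genotypes can
#' be injected.
#'
#' @param n_per_pop Integer vector of diploid individual counts for
#'   (P1, P2, P3, outgroup).
#' @param n_sites Number of polarizable SNP sites to generate.
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments and the seed.
#' @param profile Either `"uniform"` (each polymorphic-in-ingroup cell of the
#'   joint SFS equally likely) or a numeric 3D array of cell probabilities
#'   with dimensions `(2*n1+1, 2*n2+1, 2*n3+1)`.
#' @param prop_ref_ancestral Proportion of sites written with REF as the
#'   ancestral allele (the rest have ALT ancestral, i.e. the outgroup is
#'   fixed ALT and counts must be complemented on reading). Default 0.5.
#' @param n_outgroup_poly Number of extra sites with a heterozygous outgroup
#'   (these must be discarded by polarization). Default 0.
#' @param missing_rate Per-genotype missingness probability applied to
#'   ingroup genotypes (default 0: fully called).
#' @param path Output VCF path (default a tempfile).
#' @return A list with `path`, `truth` (the true polarized `joint_sfs` over
#'   haploid sizes `2 * n_per_pop[1:3]`, fully-called sites only), `popmap`
#'   (a tibble usable with [read_sites()]), and `n_sites_written`.
#' @export
make_fixture_vcf <- function(n_per_pop = c(2L, 2L, 2L, 1L), n_sites = 100L,
                             seed = 1L, profile = "uniform",
                             prop_ref_ancestral = 0.5,
                             n_outgroup_poly = 0L, missing_rate = 0,
                             path = tempfile(fileext = ".vcf")) {
  stopifnot(length(n_per_pop) == 4L, all(n_per_pop >= 1L))
  set.seed(seed)
  nh <- 2L * n_per_pop[1:3]  # haploid sizes of the three ingroups

  if (identical(profile, "uniform")) {
    prob <- array(1, dim = nh + 1L)
    # exclude sites monomorphic ancestral everywhere (invisible in a VCF)
    prob[1, 1, 1] <- 0
  } else {
    prob <- profile
    stopifnot(identical(dim(prob), as.integer(nh + 1L)))
  }
  cells <- which(prob > 0, arr.ind = TRUE)
  draw <- sample(nrow(cells), n_sites, replace = TRUE,
                 prob = prob[cells])
  derived <- cells[draw, , drop = FALSE] - 1L  # derived counts per pop

  pops <- c("P1", "P2", "P3", "outgroup")
  samples <- unlist(lapply(seq_along(pops), function(i) {
    sprintf("%s_ind%d", pops[i], seq_len(n_per_pop[i]))
  }))
  popmap <- tibble::tibble(
    sample = samples,
    pop = rep(pops, times = n_per_pop)
  )

  truth <- array(0, dim = nh + 1L)

  ref_anc <- stats::runif(n_sites) < prop_ref_ancestral
  bases <- c("A", "C", "G", "T")

  gt_for_pop <- function(n_ind, n_derived, derived_allele, miss) {
    # distribute derived copies over 2*n_ind allele slots, then pair them
    slots <- rep(1L - derived_allele, 2L * n_ind)  # ancestral allele code
    if (n_derived > 0) {
      slots[sample.int(2L * n_ind, n_derived)] <- derived_allele
    }
    g <- matrix(slots, nrow = 2L)
    gt <- paste(g[1L, ], g[2L, ], sep = "/")
    if (miss > 0) gt[stats::runif(n_ind) < miss] <- "./."
    gt
  }

  rows <- character(n_sites + n_outgroup_poly)
  for (s in seq_len(n_sites)) {
    anc_b <- sample(bases, 1L)
    der_b <- sample(setdiff(bases, anc_b), 1L)
    if (ref_anc[s]) { ref <- anc_b; alt <- der_b; der_code <- 1L
    } else { ref <- der_b; alt <- anc_b; der_code <- 0L }
    gts <- character(0)
    full <- TRUE
    for (p in 1:3) {
      g <- gt_for_pop(n_per_pop[p], derived[s, p], der_code, missing_rate)
      if (any(g == "./.")) full <- FALSE
      gts <- c(gts, g)
    }
    # outgroup fixed ancestral
    og <- rep(paste(1L - der_code, 1L - der_code, sep = "/"), n_per_pop[4])
    gts <- c(gts, og)
    if (full) {
      truth[derived[s, 1] + 1L, derived[s, 2] + 1L, derived[s, 3] + 1L] <-
        truth[derived[s, 1] + 1L, derived[s, 2] + 1L, derived[s, 3] + 1L] + 1
    }
    rows[s] <- paste(c("chr1", s, ".", ref, alt, ".", "PASS", ".", "GT", gts),
                     collapse = "\t")
  }
  if (n_outgroup_poly > 0) {
    for (j in seq_len(n_outgroup_poly)) {
      gts <- c(rep("0/0", sum(n_per_pop[1:2])),
               rep("0/1", n_per_pop[3]),
               c("0/1", rep("0/0", n_per_pop[4] - 1L)))
      rows[n_sites + j] <- paste(
        c("chr1", n_sites + j, ".", "A", "G", ".", "PASS", ".", "GT", gts),
        collapse = "\t")
    }
  }

  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)

  list(
    path = path,
    truth = joint_sfs(truth, sample_sizes = nh, polarized = TRUE),
    popmap = popmap,
    n_sites_written = n_sites + n_outgroup_poly
  )
}
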