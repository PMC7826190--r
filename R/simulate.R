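#' Simulate a polarized joint SFS at unlinked sites
#'
#' Monte Carlo structured coalescent: for each site an independent genealogy
#' is drawn under the model, one mutation is placed uniformly at random on
#' total branch length (optionally restricted to segments inside the model's
#' mutation window), and the derived-allele counts of the three sampled
#' populations index a cell of the joint SFS. The spectrum is polarized by
#' construction (no outgroup is simulated), emulating analyses in which an
#' outgroup identifies the ancestral allele. Output is a deterministic
#' function of the model, sample sizes, site count and seed.
#'
#' Sites whose genealogy carries no branch length inside the mutation window
#' are re-drawn; the number of re-draws is recorded in the attribute
#' `resampled`.
#'
#' @param model A `demographic_model` (e.g. from [presets()] or
#'   [three_pop_model()]).
#' @param samples Integer vector of haploid sample sizes per population.
#'   Populations beyond the third are never sampled. Default `c(8, 8, 8)`.
#' @param n_sites Number of unlinked sites.
#' @param seed Integer seed.
#' @param mutation_window Optional override of the model's mutation window.
#' @return A polarized `joint_sfs` with attribute `resampled`.
#' @export
#' @examples
#' sfs <- simulate_joint_sfs(presets("no_geneflow"), n_sites = 1000, seed = 1)
#' glance(dfs(sfs))
simulate_joint_sfs <- function(model, samples = c(8L, 8L, 8L), n_sites,
                               seed, mutation_window = NULL) {
  stopifnot(inherits(model, "demographic_model"), n_sites >= 1)
  win <- if (is.null(mutation_window)) model$mutation_window else as.numeric(mutation_window)
  samp <- integer(model$npop)
  samples <- as.integer(samples)
  samp[seq_along(samples)] <- samples
  if (sum(samp) < 2L) stop("need at least two sampled lineages", call. = FALSE)
  mm <- model_matrices(model)
  res <- sim_joint_sfs_cpp(samp, model$npop, mm$sizes, mm$merges, mm$migs,
                           as.integer(n_sites), win[1], win[2],
                           seed_pair(seed)[1], seed_pair(seed)[2])
  out <- joint_sfs(res$counts, sample_sizes = samp[1:3], polarized = TRUE)
  attr(out, "resampled") <- res$resampled
  out
}

# two non-negative doubles < 2^32 feeding the engine's seed sequence
seed_pair <- function(seed) {
  seed <- as.numeric(seed)
  if (length(seed) != 1L || is.na(seed)) stop("`seed` must be a single integer", call. = FALSE)
  c(abs(seed) %% 2^31, (abs(seed) * 2654435761) %% 2^31)
}

#' Simulate a single labeled genealogy
#'
#' Draws one genealogy under the structured coalescent and returns its node
#' table: every node's (backward) time, its parent (0 for the root) and the
#' number of sampled leaves it subtends in each of the three sampled
#' populations. Leaves come first, in population order; internal nodes are
#' numbered in coalescence order.
#'
#' @inheritParams simulate_joint_sfs
#' @return A tibble with columns `node`, `parent`, `time`, `leaves_p1`,
#'   `leaves_p2`, `leaves_p3`.
#' @export
simulate_genealogy <- function(model, samples = c(8L, 8L, 8L), seed) {
  stopifnot(inherits(model, "demographic_model"))
  samp <- integer(model$npop)
  samples <- as.integer(samples)
  samp[seq_along(samples)] <- samples
  mm <- model_matrices(model)
  g <- sim_genealogy_cpp(samp, model$npop, mm$sizes, mm$merges, mm$migs,
                         seed_pair(seed)[1], seed_pair(seed)[2])
  tibble::tibble(
    node = seq_along(g$time),
    parent = g$parent,
    time = g$time,
    leaves_p1 = g$leaves[, 1],
    leaves_p2 = g$leaves[, 2],
    leaves_p3 = g$leaves[, 3]
  )
}

#' Pairwise and total TMRCA replicates under a model
#'
#' Draws many independent genealogies and returns the time to the most
#' recent common ancestor of the full sample in each, mainly for calibrating
#' and testing the engine (e.g. the classical expectation that two lineages
#' in a single population of relative size `nu` coalesce after `nu` units of
#' `2N` generations on average).
#'
#' @inheritParams simulate_joint_sfs
#' @param n_rep Number of replicate genealogies.
#' @return Numeric vector of root times, length `n_rep`.
#' @export
simulate_tmrca <- function(model, samples = c(2L, 0L, 0L), n_rep, seed) {
  stopifnot(inherits(model, "demographic_model"))
  samp <- integer(model$npop)
  samples <- as.integer(samples)
  samp[seq_along(samples)] <- samples
  mm <- model_matrices(model)
  sim_tmrca_cpp(samp, model$npop, mm$sizes, mm$merges, mm$migs,
                as.integer(n_rep), seed_pair(seed)[1], seed_pair(seed)[2])
}

#' Run the D frequency spectrum over a grid of scenario parameters
#'
#' Batch driver: for every row of `grid`, builds the named preset with that
#' row's columns as overrides, simulates a joint SFS and computes the D
#' frequency spectrum. Per-row seeds are derived from the master seed so the
#' whole table is reproducible; rows that fail are recorded with the error
#' message and the run continues.
#'
#' @param preset Preset name (see [presets()]).
#' @param grid A data frame; each column must match a preset argument, each
#'   row is one parameter combination. An empty or `NULL` grid runs the
#'   preset once with defaults.
#' @param samples,n_sites,seed As in [simulate_joint_sfs()].
#' @return A tibble with one row per combination: the grid columns,
#'   `d_overall`, `abba_total`, `baba_total`, `error` (NA on success) and a
#'   list-column `bins` of per-bin tibbles.
#' @export
dfs_grid <- function(preset, grid = NULL, samples = c(8L, 8L, 8L),
                     n_sites = 1e5, seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0L) grid <- tibble::tibble(.row = 1L)
  grid <- tibble::as_tibble(grid)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    overrides <- as.list(grid[i, setdiff(names(grid), ".row"), drop = FALSE])
    row_seed <- (abs(as.numeric(seed)) + 7919 * i) %% 2^31
    res <- tryCatch({
      model <- do.call(presets, c(list(name = preset), overrides))
      sfs <- simulate_joint_sfs(model, samples = samples,
                                n_sites = n_sites, seed = row_seed)
      d <- dfs(sfs)
      tibble::tibble(
        d_overall = d$d_overall,
        abba_total = d$abba_total,
        baba_total = d$baba_total,
        error = NA_character_,
        bins = list(tidy(d))
      )
    }, error = function(e) {
      tibble::tibble(d_overall = NA_real_, abba_total = NA_real_,
                     baba_total = NA_real_,
                     error = conditionMessage(e), bins = list(NULL))
    })
    out[[i]] <- dplyr::bind_cols(grid[i, setdiff(names(grid), ".row"), drop = FALSE], res)
  }
  dplyr::bind_rows(out)
}
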