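#' Construct a demographic model for coalescent simulation
#'
#' A piecewise-constant demographic history over `npop` populations,
#' described in backward time, in coalescent units of `2 * N_ref`
#' generations. Population relative sizes `nu = N / N_ref` may change at
#' stated times; population splits are backward-time merges of one lineage
#' pool into another; gene flow is specified forward in time (donor ->
#' recipient at population-scaled rate `M = 2Nm`) over an interval, and is
#' converted internally to the backward convention in which each lineage in
#' the recipient jumps to the donor at per-lineage rate `M` per `2N_ref`
#' generations. An optional mutation window restricts where on the genealogy
#' mutations may be placed.
#'
#' @param npop Number of populations (sampled populations are 1 = P1,
#'   2 = P2, 3 = P3; further indices may serve as unsampled ancestral demes).
#' @param sizes Data frame with columns `pop`, `start`, `nu`: population
#'   `pop` has relative size `nu` from backward time `start` until the next
#'   stated change. Populations without an entry have `nu = 1` throughout.
#' @param merges Data frame with columns `time`, `from`, `to`: at backward
#'   time `time`, all lineages in population `from` move into `to`
#'   (a population split viewed backward). Every population must ultimately
#'   merge into a single pool.
#' @param migration Data frame with columns `donor`, `recipient`, `start`,
#'   `end`, `M`: forward gene flow from `donor` into `recipient` at rate
#'   `M = 2Nm` over backward-time interval `[start, end)`. May be empty.
#' @param mutation_window Length-2 numeric `(t_min, t_max)`; mutations are
#'   only placed on branch segments within this backward-time window.
#'   Default `c(0, Inf)` (anywhere).
#' @return An object of class `demographic_model`.
#' @seealso [three_pop_model()], [presets()], [simulate_joint_sfs()]
#' @export
demographic_model <- function(npop = 3L,
                              sizes = NULL,
                              merges = NULL,
                              migration = NULL,
                              mutation_window = c(0, Inf)) {
  npop <- as.integer(npop)
  empty <- function(...) {
    tibble::as_tibble(stats::setNames(rep(list(numeric(0)), length(c(...))), c(...)))
  }
  sizes <- if (is.null(sizes)) empty("pop", "start", "nu") else tibble::as_tibble(sizes)
  merges <- if (is.null(merges)) empty("time", "from", "to") else tibble::as_tibble(merges)
  migration <- if (is.null(migration)) {
    empty("donor", "recipient", "start", "end", "M")
  } else tibble::as_tibble(migration)

  pops_ref <- c(sizes$pop, merges$from, merges$to,
                migration$donor, migration$recipient)
  if (length(pops_ref) && (any(pops_ref < 1) || any(pops_ref > npop))) {
    stop("an event references a population outside 1..npop", call. = FALSE)
  }
  if (any(sizes$nu <= 0)) stop("relative sizes must be positive", call. = FALSE)
  if (any(c(sizes$start, merges$time, migration$start) < 0)) {
    stop("event times must be non-negative", call. = FALSE)
  }
  if (nrow(migration) && any(migration$M < 0)) {
    stop("migration rates must be non-negative", call. = FALSE)
  }
  if (nrow(migration) && any(migration$end <= migration$start)) {
    stop("migration epochs must have end > start", call. = FALSE)
  }
  if (length(mutation_window) != 2L || mutation_window[2] <= mutation_window[1]) {
    stop("`mutation_window` must be (t_min, t_max) with t_max > t_min", call. = FALSE)
  }
  merges <- merges[order(merges$time), , drop = FALSE]
  structure(
    list(npop = npop, sizes = sizes, merges = merges, migration = migration,
         mutation_window = as.numeric(mutation_window)),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model: %d population(s)\n", x$npop))
  if (nrow(x$merges)) {
    cat("  merges (backward):",
        paste(sprintf("%d->%d @ %.3g", x$merges$from, x$merges$to, x$merges$time),
              collapse = ", "), "\n")
  }
  if (nrow(x$sizes)) {
    cat("  size changes:",
        paste(sprintf("pop %d nu=%.3g @ %.3g", x$sizes$pop, x$sizes$nu, x$sizes$start),
              collapse = ", "), "\n")
  }
  if (nrow(x$migration)) {
    cat("  gene flow (forward):",
        paste(sprintf("%d->%d M=%.3g [%.3g, %.3g)", x$migration$donor,
                      x$migration$recipient, x$migration$M,
                      x$migration$start, x$migration$end),
              collapse = ", "), "\n")
  }
  if (is.finite(x$mutation_window[2]) || x$mutation_window[1] > 0) {
    cat(sprintf("  mutation window: [%.3g, %.3g)\n",
                x$mutation_window[1], x$mutation_window[2]))
  }
  invisible(x)
}

#' Three-population model with the (((P1, P2), P3), O) topology
#'
#' Convenience constructor covering the scenarios used throughout the
#' package: P1 and P2 diverge at backward time `t12`, their ancestor and P3
#' at `t123`; optional gene-flow epochs, bottlenecks, donor-size changes and
#' an ancestral-structure phase. The outgroup is not simulated: spectra are
#' polarized by construction.
#'
#' @param t12 Backward time of the P1/P2 split (default 0.5, in units of 2N
#'   generations).
#' @param t123 Backward time of the split between the P1/P2 ancestor and P3
#'   (default 1.0).
#' @param nu Length-3 relative sizes for P1, P2, P3 (each constant from the
#'   present back to its merge). Default `c(1, 1, 1)`.
#' @param geneflow Data frame with columns `donor`, `recipient`, `start`,
#'   `end`, `M` (forward semantics as in [demographic_model()]); or `NULL`.
#' @param bottlenecks Data frame with columns `pop`, `start`, `end`, `nu`:
#'   population `pop` has relative size `nu` over backward interval
#'   `[start, end)`; or `NULL`.
#' @param ancestral_structure `NULL`, or a list with elements `M` (symmetric
#'   P1-ancestor/P2-ancestor migration rate) and `t_end` (backward time at
#'   which the two ancestral demes finally merge). When given, P1 and P2 do
#'   not merge at `t12`; instead their ancestral demes exchange migrants at
#'   rate `M` from `t12` until `t_end`, P3 merges into the P2-side deme at
#'   `t123`, and the demes merge at `t_end`. This emulates a structured
#'   ancestral population persisting from before the P3 split until the
#'   P1/P2 split.
#' @param mutation_window As in [demographic_model()].
#' @return A `demographic_model`.
#' @export
three_pop_model <- function(t12 = 0.5, t123 = 1.0, nu = c(1, 1, 1),
                            geneflow = NULL, bottlenecks = NULL,
                            ancestral_structure = NULL,
                            mutation_window = c(0, Inf)) {
  stopifnot(t123 > t12, t12 > 0, length(nu) == 3L)
  sizes <- tibble::tibble(pop = 1:3, start = 0, nu = as.numeric(nu))
  if (!is.null(bottlenecks)) {
    b <- tibble::as_tibble(bottlenecks)
    for (i in seq_len(nrow(b))) {
      sizes <- rbind(sizes,
                     tibble::tibble(pop = b$pop[i], start = b$start[i], nu = b$nu[i]),
                     tibble::tibble(pop = b$pop[i], start = b$end[i],
                                    nu = as.numeric(nu[b$pop[i]])))
    }
  }
  if (is.null(ancestral_structure)) {
    merges <- tibble::tibble(time = c(t12, t123), from = c(1, 3), to = c(2, 2))
    migration <- geneflow
  } else {
    stopifnot(is.list(ancestral_structure),
              ancestral_structure$t_end > t123)
    merges <- tibble::tibble(time = c(t123, ancestral_structure$t_end),
                             from = c(3, 1), to = c(2, 2))
    struct_mig <- tibble::tibble(
      donor = c(1, 2), recipient = c(2, 1),
      start = t12, end = ancestral_structure$t_end,
      M = ancestral_structure$M
    )
    migration <- if (is.null(geneflow)) struct_mig else rbind(tibble::as_tibble(geneflow), struct_mig)
  }
  demographic_model(npop = 3L, sizes = sizes, merges = merges,
                    migration = migration, mutation_window = mutation_window)
}

# flatten a model to the 0-based matrices the C++ engine consumes
model_matrices <- function(model) {
  s <- model$sizes
  m <- model$merges
  g <- model$migration
  list(
    sizes = if (nrow(s)) cbind(s$pop - 1, s$start, s$nu) else matrix(0, 0, 3),
    merges = if (nrow(m)) cbind(m$time, m$from - 1, m$to - 1) else matrix(0, 0, 3),
    # backward convention: lineage in recipient jumps to donor at rate M
    migs = if (!is.null(g) && nrow(g)) {
      cbind(g$recipient - 1, g$donor - 1, g$start, g$end, g$M)
    } else matrix(0, 0, 5)
  )
}

#' Serialize a demographic model to a YAML file
#'
#' @param model A `demographic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  obj <- list(
    npop = model$npop,
    sizes = lapply(seq_len(nrow(model$sizes)), function(i) as.list(model$sizes[i, ])),
    merges = lapply(seq_len(nrow(model$merges)), function(i) as.list(model$merges[i, ])),
    migration = lapply(seq_len(nrow(model$migration)), function(i) as.list(model$migration[i, ])),
    mutation_window = ifelse(is.finite(model$mutation_window),
                             model$mutation_window, c(NA, NA))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a demographic model from a YAML file written by [write_model()]
#'
#' @param path Path to the YAML file.
#' @return A `demographic_model`.
#' @export
read_model <- function(path) {
  obj <- yaml::read_yaml(path)
  to_tbl <- function(lst) {
    if (!length(lst)) return(NULL)
    dplyr::bind_rows(lapply(lst, tibble::as_tibble))
  }
  win <- unlist(obj$mutation_window)
  win[is.na(win)] <- c(0, Inf)[is.na(win)]
  demographic_model(npop = obj$npop,
                    sizes = to_tbl(obj$sizes),
                    merges = to_tbl(obj$merges),
                    migration = to_tbl(obj$migration),
                    mutation_window = win)
}
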