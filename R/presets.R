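#' Named demographic scenario presets
#'
#' A registry of fully parameterized three-population scenarios covering the
#' canonical behaviours of the D frequency spectrum: the timing of P3-to-P2
#' gene flow (recent / old / ancient), bottlenecks with and without gene
#' flow, outward and bidirectional flow, flow into both focal populations,
#' donor-size variation, mutation-age restriction, P1-P2 exchange, and
#' ancestral population structure. All presets share the default topology
#' (((P1, P2), P3)): P1/P2 split at backward time `t12 = 0.5` and P3 split at
#' `t123 = 1.0` (coalescent units of 2N generations), relative sizes 1 unless
#' stated. Gene-flow epochs occupy the most recent fifth of the post-split
#' epoch (`[0, 0.1]`) for "recent", the middle (`[0.2, 0.3]`) for "old" and
#' the most ancient fifth (`[0.4, 0.5]`) for "ancient" flow; bottlenecks
#' shrink a population to `nu = 0.05` for 0.05 time units. Population-scaled
#' migration rates `M = 2Nm` follow the scenario definitions (2 for recent
#' flow; 3 for old/ancient flow).
#'
#' Every numeric knob can be overridden through `...`, which is passed to
#' the preset's constructor; see each constructor's formals via
#' `preset_args(name)`.
#'
#' @param name Preset name; call `preset_names()` for the list.
#' @param ... Overrides of the preset's parameters (e.g. `M = 5`,
#'   `t12 = 0.8`).
#' @return A `demographic_model`.
#' @export
#' @examples
#' presets("fig2a_recent_geneflow")
#' presets("fig2a_recent_geneflow", M = 5)
presets <- function(name, ...) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown preset '%s'; available presets:\n  %s",
                 name, paste(names(reg), collapse = "\n  ")), call. = FALSE)
  }
  reg[[name]](...)
}

#' @rdname presets
#' @export
preset_names <- function() names(preset_registry())

#' @rdname presets
#' @export
preset_args <- function(name) formals(preset_registry()[[name]])

preset_registry <- function() {
  flow <- function(donor, recipient, start, end, M) {
    tibble::tibble(donor = donor, recipient = recipient,
                   start = start, end = end, M = M)
  }
  bneck <- function(pop, start, end, nu) {
    tibble::tibble(pop = pop, start = start, end = end, nu = nu)
  }
  list(
    no_geneflow = function(t12 = 0.5, t123 = 1.0, nu = c(1, 1, 1)) {
      three_pop_model(t12, t123, nu)
    },
    fig2a_recent_geneflow = function(t12 = 0.5, t123 = 1.0, M = 2,
                                     flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123,
                      geneflow = flow(3, 2, flow_start, flow_end, M))
    },
    fig2b_old_geneflow = function(t12 = 0.5, t123 = 1.0, M = 3,
                                  flow_start = 0.2, flow_end = 0.3) {
      three_pop_model(t12, t123,
                      geneflow = flow(3, 2, flow_start, flow_end, M))
    },
    fig2c_ancient_geneflow = function(t12 = 0.5, t123 = 1.0, M = 3,
                                      flow_start = 0.4, flow_end = 0.5) {
      three_pop_model(t12, t123,
                      geneflow = flow(3, 2, flow_start, flow_end, M))
    },
    fig3a_bottleneck = function(t12 = 0.5, t123 = 1.0,
                                bneck_start = 0.2, bneck_end = 0.25,
                                bneck_nu = 0.05) {
      three_pop_model(t12, t123,
                      bottlenecks = bneck(2, bneck_start, bneck_end, bneck_nu))
    },
    fig3b_bottleneck_then_geneflow = function(t12 = 0.5, t123 = 1.0, M = 2,
                                              flow_start = 0, flow_end = 0.1,
                                              bneck_start = 0.2,
                                              bneck_end = 0.25,
                                              bneck_nu = 0.05) {
      three_pop_model(t12, t123,
                      geneflow = flow(3, 2, flow_start, flow_end, M),
                      bottlenecks = bneck(2, bneck_start, bneck_end, bneck_nu))
    },
    fig3c_geneflow_then_bottleneck = function(t12 = 0.5, t123 = 1.0, M = 3,
                                              flow_start = 0.3, flow_end = 0.4,
                                              bneck_start = 0.1,
                                              bneck_end = 0.15,
                                              bneck_nu = 0.05) {
      three_pop_model(t12, t123,
                      geneflow = flow(3, 2, flow_start, flow_end, M),
                      bottlenecks = bneck(2, bneck_start, bneck_end, bneck_nu))
    },
    fig4a_outward_geneflow = function(t12 = 0.5, t123 = 1.0, M = 2,
                                      flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123,
                      geneflow = flow(2, 3, flow_start, flow_end, M))
    },
    fig4b_bidirectional = function(t12 = 0.5, t123 = 1.0,
                                   M_out = 2, M_in = 1,
                                   flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123,
                      geneflow = rbind(flow(2, 3, flow_start, flow_end, M_out),
                                       flow(3, 2, flow_start, flow_end, M_in)))
    },
    fig4c_geneflow_into_both = function(t12 = 0.5, t123 = 1.0,
                                        M_p2 = 3, M_p1 = 0.5,
                                        flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123,
                      geneflow = rbind(flow(3, 2, flow_start, flow_end, M_p2),
                                       flow(3, 1, flow_start, flow_end, M_p1)))
    },
    symmetric_geneflow = function(t12 = 0.5, t123 = 1.0, M = 2,
                                  flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123,
                      geneflow = rbind(flow(3, 2, flow_start, flow_end, M),
                                       flow(3, 1, flow_start, flow_end, M)))
    },
    s2_small_donor = function(t12 = 0.5, t123 = 1.0, M = 2, nu3 = 0.1,
                              flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123, nu = c(1, 1, nu3),
                      geneflow = flow(3, 2, flow_start, flow_end, M))
    },
    s3_ancient_mutations_only = function(t12 = 0.5, t123 = 1.0, M = 2,
                                         flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123,
                      geneflow = flow(3, 2, flow_start, flow_end, M),
                      mutation_window = c(t123, Inf))
    },
    s4_low_reverse_flow = function(t12 = 0.5, t123 = 1.0,
                                   M_out = 2, M_in = 0.2,
                                   flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123,
                      geneflow = rbind(flow(2, 3, flow_start, flow_end, M_out),
                                       flow(3, 2, flow_start, flow_end, M_in)))
    },
    s5_p1_p2_geneflow = function(t12 = 0.5, t123 = 1.0, M = 2, M_12 = 1,
                                 flow_start = 0, flow_end = 0.1) {
      three_pop_model(t12, t123,
                      geneflow = rbind(flow(3, 2, flow_start, flow_end, M),
                                       flow(1, 2, flow_start, flow_end, M_12),
                                       flow(2, 1, flow_start, flow_end, M_12)))
    },
    s6_ancestral_structure = function(t12 = 0.1, t123 = 1.0,
                                      M_struct = 1, t_end = 4.0) {
      three_pop_model(t12, t123,
                      ancestral_structure = list(M = M_struct, t_end = t_end))
    }
  )
}
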