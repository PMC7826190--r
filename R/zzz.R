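#' @useDynLib dfspectrum, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom dplyr bind_rows bind_cols
#' @importFrom purrr map
#' @importFrom tidyr unnest
#' @keywords internal
"_PACKAGE"
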