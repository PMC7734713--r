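#' @importFrom stats setNames runif
#' @importFrom utils head combn
#' @importFrom data.table set setorderv setcolorder setindexv
NULL

.datatable.aware <- TRUE
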