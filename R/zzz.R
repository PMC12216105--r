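#' @useDynLib demSBI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom ranger ranger
#' @importFrom xgboost xgboost
#' @importFrom nnet nnet
NULL
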