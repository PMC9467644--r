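#' @importFrom stats dist wilcox.test kruskal.test p.adjust pnorm median
#'   rnorm runif
#' @importFrom utils read.csv combn globalVariables
#' @importFrom grDevices chull
NULL

utils::globalVariables(c("group", "value"))
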