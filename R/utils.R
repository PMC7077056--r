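#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# valid node classes used across all networks
NODE_TYPES <- c("lncRNA", "mRNA", "miRNA", "protein", "TF")

new_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

# average ranks of `x` in DESCENDING order (rank 1 = largest value)
rank_desc <- function(x) rank(-x, ties.method = "average")
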