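#' Centered log-ratio transform
#'
#' Per sample (row): log(x + pseudocount) minus the row mean of the logs.
#' The standard guard against compositional (total-depth) artifacts before
#' correlation-based network inference. Rows sum to zero by construction
#' and the transform is invariant to rescaling a row when pseudocount = 0.
#'
#' @param counts samples x taxa non-negative matrix.
#' @param pseudocount added to every entry before the log; must be > 0
#'   unless all counts are strictly positive.
#' @return list with \code{values} (samples x taxa CLR matrix) and
#'   \code{pseudocount}; class \code{clr_matrix}.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  stop_if_not(pseudocount > 0 || all(counts > 0),
              "pseudocount must be positive when zero counts are present")
  lg <- log(counts + pseudocount)
  values <- lg - rowMeans(lg)
  structure(list(values = values, pseudocount = pseudocount),
            class = "clr_matrix")
}
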