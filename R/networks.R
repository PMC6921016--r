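# Characterization of predicted subunit networks. A complex with N subunits
# and M predicted physical edges has connection degree 2M / (N (N-1)), the
# fraction of the complete graph realized. Complexes are triaged into
# fully connected (degree >= full_threshold, routed to functional
# clustering), isolated (M = 0) and partially connected (routed to
# modularity clustering).

#' Connection degree of a complex
#'
#' @param N Subunit count (>= 2).
#' @param M Predicted physical edge count, between 0 and `N (N-1) / 2`.
#' @return `2 M / (N (N - 1))`, in \[0, 1\].
#' @examples
#' connection_degree(4, 6)    # complete graph: 1
#' connection_degree(37, 337) # 0.506...
#' @export
connection_degree <- function(N, M) {
  if (any(N < 2)) stop("N must be >= 2")
  if (any(M < 0) || any(M > N * (N - 1) / 2))
    stop("M must lie in [0, N(N-1)/2]")
  2 * M / (N * (N - 1))
}

#' Profile and triage predicted complex networks
#'
#' For each complex, counts its subunits (N) and predicted edges (M,
#' undetermined pairs count as non-edges), computes the connection degree and
#' assigns a category: `"fully"` if degree >= `full_threshold`, `"isolated"`
#' if M = 0, else `"partially"`. The default threshold 0.95 treats networks
#' with degree extremely close to one as fully connected, where topological
#' clustering carries no signal.
#'
#' @param networks Named list of [gene_network()] objects, one per complex
#'   (e.g. from [predict_complex_network()]).
#' @param full_threshold Degree at or above which a complex counts as fully
#'   connected (default 0.95).
#' @return Data frame sorted by descending degree: `complex`, `N`, `M`,
#'   `degree`, `category`.
#' @export
complex_profiles <- function(networks, full_threshold = 0.95) {
  out <- data.frame(
    complex = names(networks),
    N = vapply(networks, function(x) length(x$vertices), integer(1)),
    M = vapply(networks, function(x) nrow(x$edges), integer(1)),
    stringsAsFactors = FALSE)
  out$degree <- connection_degree(out$N, out$M)
  out$category <- ifelse(out$degree >= full_threshold, "fully",
                  ifelse(out$M == 0L, "isolated", "partially"))
  out <- out[order(-out$degree, out$complex), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Category fractions of a triage
#'
#' @param profiles Data frame from [complex_profiles()].
#' @return Named numeric vector of fractions (`fully`, `partially`,
#'   `isolated`) summing to 1.
#' @export
triage_fractions <- function(profiles) {
  n <- nrow(profiles)
  vapply(c("fully", "partially", "isolated"),
         function(cat) sum(profiles$category == cat) / n, numeric(1))
}
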