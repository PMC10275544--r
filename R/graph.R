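# Weighted graph-topology metrics, implemented exactly as the source
# conventions define them:
#   degree    d_i  = number of incident edges; DA = mean(d_i)
#   strength  S_i  = (1/N) sum_j w_ij  (note the 1/N prefactor, kept as
#                    printed; `convention = "sum"` gives the usual sum)
#   path len  L_ij = shortest-path distance with edge lengths 1/w_ij,
#                    with L_ij = 0 for unreachable pairs and the diagonal;
#                    LA = sum(L_ij) / (N (N - 1))
#   cluster   C_i  = (1/(d_i (d_i - 1))) sum_{j,k} (w_ij w_jk w_ki)^(1/3)
#                    on weights normalised by the network maximum
#                    (geometric-mean / Onnela form); CA = mean(C_i)
# Metrics consume |w|: the sign of an edge is display semantics
# (excitatory/inhibitory), not a length or a triangle weight.

.metricWeights <- function(net) {
  if (methods::is(net, "ThresholdedNetwork")) abs(edgeWeights(net))
  else {
    w <- abs(as.matrix(net))
    diag(w) <- 0
    w
  }
}

#' Node degree and network degree
#'
#' @param w a [ThresholdedNetwork-class] or a symmetric non-negative
#'   weight matrix with zero diagonal.
#' @return list with `d` (per-node edge counts) and `DA` (their mean).
#' @export
nodeDegree <- function(w) {
  w <- .metricWeights(w)
  d <- rowSums(w != 0)
  list(d = d, DA = mean(d))
}

#' Node strength and network strength
#'
#' @inheritParams nodeDegree
#' @param convention `"asPrinted"` (default) divides each node's incident
#'   weight sum by N; `"sum"` is the conventional plain sum.
#' @return list with `S` (per-node strengths) and `SA` (their mean).
#' @export
nodeStrength <- function(w, convention = c("asPrinted", "sum")) {
  convention <- match.arg(convention)
  w <- .metricWeights(w)
  S <- rowSums(w)
  if (convention == "asPrinted") S <- S / nrow(w)
  list(S = S, SA = mean(S))
}

#' Shortest-path-length matrix and average path length
#'
#' Edge lengths are the inverse of the edge weights; distances come from
#' Dijkstra's algorithm (via igraph). Unreachable pairs and the diagonal
#' are set to 0 by convention, so fragmented networks contribute short
#' apparent path lengths rather than infinities; `convention =
#' "harmonic"` instead returns the harmonic-mean path length (unreachable
#' pairs contribute zero inverse distance), which penalises fragmentation.
#'
#' @inheritParams nodeDegree
#' @param convention `"zeroUnreachable"` (default) or `"harmonic"`.
#' @return list with `L` (matrix) and `LA`.
#' @export
pathLength <- function(w, convention = c("zeroUnreachable", "harmonic")) {
  convention <- match.arg(convention)
  w <- .metricWeights(w)
  N <- nrow(w)
  if (N < 2L) return(list(L = matrix(0, N, N), LA = 0))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    L <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  } else {
    L <- matrix(Inf, N, N)
    diag(L) <- 0
  }
  if (convention == "harmonic") {
    inv <- 1 / L
    inv[!is.finite(inv)] <- 0      # unreachable and diagonal
    diag(inv) <- 0
    LA <- if (any(inv > 0)) N * (N - 1) / sum(inv) else 0
    L[is.infinite(L)] <- Inf
    return(list(L = L, LA = LA))
  }
  L[is.infinite(L)] <- 0
  diag(L) <- 0
  list(L = L, LA = sum(L) / (N * (N - 1)))
}

#' Weighted clustering coefficient (geometric-mean form)
#'
#' Weights are normalised by the network's maximum before taking cube
#' roots, so \eqn{C_i \in [0, 1]} (a no-op when weights are correlation
#' magnitudes, kept for generality). Nodes with degree < 2 get
#' \eqn{C_i = 0}.
#'
#' @inheritParams nodeDegree
#' @return list with `C` (per-node) and `CA` (mean over all N nodes).
#' @export
clusteringCoefficient <- function(w) {
  w <- .metricWeights(w)
  N <- nrow(w)
  d <- rowSums(w != 0)
  mx <- max(w)
  if (mx > 0) w <- w / mx
  w13 <- w^(1 / 3)
  num <- diag(w13 %*% w13 %*% w13)   # sum over ordered (j,k) pairs
  C <- ifelse(d >= 2, num / (d * (d - 1)), 0)
  list(C = C, CA = if (N) mean(C) else 0)
}

#' Compute all weighted topology metrics for one network
#'
#' Applies the |w| transform and computes degree, strength, shortest-path
#' lengths and clustering, returning node-level values and the four
#' network averages DA, SA, LA, CA.
#'
#' @param net a [ThresholdedNetwork-class] (or bare weight matrix).
#' @param strengthConvention,pathConvention forwarded to [nodeStrength()]
#'   and [pathLength()].
#' @return a [GraphMetrics-class].
#' @export
computeGraphMetrics <- function(net,
                                strengthConvention = "asPrinted",
                                pathConvention = "zeroUnreachable") {
  w <- .metricWeights(net)
  if (all(w == 0))
    warning("empty network: all metrics are 0")
  deg <- nodeDegree(w)
  str <- nodeStrength(w, strengthConvention)
  pl <- pathLength(w, pathConvention)
  cl <- clusteringCoefficient(w)
  nodes <- data.frame(node = seq_len(nrow(w)), degree = deg$d,
                      strength = str$S, clustering = cl$C)
  band <- if (methods::is(net, "ThresholdedNetwork")) bandInfo(net)
          else data.frame(name = character(0), low = numeric(0),
                          high = numeric(0))
  new("GraphMetrics", nodes = nodes, L = pl$L,
      network = c(DA = deg$DA, SA = str$SA, LA = pl$LA, CA = cl$CA),
      band = band,
      subjectId = if (methods::is(net, "ThresholdedNetwork"))
        net@subjectId else "graph",
      group = if (methods::is(net, "ThresholdedNetwork"))
        net@group else "none")
}
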