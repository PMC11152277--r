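# Classic comparison predictors: common neighbors and the truncated Katz
# index over the bipartite adjacency.

#' Baseline configuration
#'
#' @param katz_beta damping factor for the Katz index; must stay below the
#'   reciprocal spectral radius of the adjacency for the closed form to
#'   converge.
#' @param katz_max_path_length truncation length L (>= 2).
#' @param group_aggregation combine pairwise Katz scores over an object
#'   group by `"mean"` or `"min"`.
#' @return object of class `baseline_config`.
#' @export
baseline_config <- function(katz_beta = 0.05, katz_max_path_length = 6L,
                            group_aggregation = c("mean", "min")) {
  group_aggregation <- match.arg(group_aggregation)
  fl_assert(katz_beta > 0 && katz_beta < 1, "katz_beta must be in (0, 1)")
  fl_assert(katz_max_path_length >= 2, "katz_max_path_length must be >= 2")
  structure(list(katz_beta = katz_beta,
                 katz_max_path_length = as.integer(katz_max_path_length),
                 group_aggregation = group_aggregation),
            class = "baseline_config")
}

#' Common-neighbors score for an object group
#'
#' The number of attributes adjacent to every member of the group; for a
#' singleton this is the node's degree. Monotone non-increasing as the
#' group grows.
#'
#' @param network a `bipartite_network`.
#' @param group character vector of object identifiers.
#' @return non-negative integer score.
#' @export
common_neighbors_oo <- function(network, group) {
  length(derive(network, "objects", group))
}

#' Common-neighbors style score for an object-attribute pair
#'
#' Bipartite adjacency has no shared direct neighbors across sides, so the
#' standard projection form is used: the number of length-3 paths between
#' the object and the attribute, `(A A' A)[u, v]`.
#'
#' @param network a `bipartite_network`.
#' @param object,attribute node identifiers.
#' @return non-negative numeric score.
#' @export
common_neighbors_oa <- function(network, object, attribute) {
  check_ids(object, network$objects, "object")
  check_ids(attribute, network$attributes, "attribute")
  A <- network$incidence * 1
  P3 <- A %*% crossprod(A, A[, match(attribute, network$attributes),
                             drop = FALSE])
  as.numeric(P3[match(object, network$objects), 1])
}

# Symmetric adjacency over U ∪ V; rows/cols named.
bipartite_adjacency <- function(network) {
  n_o <- length(network$objects); n_a <- length(network$attributes)
  A <- matrix(0, n_o + n_a, n_o + n_a,
              dimnames = list(c(network$objects, network$attributes),
                              c(network$objects, network$attributes)))
  A[seq_len(n_o), n_o + seq_len(n_a)] <- network$incidence * 1
  A[n_o + seq_len(n_a), seq_len(n_o)] <- t(network$incidence * 1)
  A
}

#' Truncated Katz index between two nodes
#'
#' `sum_{l = min_len..L} beta^l * (number of length-l paths x to y)` over
#' the symmetric bipartite adjacency. With `min_len = 1` (the default) and
#' `beta` inside the convergence radius, the truncated sum approaches the
#' closed form `(I - beta A)^{-1} - I` as L grows; for two same-side nodes
#' all odd powers vanish, so the first contributing term is the length-2
#' path count either way.
#'
#' @param network a `bipartite_network`.
#' @param node_x,node_y node identifiers (either side).
#' @param config a [baseline_config()].
#' @param min_len smallest path length included.
#' @return numeric score.
#' @export
katz_score <- function(network, node_x, node_y, config = baseline_config(),
                       min_len = 1L) {
  all_nodes <- c(network$objects, network$attributes)
  check_ids(c(node_x, node_y), all_nodes, "node")
  A <- bipartite_adjacency(network)
  i <- match(node_x, all_nodes); j <- match(node_y, all_nodes)
  beta <- config$katz_beta
  # accumulate column j of beta^l A^l iteratively
  col <- matrix(0, nrow(A), 1); col[j, 1] <- 1
  total <- 0
  for (l in seq_len(config$katz_max_path_length)) {
    col <- beta * (A %*% col)
    if (l >= min_len) total <- total + col[i, 1]
  }
  unname(total)
}

#' Closed-form Katz matrix
#'
#' `(I - beta A)^{-1} - I`; errors when beta is at or beyond the reciprocal
#' spectral radius.
#'
#' @param network a `bipartite_network`.
#' @param config a [baseline_config()].
#' @return dense matrix over all nodes (objects then attributes).
#' @export
katz_closed_form <- function(network, config = baseline_config()) {
  A <- bipartite_adjacency(network)
  beta <- config$katz_beta
  rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  if (rho > 0 && beta >= 1 / rho) {
    fl_stop("katz_beta ", beta, " is outside the convergence radius 1/",
            signif(rho, 6))
  }
  solve(diag(nrow(A)) - beta * A) - diag(nrow(A))
}

#' Katz score for an object group
#'
#' The paper-scale Katz baseline scores a group by aggregating the pairwise
#' object-object Katz indices over all unordered member pairs (mean by
#' default, configurable min).
#'
#' @param network a `bipartite_network`.
#' @param group character vector of object identifiers (size >= 2).
#' @param config a [baseline_config()].
#' @return numeric score.
#' @export
katz_group_score <- function(network, group, config = baseline_config()) {
  fl_assert(length(group) >= 2, "group must have at least 2 objects")
  pairs <- utils::combn(group, 2, simplify = FALSE)
  vals <- vapply(pairs, function(p)
    katz_score(network, p[1], p[2], config), numeric(1))
  if (config$group_aggregation == "mean") mean(vals) else min(vals)
}
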