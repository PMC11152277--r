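# Planted-bi-clique synthetic bipartite networks: the testbed emulating
# biological bipartite data such as metabolite-reaction participation.

#' Configuration for the planted-bi-clique generator
#'
#' Networks are built as a union of planted complete bi-cliques (each a
#' uniformly sampled object subset crossed with an attribute subset) plus
#' independent noise edges over the remaining cells. Defaults describe the
#' standard benchmark used throughout the package tests: a 50 x 40 network
#' with 15 planted bi-cliques of side 3-6 and 1% add-only noise, roughly the
#' block structure of small metabolite-reaction contexts.
#'
#' @param n_objects,n_attributes node counts on each side.
#' @param n_bicliques number of planted bi-cliques.
#' @param object_side_range,attribute_side_range integer `(min, max)` size
#'   ranges for the two sides of each planted bi-clique.
#' @param noise_edge_rate probability that a non-planted cell becomes an
#'   edge, in `[0, 1)`. Noise is add-only: planted structure is never removed.
#' @param extra_bicliques_in_target bi-cliques planted only in the target
#'   network of a growth split.
#' @param seed root seed; all substreams derive from it.
#' @return object of class `planted_config`.
#' @export
planted_config <- function(n_objects = 50L, n_attributes = 40L,
                           n_bicliques = 15L,
                           object_side_range = c(3L, 6L),
                           attribute_side_range = c(3L, 6L),
                           noise_edge_rate = 0.01,
                           extra_bicliques_in_target = 3L,
                           seed = 1L) {
  fl_assert(n_objects >= 0 && n_attributes >= 0, "node counts must be >= 0")
  fl_assert(n_bicliques >= 0, "n_bicliques must be >= 0")
  fl_assert(noise_edge_rate >= 0 && noise_edge_rate < 1,
            "noise_edge_rate must be in [0, 1)")
  if (n_bicliques > 0) {
    fl_assert(object_side_range[1] >= 1 && object_side_range[2] <= n_objects &&
                object_side_range[1] <= object_side_range[2],
              "object_side_range infeasible for n_objects")
    fl_assert(attribute_side_range[1] >= 1 &&
                attribute_side_range[2] <= n_attributes &&
                attribute_side_range[1] <= attribute_side_range[2],
              "attribute_side_range infeasible for n_attributes")
  }
  structure(list(n_objects = as.integer(n_objects),
                 n_attributes = as.integer(n_attributes),
                 n_bicliques = as.integer(n_bicliques),
                 object_side_range = as.integer(object_side_range),
                 attribute_side_range = as.integer(attribute_side_range),
                 noise_edge_rate = noise_edge_rate,
                 extra_bicliques_in_target = as.integer(extra_bicliques_in_target),
                 seed = as.integer(seed)),
            class = "planted_config")
}

sample_biclique <- function(objects, attributes, o_range, a_range) {
  so <- if (o_range[1] == o_range[2]) o_range[1] else
    sample(seq(o_range[1], o_range[2]), 1)
  sa <- if (a_range[1] == a_range[2]) a_range[1] else
    sample(seq(a_range[1], a_range[2]), 1)
  list(objects = sort(sample(objects, so)),
       attributes = sort(sample(attributes, sa)))
}

#' Generate a planted-bi-clique bipartite network
#'
#' @param config a [planted_config()].
#' @param keep_bicliques also return the planted bi-cliques (attribute
#'   `"bicliques"`) for construction checks.
#' @return a `bipartite_network`, deterministic under `config$seed`.
#' @export
generate_planted_network <- function(config, keep_bicliques = TRUE) {
  objects <- paste0("o", seq_len(config$n_objects))
  attributes <- paste0("a", seq_len(config$n_attributes))
  inc <- matrix(FALSE, config$n_objects, config$n_attributes)
  bicliques <- with_seed(substream_seed(config$seed, 1L), {
    bcs <- vector("list", config$n_bicliques)
    for (b in seq_len(config$n_bicliques)) {
      bc <- sample_biclique(objects, attributes,
                            config$object_side_range,
                            config$attribute_side_range)
      inc[match(bc$objects, objects), match(bc$attributes, attributes)] <- TRUE
      bcs[[b]] <- bc
    }
    bcs
  })
  if (config$noise_edge_rate > 0 && length(inc)) {
    with_seed(substream_seed(config$seed, 2L), {
      free <- which(!inc)
      flip <- free[stats::runif(length(free)) < config$noise_edge_rate]
      inc[flip] <- TRUE
    })
  }
  net <- bipartite_network(objects, attributes, incidence = inc)
  if (keep_bicliques) attr(net, "bicliques") <- bicliques
  net
}

#' Generate a growth input/target split
#'
#' The input network is [generate_planted_network()] for `config`; the target
#' adds `extra_bicliques_in_target` further planted bi-cliques whose
#' attribute sides are new attribute nodes, so the target contains
#' object-object links that do not exist in the input (the history/current
#' construction for co-occurrence prediction). New bi-cliques are planted
#' inside existing communities: each samples its objects from the union of
#' two overlapping attribute neighborhoods of the input network (real
#' bipartite growth — new co-authorships, newly annotated reactions — joins
#' nodes that are already structurally close, and that closeness is the
#' signal link predictors exploit).
#'
#' @param config a [planted_config()] with `extra_bicliques_in_target >= 0`.
#' @return a `dataset_split` with `split_kind = "growth"`.
#' @export
generate_growth_pair <- function(config) {
  input <- generate_planted_network(config)
  n_extra <- config$extra_bicliques_in_target
  if (n_extra == 0L) {
    warning("extra_bicliques_in_target is 0: target equals input",
            call. = FALSE)
    return(dataset_split(input, input, "growth"))
  }
  extras <- with_seed(substream_seed(config$seed, 3L), {
    inc <- input$incidence * 1
    P <- tcrossprod(inc)                  # shared-attribute counts
    Q <- P %*% P                          # 4-path (2-hop community) counts
    lapply(seq_len(n_extra), function(b) {
      sa <- if (config$attribute_side_range[1] == config$attribute_side_range[2])
        config$attribute_side_range[1] else
          sample(seq(config$attribute_side_range[1],
                     config$attribute_side_range[2]), 1)
      so <- if (config$object_side_range[1] == config$object_side_range[2])
        config$object_side_range[1] else
          sample(seq(config$object_side_range[1],
                     config$object_side_range[2]), 1)
      active <- which(rowSums(inc) > 0)
      seed_o <- if (length(active)) sample(active, 1) else
        sample(config$n_objects, 1)
      # community members that do not yet share an attribute with the seed
      cand <- which(P[seed_o, ] == 0 & Q[seed_o, ] > 0)
      objs <- c(seed_o, sample(cand, min(so - 1L, length(cand))))
      if (length(objs) < so) {
        rest <- setdiff(seq_len(config$n_objects), objs)
        objs <- c(objs, sample(rest, so - length(objs)))
      }
      list(objects = sort(input$objects[objs]), n_attr = sa)
    })
  })
  new_attrs <- character()
  edges <- edge_list(input)
  next_id <- config$n_attributes
  bicliques <- list()
  for (ex in extras) {
    ids <- paste0("a", next_id + seq_len(ex$n_attr))
    next_id <- next_id + ex$n_attr
    new_attrs <- c(new_attrs, ids)
    edges <- rbind(edges, cbind(rep(ex$objects, each = length(ids)),
                                rep(ids, times = length(ex$objects))))
    bicliques[[length(bicliques) + 1L]] <- list(objects = ex$objects,
                                                attributes = ids)
  }
  target <- bipartite_network(input$objects,
                              c(input$attributes, new_attrs),
                              edges = edges)
  attr(target, "bicliques") <- c(attr(input, "bicliques"), bicliques)
  dataset_split(input, target, "growth")
}
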