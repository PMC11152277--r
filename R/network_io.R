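# Bipartite network container, TSV / Burmeister CXT readers and writers,
# and input/target dataset splits.

#' Create a bipartite network
#'
#' Structurally identical to a [formal_context()]: the two node sets play the
#' roles of objects and attributes and every edge joins one node of each set.
#'
#' @inheritParams formal_context
#' @return object of class `bipartite_network` (inherits `formal_context`).
#' @export
bipartite_network <- function(objects = character(), attributes = character(),
                              edges = NULL, incidence = NULL) {
  ctx <- formal_context(objects, attributes, edges, incidence)
  class(ctx) <- c("bipartite_network", class(ctx))
  ctx
}

#' Convert between bipartite networks and formal contexts
#'
#' The conversion is the identity on content: node sets, node order and
#' edges are preserved exactly.
#'
#' @param x a `bipartite_network` or `formal_context`.
#' @return the same data under the other class.
#' @export
as_formal_context <- function(x) {
  structure(list(objects = x$objects, attributes = x$attributes,
                 incidence = x$incidence), class = "formal_context")
}

#' @rdname as_formal_context
#' @export
as_bipartite_network <- function(x) {
  structure(list(objects = x$objects, attributes = x$attributes,
                 incidence = x$incidence),
            class = c("bipartite_network", "formal_context"))
}

#' Read a bipartite network from TSV or Burmeister CXT
#'
#' The TSV dialect is two tab-separated columns `object<TAB>attribute`, UTF-8,
#' with `#` comment lines ignored except for the declarations
#' `#obj <id>` / `#attr <id>`, which register (possibly isolated) nodes in
#' order. Node order is otherwise first-seen. Duplicate edges are
#' deduplicated with a warning. CXT is the Burmeister layout: a `B` header,
#' object/attribute counts, the names, then an `X`/`.` grid.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"cxt"`.
#' @return a `bipartite_network`.
#' @export
read_network <- function(path, format = c("tsv", "cxt")) {
  format <- match.arg(format)
  if (!file.exists(path)) fl_stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (format == "tsv") read_network_tsv(lines) else read_network_cxt(lines)
}

read_network_tsv <- function(lines) {
  objects <- character(); attributes <- character()
  eo <- character(); ea <- character()
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      if (startsWith(line, "#obj ")) {
        id <- sub("^#obj ", "", line)
        if (!(id %in% objects)) objects <- c(objects, id)
      } else if (startsWith(line, "#attr ")) {
        id <- sub("^#attr ", "", line)
        if (!(id %in% attributes)) attributes <- c(attributes, id)
      }
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
      fl_stop("malformed TSV line ", k, ": ", line)
    }
    eo <- c(eo, parts[1]); ea <- c(ea, parts[2])
  }
  for (id in eo) if (!(id %in% objects)) objects <- c(objects, id)
  objects <- unique(c(objects, character()))
  attributes <- unique(c(attributes, ea[!(ea %in% attributes)], character()))
  if (length(eo)) {
    dup <- duplicated(paste(eo, ea, sep = "\x1f"))
    if (any(dup)) {
      warning(sum(dup), " duplicate edge(s) removed", call. = FALSE)
      eo <- eo[!dup]; ea <- ea[!dup]
    }
  }
  bipartite_network(objects, attributes,
                    edges = if (length(eo)) cbind(eo, ea) else NULL)
}

read_network_cxt <- function(lines) {
  nb <- which(nzchar(trimws(lines)))
  if (!length(nb) || trimws(lines[nb[1]]) != "B") {
    fl_stop("malformed CXT: missing 'B' header at line ", if (length(nb)) nb[1] else 1L)
  }
  body <- lines[nb[-1]]                    # non-blank lines after header
  if (length(body) < 2L) fl_stop("malformed CXT: missing counts")
  n_obj <- suppressWarnings(as.integer(trimws(body[1])))
  n_att <- suppressWarnings(as.integer(trimws(body[2])))
  if (is.na(n_obj) || is.na(n_att)) fl_stop("malformed CXT: bad counts")
  need <- 2L + n_obj + n_att + n_obj
  if (length(body) < need) fl_stop("malformed CXT: truncated file")
  objects <- body[2L + seq_len(n_obj)]
  attributes <- body[2L + n_obj + seq_len(n_att)]
  grid <- body[2L + n_obj + n_att + seq_len(n_obj)]
  inc <- matrix(FALSE, n_obj, n_att)
  for (i in seq_len(n_obj)) {
    row <- grid[i]
    if (nchar(row) != n_att) {
      fl_stop("malformed CXT: grid row ", i, " has ", nchar(row),
              " cells, expected ", n_att)
    }
    inc[i, ] <- strsplit(row, "")[[1]] == "X"
  }
  bipartite_network(objects, attributes, incidence = inc)
}

#' Write a bipartite network to TSV or Burmeister CXT
#'
#' Output is deterministic for a given network and round-trips bit-exactly
#' through [read_network()]. The TSV writer emits `#obj`/`#attr` declaration
#' comments for every node (so isolated nodes and node order survive),
#' followed by one line per edge in object-major declared order.
#'
#' @param network a `bipartite_network` or `formal_context`.
#' @param path file to write.
#' @param format `"tsv"` or `"cxt"`.
#' @export
write_network <- function(network, path, format = c("tsv", "cxt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    el <- edge_list(network)
    lines <- c(paste0("#obj ", network$objects),
               paste0("#attr ", network$attributes),
               if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t"))
  } else {
    grid <- apply(network$incidence, 1, function(r)
      paste(ifelse(r, "X", "."), collapse = ""))
    if (!length(network$objects)) grid <- character()
    lines <- c("B", "",
               length(network$objects), length(network$attributes), "",
               network$objects, network$attributes, grid)
  }
  writeLines(as.character(lines), path, useBytes = TRUE)
  invisible(NULL)
}

#' Construct an input/target dataset split
#'
#' @param input_network the observed network C.
#' @param target_network the target network C' (C plus the links to predict).
#' @param split_kind `"edge_removal"` (same node sets, input edges a subset)
#'   or `"growth"` (target may add nodes and edges).
#' @return object of class `dataset_split`.
#' @export
dataset_split <- function(input_network, target_network,
                          split_kind = c("edge_removal", "growth")) {
  split_kind <- match.arg(split_kind)
  ein <- apply(edge_list(input_network), 1, paste, collapse = "\x1f")
  eta <- apply(edge_list(target_network), 1, paste, collapse = "\x1f")
  fl_assert(all(ein %in% eta), "input edges must be a subset of target edges")
  if (split_kind == "edge_removal") {
    fl_assert(identical(input_network$objects, target_network$objects) &&
                identical(input_network$attributes, target_network$attributes),
              "edge_removal split requires identical node sets")
  } else {
    fl_assert(all(input_network$objects %in% target_network$objects) &&
                all(input_network$attributes %in% target_network$attributes),
              "growth split requires input node sets within target node sets")
  }
  structure(list(input_network = input_network,
                 target_network = target_network,
                 split_kind = split_kind),
            class = "dataset_split")
}

#' Random edge-removal split
#'
#' Removes `floor(fraction * |E|)` edges sampled uniformly without
#' replacement to form the input network; the full network is the target.
#' Node sets are unchanged, so removed edges may leave nodes isolated.
#'
#' @param network the full network.
#' @param fraction fraction of edges to remove, in `[0, 1)`.
#' @param seed RNG seed; identical seeds give identical splits.
#' @return a `dataset_split` with `split_kind = "edge_removal"`.
#' @export
random_edge_removal_split <- function(network, fraction, seed) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    fl_stop("fraction must be in [0, 1)")
  }
  el <- edge_list(network)
  n_rm <- floor(fraction * nrow(el))
  keep <- el
  if (n_rm > 0) {
    drop <- with_seed(seed, sample.int(nrow(el), n_rm))
    keep <- el[-drop, , drop = FALSE]
  }
  input <- bipartite_network(network$objects, network$attributes,
                             edges = if (nrow(keep)) keep else NULL)
  dataset_split(input, network, "edge_removal")
}
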