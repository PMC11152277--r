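# Formal contexts, derivation operators, concept enumeration (NextClosure),
# lattice order / Hasse edges, and the topological-sort lower-neighbor pass.

#' Create a formal context
#'
#' A formal context is a triple (objects, attributes, incidence): two ordered
#' sets of identifiers plus a binary incidence relation saying which object
#' carries which attribute. It is the same structure as a bipartite network
#' with objects and attributes as the two node sets and incident pairs as
#' edges.
#'
#' @param objects character vector of unique object identifiers.
#' @param attributes character vector of unique attribute identifiers.
#' @param edges two-column matrix or data.frame of (object, attribute) pairs,
#'   or `NULL` for an empty relation.
#' @param incidence alternatively, a logical matrix of dimension
#'   `length(objects) x length(attributes)`; ignored when `edges` is given.
#' @return an object of class `formal_context` with fields `objects`,
#'   `attributes` and the logical `incidence` matrix.
#' @examples
#' ctx <- formal_context(c("o1", "o2"), c("a", "b"),
#'                       edges = rbind(c("o1", "a"), c("o1", "b"), c("o2", "a")))
#' derive(ctx, "objects", c("o1", "o2"))
#' @export
formal_context <- function(objects = character(), attributes = character(),
                           edges = NULL, incidence = NULL) {
  objects <- as.character(objects)
  attributes <- as.character(attributes)
  if (anyDuplicated(objects)) fl_stop("duplicate object identifiers")
  if (anyDuplicated(attributes)) fl_stop("duplicate attribute identifiers")
  inc <- matrix(FALSE, length(objects), length(attributes),
                dimnames = list(objects, attributes))
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (nrow(edges)) {
      eo <- as.character(edges[, 1]); ea <- as.character(edges[, 2])
      bad_o <- setdiff(unique(eo), objects)
      if (length(bad_o)) fl_stop("edge references unknown object: ", bad_o[1])
      bad_a <- setdiff(unique(ea), attributes)
      if (length(bad_a)) fl_stop("edge references unknown attribute: ", bad_a[1])
      inc[cbind(match(eo, objects), match(ea, attributes))] <- TRUE
    }
  } else if (!is.null(incidence)) {
    incidence <- as.matrix(incidence)
    fl_assert(all(dim(incidence) == dim(inc)), "incidence has wrong dimensions")
    inc[] <- as.logical(incidence)
  }
  structure(list(objects = objects, attributes = attributes, incidence = inc),
            class = "formal_context")
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf("<%s> %d objects x %d attributes, %d edges\n",
              class(x)[1], length(x$objects), length(x$attributes),
              sum(x$incidence)))
  invisible(x)
}

#' Number of incident pairs (edges) of a context or network
#' @param context a `formal_context` or `bipartite_network`.
#' @return integer edge count.
#' @export
n_edges <- function(context) sum(context$incidence)

#' Edge list of a context or network
#' @param context a `formal_context` or `bipartite_network`.
#' @return character matrix with columns `object`, `attribute`, ordered
#'   object-major by declared node order.
#' @export
edge_list <- function(context) {
  idx <- which(t(context$incidence), arr.ind = TRUE) # t(): object-major order
  cbind(object = context$objects[idx[, 2]],
        attribute = context$attributes[idx[, 1]])
}

check_ids <- function(ids, universe, what) {
  bad <- setdiff(ids, universe)
  if (length(bad)) fl_stop("unknown ", what, " identifier: ", bad[1])
}

#' Derivation (prime) operator
#'
#' For a set of objects, returns every attribute shared by all of them; for
#' a set of attributes, dually. The empty set derives to the whole opposite
#' side. The operator is antitone: enlarging `S` can only shrink the result.
#'
#' @param context a `formal_context`.
#' @param side `"objects"` or `"attributes"`: which side `S` lives on.
#' @param S identifier set (character vector) drawn from that side.
#' @return character vector of identifiers of the opposite side, in declared
#'   order.
#' @export
derive <- function(context, side = c("objects", "attributes"), S) {
  side <- match.arg(side)
  S <- unique(as.character(S))
  inc <- context$incidence
  if (side == "objects") {
    check_ids(S, context$objects, "object")
    if (!length(S)) return(context$attributes)
    rows <- inc[match(S, context$objects), , drop = FALSE]
    context$attributes[colSums(rows) == length(S)]
  } else {
    check_ids(S, context$attributes, "attribute")
    if (!length(S)) return(context$objects)
    cols <- inc[, match(S, context$attributes), drop = FALSE]
    context$objects[rowSums(cols) == length(S)]
  }
}

#' Closure of an object set
#'
#' The double-prime operator: `derive(derive(A))`. Idempotent and extensive;
#' its fixed points are exactly the extents of the context.
#'
#' @inheritParams derive
#' @param A character vector of object identifiers.
#' @return character vector: the smallest extent containing `A`.
#' @export
closure <- function(context, A) {
  derive(context, "attributes", derive(context, "objects", A))
}

#' Test whether (A, B) is a formal concept
#'
#' True iff A' = B and B' = A, i.e. (A, B) is a maximal bi-clique of the
#' underlying bipartite network.
#'
#' @inheritParams derive
#' @param A object identifier set.
#' @param B attribute identifier set.
#' @return logical scalar.
#' @export
is_concept <- function(context, A, B) {
  setequal(derive(context, "objects", A), B) &&
    setequal(derive(context, "attributes", B), A)
}

# Closure on attribute index masks; used by the NextClosure enumeration.
# ctx sides are swapped by the caller when enumerating over objects.
close_attr_mask <- function(inc, bmask) {
  nb <- sum(bmask)
  rows <- if (nb == 0L) rep(TRUE, nrow(inc))
          else rowSums(inc[, bmask, drop = FALSE]) == nb
  nr <- sum(rows)
  intent <- if (nr == 0L) rep(TRUE, ncol(inc))
            else colSums(inc[rows, , drop = FALSE]) == nr
  list(intent = intent, extent = rows)
}

# NextClosure over the columns of `inc`; returns a list of
# list(extent = row mask, intent = col mask) covering every concept.
next_closure_enumerate <- function(inc) {
  m <- ncol(inc)
  out <- list()
  cl <- close_attr_mask(inc, rep(FALSE, m))
  out[[1]] <- cl
  if (m == 0L) return(out)
  B <- cl$intent
  repeat {
    if (all(B)) break
    found <- FALSE
    for (i in rev(seq_len(m))) {
      if (B[i]) {
        B[i] <- FALSE
      } else {
        cand <- B
        cand[i] <- TRUE
        cl <- close_attr_mask(inc, cand)
        D <- cl$intent
        # lectic validity: no new attribute before position i
        if (i == 1L || !any(D[seq_len(i - 1L)] & !B[seq_len(i - 1L)])) {
          out[[length(out) + 1L]] <- cl
          B <- D
          found <- TRUE
          break
        }
      }
    }
    if (!found) break
  }
  out
}

canonical_concept_order <- function(concepts) {
  sizes <- vapply(concepts, function(cc) length(cc$extent), integer(1))
  keys <- vapply(concepts, function(cc) set_key(cc$extent), character(1))
  order(sizes, keys)
}

#' Enumerate all formal concepts of a context
#'
#' Uses the NextClosure algorithm over the smaller side of the context (the
#' set of closed attribute sets is enumerated in lectic order, or dually the
#' closed object sets when there are fewer objects than attributes). The
#' output is the complete concept set — every maximal bi-clique — in a
#' canonical order: extent cardinality ascending, ties broken by the sorted
#' extent identifiers.
#'
#' @inheritParams derive
#' @return list of concepts, each a list with character fields `extent` and
#'   `intent` (sorted lexicographically).
#' @export
extract_concepts <- function(context) {
  inc <- context$incidence
  swap <- length(context$objects) < length(context$attributes)
  # enumerate over the smaller side: columns of `work`
  work <- if (swap) t(inc) else inc
  raw <- next_closure_enumerate(work)
  concepts <- lapply(raw, function(cl) {
    if (swap) {
      list(extent = sort(context$objects[cl$intent]),
           intent = sort(context$attributes[cl$extent]))
    } else {
      list(extent = sort(context$objects[cl$extent]),
           intent = sort(context$attributes[cl$intent]))
    }
  })
  concepts[canonical_concept_order(concepts)]
}

#' Brute-force concept enumeration (test oracle)
#'
#' Enumerates every subset of the smaller side, closes it, and deduplicates.
#' Exponential; refuses when the smaller side exceeds `max_side` elements.
#' Intended as an independent oracle for [extract_concepts()].
#'
#' @inheritParams derive
#' @param max_side refuse when `min(|objects|, |attributes|)` exceeds this.
#' @return list of concepts in the same canonical order as
#'   [extract_concepts()].
#' @export
brute_force_concepts <- function(context, max_side = 20L) {
  n_o <- length(context$objects); n_a <- length(context$attributes)
  small <- min(n_o, n_a)
  if (small > max_side) {
    fl_stop("smaller side has ", small, " elements; limit is ", max_side)
  }
  over_objects <- n_o <= n_a
  side_ids <- if (over_objects) context$objects else context$attributes
  seen <- new.env(parent = emptyenv())
  concepts <- list()
  n <- length(side_ids)
  for (code in 0:(2^n - 1)) {
    pick <- side_ids[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
    if (over_objects) {
      B <- derive(context, "objects", pick)
      A <- derive(context, "attributes", B)
    } else {
      A <- derive(context, "attributes", pick)
      B <- derive(context, "objects", A)
    }
    key <- set_key(A)
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      concepts[[length(concepts) + 1L]] <- list(extent = sort(A),
                                                intent = sort(B))
    }
  }
  concepts[canonical_concept_order(concepts)]
}

#' Build the concept lattice
#'
#' Orders concepts by strict extent inclusion, and computes the Hasse
#' (neighbor) edges as the transitive reduction of that order: (i, j) is a
#' Hasse edge iff concept i sits strictly below concept j with no concept
#' strictly between. The Algorithm-style one-lower-neighbor map is left
#' empty; fill it with [algorithm1_lower_neighbors()].
#'
#' @param concepts complete concept set of one context, as returned by
#'   [extract_concepts()].
#' @return object of class `concept_lattice`: fields `concepts`,
#'   `order` (logical matrix, `order[i, j]` iff i < j), `order_pairs` and
#'   `hasse_edges` (two-column index matrices, lower first), and
#'   `lower_neighbor_map` (integer vector, all `NA` until filled).
#' @export
build_lattice <- function(concepts) {
  n <- length(concepts)
  keys <- vapply(concepts, function(cc) set_key(cc$extent), character(1))
  if (anyDuplicated(keys)) fl_stop("duplicate concepts in input")
  universe <- sort(unique(unlist(lapply(concepts, `[[`, "extent"))))
  ext <- matrix(FALSE, n, max(1L, length(universe)))
  for (i in seq_len(n)) {
    if (length(concepts[[i]]$extent)) {
      ext[i, match(concepts[[i]]$extent, universe)] <- TRUE
    }
  }
  sizes <- rowSums(ext)
  inter <- tcrossprod(ext * 1)            # |extent_i ∩ extent_j|
  ord <- (inter == sizes) & outer(sizes, sizes, `<`)  # extent_i ⊂ extent_j
  diag(ord) <- FALSE
  two_step <- ((ord * 1) %*% (ord * 1)) > 0
  hasse <- ord & !two_step
  structure(list(
    concepts = concepts,
    order = ord,
    order_pairs = which(ord, arr.ind = TRUE, useNames = FALSE),
    hasse_edges = which(hasse, arr.ind = TRUE, useNames = FALSE),
    lower_neighbor_map = rep(NA_integer_, n)
  ), class = "concept_lattice")
}

#' @export
print.concept_lattice <- function(x, ...) {
  cat(sprintf("<concept_lattice> %d concepts, %d order pairs, %d hasse edges\n",
              length(x$concepts), nrow(x$order_pairs), nrow(x$hasse_edges)))
  invisible(x)
}

#' One lower neighbor per concept via topological sorting
#'
#' Processes concepts in a breadth-first topological order of the lattice:
#' every concept starts with a counter equal to the number of concepts
#' strictly below it; minimal concepts enter a FIFO queue; popping a concept
#' decrements the counter of everything above it, and the concept whose
#' decrement drives a counter to zero is recorded as that concept's lower
#' neighbor. The recorded concept is always a true lower neighbor (it is
#' maximal among the concepts below), and every non-minimal concept receives
#' exactly one entry.
#'
#' @param lattice a `concept_lattice` with the order populated.
#' @return integer vector `N` of length `|concepts|`: `N[i]` is the index of
#'   one lower neighbor of concept i, or `NA` for minimal concepts.
#' @export
algorithm1_lower_neighbors <- function(lattice) {
  ord <- lattice$order
  n <- nrow(ord)
  if (n == 0L) return(integer(0))
  if (any(diag(ord))) fl_stop("order relation is not irreflexive")
  reach <- ((ord * 1) %*% (ord * 1)) > 0
  if (any(reach & !ord)) fl_stop("order relation is not transitive")
  D <- colSums(ord)                       # concepts strictly below each
  N <- rep(NA_integer_, n)
  queue <- which(D == 0)                  # FIFO of ready concepts
  head <- 1L
  while (head <= length(queue)) {
    cur <- queue[head]; head <- head + 1L
    above <- which(ord[cur, ])
    for (c1 in above) {
      D[c1] <- D[c1] - 1L
      if (D[c1] == 0L) {
        N[c1] <- cur
        queue <- c(queue, c1)
      }
    }
  }
  N
}
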