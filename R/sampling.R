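# Labeled sample generation for the four learning tasks: object-group
# (O-O) train/test samples, object-attribute (O-A) pairs, neighboring-
# concepts (NCP) pairs, and masked-token (MTP) instances.

#' Sampling configuration
#'
#' @param eps_p maximum object-group size for the O-O task (>= 2). Groups of
#'   size 2..`eps_p` are enumerated; the cap keeps the sample count from
#'   growing exponentially.
#' @param mask_rate fraction of non-special tokens selected for masking.
#' @param max_masked hard cap on masked positions per instance.
#' @param seed RNG seed used by the generators.
#' @param neighbor_source which neighbor relation feeds NCP positives:
#'   `"hasse"` (all lattice neighbor pairs, default) or `"algorithm1"` (the
#'   one-lower-neighbor-per-concept map).
#' @return object of class `sampling_config`; `min_group_size` is fixed at 2.
#' @export
sampling_config <- function(eps_p = 3L, mask_rate = 0.15, max_masked = 4L,
                            seed = 1L,
                            neighbor_source = c("hasse", "algorithm1")) {
  neighbor_source <- match.arg(neighbor_source)
  fl_assert(eps_p >= 2, "eps_p must be >= 2")
  fl_assert(mask_rate > 0 && mask_rate <= 1, "mask_rate must be in (0, 1]")
  fl_assert(max_masked >= 1, "max_masked must be >= 1")
  structure(list(eps_p = as.integer(eps_p), min_group_size = 2L,
                 mask_rate = mask_rate, max_masked = as.integer(max_masked),
                 seed = as.integer(seed), neighbor_source = neighbor_source),
            class = "sampling_config")
}

#' Does a group of objects have an object-object link?
#'
#' True iff some attribute is adjacent to every member of the group, i.e.
#' the group's derivation is non-empty.
#'
#' @param network a `bipartite_network` or `formal_context`.
#' @param group character vector of object identifiers.
#' @return logical scalar.
#' @export
has_oo_link <- function(network, group) {
  length(derive(network, "objects", group)) > 0
}

group_df <- function(groups, labels) {
  data.frame(label = as.integer(labels),
             size = vapply(groups, length, integer(1)),
             objects = I(groups))
}

# Enumerate all positive O-O groups of sizes 2..eps_p: for each attribute,
# all subsets of its neighborhood. `inc` logical objects x attributes.
enumerate_oo_positive_groups <- function(objects, inc, eps_p) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (j in seq_len(ncol(inc))) {
    nb <- objects[inc[, j]]
    if (length(nb) < 2L) next
    for (s in 2:min(eps_p, length(nb))) {
      combos <- utils::combn(sort(nb), s, simplify = FALSE)
      for (g in combos) {
        key <- paste(g, collapse = "\x1f")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1L]] <- g
        }
      }
    }
  }
  out
}

# Sample `need` distinct groups of size s from `objects` satisfying
# `pred(group)`, uniformly, excluding keys in `exclude` env. Falls back to
# full enumeration when the universe is small; logs a shortfall otherwise.
sample_groups <- function(objects, s, need, pred, exclude = NULL) {
  if (need == 0L) return(list())
  n <- length(objects)
  if (n < s) return(list())
  total <- choose(n, s)
  taken <- new.env(parent = emptyenv())
  out <- list()
  is_excluded <- function(key) {
    !is.null(exclude) && exists(key, envir = exclude, inherits = FALSE)
  }
  if (total <= 50000) {
    all_g <- utils::combn(sort(objects), s, simplify = FALSE)
    ok <- Filter(function(g) {
      key <- paste(g, collapse = "\x1f")
      !is_excluded(key) && pred(g)
    }, all_g)
    if (length(ok) <= need) {
      if (length(ok) < need) {
        message("negative shortfall: needed ", need, " size-", s,
                " groups, only ", length(ok), " exist")
      }
      return(ok)
    }
    return(ok[sample.int(length(ok), need)])
  }
  tries <- 0L
  max_tries <- need * 200L + 1000L
  while (length(out) < need && tries < max_tries) {
    tries <- tries + 1L
    g <- sort(sample(objects, s))
    key <- paste(g, collapse = "\x1f")
    if (exists(key, envir = taken, inherits = FALSE) || is_excluded(key)) next
    if (pred(g)) {
      assign(key, TRUE, envir = taken)
      out[[length(out) + 1L]] <- g
    }
  }
  if (length(out) < need) {
    message("negative shortfall: needed ", need, " size-", s,
            " groups, sampled ", length(out))
  }
  out
}

#' Generate balanced O-O training samples
#'
#' Positives are all object groups of size 2..`eps_p` that share at least
#' one attribute (enumerated per attribute over its neighborhood and
#' deduplicated). Negatives are drawn uniformly without replacement from
#' groups sharing no attribute, matching the positives in total count and in
#' per-size counts.
#'
#' @param network a `bipartite_network`.
#' @param config a [sampling_config()].
#' @return data.frame with columns `label` (1/0), `size`, and list-column
#'   `objects`.
#' @export
generate_oo_train <- function(network, config) {
  pos <- enumerate_oo_positive_groups(network$objects, network$incidence,
                                      config$eps_p)
  if (!length(pos)) return(group_df(list(), integer(0)))
  sizes <- vapply(pos, length, integer(1))
  neg <- with_seed(substream_seed(config$seed, 11L), {
    unlist(lapply(sort(unique(sizes)), function(s) {
      sample_groups(network$objects, s, sum(sizes == s),
                    function(g) !has_oo_link(network, g))
    }), recursive = FALSE)
  })
  group_df(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))))
}

#' Generate balanced O-O test samples from an input/target split
#'
#' Positives are groups of size 2..`eps_p` for which some target attribute
#' is joined to every group member by edges that are all new (present in the
#' target but not the input), and which have no object-object link in the
#' input network. Negatives are groups with no object-object link in the
#' target network, matched to the positives per size.
#'
#' @param split a `dataset_split`.
#' @param config a [sampling_config()].
#' @return data.frame as in [generate_oo_train()].
#' @export
generate_oo_test <- function(split, config) {
  input <- split$input_network
  target <- split$target_network
  seen <- new.env(parent = emptyenv())
  pos <- list()
  for (j in seq_along(target$attributes)) {
    v <- target$attributes[j]
    tgt_nb <- target$objects[target$incidence[, j]]
    ji <- match(v, input$attributes)
    in_nb <- if (is.na(ji)) character() else
      input$objects[input$incidence[, ji]]
    new_nb <- setdiff(tgt_nb, in_nb)      # u with (u, v) in E' - E
    new_nb <- intersect(new_nb, input$objects)
    if (length(new_nb) < 2L) next
    for (s in 2:min(config$eps_p, length(new_nb))) {
      for (g in utils::combn(sort(new_nb), s, simplify = FALSE)) {
        key <- paste(g, collapse = "\x1f")
        if (!exists(key, envir = seen, inherits = FALSE) &&
            !has_oo_link(input, g)) {
          assign(key, TRUE, envir = seen)
          pos[[length(pos) + 1L]] <- g
        }
      }
    }
  }
  if (!length(pos)) return(group_df(list(), integer(0)))
  sizes <- vapply(pos, length, integer(1))
  neg <- with_seed(substream_seed(config$seed, 12L), {
    unlist(lapply(sort(unique(sizes)), function(s) {
      sample_groups(input$objects, s, sum(sizes == s),
                    function(g) !has_oo_link(target, g))
    }), recursive = FALSE)
  })
  group_df(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))))
}

#' Generate balanced O-A pair samples
#'
#' In train mode (`exclusion_network = NULL`) the positives are every edge
#' of `network_for_positives` and the negatives an equal count of uniformly
#' sampled non-edges of the same network. In test mode the positives are the
#' edges of `network_for_positives` (the target) absent from
#' `exclusion_network` (the input), and the negatives are non-edges of the
#' target.
#'
#' @param network_for_positives network whose edges define the positives.
#' @param exclusion_network optional input network C whose edges are
#'   excluded from the positives (test mode).
#' @param seed RNG seed for negative sampling.
#' @return data.frame with columns `object`, `attribute`, `label`.
#' @export
generate_oa_samples <- function(network_for_positives,
                                exclusion_network = NULL, seed = 1L) {
  net <- network_for_positives
  inc <- net$incidence
  pos_mask <- inc
  if (!is.null(exclusion_network)) {
    excl <- matrix(FALSE, nrow(inc), ncol(inc))
    oi <- match(exclusion_network$objects, net$objects)
    ai <- match(exclusion_network$attributes, net$attributes)
    eidx <- which(exclusion_network$incidence, arr.ind = TRUE)
    if (nrow(eidx)) excl[cbind(oi[eidx[, 1]], ai[eidx[, 2]])] <- TRUE
    pos_mask <- inc & !excl
  }
  pos_idx <- which(pos_mask)
  non_edges <- which(!inc)                # negatives are non-edges of `net`
  n_need <- length(pos_idx)
  n_take <- min(n_need, length(non_edges))
  if (n_take < n_need) {
    message("negative shortfall: needed ", n_need, " non-edges, only ",
            length(non_edges), " exist")
  }
  neg_idx <- if (n_take)
    with_seed(substream_seed(seed, 13L),
              non_edges[sample.int(length(non_edges), n_take)])
  else integer(0)
  idx <- c(pos_idx, neg_idx)
  rows <- ((idx - 1L) %% nrow(inc)) + 1L
  cols <- ((idx - 1L) %/% nrow(inc)) + 1L
  data.frame(object = net$objects[rows],
             attribute = net$attributes[cols],
             label = c(rep(1L, length(pos_idx)), rep(0L, length(neg_idx))))
}

order_pair_extents <- function(ea, eb) {
  ka <- set_key(ea); kb <- set_key(eb)
  if (length(ea) > length(eb) ||
      (length(ea) == length(eb) && ka <= kb)) list(ea, eb) else list(eb, ea)
}

#' Generate balanced neighboring-concepts (NCP) examples
#'
#' Positives are all concept pairs in the chosen neighbor relation whose
#' extents are both non-empty; negatives are an equal count of uniformly
#' sampled non-neighboring concept pairs (never lattice neighbors, whatever
#' the positive source). Within each example the two extents are presented
#' larger-cardinality first, ties broken lexicographically — the same
#' label-free rule for both classes.
#'
#' @param lattice a `concept_lattice`.
#' @param config a [sampling_config()]; `config$neighbor_source` selects the
#'   positive relation, and `config$seed` drives negative sampling.
#' @return list of examples, each `list(extent_a, extent_b, label)`.
#' @export
make_ncp_examples <- function(lattice, config) {
  concepts <- lattice$concepts
  usable <- which(vapply(concepts, function(cc) length(cc$extent) > 0,
                         logical(1)))
  if (length(usable) < 2L) {
    warning("lattice has fewer than 2 concepts with non-empty extents",
            call. = FALSE)
    return(list())
  }
  hasse <- lattice$hasse_edges
  if (config$neighbor_source == "hasse") {
    src <- hasse
  } else {
    N <- algorithm1_lower_neighbors(lattice)
    idx <- which(!is.na(N))
    src <- cbind(N[idx], idx)
  }
  keep <- src[, 1] %in% usable & src[, 2] %in% usable
  src <- src[keep, , drop = FALSE]
  mk <- function(i, j, label) {
    e <- order_pair_extents(concepts[[i]]$extent, concepts[[j]]$extent)
    list(extent_a = e[[1]], extent_b = e[[2]], label = label)
  }
  pos <- lapply(seq_len(nrow(src)), function(r) mk(src[r, 1], src[r, 2], 1L))
  # negatives: unordered usable pairs that are not lattice neighbors
  nkey <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(hasse))) {
    assign(paste(sort(hasse[r, ]), collapse = "_"), TRUE, envir = nkey)
  }
  k <- length(usable)
  need <- length(pos)
  neg_pairs <- with_seed(substream_seed(config$seed, 14L), {
    if (choose(k, 2) <= 200000) {
      all_pairs <- utils::combn(usable, 2, simplify = FALSE)
      ok <- Filter(function(p) {
        !exists(paste(sort(p), collapse = "_"), envir = nkey, inherits = FALSE)
      }, all_pairs)
      if (length(ok) <= need) {
        if (length(ok) < need) {
          message("negative shortfall: needed ", need,
                  " non-neighbor pairs, only ", length(ok), " exist")
        }
        ok
      } else ok[sample.int(length(ok), need)]
    } else {
      taken <- new.env(parent = emptyenv())
      out <- list(); tries <- 0L
      while (length(out) < need && tries < need * 200L + 1000L) {
        tries <- tries + 1L
        p <- sort(sample(usable, 2))
        key <- paste(p, collapse = "_")
        if (exists(key, envir = taken, inherits = FALSE) ||
            exists(key, envir = nkey, inherits = FALSE)) next
        assign(key, TRUE, envir = taken)
        out[[length(out) + 1L]] <- p
      }
      if (length(out) < need) {
        message("negative shortfall: needed ", need,
                " non-neighbor pairs, sampled ", length(out))
      }
      out
    }
  })
  neg <- lapply(neg_pairs, function(p) mk(p[1], p[2], 0L))
  c(pos, neg)
}

#' Corrupt a token sequence for masked token prediction
#'
#' Selects `min(max_masked, max(1, round(mask_rate * n)))` of the `n`
#' non-special token positions uniformly without replacement. Each selected
#' token is replaced by `[MASK]` with probability 0.8, by a uniformly random
#' non-special vocabulary token with probability 0.1, or kept unchanged with
#' probability 0.1; the original token is always recorded as the prediction
#' target. Special tokens (`[PAD]`, `[CLS]`, `[SEP]`) are never selected.
#' Draws come from the ambient RNG stream so training loops control
#' reproducibility with a single seed.
#'
#' @param sequence a `token_sequence` from [encode_pair()] or
#'   [encode_group()].
#' @param config a [sampling_config()] (uses `mask_rate`, `max_masked`).
#' @param vocabulary the [build_vocab()] vocabulary of the sequence.
#' @return object of class `masked_instance`: `input_ids`, `segment_ids`,
#'   `masked_positions` (1-based), `target_ids`.
#' @export
mask_tokens <- function(sequence, config, vocabulary) {
  ids <- sequence$ids
  cand <- which(ids >= 4L)                # non-special positions
  if (!length(cand)) fl_stop("sequence contains only special tokens")
  k <- min(config$max_masked, max(1L, round(config$mask_rate * length(cand))))
  sel <- sort(if (length(cand) == 1L) cand else sample(cand, min(k, length(cand))))
  targets <- ids[sel]
  vocab_tokens <- 4:(vocabulary$size - 1L)
  u <- stats::runif(length(sel))
  new_ids <- ids
  for (t in seq_along(sel)) {
    if (u[t] < 0.8) {
      new_ids[sel[t]] <- 3L               # [MASK]
    } else if (u[t] < 0.9) {
      new_ids[sel[t]] <- if (length(vocab_tokens) == 1L) vocab_tokens else
        sample(vocab_tokens, 1L)
    }                                     # else keep unchanged
  }
  structure(list(input_ids = new_ids,
                 segment_ids = sequence$segment_ids,
                 masked_positions = sel,
                 target_ids = targets),
            class = "masked_instance")
}

#' Write samples as JSON-lines
#'
#' O-O groups serialize as `{"objects": [...], "label": 1}`, O-A pairs as
#' `{"object": u, "attribute": v, "label": 0}`, NCP examples as
#' `{"extent_a": [...], "extent_b": [...], "label": 1}`. Output is
#' deterministic for a given sample list.
#'
#' @param samples a data.frame from the O-O/O-A generators or the list from
#'   [make_ncp_examples()].
#' @param path file to write.
#' @export
write_samples_jsonl <- function(samples, path) {
  lines <- if (is.data.frame(samples) && "objects" %in% names(samples)) {
    vapply(seq_len(nrow(samples)), function(i) {
      jsonlite::toJSON(list(objects = samples$objects[[i]],
                            label = samples$label[i]), auto_unbox = TRUE)
    }, character(1))
  } else if (is.data.frame(samples)) {
    vapply(seq_len(nrow(samples)), function(i) {
      jsonlite::toJSON(list(object = samples$object[i],
                            attribute = samples$attribute[i],
                            label = samples$label[i]), auto_unbox = TRUE)
    }, character(1))
  } else {
    vapply(samples, function(s) {
      jsonlite::toJSON(list(extent_a = s$extent_a, extent_b = s$extent_b,
                            label = s$label), auto_unbox = TRUE)
    }, character(1))
  }
  writeLines(as.character(lines), path, useBytes = TRUE)
  invisible(NULL)
}
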