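# Vocabulary construction and encoder input sequences. One vocabulary per
# network side: the object model tokenizes extents, the attribute model
# intents. Token ids are 0-based ([PAD]=0, [CLS]=1, [SEP]=2, [MASK]=3);
# node tokens follow in sorted-identifier order.

#' Build a vocabulary over node identifiers
#'
#' @param ids unique node identifiers for one network side.
#' @return object of class `fl_vocab`: `specials` (named 0..3), `id_map`
#'   (identifier -> token id, sorted-id order from 4), `size` (total token
#'   count including specials).
#' @export
build_vocab <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) fl_stop("duplicate identifiers in vocabulary input")
  sorted <- sort(ids)
  id_map <- if (length(sorted)) {
    stats::setNames(3L + seq_along(sorted), sorted)
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(specials = c("[PAD]" = 0L, "[CLS]" = 1L,
                              "[SEP]" = 2L, "[MASK]" = 3L),
                 id_map = id_map,
                 size = 4L + length(sorted)),
            class = "fl_vocab")
}

#' Persist / load a vocabulary as JSON
#' @param vocab an `fl_vocab`.
#' @param path JSON file path.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(as.list(c(vocab$specials, vocab$id_map)), path,
                       auto_unbox = TRUE)
  invisible(NULL)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  m <- unlist(jsonlite::read_json(path))
  node <- sort(names(m)[!(names(m) %in% c("[PAD]", "[CLS]", "[SEP]", "[MASK]"))])
  build_vocab(node)
}

tokens_of <- function(ids, vocab) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, names(vocab$id_map))
  if (length(unknown)) fl_stop("identifier not in vocabulary: ", unknown[1])
  unname(vocab$id_map[ids])
}

# Seeded uniform subsampling used when a pair overflows max_len.
truncate_extents <- function(a, b, avail) {
  la <- length(a); lb <- length(b)
  if (la + lb <= avail) return(list(a = a, b = b))
  message("truncating extent pair (", la, " + ", lb,
          " tokens) to fit max_len")
  keep_a <- min(la, max(1L, ceiling(avail * la / (la + lb))))
  keep_b <- avail - keep_a
  if (keep_b > lb) { keep_a <- avail - lb; keep_b <- lb }
  if (keep_b < 0L) { keep_a <- avail; keep_b <- 0L }
  list(a = sort(sample(a, keep_a)),
       b = if (keep_b) sort(sample(b, keep_b)) else character(0))
}

finish_sequence <- function(ids, seg, max_len) {
  n_pad <- max_len - length(ids)
  last_seg <- if (length(seg)) seg[length(seg)] else 0L
  structure(list(ids = c(ids, rep(0L, n_pad)),
                 segment_ids = c(seg, rep(last_seg, n_pad)),
                 pad_mask = c(rep(FALSE, length(ids)), rep(TRUE, n_pad))),
            class = "token_sequence")
}

#' Encode an extent pair as an encoder input
#'
#' Layout is `[CLS] a1..an [SEP] b1..bm [PAD]...`; set elements are emitted
#' in sorted order (the encoding is permutation-invariant over the input
#' sets). Segment ids are 0 up to and including the separator and 1 for the
#' second extent; trailing padding repeats the last segment value so the
#' segment sequence is non-decreasing. Pairs longer than `max_len` are
#' reduced by seeded uniform subsampling of the extents.
#'
#' @param extent_a,extent_b identifier sets.
#' @param vocab an `fl_vocab` covering all identifiers.
#' @param max_len fixed output length.
#' @return object of class `token_sequence`: integer `ids`, integer
#'   `segment_ids`, logical `pad_mask` (TRUE at `[PAD]`).
#' @export
encode_pair <- function(extent_a, extent_b, vocab, max_len) {
  tr <- truncate_extents(unique(as.character(extent_a)),
                         unique(as.character(extent_b)), max_len - 2L)
  a <- sort(tr$a); b <- sort(tr$b)
  ids <- c(1L, tokens_of(a, vocab), 2L, tokens_of(b, vocab))
  seg <- c(rep(0L, length(a) + 2L), rep(1L, length(b)))
  finish_sequence(ids, seg, max_len)
}

#' Encode a single group as an encoder input
#'
#' Layout `[CLS] tokens [PAD]...` with all segment ids 0; elements emitted
#' in sorted order.
#'
#' @param ids identifier set.
#' @inheritParams encode_pair
#' @return a `token_sequence`.
#' @export
encode_group <- function(ids, vocab, max_len) {
  ids <- sort(unique(as.character(ids)))
  if (length(ids) > max_len - 1L) {
    message("truncating group of ", length(ids), " tokens to fit max_len")
    ids <- sort(sample(ids, max_len - 1L))
  }
  toks <- c(1L, tokens_of(ids, vocab))
  finish_sequence(toks, rep(0L, length(toks)), max_len)
}

#' Decode the non-special tokens of a sequence
#' @param sequence a `token_sequence`.
#' @param vocab the matching `fl_vocab`.
#' @return list with character vectors `segment_a` and `segment_b`.
#' @export
decode_sequence <- function(sequence, vocab) {
  inv <- stats::setNames(names(vocab$id_map), vocab$id_map)
  keep <- sequence$ids >= 4L
  list(segment_a = unname(inv[as.character(sequence$ids[keep &
                                             sequence$segment_ids == 0L])]),
       segment_b = unname(inv[as.character(sequence$ids[keep &
                                             sequence$segment_ids == 1L])]))
}

#' Default maximum sequence length for a concept corpus
#'
#' Twice the longest extent (or intent) plus three special positions, the
#' layout bound for an un-truncated pair.
#'
#' @param extents list of identifier sets.
#' @param cap optional hard upper bound (longer pairs are subsampled).
#' @return integer length.
#' @export
default_max_len <- function(extents, cap = Inf) {
  longest <- if (length(extents)) max(vapply(extents, length, integer(1))) else 1L
  as.integer(min(2L * longest + 3L, cap))
}
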