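# Shared fixtures: tiny hand-checkable contexts, seeded random contexts,
# and a session-level cache so expensive trained models are built once.

# {o1: a,b; o2: a} — two concepts forming a 2-chain
ctx_small <- function() {
  formal_context(c("o1", "o2"), c("a", "b"),
                 edges = rbind(c("o1", "a"), c("o1", "b"), c("o2", "a")))
}

# adds an attribute held by no object: extents form the 3-chain
# {} < {o1} < {o1, o2}
ctx_chain3 <- function() {
  formal_context(c("o1", "o2"), c("a", "b", "c"),
                 edges = rbind(c("o1", "a"), c("o1", "b"), c("o2", "a")))
}

# 2x2 identity: 4 concepts in a diamond
ctx_identity2 <- function() {
  formal_context(c("o1", "o2"), c("a", "b"),
                 edges = rbind(c("o1", "a"), c("o2", "b")))
}

random_context <- function(seed, n_obj, n_att, density) {
  set.seed(seed)
  formal_context(paste0("o", seq_len(n_obj)), paste0("a", seq_len(n_att)),
                 incidence = matrix(stats::runif(n_obj * n_att) < density,
                                    n_obj, n_att))
}

concept_keys <- function(concepts) {
  sort(vapply(concepts, function(cc)
    paste(paste(cc$extent, collapse = ","), "|",
          paste(cc$intent, collapse = ",")), character(1)))
}

# Independent brute-force transitive reduction: (i, j) is a Hasse edge iff
# i < j and no k lies strictly between (explicit no-intermediate test per
# ordered pair; no matrix products).
brute_force_hasse <- function(ord) {
  pairs <- which(ord, arr.ind = TRUE)
  edges <- NULL
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!any(ord[i, ] & ord[, j])) edges <- rbind(edges, c(i, j))
  }
  edges
}

# oracle: concordance-counting AUC (pairwise loop, no ranks)
bf_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# oracle: AUPR by explicit threshold walk over unique scores
bf_aupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  n_pos <- sum(labels == 1)
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# session-level cache for trained models shared across test files
fl_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fl_test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = fl_test_cache)
  }
  get(key, envir = fl_test_cache, inherits = FALSE)
}

tiny_cfg <- function(vocab, max_len = 7L, dropout = 0) {
  encoder_config(d_model = 8L, n_heads = 2L, n_layers = 2L, d_ffn = 12L,
                 max_len = max_len, vocab_size = vocab$size, d_hidden = 5L,
                 dropout = dropout)
}
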