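# Position-embedding-free transformer encoder, task heads, and losses.
#
# The encoder is the standard post-layer-norm BERT block (multi-head
# self-attention + GELU feed-forward, residual connections, layer norm)
# with one deliberate architectural change: the input embedding is the sum
# of token and segment embeddings only — there is no position term, because
# extents and intents are sets, not sequences. Removing it makes the
# [CLS] representation invariant under permutations of the input tokens,
# which the tests assert directly.
#
# Everything is plain R matrix code (double precision, BLAS-backed); the
# backward pass lives in model_grad.R and is verified against numerical
# differentiation in the test suite.

LN_EPS <- 1e-5

#' Encoder configuration
#'
#' Defaults follow the full-scale setting (embedding width 768, 12 heads,
#' 6 encoder layers, feed-forward width 3072, task-head hidden width 512);
#' [test_encoder_config()] gives the small preset used for fast CPU runs.
#'
#' @param d_model embedding width; must be divisible by `n_heads`.
#' @param n_heads attention heads.
#' @param n_layers stacked encoder blocks.
#' @param d_ffn feed-forward inner width.
#' @param max_len fixed input sequence length.
#' @param vocab_size token count including the 4 specials.
#' @param d_hidden hidden width of the fine-tuning output heads.
#' @param dropout dropout rate (applied in training only).
#' @param tie_mtp tie the masked-token output projection to the token
#'   embedding matrix.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(d_model = 768L, n_heads = 12L, n_layers = 6L,
                           d_ffn = 3072L, max_len, vocab_size,
                           d_hidden = 512L, dropout = 0.1, tie_mtp = TRUE) {
  fl_assert(d_model %% n_heads == 0, "d_model must be divisible by n_heads")
  fl_assert(all(c(d_model, n_heads, n_layers, d_ffn, max_len, vocab_size,
                  d_hidden) >= 1), "all dimensions must be positive")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), d_ffn = as.integer(d_ffn),
                 max_len = as.integer(max_len),
                 vocab_size = as.integer(vocab_size),
                 d_hidden = as.integer(d_hidden), dropout = dropout,
                 tie_mtp = isTRUE(tie_mtp)),
            class = "encoder_config")
}

#' @rdname encoder_config
#' @export
test_encoder_config <- function(max_len, vocab_size, d_hidden = 32L,
                                dropout = 0.1, tie_mtp = TRUE) {
  encoder_config(d_model = 32L, n_heads = 4L, n_layers = 2L, d_ffn = 64L,
                 max_len = max_len, vocab_size = vocab_size,
                 d_hidden = d_hidden, dropout = dropout, tie_mtp = tie_mtp)
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), sd = sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

tn_mat <- function(nr, nc) matrix(trunc_normal(nr * nc), nr, nc)

pname <- function(l, n) paste0("l", l, "_", n)

#' Initialize encoder and head parameters
#'
#' Weights are truncated-normal (sd 0.02, clipped at 2 sd), layer-norm
#' gains 1, biases 0; draws are seeded. Returns a flat named list of
#' matrices/vectors covering the encoder, the masked-token and
#' neighboring-concepts pre-training heads, and the object-object and
#' object-attribute fine-tuning heads.
#'
#' @param config an [encoder_config()].
#' @param seed RNG seed.
#' @return named list of parameter arrays.
#' @export
init_params <- function(config, seed = 1L) {
  d <- config$d_model; V <- config$vocab_size
  with_seed(seed, {
    p <- list(tok_emb = tn_mat(V, d), seg_emb = tn_mat(2L, d))
    for (l in seq_len(config$n_layers)) {
      p[[pname(l, "Wq")]] <- tn_mat(d, d); p[[pname(l, "bq")]] <- numeric(d)
      p[[pname(l, "Wk")]] <- tn_mat(d, d); p[[pname(l, "bk")]] <- numeric(d)
      p[[pname(l, "Wv")]] <- tn_mat(d, d); p[[pname(l, "bv")]] <- numeric(d)
      p[[pname(l, "Wo")]] <- tn_mat(d, d); p[[pname(l, "bo")]] <- numeric(d)
      p[[pname(l, "ln1_g")]] <- rep(1, d); p[[pname(l, "ln1_b")]] <- numeric(d)
      p[[pname(l, "W1")]] <- tn_mat(d, config$d_ffn)
      p[[pname(l, "b1")]] <- numeric(config$d_ffn)
      p[[pname(l, "W2")]] <- tn_mat(config$d_ffn, d)
      p[[pname(l, "b2")]] <- numeric(d)
      p[[pname(l, "ln2_g")]] <- rep(1, d); p[[pname(l, "ln2_b")]] <- numeric(d)
    }
    p$mtp_b <- numeric(V)
    if (!config$tie_mtp) p$mtp_W <- tn_mat(d, V)
    p$ncp_w <- tn_mat(d, 1L); p$ncp_b <- 0
    p$oo_Wcls <- tn_mat(d, config$d_hidden)
    p$oo_Wout <- tn_mat(config$d_hidden, 1L)
    p$oa_Wcls <- tn_mat(2L * d, config$d_hidden)
    p$oa_Wout <- tn_mat(config$d_hidden, 1L)
    p
  })
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  istd <- 1 / sqrt(rowMeans(Xc * Xc) + LN_EPS)
  xhat <- Xc * istd
  list(out = add_bias(xhat * matrix(g, nrow(X), length(g), byrow = TRUE), b),
       xhat = xhat, istd = istd)
}

# Stack a list of token_sequences (or masked_instances) into batch matrices.
build_batch <- function(sequences) {
  ids <- do.call(rbind, lapply(sequences, function(s)
    if (!is.null(s$input_ids)) s$input_ids else s$ids))
  seg <- do.call(rbind, lapply(sequences, `[[`, "segment_ids"))
  list(ids = ids, seg = seg, pad = ids == 0L)
}

#' Input embedding of a token sequence (no position term)
#'
#' Each position's vector is the token embedding plus the segment embedding;
#' identical tokens in identical segments embed identically regardless of
#' position.
#'
#' @param sequence a `token_sequence` or `masked_instance`.
#' @param params parameter list from [init_params()].
#' @return numeric matrix, one row per position.
#' @export
embed_tokens <- function(sequence, params) {
  ids <- if (!is.null(sequence$input_ids)) sequence$input_ids else sequence$ids
  if (any(ids + 1L > nrow(params$tok_emb))) fl_stop("token id out of range")
  params$tok_emb[ids + 1L, , drop = FALSE] +
    params$seg_emb[sequence$segment_ids + 1L, , drop = FALSE]
}

# Core batched forward pass. ids/seg: B x L integer matrices (0-based ids);
# pad: B x L logical. Returns flat (B*L) x d hidden states (item-major),
# cls rows, and optionally the full cache for the backward pass.
encoder_forward <- function(params, cfg, ids, seg, pad, train = FALSE,
                            keep = FALSE) {
  B <- nrow(ids); L <- ncol(ids); d <- cfg$d_model; nh <- cfg$n_heads
  N <- B * L
  ids_flat <- as.vector(t(ids)); seg_flat <- as.vector(t(seg))
  pad_flat <- as.vector(t(pad))
  if (any(ids_flat + 1L > nrow(params$tok_emb))) fl_stop("token id out of range")
  X <- params$tok_emb[ids_flat + 1L, , drop = FALSE] +
    params$seg_emb[seg_flat + 1L, , drop = FALSE]
  use_drop <- train && cfg$dropout > 0
  caches <- if (keep) vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    X_in <- X
    Qc <- add_bias(X %*% params[[pname(l, "Wq")]], params[[pname(l, "bq")]])
    Kc <- add_bias(X %*% params[[pname(l, "Wk")]], params[[pname(l, "bk")]])
    Vc <- add_bias(X %*% params[[pname(l, "Wv")]], params[[pname(l, "bv")]])
    at <- .attn_forward(Qc, Kc, Vc, pad_flat, B, L, nh)
    O <- at$O
    A_store <- if (keep) at$A
    P <- add_bias(O %*% params[[pname(l, "Wo")]], params[[pname(l, "bo")]])
    drop1 <- NULL
    if (use_drop) {
      drop1 <- matrix((stats::runif(N * d) >= cfg$dropout) /
                        (1 - cfg$dropout), N, d)
      P <- P * drop1
    }
    R1 <- X_in + P
    ln1 <- ln_forward(R1, params[[pname(l, "ln1_g")]],
                      params[[pname(l, "ln1_b")]])
    X1 <- ln1$out
    F1 <- add_bias(X1 %*% params[[pname(l, "W1")]], params[[pname(l, "b1")]])
    G <- gelu(F1)
    F2 <- add_bias(G %*% params[[pname(l, "W2")]], params[[pname(l, "b2")]])
    drop2 <- NULL
    if (use_drop) {
      drop2 <- matrix((stats::runif(N * d) >= cfg$dropout) /
                        (1 - cfg$dropout), N, d)
      F2 <- F2 * drop2
    }
    R2 <- X1 + F2
    ln2 <- ln_forward(R2, params[[pname(l, "ln2_g")]],
                      params[[pname(l, "ln2_b")]])
    X <- ln2$out
    if (keep) {
      caches[[l]] <- list(X_in = X_in, Qc = Qc, Kc = Kc, Vc = Vc,
                          A = A_store, O = O, drop1 = drop1,
                          xhat1 = ln1$xhat, istd1 = ln1$istd, X1 = X1,
                          F1 = F1, G = G, drop2 = drop2,
                          xhat2 = ln2$xhat, istd2 = ln2$istd)
    }
  }
  cls_rows <- (seq_len(B) - 1L) * L + 1L
  list(hidden = X, cls = X[cls_rows, , drop = FALSE],
       cache = if (keep) list(layers = caches, ids_flat = ids_flat,
                              seg_flat = seg_flat, pad_flat = pad_flat,
                              B = B, L = L))
}

#' Encode token sequences
#'
#' Runs the encoder stack over one or more sequences and returns the
#' per-position hidden states and the final-layer `[CLS]` vector of each.
#' Deterministic in evaluation mode (`train = FALSE`, no dropout).
#'
#' @param params parameter list.
#' @param config an [encoder_config()].
#' @param sequences a single `token_sequence` or a list of them.
#' @param train apply dropout from the ambient RNG stream.
#' @return list with `hidden` (list of per-position matrices) and
#'   `cls` (matrix, one row per sequence).
#' @export
encode_sequences <- function(params, config, sequences, train = FALSE) {
  if (inherits(sequences, "token_sequence") ||
      inherits(sequences, "masked_instance")) sequences <- list(sequences)
  bt <- build_batch(sequences)
  out <- encoder_forward(params, config, bt$ids, bt$seg, bt$pad, train = train)
  L <- ncol(bt$ids)
  hidden <- lapply(seq_along(sequences), function(b)
    out$hidden[((b - 1L) * L + 1L):(b * L), , drop = FALSE])
  list(hidden = hidden, cls = out$cls)
}

#' Masked-token prediction logits
#'
#' One row of vocabulary scores per masked position. The projection is tied
#' to the token embedding matrix when the configuration says so.
#'
#' @param hidden per-position hidden-state matrix of one sequence.
#' @param masked_positions 1-based positions.
#' @param params parameter list.
#' @param config an [encoder_config()].
#' @return matrix `length(masked_positions) x vocab_size`.
#' @export
mtp_logits <- function(hidden, masked_positions, params, config) {
  if (any(masked_positions < 1L | masked_positions > nrow(hidden))) {
    fl_stop("masked position out of range")
  }
  H <- hidden[masked_positions, , drop = FALSE]
  W <- if (config$tie_mtp) t(params$tok_emb) else params$mtp_W
  add_bias(H %*% W, params$mtp_b)
}

#' Neighboring-concepts prediction score
#'
#' Sigmoid of a linear head on the `[CLS]` state: the probability that the
#' encoded extent pair belongs to neighboring concepts.
#'
#' @param cls_state numeric vector or matrix (rows = samples).
#' @param params parameter list (uses `ncp_w`, `ncp_b`).
#' @return numeric vector of probabilities in (0, 1).
#' @export
ncp_score <- function(cls_state, params) {
  cls_state <- rbind(cls_state)
  as.vector(sigmoid(cls_state %*% params$ncp_w + params$ncp_b))
}

#' Object-object head
#'
#' Exactly `sigmoid(relu(h %*% W_cls) %*% W_out)` on the `[CLS]`
#' representation `h`; no bias terms.
#'
#' @param cls_state numeric vector or matrix (rows = samples).
#' @param head list with `W_cls` (`d_model x d_hidden`) and `W_out`
#'   (`d_hidden x 1`).
#' @return numeric vector of probabilities in (0, 1).
#' @export
oo_score <- function(cls_state, head) {
  h <- rbind(cls_state)
  fl_assert(ncol(h) == nrow(head$W_cls), "cls_state width must match W_cls")
  z <- h %*% head$W_cls
  as.vector(sigmoid(pmax(z, 0) %*% head$W_out))
}

#' Object-attribute head
#'
#' The object-tower and attribute-tower `[CLS]` states are concatenated
#' (object first) and passed through the same relu-sigmoid head with a
#' `2*d_model x d_hidden` first layer.
#'
#' @param cls_state_object,cls_state_attribute vectors or matrices of
#'   matching row count.
#' @param head list with `W_cls` (`2*d_model x d_hidden`) and `W_out`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
oa_score <- function(cls_state_object, cls_state_attribute, head) {
  h <- cbind(rbind(cls_state_object), rbind(cls_state_attribute))
  oo_score(h, head)
}

softmax_rows <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - mx)
  E / rowSums(E)
}

# Numerically stable binary cross-entropy from logits.
bce_from_logits <- function(s, y) {
  mean(pmax(s, 0) - s * y + log1p(exp(-abs(s))))
}

#' Joint pre-training loss
#'
#' Mean cross-entropy over the vocabulary at masked positions plus binary
#' cross-entropy of the neighboring-concepts score; the two task losses are
#' summed. With no masked positions the masked-token term is 0 (warned).
#'
#' @param logits matrix of masked-position vocabulary scores (rows =
#'   positions), or `NULL`/zero-row when nothing is masked.
#' @param target_ids 0-based original token ids at the masked positions.
#' @param ncp_prob neighboring-concepts probabilities in (0, 1).
#' @param ncp_label binary labels.
#' @return scalar loss (non-negative).
#' @export
pretrain_loss <- function(logits, target_ids, ncp_prob, ncp_label) {
  if (is.null(logits) || nrow(rbind(logits)) == 0L) {
    warning("no masked positions: masked-token loss term is 0", call. = FALSE)
    mtp <- 0
  } else {
    logits <- rbind(logits)
    P <- softmax_rows(logits)
    picked <- P[cbind(seq_len(nrow(P)), as.integer(target_ids) + 1L)]
    mtp <- mean(-log(pmax(picked, 1e-300)))
  }
  p <- pmin(pmax(ncp_prob, 1e-12), 1 - 1e-12)
  ncp <- mean(-(ncp_label * log(p) + (1 - ncp_label) * log(1 - p)))
  mtp + ncp
}
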