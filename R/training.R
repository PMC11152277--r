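# Pre-training and fine-tuning loops: seeded, fixed-epoch, Adam-optimized,
# with the two ablation switches (partial NCP pre-training corpus and
# skipping pre-training entirely).

#' Training configuration
#'
#' @param batch_size samples per optimization step (default 24).
#' @param lr Adam learning rate.
#' @param epochs fixed epoch count (no early stopping).
#' @param seed RNG seed; two runs with identical config and data are
#'   identical.
#' @param weight_decay decoupled weight decay applied to weight matrices
#'   and embeddings (0 disables it).
#' @param pretrain_fraction fraction of NCP examples used for pre-training;
#'   the remainder is held out and scored after training (first ablation).
#' @param skip_pretrain fine-tune from random weights instead of a
#'   checkpoint (second ablation).
#' @param swa_start when set, fine-tuning averages the weights of all
#'   epochs from this one on (stochastic weight averaging) and returns the
#'   averaged model; reduces run-to-run variance on small sample sets.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 24L, lr = 1e-3, epochs = 20L,
                         seed = 1L, weight_decay = 0,
                         pretrain_fraction = 1.0,
                         skip_pretrain = FALSE, swa_start = NULL) {
  fl_assert(batch_size >= 1, "batch_size must be >= 1")
  fl_assert(pretrain_fraction > 0 && pretrain_fraction <= 1,
            "pretrain_fraction must be in (0, 1]")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 weight_decay = weight_decay,
                 pretrain_fraction = pretrain_fraction,
                 skip_pretrain = isTRUE(skip_pretrain),
                 swa_start = if (!is.null(swa_start)) as.integer(swa_start)),
            class = "train_config")
}

batch_indices <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

swa_update <- function(avg, params, n_avg) {
  if (is.null(avg)) return(params)
  for (nm in names(params)) {
    avg[[nm]] <- avg[[nm]] + (params[[nm]] - avg[[nm]]) / n_avg
  }
  avg
}

#' Pre-train an encoder on masked-token and neighboring-concepts tasks
#'
#' Each batch encodes a set of extent pairs, corrupts them with
#' [mask_tokens()], and minimizes the joint loss: masked-token
#' cross-entropy plus neighboring-concepts binary cross-entropy — the two
#' tasks are trained simultaneously on the same batches. When
#' `pretrain_fraction < 1`, a seeded split holds out the remaining examples
#' and reports their F1 / AUC / AUPR after training.
#'
#' @param examples NCP examples from [make_ncp_examples()] (the balanced
#'   positive/negative pair corpus).
#' @param vocab an `fl_vocab` covering every identifier in the corpus.
#' @param encoder_config an [encoder_config()].
#' @param config a [train_config()].
#' @param sampling a [sampling_config()] supplying `mask_rate`/`max_masked`.
#' @return object of class `fl_checkpoint`: `params`, `config`, `vocab`,
#'   per-epoch `history`, and `heldout` metrics when a split was made.
#' @export
pretrain <- function(examples, vocab, encoder_config, config,
                     sampling = sampling_config()) {
  if (!length(examples)) fl_stop("empty pre-training corpus")
  cfg <- encoder_config
  with_seed(config$seed, {
    n <- length(examples)
    heldout_ex <- list()
    if (config$pretrain_fraction < 1) {
      n_hold <- round((1 - config$pretrain_fraction) * n)
      if (n_hold > 0) {
        hold <- sample.int(n, n_hold)
        heldout_ex <- examples[hold]
        examples <- examples[-hold]
      }
    }
    sequences <- lapply(examples, function(e)
      encode_pair(e$extent_a, e$extent_b, vocab, cfg$max_len))
    labels <- vapply(examples, `[[`, integer(1), "label")
    params <- init_params(cfg, seed = sample.int(2^30, 1))
    state <- adam_init()
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      losses <- c()
      for (idx in batch_indices(length(sequences), config$batch_size)) {
        instances <- lapply(sequences[idx], mask_tokens, config = sampling,
                            vocabulary = vocab)
        st <- pretrain_step(params, cfg, instances, labels[idx], train = TRUE)
        upd <- adam_step(params, st$grads, state, config$lr,
                         weight_decay = config$weight_decay)
        params <- upd$params; state <- upd$state
        losses <- c(losses, st$loss)
      }
      history[ep] <- mean(losses)
    }
    heldout <- NULL
    if (length(heldout_ex)) {
      hseq <- lapply(heldout_ex, function(e)
        encode_pair(e$extent_a, e$extent_b, vocab, cfg$max_len))
      hlab <- vapply(heldout_ex, `[[`, integer(1), "label")
      scores <- ncp_score(encode_sequences(params, cfg, hseq)$cls, params)
      heldout <- c(evaluate_scores(scores, hlab),
                   list(scores = scores, labels = hlab))
    }
    structure(list(params = params, config = cfg, vocab = vocab,
                   history = history, heldout = heldout),
              class = "fl_checkpoint")
  })
}

ft_init <- function(checkpoint, config, encoder_config, vocab) {
  if (config$skip_pretrain || is.null(checkpoint)) {
    fl_assert(!is.null(encoder_config) && !is.null(vocab),
              "encoder_config and vocab are required without a checkpoint")
    list(params = init_params(encoder_config, seed = sample.int(2^30, 1)),
         cfg = encoder_config, vocab = vocab)
  } else {
    fl_assert(inherits(checkpoint, "fl_checkpoint"), "not a checkpoint")
    list(params = checkpoint$params, cfg = checkpoint$config,
         vocab = checkpoint$vocab)
  }
}

check_vocab_covers <- function(vocab, ids) {
  missing <- setdiff(ids, names(vocab$id_map))
  if (length(missing)) {
    fl_stop("vocabulary does not cover identifier: ", missing[1])
  }
}

#' Fine-tune for object-object link prediction
#'
#' Optimizes binary cross-entropy of the object-object head on encoded
#' groups. Encoder weights start from the checkpoint (or from seeded random
#' initialization when `config$skip_pretrain` or no checkpoint is given)
#' and are updated together with the head.
#'
#' @param checkpoint an `fl_checkpoint` from [pretrain()], or `NULL`.
#' @param samples data.frame from [generate_oo_train()].
#' @param config a [train_config()].
#' @param encoder_config,vocab required when training from scratch.
#' @return object of class `fl_oo_model`.
#' @export
finetune_oo <- function(checkpoint, samples, config,
                        encoder_config = NULL, vocab = NULL) {
  with_seed(substream_seed(config$seed, 21L), {
    ini <- ft_init(checkpoint, config, encoder_config, vocab)
    check_vocab_covers(ini$vocab, unique(unlist(samples$objects)))
    max_group <- max(samples$size)
    L <- min(ini$cfg$max_len, max_group + 1L)
    sequences <- lapply(samples$objects, encode_group, vocab = ini$vocab,
                        max_len = L)
    labels <- samples$label
    params <- ini$params
    state <- adam_init()
    history <- numeric(config$epochs)
    swa <- NULL; n_avg <- 0L
    for (ep in seq_len(config$epochs)) {
      losses <- c()
      for (idx in batch_indices(length(sequences), config$batch_size)) {
        st <- oo_step(params, ini$cfg, sequences[idx], labels[idx],
                      train = TRUE)
        upd <- adam_step(params, st$grads, state, config$lr,
                         weight_decay = config$weight_decay)
        params <- upd$params; state <- upd$state
        losses <- c(losses, st$loss)
      }
      history[ep] <- mean(losses)
      if (!is.null(config$swa_start) && ep >= config$swa_start) {
        n_avg <- n_avg + 1L
        swa <- swa_update(swa, params, n_avg)
      }
    }
    if (!is.null(swa)) params <- swa
    structure(list(params = params, config = ini$cfg, vocab = ini$vocab,
                   history = history),
              class = "fl_oo_model")
  })
}

#' Score object groups with a fine-tuned object-object model
#'
#' @param model an `fl_oo_model`.
#' @param groups list of object-id vectors, or a data.frame with an
#'   `objects` list-column.
#' @return numeric vector of probabilities.
#' @export
predict_oo <- function(model, groups) {
  if (is.data.frame(groups)) groups <- groups$objects
  check_vocab_covers(model$vocab, unique(unlist(groups)))
  L <- min(model$config$max_len,
           max(vapply(groups, length, integer(1))) + 1L)
  sequences <- lapply(groups, encode_group, vocab = model$vocab, max_len = L)
  cls <- encode_sequences(model$params, model$config, sequences)$cls
  oo_score(cls, list(W_cls = model$params$oo_Wcls,
                     W_out = model$params$oo_Wout))
}

#' Fine-tune the two-tower object-attribute model
#'
#' The object token feeds the (pre-trained) object tower and the attribute
#' token the attribute tower; their `[CLS]` states are concatenated into the
#' object-attribute head. Both towers and the head are updated jointly.
#'
#' @param object_checkpoint,attribute_checkpoint `fl_checkpoint`s from
#'   [pretrain()], or `NULL` with `config$skip_pretrain`.
#' @param samples data.frame from [generate_oa_samples()].
#' @param config a [train_config()].
#' @param object_encoder_config,object_vocab,attribute_encoder_config,attribute_vocab
#'   required when training from scratch.
#' @param resample_negatives_from optional `bipartite_network` (the input
#'   network C): when given, the negative half of the training set is
#'   redrawn from C's non-edges every epoch (seeded). The model then sees
#'   the whole non-edge manifold over training instead of one fixed
#'   negative sample, which curbs memorization on small networks; class
#'   balance within every epoch is unchanged.
#' @return object of class `fl_oa_model`.
#' @export
finetune_oa <- function(object_checkpoint, attribute_checkpoint, samples,
                        config,
                        object_encoder_config = NULL, object_vocab = NULL,
                        attribute_encoder_config = NULL,
                        attribute_vocab = NULL,
                        resample_negatives_from = NULL) {
  with_seed(substream_seed(config$seed, 22L), {
    io <- ft_init(object_checkpoint, config, object_encoder_config,
                  object_vocab)
    ia <- ft_init(attribute_checkpoint, config, attribute_encoder_config,
                  attribute_vocab)
    check_vocab_covers(io$vocab, unique(samples$object))
    check_vocab_covers(ia$vocab, unique(samples$attribute))
    enc_o <- lapply(stats::setNames(nm = names(io$vocab$id_map)),
                    encode_group, vocab = io$vocab, max_len = 2L)
    enc_a <- lapply(stats::setNames(nm = names(ia$vocab$id_map)),
                    encode_group, vocab = ia$vocab, max_len = 2L)
    pool <- NULL
    if (!is.null(resample_negatives_from)) {
      non <- which(!resample_negatives_from$incidence, arr.ind = TRUE)
      pool <- data.frame(
        object = resample_negatives_from$objects[non[, 1]],
        attribute = resample_negatives_from$attributes[non[, 2]])
      check_vocab_covers(io$vocab, unique(pool$object))
      check_vocab_covers(ia$vocab, unique(pool$attribute))
      samples <- samples[samples$label == 1L, ]
    }
    cur <- samples
    seq_o <- enc_o[cur$object]
    seq_a <- enc_a[cur$attribute]
    labels <- cur$label
    p_o <- io$params; p_a <- ia$params
    st_o <- adam_init(); st_a <- adam_init()
    history <- numeric(config$epochs)
    swa_o <- NULL; swa_a <- NULL; n_avg <- 0L
    for (ep in seq_len(config$epochs)) {
      if (!is.null(pool)) {
        neg <- pool[sample.int(nrow(pool), min(nrow(samples), nrow(pool))), ]
        cur <- rbind(samples[, c("object", "attribute", "label")],
                     cbind(neg, label = 0L))
        seq_o <- enc_o[cur$object]
        seq_a <- enc_a[cur$attribute]
        labels <- cur$label
      }
      losses <- c()
      for (idx in batch_indices(length(seq_o), config$batch_size)) {
        st <- oa_step(p_o, p_a, io$cfg, ia$cfg, seq_o[idx], seq_a[idx],
                      labels[idx], train = TRUE)
        u1 <- adam_step(p_o, st$grads_obj, st_o, config$lr,
                        weight_decay = config$weight_decay)
        p_o <- u1$params; st_o <- u1$state
        u2 <- adam_step(p_a, st$grads_att, st_a, config$lr,
                        weight_decay = config$weight_decay)
        p_a <- u2$params; st_a <- u2$state
        losses <- c(losses, st$loss)
      }
      history[ep] <- mean(losses)
      if (!is.null(config$swa_start) && ep >= config$swa_start) {
        n_avg <- n_avg + 1L
        swa_o <- swa_update(swa_o, p_o, n_avg)
        swa_a <- swa_update(swa_a, p_a, n_avg)
      }
    }
    if (!is.null(swa_o)) { p_o <- swa_o; p_a <- swa_a }
    structure(list(object = list(params = p_o, config = io$cfg,
                                 vocab = io$vocab),
                   attribute = list(params = p_a, config = ia$cfg,
                                    vocab = ia$vocab),
                   history = history),
              class = "fl_oa_model")
  })
}

#' Score object-attribute pairs with a fine-tuned two-tower model
#'
#' @param model an `fl_oa_model`.
#' @param pairs data.frame with columns `object` and `attribute`.
#' @return numeric vector of probabilities.
#' @export
predict_oa <- function(model, pairs) {
  check_vocab_covers(model$object$vocab, unique(pairs$object))
  check_vocab_covers(model$attribute$vocab, unique(pairs$attribute))
  seq_o <- lapply(pairs$object, encode_group, vocab = model$object$vocab,
                  max_len = 2L)
  seq_a <- lapply(pairs$attribute, encode_group,
                  vocab = model$attribute$vocab, max_len = 2L)
  cls_o <- encode_sequences(model$object$params, model$object$config,
                            seq_o)$cls
  cls_a <- encode_sequences(model$attribute$params, model$attribute$config,
                            seq_a)$cls
  oa_score(cls_o, cls_a, list(W_cls = model$object$params$oa_Wcls,
                              W_out = model$object$params$oa_Wout))
}

#' Save / load a checkpoint or fine-tuned model
#'
#' Checkpoints carry the encoder configuration, vocabulary and all weight
#' tensors; loading verifies the class.
#'
#' @param object an `fl_checkpoint`, `fl_oo_model` or `fl_oa_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(object, path) {
  fl_assert(inherits(object, c("fl_checkpoint", "fl_oo_model", "fl_oa_model")),
            "not a checkpoint or model")
  saveRDS(object, path)
  invisible(NULL)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  fl_assert(inherits(obj, c("fl_checkpoint", "fl_oo_model", "fl_oa_model")),
            "file does not contain a checkpoint or model")
  obj
}
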