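# Standard planted-bi-clique benchmark protocols. These wrap the full
# pipeline — network generation, concept extraction, sample generation,
# pre-training, fine-tuning, evaluation — at the problem sizes the package
# uses for its own validation: a 50 x 40 network with 15 planted
# bi-cliques (side 3-6), 1% noise, test-preset encoders.

#' The standard planted benchmark network
#'
#' @param seed generator seed for [planted_config()] (default 7, the fixed
#'   benchmark instance).
#' @return a `bipartite_network`.
#' @export
standard_network <- function(seed = 7L) {
  generate_planted_network(planted_config(seed = seed))
}

#' Swap the two sides of a network
#'
#' The dual network presents attributes as objects; pre-training the
#' attribute model runs the object pipeline on the dual (its extents are
#' the original intents).
#'
#' @param network a `bipartite_network`.
#' @return the transposed `bipartite_network`.
#' @export
dual_network <- function(network) {
  bipartite_network(network$attributes, network$objects,
                    incidence = t(network$incidence))
}

#' Pre-train an encoder on one side of a network
#'
#' Runs concept extraction, lattice construction, balanced NCP example
#' generation, and [pretrain()] with the test-preset encoder. The sequence
#' length is capped (long extents are subsampled at encoding time) to keep
#' single-CPU runs fast.
#'
#' @param network a `bipartite_network`.
#' @param train_seed seed for sampling, initialization and batching.
#' @param side `"object"` (extents) or `"attribute"` (intents, via the dual
#'   network).
#' @param epochs,lr training schedule (defaults: 25 epochs, Adam 3e-3).
#' @param pretrain_fraction NCP corpus fraction (< 1 holds out the rest).
#' @param max_len_cap sequence-length cap.
#' @return an `fl_checkpoint`.
#' @export
pretrain_on_network <- function(network, train_seed,
                                side = c("object", "attribute"),
                                epochs = 25L, lr = 3e-3,
                                pretrain_fraction = 1.0,
                                max_len_cap = 32L,
                                max_examples = Inf) {
  side <- match.arg(side)
  net <- if (side == "attribute") dual_network(network) else network
  lat <- build_lattice(extract_concepts(net))
  sc <- sampling_config(seed = train_seed)
  ex <- make_ncp_examples(lat, sc)
  if (length(ex) > max_examples) {
    ex <- with_seed(substream_seed(train_seed, 51L),
                    ex[sample.int(length(ex), max_examples)])
  }
  vocab <- build_vocab(net$objects)
  max_len <- default_max_len(lapply(lat$concepts, `[[`, "extent"),
                             cap = max_len_cap)
  cfg <- test_encoder_config(max_len = max_len, vocab_size = vocab$size)
  tc <- train_config(batch_size = 24L, lr = lr, epochs = epochs,
                     seed = train_seed,
                     pretrain_fraction = pretrain_fraction)
  pretrain(ex, vocab, cfg, tc, sampling = sc)
}

#' End-to-end object-attribute benchmark
#'
#' On the standard planted network: removes 10% of edges uniformly,
#' pre-trains both towers (unless `skip_pretrain`), fine-tunes the
#' two-tower model on the input network's edges, and evaluates on the
#' removed edges against an equal number of target non-edges. Also reports
#' the common-neighbors (3-path) baseline AUC on the same test pairs.
#'
#' Fine-tuning redraws the negative half of the training set from the
#' input network's non-edges every epoch and averages the weights of the
#' last 30% of epochs: on a network this small a single fixed negative
#' sample is memorized within a few epochs, while resampling pushes the
#' whole non-edge manifold down (as matrix-completion methods do) and the
#' weight average suppresses run-to-run optimization noise. Dropout is
#' disabled during fine-tuning.
#'
#' @param seed run seed (controls the split, sampling and training).
#' @param network benchmark network (default [standard_network()]).
#' @param pretrain_epochs,finetune_epochs,lr schedule.
#' @param skip_pretrain fine-tune from random weights.
#' @return list: `metrics` (model test metrics), `cn_auc`, `model`,
#'   `n_test`.
#' @export
benchmark_oa <- function(seed, network = standard_network(),
                         pretrain_epochs = 10L, finetune_epochs = 300L,
                         lr = 3e-3, skip_pretrain = FALSE) {
  split <- random_edge_removal_split(network, 0.1,
                                     seed = substream_seed(seed, 31L))
  input <- split$input_network
  train_samples <- generate_oa_samples(input, seed = substream_seed(seed, 32L))
  test_samples <- generate_oa_samples(split$target_network, input,
                                      seed = substream_seed(seed, 33L))
  tc <- train_config(batch_size = 24L, lr = 1e-3, epochs = finetune_epochs,
                     seed = seed, skip_pretrain = skip_pretrain,
                     swa_start = ceiling(0.7 * finetune_epochs))
  if (skip_pretrain) {
    vo <- build_vocab(input$objects)
    va <- build_vocab(input$attributes)
    model <- finetune_oa(NULL, NULL, train_samples, tc,
                         object_encoder_config =
                           test_encoder_config(max_len = 2L,
                                               vocab_size = vo$size,
                                               dropout = 0),
                         object_vocab = vo,
                         attribute_encoder_config =
                           test_encoder_config(max_len = 2L,
                                               vocab_size = va$size,
                                               dropout = 0),
                         attribute_vocab = va,
                         resample_negatives_from = input)
  } else {
    ck_o <- pretrain_on_network(input, substream_seed(seed, 34L),
                                side = "object", epochs = pretrain_epochs,
                                lr = lr)
    ck_a <- pretrain_on_network(input, substream_seed(seed, 35L),
                                side = "attribute", epochs = pretrain_epochs,
                                lr = lr)
    ck_o$config$dropout <- 0
    ck_a$config$dropout <- 0
    model <- finetune_oa(ck_o, ck_a, train_samples, tc,
                         resample_negatives_from = input)
  }
  scores <- predict_oa(model, test_samples)
  cn <- vapply(seq_len(nrow(test_samples)), function(i)
    common_neighbors_oa(input, test_samples$object[i],
                        test_samples$attribute[i]), numeric(1))
  list(metrics = evaluate_scores(scores, test_samples$label),
       cn_auc = roc_auc(cn, test_samples$label),
       model = model, n_test = nrow(test_samples))
}

#' Generator configuration for the object-object growth benchmark
#'
#' Larger than the edge-recovery instance on the object side: with few
#' objects the group space is so small that the balanced negative sample
#' covers it entirely, and every future link would also be a training
#' negative — making the growth task degenerate. 120 objects keep the
#' negative sample a small fraction of the group space, as in real
#' networks.
#'
#' @param seed generator seed.
#' @return a [planted_config()].
#' @export
oo_benchmark_config <- function(seed = 7L) {
  planted_config(n_objects = 120L, n_attributes = 60L, n_bicliques = 30L,
                 noise_edge_rate = 0.005,
                 extra_bicliques_in_target = 6L, seed = seed)
}

#' End-to-end object-object benchmark
#'
#' On the planted growth split ([oo_benchmark_config()]): fine-tunes the
#' object model on balanced training groups from the input network and
#' evaluates on groups newly linked in the target. Training groups and the
#' NCP pre-training corpus are capped by seeded subsampling to keep
#' single-CPU runs short; fine-tuning runs few epochs so pre-trained
#' structure survives.
#'
#' @param seed run seed.
#' @param config benchmark generator configuration.
#' @param pretrain_epochs,finetune_epochs,lr schedule.
#' @param max_train,max_pretrain corpus caps (seeded subsampling).
#' @param skip_pretrain fine-tune from random weights (ablation arm).
#' @return list: `metrics`, `model`, `n_train`, `n_test`.
#' @export
benchmark_oo <- function(seed, config = oo_benchmark_config(),
                         pretrain_epochs = 10L, finetune_epochs = 4L,
                         lr = 3e-3, max_train = 4000L,
                         max_pretrain = 1200L, skip_pretrain = FALSE) {
  split <- generate_growth_pair(config)
  input <- split$input_network
  sc <- sampling_config(eps_p = 3L, seed = substream_seed(seed, 41L))
  train_samples <- generate_oo_train(input, sc)
  if (nrow(train_samples) > max_train) {
    train_samples <- with_seed(substream_seed(seed, 43L),
      train_samples[sample.int(nrow(train_samples), max_train), ])
  }
  test_samples <- generate_oo_test(split, sc)
  tc <- train_config(batch_size = 24L, lr = 1e-3, epochs = finetune_epochs,
                     seed = seed, skip_pretrain = skip_pretrain)
  if (skip_pretrain) {
    vo <- build_vocab(input$objects)
    model <- finetune_oo(NULL, train_samples, tc,
                         encoder_config =
                           test_encoder_config(max_len = 8L,
                                               vocab_size = vo$size),
                         vocab = vo)
  } else {
    ck <- pretrain_on_network(input, substream_seed(seed, 42L),
                              side = "object", epochs = pretrain_epochs,
                              lr = lr, max_examples = max_pretrain)
    model <- finetune_oo(ck, train_samples, tc)
  }
  scores <- predict_oo(model, test_samples)
  list(metrics = evaluate_scores(scores, test_samples$label),
       model = model, n_train = nrow(train_samples),
       n_test = nrow(test_samples))
}
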