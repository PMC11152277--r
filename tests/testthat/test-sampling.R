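# Labeled-sample generation: predicates, balance contracts, determinism,
# and masking behaviour.

test_that("has_oo_link detects a shared attribute", {
  net <- bipartite_network(c("o1", "o2"), c("a", "b"),
                           edges = rbind(c("o1", "a"), c("o2", "a"),
                                         c("o2", "b")))
  expect_true(has_oo_link(net, c("o1", "o2")))
  net2 <- bipartite_network(c("o1", "o2"), c("a", "b"),
                            edges = rbind(c("o1", "a"), c("o2", "b")))
  expect_false(has_oo_link(net2, c("o1", "o2")))
  expect_true(has_oo_link(net2, "o1"))    # singleton with an edge
  expect_error(has_oo_link(net2, "zz"), "zz")
})

test_that("O-O training positives are exhaustive and negatives size-matched", {
  net <- bipartite_network(c("o1", "o2", "o3"), c("a", "b"),
                           edges = rbind(c("o1", "a"), c("o2", "a"),
                                         c("o3", "b")))
  s <- generate_oo_train(net, sampling_config(eps_p = 2, seed = 1))
  pos <- s[s$label == 1, ]
  neg <- s[s$label == 0, ]
  expect_identical(nrow(pos), 1L)
  expect_identical(sort(pos$objects[[1]]), c("o1", "o2"))
  expect_identical(nrow(neg), 1L)
  expect_true(paste(sort(neg$objects[[1]]), collapse = ",") %in%
                c("o1,o3", "o2,o3"))
  # no shared attributes at all: empty sample set
  none <- bipartite_network(c("x", "y"), c("p", "q"),
                            edges = rbind(c("x", "p"), c("y", "q")))
  expect_identical(nrow(generate_oo_train(none,
                                          sampling_config(seed = 1))), 0L)
})

test_that("every emitted O-O label satisfies its defining predicate, with per-size balance", {
  net <- generate_planted_network(planted_config(seed = 5))
  sc <- sampling_config(eps_p = 3, seed = 5)
  s <- generate_oo_train(net, sc)
  expect_gt(nrow(s), 0)
  for (i in seq_len(nrow(s))) {
    expect_identical(has_oo_link(net, s$objects[[i]]), s$label[i] == 1L)
    expect_true(length(s$objects[[i]]) %in% 2:3)
  }
  tab <- table(s$size, s$label)
  expect_identical(unname(tab[, "0"]), unname(tab[, "1"]))
  # determinism: identical config gives byte-identical serialized samples
  s2 <- generate_oo_train(net, sc)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_samples_jsonl(s, f1); write_samples_jsonl(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("O-O test samples use new-edge witnesses and target non-links", {
  # input: o1,o2 share a; target adds attribute x joined to o1, o3
  input <- bipartite_network(c("o1", "o2", "o3"), c("a"),
                             edges = rbind(c("o1", "a"), c("o2", "a")))
  target <- bipartite_network(c("o1", "o2", "o3"), c("a", "x"),
                              edges = rbind(c("o1", "a"), c("o2", "a"),
                                            c("o1", "x"), c("o3", "x")))
  sp <- dataset_split(input, target, "growth")
  s <- generate_oo_test(sp, sampling_config(eps_p = 2, seed = 2))
  pos <- s[s$label == 1, ]
  expect_identical(nrow(pos), 1L)
  expect_identical(sort(pos$objects[[1]]), c("o1", "o3"))
  neg <- s[s$label == 0, ]
  for (i in seq_len(nrow(neg))) {
    expect_false(has_oo_link(target, neg$objects[[i]]))
  }
  # input == target: no positives
  sp0 <- dataset_split(input, input, "growth")
  expect_identical(nrow(generate_oo_test(sp0,
                                         sampling_config(seed = 1))), 0L)
})

test_that("O-O test positives never overlap training positives of the input", {
  sp <- generate_growth_pair(planted_config(seed = 21))
  sc <- sampling_config(eps_p = 3, seed = 21)
  train <- generate_oo_train(sp$input_network, sc)
  test <- generate_oo_test(sp, sc)
  tr_keys <- vapply(train$objects[train$label == 1],
                    function(g) paste(sort(g), collapse = ","), character(1))
  te_keys <- vapply(test$objects[test$label == 1],
                    function(g) paste(sort(g), collapse = ","), character(1))
  expect_gt(length(te_keys), 0)
  expect_length(intersect(tr_keys, te_keys), 0)
})

test_that("O-A samples are balanced and negatives are verified non-edges", {
  id2 <- bipartite_network(c("o1", "o2"), c("a", "b"),
                           edges = rbind(c("o1", "a"), c("o2", "b")))
  s <- generate_oa_samples(id2, seed = 1)
  expect_identical(sum(s$label == 1), 2L)
  expect_identical(sum(s$label == 0), 2L)
  for (i in seq_len(nrow(s))) {
    has_edge <- id2$incidence[match(s$object[i], id2$objects),
                              match(s$attribute[i], id2$attributes)]
    expect_identical(unname(has_edge), s$label[i] == 1L)
  }
  # test mode: positives are target-minus-input edges
  net <- as_bipartite_network(random_context(31, 10, 8, 0.4))
  sp <- random_edge_removal_split(net, 0.2, seed = 4)
  st <- generate_oa_samples(sp$target_network, sp$input_network, seed = 5)
  n_removed <- n_edges(net) - n_edges(sp$input_network)
  expect_identical(sum(st$label == 1), as.integer(n_removed))
  for (i in which(st$label == 1)) {
    expect_false(sp$input_network$incidence[
      match(st$object[i], net$objects), match(st$attribute[i], net$attributes)])
    expect_true(sp$target_network$incidence[
      match(st$object[i], net$objects), match(st$attribute[i], net$attributes)])
  }
  # input == target: zero positives
  s0 <- generate_oa_samples(net, net, seed = 1)
  expect_identical(sum(s0$label == 1), 0L)
})

test_that("NCP examples are balanced neighbor/non-neighbor pairs", {
  # 3-chain with the empty-extent bottom excluded: 1 usable neighbor pair
  lat <- build_lattice(extract_concepts(ctx_chain3()))
  expect_message(ex <- make_ncp_examples(lat, sampling_config(seed = 1)),
                 "shortfall", all = FALSE)
  # usable concepts: {o1} and {o1,o2}; 1 positive, no non-neighbor pair left
  expect_identical(sum(vapply(ex, `[[`, integer(1), "label") == 1), 1L)
  # diamond: 4 concepts but bottom extent empty -> positives are the 2 upper
  # Hasse edges; negatives come from non-neighboring pairs
  lat2 <- build_lattice(extract_concepts(ctx_identity2()))
  ex2 <- make_ncp_examples(lat2, sampling_config(seed = 1))
  labs <- vapply(ex2, `[[`, integer(1), "label")
  expect_identical(sum(labs == 1), 2L)
  hasse_ext_keys <- apply(lat2$hasse_edges, 1, function(e)
    paste(sort(c(paste(sort(lat2$concepts[[e[1]]]$extent), collapse = ","),
                 paste(sort(lat2$concepts[[e[2]]]$extent), collapse = ","))),
          collapse = "|"))
  for (e in ex2) {
    key <- paste(sort(c(paste(sort(e$extent_a), collapse = ","),
                        paste(sort(e$extent_b), collapse = ","))),
                 collapse = "|")
    expect_identical(key %in% hasse_ext_keys, e$label == 1L)
  }
})

test_that("NCP presentation order is larger extent first for both classes", {
  net <- generate_planted_network(planted_config(seed = 3))
  lat <- build_lattice(extract_concepts(net))
  ex <- make_ncp_examples(lat, sampling_config(seed = 3))
  for (e in ex) {
    la <- length(e$extent_a); lb <- length(e$extent_b)
    expect_true(la > lb || (la == lb &&
                  paste(sort(e$extent_a), collapse = ",") <=
                    paste(sort(e$extent_b), collapse = ",")))
  }
  # determinism
  ex2 <- make_ncp_examples(lat, sampling_config(seed = 3))
  expect_identical(ex, ex2)
})

test_that("algorithm1 neighbor source restricts positives to the one-per-concept map", {
  net <- generate_planted_network(planted_config(
    n_objects = 15, n_attributes = 12, n_bicliques = 5, seed = 9))
  lat <- build_lattice(extract_concepts(net))
  ex_h <- make_ncp_examples(lat, sampling_config(seed = 1))
  ex_a <- make_ncp_examples(lat, sampling_config(seed = 1,
                                                 neighbor_source = "algorithm1"))
  n_pos_h <- sum(vapply(ex_h, `[[`, integer(1), "label") == 1)
  n_pos_a <- sum(vapply(ex_a, `[[`, integer(1), "label") == 1)
  expect_lte(n_pos_a, n_pos_h)
  expect_gt(n_pos_a, 0)
})

test_that("mask_tokens respects count rules and never touches specials", {
  vocab <- build_vocab(paste0("o", 1:8))
  sc <- sampling_config(mask_rate = 1.0, max_masked = 4, seed = 1)
  seq3 <- encode_pair(c("o1", "o2"), "o3", vocab, 8)
  set.seed(5)
  inst <- mask_tokens(seq3, sc, vocab)
  expect_identical(length(inst$masked_positions), 3L)  # min(3 tokens, cap 4)
  # cap binds for longer sequences
  seq6 <- encode_pair(c("o1", "o2", "o3"), c("o4", "o5", "o6"), vocab, 9)
  for (k in 1:25) {
    inst6 <- mask_tokens(seq6, sc, vocab)
    expect_lte(length(inst6$masked_positions), 4L)
    expect_true(all(seq6$ids[inst6$masked_positions] >= 4L))
    # targets record the originals
    expect_identical(inst6$target_ids, seq6$ids[inst6$masked_positions])
    # non-masked positions unchanged
    untouched <- setdiff(seq_along(seq6$ids), inst6$masked_positions)
    expect_identical(inst6$input_ids[untouched], seq6$ids[untouched])
  }
  only_special <- structure(list(ids = c(1L, 2L, 0L),
                                 segment_ids = c(0L, 0L, 0L),
                                 pad_mask = c(FALSE, FALSE, TRUE)),
                            class = "token_sequence")
  expect_error(mask_tokens(only_special, sc, vocab), "special")
})

test_that("mask/replace/keep frequencies approach 80/10/10", {
  vocab <- build_vocab(paste0("o", 1:10))
  sc <- sampling_config(mask_rate = 1.0, max_masked = 4, seed = 1)
  sq <- encode_pair(c("o1", "o2"), c("o3", "o4"), vocab, 8)
  set.seed(99)
  n_mask <- 0; n_rand <- 0; n_keep <- 0
  for (k in 1:2000) {
    inst <- mask_tokens(sq, sc, vocab)
    orig <- sq$ids[inst$masked_positions]
    new <- inst$input_ids[inst$masked_positions]
    n_mask <- n_mask + sum(new == 3L)
    n_keep <- n_keep + sum(new == orig)
    n_rand <- n_rand + sum(new != 3L & new != orig)
  }
  tot <- n_mask + n_rand + n_keep
  expect_lt(abs(n_mask / tot - 0.8), 0.03)
  # random replacement can coincide with the original token, so the
  # observed "keep" rate absorbs ~1/10 of the random draws
  expect_lt(abs(n_rand / tot - 0.1), 0.03)
})
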