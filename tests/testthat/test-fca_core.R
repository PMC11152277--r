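# Derivation operators, concept enumeration against the brute-force
# oracle, lattice order/Hasse construction, and the topological-sort
# lower-neighbor pass.

test_that("derive matches the shared-attribute definition", {
  ctx <- ctx_small()
  expect_setequal(derive(ctx, "objects", c("o1", "o2")), "a")
  expect_setequal(derive(ctx, "objects", "o1"), c("a", "b"))
  expect_setequal(derive(ctx, "attributes", "a"), c("o1", "o2"))
  # empty set derives to the whole opposite side
  expect_setequal(derive(ctx, "objects", character(0)), c("a", "b"))
  expect_error(derive(ctx, "objects", "nope"), "nope")
})

test_that("derive is antitone on nested subsets", {
  for (seed in 1:25) {
    ctx <- random_context(seed, 8, 6, 0.4)
    set.seed(seed + 1000)
    big <- sample(ctx$objects, sample(2:6, 1))
    small <- sample(big, sample(seq_len(length(big) - 1), 1))
    expect_true(all(derive(ctx, "objects", big) %in%
                      derive(ctx, "objects", small)))
  }
})

test_that("closure is idempotent, extensive, and matches hand cases", {
  ctx <- ctx_small()
  expect_setequal(closure(ctx, "o2"), c("o1", "o2"))
  for (seed in 1:40) {
    ctx <- random_context(seed, 7, 6, 0.4)
    set.seed(seed)
    A <- sample(ctx$objects, sample(0:4, 1))
    cl <- closure(ctx, A)
    expect_true(all(A %in% cl))                       # extensive
    expect_setequal(closure(ctx, cl), cl)             # idempotent
  }
})

test_that("is_concept accepts exactly the closed pairs", {
  ctx <- ctx_small()
  expect_true(is_concept(ctx, "o1", c("a", "b")))
  expect_false(is_concept(ctx, "o1", "a"))
  full <- formal_context(c("x", "y"), c("p", "q"),
                         incidence = matrix(TRUE, 2, 2))
  expect_true(is_concept(full, c("x", "y"), c("p", "q")))
})

test_that("extract_concepts matches hand-enumerated cases", {
  cc <- extract_concepts(ctx_identity2())
  expect_length(cc, 4)
  expect_identical(concept_keys(cc),
                   concept_keys(list(
                     list(extent = character(0), intent = c("a", "b")),
                     list(extent = "o1", intent = "a"),
                     list(extent = "o2", intent = "b"),
                     list(extent = c("o1", "o2"), intent = character(0)))))
  # full incidence: single concept
  full <- formal_context(paste0("o", 1:3), paste0("a", 1:2),
                         incidence = matrix(TRUE, 3, 2))
  expect_length(extract_concepts(full), 1)
  # empty incidence: top and bottom only
  empty <- formal_context(paste0("o", 1:3), paste0("a", 1:2))
  expect_length(extract_concepts(empty), 2)
})

test_that("extract_concepts equals the brute-force oracle on random contexts", {
  for (seed in 1:40) {
    for (dens in c(0.2, 0.4, 0.6)) {
      ctx <- random_context(seed * 100 + dens * 10, sample(2:10, 1),
                            sample(2:8, 1), dens)
      a <- extract_concepts(ctx)
      b <- brute_force_concepts(ctx)
      expect_identical(concept_keys(a), concept_keys(b))
      for (cc in a) expect_true(is_concept(ctx, cc$extent, cc$intent))
    }
  }
})

test_that("brute_force_concepts refuses oversized inputs", {
  big <- formal_context(paste0("o", 1:25), paste0("a", 1:25))
  expect_error(brute_force_concepts(big), "limit")
})

test_that("canonical concept order is extent size then lexicographic", {
  cc <- extract_concepts(ctx_identity2())
  sizes <- vapply(cc, function(x) length(x$extent), integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_identical(cc[[2]]$extent, "o1")   # "o1" sorts before "o2"
  expect_identical(cc[[3]]$extent, "o2")
})

test_that("build_lattice produces order pairs and Hasse edges for known shapes", {
  # 3-chain
  lat <- build_lattice(extract_concepts(ctx_chain3()))
  expect_identical(nrow(lat$order_pairs), 3L)
  expect_identical(nrow(lat$hasse_edges), 2L)
  # diamond
  lat2 <- build_lattice(extract_concepts(ctx_identity2()))
  expect_identical(nrow(lat2$order_pairs), 5L)
  expect_identical(nrow(lat2$hasse_edges), 4L)
  # single concept
  lat3 <- build_lattice(extract_concepts(
    formal_context("x", "p", edges = cbind("x", "p"))))
  expect_identical(nrow(lat3$order_pairs), 0L)
  expect_identical(nrow(lat3$hasse_edges), 0L)
  expect_error(build_lattice(c(lat2$concepts, lat2$concepts[1])), "duplicate")
})

test_that("order is extent containment and Hasse equals brute-force reduction", {
  for (seed in c(3, 14, 27)) {
    ctx <- random_context(seed, 7, 6, 0.35)
    cc <- extract_concepts(ctx)
    lat <- build_lattice(cc)
    for (i in seq_along(cc)) {
      for (j in seq_along(cc)) {
        expected <- length(cc[[i]]$extent) < length(cc[[j]]$extent) &&
          all(cc[[i]]$extent %in% cc[[j]]$extent)
        expect_identical(unname(lat$order[i, j]), expected)
      }
    }
    bf <- brute_force_hasse(lat$order)
    got <- lat$hasse_edges[order(lat$hasse_edges[, 1], lat$hasse_edges[, 2]), ,
                           drop = FALSE]
    bf <- bf[order(bf[, 1], bf[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(bf))
  }
})

test_that("lower-neighbor pass assigns true lower neighbors, one per non-minimal concept", {
  # hand-traced chain: N(mid) = bottom, N(top) = mid
  lat <- build_lattice(extract_concepts(ctx_chain3()))
  N <- algorithm1_lower_neighbors(lat)
  sizes <- vapply(lat$concepts, function(x) length(x$extent), integer(1))
  bottom <- which(sizes == 0); mid <- which(sizes == 1); top <- which(sizes == 2)
  expect_true(is.na(N[bottom]))
  expect_identical(N[mid], bottom)
  expect_identical(N[top], mid)
  # diamond: both sides get the bottom; top gets either side, but always a
  # true lower neighbor under the no-intermediate definition
  lat2 <- build_lattice(extract_concepts(ctx_identity2()))
  N2 <- algorithm1_lower_neighbors(lat2)
  hasse_keys <- paste(lat2$hasse_edges[, 1], lat2$hasse_edges[, 2])
  for (i in which(!is.na(N2))) {
    expect_true(paste(N2[i], i) %in% hasse_keys)
  }
  # random contexts: assignments lie in the Hasse relation and the count is
  # |concepts| - #minimal
  for (seed in c(5, 21, 33)) {
    ctx <- random_context(seed, 8, 6, 0.4)
    lat <- build_lattice(extract_concepts(ctx))
    N <- algorithm1_lower_neighbors(lat)
    hk <- paste(lat$hasse_edges[, 1], lat$hasse_edges[, 2])
    for (i in which(!is.na(N))) expect_true(paste(N[i], i) %in% hk)
    n_minimal <- sum(colSums(lat$order) == 0)
    expect_identical(sum(!is.na(N)), length(lat$concepts) - n_minimal)
  }
  # single concept: empty map
  single <- build_lattice(extract_concepts(
    formal_context("x", "p", edges = cbind("x", "p"))))
  expect_true(all(is.na(algorithm1_lower_neighbors(single))))
})
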