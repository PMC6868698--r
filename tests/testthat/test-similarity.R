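# independent oracle: double loop over profile pairs
brute_force_kernel <- function(profiles, scale, offset) {
  n <- nrow(profiles)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- tanh(scale * sum(profiles[i, ] * profiles[j, ]) + offset)
    }
  }
  K
}

test_that("sigmoid kernel reproduces hand-computed and limit cases", {
  # both drugs share 2 of 4 diseases: tanh(2/4)
  A <- toy_assoc(cbind(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  K <- sigmoid_kernel(A, "drugs")
  expect_equal(K["r1", "r2"], tanh(0.5), tolerance = 1e-12)
  expect_equal(K["r1", "r2"], 0.46212, tolerance = 1e-5)

  # all-zero profiles give tanh(0) = 0
  Z <- toy_assoc(matrix(0, 3, 2))
  expect_true(all(unclass(sigmoid_kernel(Z, "drugs")) == 0))

  # all-ones association matrix: every drug pair at tanh(1)
  O <- toy_assoc(matrix(1, 5, 4))
  expect_true(all(abs(unclass(sigmoid_kernel(O, "drugs")) - tanh(1)) < 1e-12))

  expect_error(sigmoid_kernel(toy_assoc(matrix(0, 3, 2))[, 0, drop = FALSE]),
               class = "error")
})

test_that("sigmoid kernel matches the brute-force oracle on random matrices", {
  for (seed in 1:20) {
    A <- random_assoc(6, 8, density = 0.4, seed = seed)
    for (axis in c("drugs", "diseases")) {
      profiles <- if (axis == "drugs") t(unclass(A)) else unclass(A)
      expected <- brute_force_kernel(profiles, 1 / ncol(profiles), 0)
      expect_lt(max(abs(unclass(sigmoid_kernel(A, axis)) - expected)), 1e-12)
    }
  }
})

test_that("logistic rescaling matches its closed form and preserves order", {
  S <- toy_sim(rbind(c(1, 0), c(0, 1)))
  L <- logistic_adjust(S)
  expect_equal(L["x1", "x2"], 1 / (1 + 9999), tolerance = 1e-12)  # L(0) = 1e-4
  S2 <- toy_sim(rbind(c(1, 1), c(1, 1)) - diag(2) * 0)
  L2 <- logistic_adjust(S2)
  expect_equal(L2["x1", "x2"], 1 / (1 + exp(log(9999) - 15)), tolerance = 1e-12)
  expect_equal(L2["x1", "x2"], 0.9970, tolerance = 1e-3)

  # diagonal is left at its input value
  expect_equal(diag(unclass(L)), c(1, 1), ignore_attr = TRUE)

  # monotone increasing for negative steepness
  xs <- seq(0, 1, by = 0.05)
  S3 <- similarity_matrix(outer(xs, xs, function(a, b) (a + b) / 2),
                          entity_ids = sprintf("v%d", seq_along(xs)))
  L3 <- logistic_adjust(S3)
  ord <- order(unclass(S3)[1, -1])
  expect_false(is.unsorted(unclass(L3)[1, -1][ord]))
})

test_that("co-association weights equal shared-partner counts", {
  # two drugs treating the same single disease: one edge of weight 1
  A <- toy_assoc(rbind(c(1, 1), c(0, 0)))
  g <- build_coassociation_graph(A, "drugs")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)

  # disjoint disease sets: no edge
  B <- toy_assoc(rbind(c(1, 0), c(0, 1)))
  expect_equal(igraph::ecount(build_coassociation_graph(B, "drugs")), 0)

  # weights equal the off-diagonal of t(A) %*% A
  for (seed in 1:10) {
    A <- random_assoc(7, 9, density = 0.35, seed = seed)
    W <- igraph::as_adjacency_matrix(build_coassociation_graph(A, "drugs"),
                                     attr = "weight", sparse = FALSE)
    expected <- crossprod(unclass(A))
    diag(expected) <- 0
    expect_equal(W, expected, ignore_attr = TRUE)
  }
})

test_that("similarity fusion falls back to side similarity for empty profiles", {
  # r3 has an all-zero profile; all other drugs are informative
  A <- toy_assoc(rbind(c(1, 1, 0), c(0, 1, 0)))
  kern <- sigmoid_kernel(A, "drugs")
  side <- similarity_matrix(matrix(0.3, 3, 3) + 0.7 * diag(3),
                            entity_ids = colnames(A))
  fused <- fuse_similarity(kern, side, A, "drugs")
  expect_equal(fused["r1", "r2"], kern["r1", "r2"])     # both informative
  expect_equal(fused["r1", "r3"], side["r1", "r3"])     # empty profile branch
  expect_equal(fused["r2", "r3"], side["r2", "r3"])
  expect_equal(diag(unclass(fused)), rep(0.99, 3), ignore_attr = TRUE)
  expect_identical(unclass(fused), t(unclass(fused)))

  expect_error(fuse_similarity(kern, toy_sim(diag(3)), A, "drugs"),
               "identifiers")
})

test_that("the fused similarity pipeline keeps all values in [0, 0.99]", {
  for (seed in 1:3) {
    syn <- generate_synthetic(synth_config(n_drugs = 20, n_diseases = 14,
                                           n_blocks = 2), seed = seed)
    sims <- similarity_pipeline(syn$association, syn$drug_similarity,
                                syn$disease_similarity)
    for (S in list(sims$drug, sims$disease)) {
      expect_gte(min(S), 0)
      expect_lte(max(S), 0.99)
      expect_identical(unclass(S), t(unclass(S)))
    }
  }
})

test_that("tanimoto similarity equals set arithmetic on hand-built fingerprints", {
  # 2 shared bits, 4 set in each, union of 6
  fp <- rbind(a = c(1, 1, 1, 1, 0, 0, 0),
              b = c(1, 1, 0, 0, 1, 1, 0))
  S <- tanimoto_similarity(fp)
  expect_equal(S["a", "b"], 2 / 6, tolerance = 1e-12)
  expect_equal(diag(unclass(S)), c(1, 1), ignore_attr = TRUE)

  # identical fingerprints
  S2 <- tanimoto_similarity(rbind(a = c(1, 0, 1), b = c(1, 0, 1)))
  expect_equal(S2["a", "b"], 1)

  # disjoint fingerprints
  S3 <- tanimoto_similarity(rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1)))
  expect_equal(S3["a", "b"], 0)

  expect_error(tanimoto_similarity(rbind(a = c(1, 2))), "binary")
})

test_that("structure similarity from SMILES agrees with ChemmineR's Tanimoto", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  catalog <- tibble::tibble(
    drug_id = c("ibuprofen", "phenol", "aspirin", "nosmiles"),
    smiles = c("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1ccccc1O",
               "CC(=O)Oc1ccccc1C(=O)O", NA))
  expect_warning(S <- tanimoto_structure_similarity(catalog), "structure")
  expect_equal(dim(S), c(4, 4))
  expect_equal(S["ibuprofen", "ibuprofen"], 1)
  expect_true(all(S["nosmiles", c("ibuprofen", "phenol", "aspirin")] == 0))

  # cross-check one off-diagonal value against ChemmineR's own similarity
  # (addone = 0 gives the plain intersection-over-union coefficient)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(catalog$smiles[1:3]))
  ChemmineR::cid(sdf) <- catalog$drug_id[1:3]
  ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
  env <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = env)
  fp <- ChemmineR::desc2fp(ap, descnames = as.character(env$apfp$AP)[seq_len(1024)])
  ref <- ChemmineR::fpSim(fp["ibuprofen"], fp["aspirin"], method = "Tanimoto",
                          addone = 0)
  expect_gt(ref, 0)
  expect_equal(unname(S["ibuprofen", "aspirin"]), unname(ref), tolerance = 1e-9)
})
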