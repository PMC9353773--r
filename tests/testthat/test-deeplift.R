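test_that("references are built per mode and validated", {
  X <- matrix(rep(c(2, -1, 0.5), 4), 3, 4,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  expect_equal(make_reference(X, "train_mean")$values, c(a = 2, b = -1, c = 0.5))
  expect_equal(unname(make_reference(X, "zeros")$values), rep(0, 3))
  expect_equal(unname(make_reference(X, "custom", values = 1:3)$values), 1:3)
  expect_error(make_reference(X, "custom", values = 1:2), "one value per gene")
})

test_that("the linear rule gives w * (x - x0) for a single affine layer", {
  net <- init_network(c(4, 1), "linear", seed = 2)
  w <- rnorm(4); net$layers[[1]]$W[] <- w; net$layers[[1]]$b <- 3
  x <- rnorm(4); x0 <- rnorm(4)
  att <- deeplift_attribute(net, x, x0)
  expect_equal(unname(att$contributions[1, ]), w * (x - x0))
  expect_equal(att$delta, sum(w * (x - x0)))
})

test_that("attribution of the reference to itself is exactly zero", {
  net <- rand_net(12, n_in = 6)
  x0 <- rnorm(6)
  att <- deeplift_attribute(net, x0, x0)
  expect_equal(unname(att$contributions[1, ]), rep(0, 6))
  expect_equal(att$delta, 0)
})

test_that("contributions sum to the output delta on random relu networks", {
  for (seed in 1:8) {
    net <- rand_net(seed * 13, n_in = 7)
    set.seed(seed)
    X <- matrix(rnorm(20 * 7), 20, 7)
    x0 <- rnorm(7)
    att <- deeplift_attribute(net, X, x0)
    scale <- pmax(abs(att$delta), 1e-3)
    expect_lt(max(abs(rowSums(att$contributions) - att$delta) / scale), 1e-6)
  }
})

test_that("purely linear networks match the weight-product closed form", {
  net <- init_network(c(5, 4, 3, 2), c("linear", "linear", "linear"), seed = 6)
  for (l in 1:3) net$layers[[l]]$b <- rnorm(length(net$layers[[l]]$b))
  M <- net$layers[[1]]$W %*% net$layers[[2]]$W %*% net$layers[[3]]$W
  X <- matrix(rnorm(6 * 5), 6, 5)
  x0 <- rnorm(5)
  att <- deeplift_attribute(net, X, x0, neuron = 2)
  closed <- sweep(X, 2, x0) * matrix(M[, 2], 6, 5, byrow = TRUE)
  expect_equal(att$contributions, closed, tolerance = 1e-12)

  # scaling equivariance: doubling (x - x0) doubles every contribution
  X2 <- sweep(sweep(X, 2, x0) * 2, 2, x0, "+")
  att2 <- deeplift_attribute(net, X2, x0, neuron = 2)
  expect_equal(att2$contributions, 2 * att$contributions, tolerance = 1e-12)
})

test_that("targets can be internal neurons and are bounds-checked", {
  net <- rand_net(31, n_in = 5)
  X <- matrix(rnorm(10 * 5), 10, 5)
  x0 <- rnorm(5)
  att <- deeplift_attribute(net, X, x0, layer = 1, neuron = 2)
  rec_x <- forward(net, X, record_activations = TRUE)
  rec_0 <- forward(net, matrix(x0, 1), record_activations = TRUE)
  delta <- rec_x$post[[1]][, 2] - rec_0$post[[1]][1, 2]
  expect_equal(att$delta, delta)
  expect_lt(max(abs(rowSums(att$contributions) - delta)), 1e-8)

  expect_error(deeplift_attribute(net, X, x0, layer = 99), "layer out of range")
  expect_error(deeplift_attribute(net, X, x0, neuron = 999), "neuron out of range")
  expect_error(deeplift_attribute(net, X, rnorm(4)), "width")
})

test_that("neuron relevance is conserved layer by layer", {
  net <- init_network(c(6, 10, 8, 4), c("relu", "relu", "softmax"), seed = 9)
  for (l in 1:3) net$layers[[l]]$b <- rnorm(length(net$layers[[l]]$b), sd = 0.2)
  set.seed(2)
  X <- matrix(rnorm(15 * 6), 15, 6)
  x0 <- rnorm(6)
  prof <- neuron_relevance(net, X, x0, class = 3)
  for (R in prof$layers)
    expect_lt(max(abs(rowSums(R) - prof$delta) / pmax(abs(prof$delta), 1e-3)), 1e-6)

  # output layer holds the full delta on the target class only
  out <- prof$layers$output
  expect_equal(out[, 3], prof$delta)
  expect_true(all(out[, -3] == 0))

  expect_error(neuron_relevance(net, X[0, , drop = FALSE], x0, class = 1),
               "no samples")
})

test_that("a hidden neuron with zero outgoing weights has zero relevance", {
  net <- init_network(c(4, 6, 2), c("relu", "softmax"), seed = 5)
  net$layers[[2]]$W[3, ] <- 0
  X <- matrix(rnorm(12 * 4), 12, 4)
  prof <- neuron_relevance(net, X, rnorm(4), class = 1)
  expect_equal(unname(prof$layers$hidden_1[, 3]), rep(0, 12))
})

test_that("gene ranking zeroes reference-constant genes and is permutation-equivariant", {
  set.seed(14)
  X <- matrix(rnorm(8 * 30), 8, 30,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%02d", 1:30)))
  X[5, ] <- 1.7  # constant gene equal to its train_mean reference
  ae <- init_network(c(8, 6, 3, 6, 8), c("relu", "relu", "relu", "linear"), seed = 3)
  rk <- rank_genes(ae, X)
  expect_identical(rk$gene[8], "g5")
  expect_equal(rk$importance[8], 0)
  expect_true(all(diff(rk$importance) <= 0))

  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  Xp <- X[perm, ]
  aep <- ae
  aep$layers[[1]]$W <- ae$layers[[1]]$W[perm, ]
  aep$layers[[4]]$W <- ae$layers[[4]]$W[, perm]
  aep$layers[[4]]$b <- ae$layers[[4]]$b[perm]
  rkp <- rank_genes(aep, Xp)
  expect_identical(rkp$gene, rk$gene)
  expect_equal(rkp$importance, rk$importance)

  expect_error(rank_genes(ae, X[1:7, ]), "input width")
})
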