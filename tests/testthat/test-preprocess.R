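test_that("quantile normalization matches the hand-computed 2x2 case", {
  X <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  # sort each column, average across columns per rank, map back by rank
  expect_equal(unname(quantile_normalize(X)),
               matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))
})

test_that("quantile normalization equalizes column distributions and is idempotent", {
  set.seed(7)
  X <- matrix(rnorm(200, sd = 3), 40, 5,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:5)))
  qn <- quantile_normalize(X)
  sorted <- apply(qn, 2, sort)
  for (j in 2:ncol(qn)) expect_equal(sorted[, j], sorted[, 1])
  expect_equal(quantile_normalize(qn), qn)
  expect_identical(dimnames(qn), dimnames(X))

  # total mass is preserved when columns are permutations of each other
  base <- rnorm(30)
  P <- cbind(s1 = base, s2 = sample(base), s3 = sample(base))
  rownames(P) <- sprintf("g%02d", 1:30)
  expect_equal(sum(quantile_normalize(P)), sum(P))

  expect_error(quantile_normalize(X[, 1, drop = FALSE]), "two samples")
})

test_that("tied values share the mean of the rank-means they span", {
  X <- matrix(c(1, 1, 5, 2, 3, 4), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  # rank-means: (1.5, 2, 4.5); the tie in column 1 spans ranks 1-2
  qn <- quantile_normalize(X)
  expect_equal(unname(qn[, 1]), c(1.75, 1.75, 4.5))
  expect_equal(unname(qn[, 2]), c(1.5, 2, 4.5))
})

test_that("quantile normalization agrees with the limma implementation", {
  skip_if_not_installed("limma")
  set.seed(11)
  X <- matrix(rexp(300), 60, 5,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%d", 1:5)))
  expect_equal(unname(quantile_normalize(X)),
               unname(limma::normalizeQuantiles(X)), tolerance = 1e-12)
})

test_that("probe collapse keeps the highest-average probe per gene", {
  probes <- rbind(p_low = c(1, 3), p_high = c(4, 6), q_only = c(7, 7))
  colnames(probes) <- c("s1", "s2")
  map <- data.frame(probe_id = c("p_low", "p_high", "q_only", "unused"),
                    gene_id = c("GENE1", "GENE1", "GENE2", "GENE3"))
  out <- collapse_probes(probes, map)
  expect_identical(rownames(out), c("GENE1", "GENE2"))
  expect_equal(unname(out["GENE1", ]), c(4, 6))   # mean 5 beats mean 2

  # equal means: lexicographically smaller probe id wins
  tie <- rbind(pB = c(2, 4), pA = c(4, 2))
  colnames(tie) <- c("s1", "s2")
  tie_map <- data.frame(probe_id = c("pA", "pB"), gene_id = c("G", "G"))
  expect_equal(unname(collapse_probes(tie, tie_map)["G", ]), c(4, 2))

  # one probe per gene is the identity on values; unmapped probes are dropped
  single <- expr_fixture(4, 3)
  rownames(single) <- paste0("probe", 1:4)
  map1 <- data.frame(probe_id = paste0("probe", 1:3),
                     gene_id = paste0("gene", 1:3))
  out1 <- collapse_probes(single, map1)
  expect_equal(nrow(out1), 3L)
  expect_equal(unname(out1), unname(single[1:3, ]))

  expect_error(collapse_probes(single, map1[0, ]), "empty")
})

test_that("SMOTE balances classes with interpolated minority samples", {
  data <- toy_binary(n_genes = 4, n_pos = 8, n_neg = 20, seed = 5)
  out <- smote_oversample(data, k_neighbors = 3, seed = 9)
  expect_equal(as.vector(table(out$labels)), c(20L, 20L))
  # originals are untouched and lead the matrix
  expect_identical(out$matrix[, 1:28], data$matrix)
  expect_identical(which(out$synthetic), 29:40)

  # every synthetic point lies on a segment between two original minority points
  minority <- t(data$matrix[, data$labels == "bone"])
  synth <- t(out$matrix[, out$synthetic])
  for (i in seq_len(nrow(synth))) {
    p <- synth[i, ]
    ok <- FALSE
    for (a in seq_len(nrow(minority) - 1)) {
      for (b in (a + 1):nrow(minority)) {
        gap <- stats::dist(rbind(minority[a, ], p, minority[b, ]))
        if (abs(gap[1] + gap[3] - gap[2]) < 1e-8) ok <- TRUE
      }
    }
    expect_true(ok)
  }
})

test_that("SMOTE is seed-deterministic and respects its preconditions", {
  data <- toy_binary(n_genes = 3, n_pos = 7, n_neg = 15, seed = 2)
  a <- smote_oversample(data, k_neighbors = 2, seed = 4)
  b <- smote_oversample(data, k_neighbors = 2, seed = 4)
  expect_identical(a$matrix, b$matrix)
  c <- smote_oversample(data, k_neighbors = 2, seed = 5)
  expect_false(identical(a$matrix, c$matrix))

  balanced <- toy_binary(n_pos = 10, n_neg = 10, seed = 3)
  expect_identical(smote_oversample(balanced, seed = 1), balanced)

  expect_error(smote_oversample(data, k_neighbors = 7), "smaller")
})

test_that("with k = 1 synthetic points stay on the two-point segment", {
  X <- matrix(c(0, 0, 4, 2, rnorm(8, 10)), 2, 6,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  data <- labeled_dataset(X, factor(c("bone", "bone", rep("primary", 4)),
                                    levels = c("primary", "bone")))
  out <- smote_oversample(data, k_neighbors = 1, seed = 3)
  synth <- out$matrix[, out$synthetic, drop = FALSE]
  # segment between (0,0) and (4,2): y = x/2, 0 <= x <= 4
  expect_true(all(abs(synth["g2", ] - synth["g1", ] / 2) < 1e-12))
  expect_true(all(synth["g1", ] >= 0 & synth["g1", ] <= 4))
})

test_that("standardization fits, applies and round-trips training statistics", {
  X <- expr_fixture(6, 8, seed = 4)
  fit <- standardize(X)
  expect_equal(unname(rowMeans(fit$matrix)), rep(0, 6))
  expect_equal(unname(apply(fit$matrix, 1, sd)), rep(1, 6))

  # applying the training stats to shifted data moves means, not sds
  shifted <- X + 2
  app <- standardize(shifted, fit$stats)
  expect_equal(unname(rowMeans(app$matrix)), 2 / unname(fit$stats$sd))
  expect_equal(unname(apply(app$matrix, 1, sd)), rep(1, 6))

  const <- X
  const[2, ] <- 7
  expect_message(res <- standardize(const), "zero-variance")
  expect_equal(unname(res$matrix[2, ]), rep(0, ncol(X)))

  bad <- fit$stats
  names(bad$mean)[1] <- "OTHER"
  expect_error(standardize(X, bad), "genes")
})
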