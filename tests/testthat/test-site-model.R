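# A hand-built two-class site model whose argmax rule is "class2 iff
# z-scored gene2 exceeds z-scored gene1" -- lets metric formulas be tested
# against printed confusion counts.
manual_model <- function() {
  net <- init_network(c(2, 2), "softmax", seed = 1)
  net$layers[[1]]$W <- matrix(c(10, -10, -10, 10), 2, 2)
  net$layers[[1]]$b <- c(0, 0)
  structure(list(network = net, classes = c("primary", "bone"),
                 panel_genes = c("g1", "g2"),
                 stats = list(mean = c(g1 = 0, g2 = 0), sd = c(g1 = 1, g2 = 1)),
                 training = list()),
            class = "site_model")
}

test_that("panel assembly deduplicates order-preservingly with provenance", {
  p <- assemble_panel(list(bone = c("A", "B"), brain = c("B", "C")))
  expect_identical(p$genes, c("A", "B", "C"))
  expect_identical(p$provenance$B, c("bone", "brain"))

  disjoint <- assemble_panel(list(a = c("X", "Y"), b = c("Z")))
  expect_length(disjoint$genes, 3)

  # four site lists totalling 190 entries with 6 duplicated entries -> 184
  lists <- list(bone = sprintf("G%03d", 1:60),
                brain = sprintf("G%03d", 55:104),   # 6 overlap with bone
                lung = sprintf("G%03d", 105:144),
                liver = sprintf("G%03d", 145:184))
  expect_equal(sum(lengths(lists)), 190)
  expect_length(assemble_panel(lists)$genes, 184)

  expect_error(assemble_panel(list(a = character(0))), "non-empty")
})

test_that("roc_auc is the normalized Mann-Whitney statistic", {
  labs <- factor(rep(c("neg", "pos"), each = 4), levels = c("neg", "pos"))
  expect_equal(roc_auc(c(1:4, 5:8), labs), 1.0)
  expect_equal(roc_auc(c(5:8, 1:4), labs), 0.0)
  expect_equal(roc_auc(rep(2, 8), labs), 0.5)

  set.seed(3)
  scores <- rnorm(40)
  labs2 <- factor(sample(rep(c("neg", "pos"), 20)), levels = c("neg", "pos"))
  a <- roc_auc(scores, labs2)
  expect_equal(a + roc_auc(-scores, labs2), 1.0)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(scores / 2), labs2), a)

  expect_error(roc_auc(scores, factor(rep("pos", 40))), "two classes")
})

test_that("roc_auc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- c(rnorm(25), rnorm(30, 0.8))
  labs <- rep(c(0, 1), c(25, 30))
  expect_equal(roc_auc(scores, labs == 1),
               as.numeric(pROC::auc(pROC::roc(labs, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("threshold metrics match the printed confusion counts", {
  model <- manual_model()
  # 8 samples: predicted bone iff g2 > g1; engineered TP=3 FP=1 FN=1 TN=3
  X <- rbind(g1 = c(0, 0, 0, 1, 0, 1, 1, 1),
             g2 = c(1, 1, 1, 0, 1, 0, 0, 0))
  colnames(X) <- sprintf("s%d", 1:8)
  labels <- factor(c("bone", "bone", "bone", "bone",
                     "primary", "primary", "primary", "primary"),
                   levels = c("primary", "bone"))
  data <- labeled_dataset(X, labels)
  rep <- evaluate_sites(model, data)
  bone <- rep$metrics[rep$metrics$class == "bone", ]
  expect_equal(bone$precision, 0.75)
  expect_equal(bone$sensitivity, 0.75)
  expect_equal(bone$f1, 0.75)
  expect_equal(bone$specificity, 0.75)
  expect_equal(rep$accuracy, 0.75)
  expect_equal(sum(diag(rep$confusion)), 6)
  expect_equal(unname(rowSums(rep$confusion)), c(4, 4))
})

test_that("predictions are proper probability rows and duplicate consistently", {
  data <- toy_binary(n_genes = 10, n_sep = 3, seed = 12)
  model <- train_site_model(data, rownames(data$matrix)[1:6], hidden = c(6, 4),
                            config = train_config("categorical_cross_entropy",
                                                  epochs = 10, seed = 3))
  pred <- predict_sites(model, data$matrix)
  expect_equal(unname(rowSums(pred$probabilities)), rep(1, ncol(data$matrix)),
               tolerance = 1e-9)

  dup <- data$matrix[, c(1, 1, 2)]
  colnames(dup) <- c("a", "b", "c")
  pd <- predict_sites(model, dup)
  expect_equal(unname(pd$probabilities[1, ]), unname(pd$probabilities[2, ]))

  expect_error(predict_sites(model, data$matrix[-1, ]),
               "missing panel genes: G001")
})

test_that("site-model training validates inputs and is seed-deterministic", {
  data <- toy_binary(n_genes = 8, n_sep = 2, seed = 8)
  cfg <- train_config("categorical_cross_entropy", epochs = 6, seed = 4)
  m1 <- train_site_model(data, rownames(data$matrix), hidden = c(5), config = cfg)
  m2 <- train_site_model(data, rownames(data$matrix), hidden = c(5), config = cfg)
  expect_identical(m1$network, m2$network)

  expect_error(train_site_model(data, c("G001", "NOPE"), config = cfg),
               "NOPE")
  missing_class <- labeled_dataset(data$matrix,
                                   factor(as.character(data$labels),
                                          levels = c("primary", "bone", "lung")))
  expect_error(train_site_model(missing_class, rownames(data$matrix), config = cfg),
               "lung")
})

test_that("classes absent from evaluation labels yield NA metrics, not numbers", {
  model <- manual_model()
  X <- rbind(g1 = c(1, 1, 0), g2 = c(0, 0, 1))
  colnames(X) <- c("s1", "s2", "s3")
  data <- labeled_dataset(X, factor(c("primary", "primary", "primary"),
                                    levels = c("primary", "bone")))
  rep <- evaluate_sites(model, data)
  expect_true(is.na(rep$auc["bone"]))
  expect_true(is.na(rep$metrics$sensitivity[rep$metrics$class == "bone"]))
})
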