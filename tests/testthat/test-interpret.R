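make_profile <- function(scores_list, class = "bone") {
  layers <- c(scores_list, list(output = matrix(1, nrow(scores_list[[1]]), 2)))
  names(layers) <- c(paste0("hidden_", seq_along(scores_list)), "output")
  structure(list(class = class, class_index = 1L, layers = layers,
                 mean = lapply(layers, colMeans),
                 delta = rowSums(scores_list[[1]]), target_is_logit = TRUE),
            class = "relevance_profile")
}

test_that("a strongly offset neuron is the only one selected", {
  set.seed(4)
  base <- matrix(rnorm(30 * 8, mean = 1, sd = 0.5), 30, 8)
  base[, 5] <- base[, 5] + 10 * 0.5  # +10 sd offset
  prof <- make_profile(list(base))
  res <- essential_neurons(prof, alpha = 0.05)
  expect_identical(res$neuron[res$essential], 5L)

  # p-values agree with the stats::t.test oracle against the layer mean
  mu0 <- mean(base)
  for (i in c(2, 5, 7))
    expect_equal(res$p_value[i], t.test(base[, i], mu = mu0)$p.value)
})

test_that("a layer of identical relevances selects nothing", {
  flat <- matrix(2.5, 20, 6)
  res <- essential_neurons(make_profile(list(flat)))
  expect_false(any(res$essential))
  expect_true(all(res$p_value == 1))
})

test_that("alpha = 1 degenerates to the upper-tail rule", {
  set.seed(8)
  sc <- matrix(rnorm(40 * 5), 40, 5)
  res <- essential_neurons(make_profile(list(sc)), alpha = 1)
  expect_identical(res$essential, res$mean_relevance > mean(sc))
})

test_that("neuron selection is invariant under affine rescaling of a layer", {
  set.seed(12)
  sc <- matrix(rnorm(25 * 7, 2), 25, 7)
  sc[, 3] <- sc[, 3] + 4
  a <- essential_neurons(make_profile(list(sc)))
  b <- essential_neurons(make_profile(list(3.7 * sc - 11)))
  expect_identical(a$essential, b$essential)
  expect_equal(a$p_value, b$p_value)
})

test_that("fewer than three samples is an error", {
  expect_error(essential_neurons(make_profile(list(matrix(1:4, 2, 2)))),
               "3 samples")
})

test_that("a dominating input gene is detected by back-attribution", {
  # layer 1: neuron 1 driven overwhelmingly by gene 2
  net <- init_network(c(4, 3, 2), c("linear", "softmax"), seed = 2)
  net$layers[[1]]$W[] <- 0.05
  net$layers[[1]]$W[2, 1] <- 5
  set.seed(3)
  X <- matrix(rnorm(30 * 4, mean = 1, sd = 0.3), 30, 4)
  colnames(X) <- paste0("g", 1:4)
  res <- essential_genes(net, X, reference = numeric(4), layer = 1, neuron = 1)
  expect_identical(res$gene[res$essential], "g2")

  # a gene pinned at its reference value contributes exactly zero
  X2 <- X; X2[, 3] <- 0
  res2 <- essential_genes(net, X2, reference = numeric(4), layer = 1, neuron = 1)
  expect_equal(res2$mean_contribution[3], 0)
  expect_false(res2$essential[3])
})

test_that("hypergeometric enrichment matches exact enumeration", {
  background <- sprintf("G%03d", 1:100)
  gene_list <- background[1:10]
  sets <- list(HIT = c(background[6:20], background[90:94]),  # size 20, overlap 5
               MISS = background[50:69])                      # size 20, overlap 0
  res <- ora_fisher(gene_list, sets, background)

  # P(K >= 5) with N=100, K=20, n=10 by direct enumeration
  enum <- sum(sapply(5:10, function(k)
    choose(20, k) * choose(80, 10 - k) / choose(100, 10)))
  expect_equal(res$p_value[res$set == "HIT"], enum, tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "MISS"], 1.0)
  expect_identical(res$set[1], "HIT")  # sorted by p
  expect_equal(res$overlap[res$set == "HIT"], 5)

  # one-sided fisher.test cross-check
  ft <- fisher.test(matrix(c(5, 15, 5, 75), 2, 2), alternative = "greater")
  expect_equal(res$p_value[res$set == "HIT"], ft$p.value, tolerance = 1e-12)
})

test_that("enrichment p-values behave monotonically and BH dominates raw p", {
  background <- sprintf("G%03d", 1:60)
  gene_list <- background[1:12]
  sets <- lapply(c(2, 5, 8, 11), function(k)
    c(background[seq_len(k)], background[30:(44 - k)]))
  names(sets) <- paste0("OV", c(2, 5, 8, 11))
  res <- ora_fisher(gene_list, sets, background)
  res <- res[match(names(sets), res$set), ]
  expect_true(all(diff(res$p_value) < 0))        # larger overlap, smaller p
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_identical(order(res$p_adjusted), order(res$p_value))

  # a list identical to a set over that background is maximally enriched
  self <- ora_fisher(background[1:15], list(S = background[1:15]), background[1:15])
  expect_equal(self$p_value, 1)  # only one attainable table for these margins

  expect_error(ora_fisher(c("NOT_THERE"), sets, background), "outside")
  expect_error(ora_fisher(gene_list, sets, character(0)), "empty")
})

test_that("interpret_model assembles neuron and gene reports per class", {
  cohort <- simulate_cohort(sim_config(n_genes = 40,
                                       class_counts = c(primary = 30, bone = 20),
                                       planted_per_site = 8, effect_size = 3,
                                       seed = 6))
  data <- cohort$data
  model <- train_site_model(data, rownames(data$matrix), hidden = c(10, 6),
                            config = train_config("categorical_cross_entropy",
                                                  epochs = 40, seed = 2))
  gmt <- list(sets = list(PLANTED = cohort$truth$planted$bone,
                          RANDOM = rownames(data$matrix)[37:40]),
              descriptions = c(PLANTED = "", RANDOM = ""))
  class(gmt) <- "gene_set_collection"
  rep <- interpret_model(model, data, gmt, alpha = 0.05,
                         max_neurons_per_layer = 3)
  expect_named(rep, c("primary", "bone"))
  expect_true(all(rep$bone$neurons$p_value >= 0 & rep$bone$neurons$p_value <= 1))
  expect_true(all(unlist(rep$bone$genes) %in% model$panel_genes))
  for (tab in rep$bone$enrichment)
    expect_true(all(tab$overlap <= pmin(tab$set_size, tab$list_size)))
})
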