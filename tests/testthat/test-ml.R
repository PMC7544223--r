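test_that("gene feature vectors collapse by sum and mean consistently", {
  b <- build_bitome(paste(rep("ACGT", 25), collapse = ""))
  genes <- feature_tbl(id = "g1", category = "cds", strand = "+",
                       intervals = list(iv(0, 4)))
  gs <- gene_feature_vectors(b, genes, "sum")
  expect_equal(sum(gs$x), 8) # 2 bits/bp x 4 bp
  gm <- gene_feature_vectors(b, genes, "mean")
  expect_equal(sum(gm$x), 2)
  # collapse equivalence: mean = sum / gene length, elementwise
  expect_equal(gm$x, gs$x / 4)
})

test_that("50 synthetic genes match a per-gene extract+sum loop oracle", {
  b <- small_bitome()
  ann <- small_ann()
  genes <- head(ann$features[ann$features$category == "cds", ], 50)
  gfm <- gene_feature_vectors(b, genes, "sum")
  for (k in seq_len(nrow(genes))) {
    sp <- span_of(genes$intervals[[k]])
    sub <- bitome_extract(b, sp[1], sp[2])
    expect_equal(unname(gfm$x[k, ]), unname(Matrix::rowSums(sub$matrix)),
                 label = genes$id[k])
  }
  # mean-collapse equals sum-collapse / length for multi-gene input
  gmm <- gene_feature_vectors(b, genes, "mean")
  lens <- purrr::map_int(genes$intervals, ~ sum(.x$end - .x$start))
  expect_equal(gmm$x, gfm$x / lens)
})

test_that("SNP labels flag genes containing at least one SNP position", {
  genes <- feature_tbl(id = c("g1", "g2"), category = "cds", strand = "+",
                       intervals = list(iv(10, 20), iv(30, 40)))
  sn <- tibble::tibble(position = 15L, ref = "A", alt = "G", source_id = "e")
  expect_equal(unname(label_from_snps(genes, sn)), c(1L, 0L))
  none <- sn[0, ]
  expect_equal(unname(label_from_snps(genes, none)), c(0L, 0L))
  # membership oracle on random data
  set.seed(51)
  pos <- sample.int(2000, 60) - 1L
  genes2 <- feature_tbl(id = sprintf("g%02d", 1:20), category = "cds",
                        strand = "+",
                        intervals = purrr::map(0:19, ~ iv(.x * 100, .x * 100 + 70)))
  sn2 <- tibble::tibble(position = pos, ref = "A", alt = "G", source_id = "e")
  lab <- label_from_snps(genes2, sn2)
  oracle <- vapply(0:19, function(g)
    as.integer(any(pos >= g * 100 & pos < g * 100 + 70)), integer(1))
  expect_equal(unname(lab), oracle)
})

test_that("min/max normalization is columnwise, degenerate-safe and idempotent", {
  m <- cbind(a = c(0, 5, 10), b = c(3, 3, 3), c = c(-1, 0, 1))
  n1 <- minmax_normalize(m)
  expect_equal(unname(n1[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(n1[, "b"]), c(0, 0, 0))
  expect_equal(minmax_normalize(n1), n1)
  expect_true(all(n1 >= 0 & n1 <= 1))
})

test_that("lockbox split is stratified, seeded and leak-free", {
  gfm <- random_gfm(100, 10, seed = 1)
  gfm <- set_labels(gfm, setNames(rep(c(1L, 0L), c(60, 40)), rownames(gfm$x)))
  sp <- lockbox_split(gfm, 0.2, seed = 3)
  expect_equal(nrow(sp$lockbox$x), 20)
  expect_equal(sum(sp$lockbox$labels == 1), 12)
  expect_equal(sum(sp$lockbox$labels == 0), 8)
  # same seed reproduces; different seed differs
  sp2 <- lockbox_split(gfm, 0.2, seed = 3)
  expect_identical(rownames(sp$lockbox$x), rownames(sp2$lockbox$x))
  sp3 <- lockbox_split(gfm, 0.2, seed = 4)
  expect_false(identical(rownames(sp$lockbox$x), rownames(sp3$lockbox$x)))
  # leakage guard on gene ids
  expect_length(intersect(rownames(sp$train$x), rownames(sp$lockbox$x)), 0)
  expect_setequal(c(rownames(sp$train$x), rownames(sp$lockbox$x)),
                  rownames(gfm$x))
  # class proportions stay within one member across seeds
  for (s in 1:20) {
    lk <- lockbox_split(gfm, 0.2, seed = s)$lockbox
    expect_lte(abs(sum(lk$labels == 1) - 12), 1)
  }
  tiny <- set_labels(random_gfm(5, 3, 1), c(1L, 0L, 0L, 0L, 0L))
  expect_error(lockbox_split(tiny), "at least 2")
})

test_that("downsampling balances the majority class without replacement", {
  gfm <- set_labels(random_gfm(300, 5, 2),
                    setNames(rep(c(1L, 0L), c(200, 100)), NULL))
  ds <- downsample_majority(gfm, seed = 1)
  expect_equal(as.integer(table(ds$labels)), c(100L, 100L))
  expect_false(any(duplicated(rownames(ds$x))))
  bal <- set_labels(random_gfm(10, 3, 3), rep(c(0L, 1L), 5))
  expect_identical(downsample_majority(bal, 1), bal)
  # union over seeds covers the majority class
  seen <- character()
  for (s in 1:40) {
    seen <- union(seen, rownames(downsample_majority(gfm, s)$x))
  }
  expect_setequal(seen, rownames(gfm$x))
})

test_that("cross-validation separates separable data and not shuffled labels", {
  set.seed(61)
  n <- 300
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("f%02d", 1:10)))
  y <- as.integer(x[, 1] + x[, 2] > 0)
  x[, 1] <- x[, 1] + 2 * y # widen the margin
  gfm <- set_labels(as_gene_feature_matrix(minmax_normalize(x)), y)
  spec <- model_spec_svm_l1(C = 1)
  ev <- cv_evaluate(spec, gfm, seed = 5)
  expect_gt(ev$mean_accuracy, 0.9)
  expect_equal(nrow(ev$runs), 25)
  expect_equal(ev$mean_accuracy, mean(ev$runs$accuracy)) # hand aggregation
  expect_equal(ev$sd_accuracy, sd(ev$runs$accuracy))
  ctrl <- shuffled_label_control(spec, gfm, seed = 5)
  expect_lt(ctrl$mean_accuracy, 0.62)
  expect_lt(ctrl$mean_accuracy, ev$mean_accuracy)
})

test_that("the sequence-only baseline restricts features to nucleobase rows", {
  b <- small_bitome()
  ann <- small_ann()
  genes <- ann$features[ann$features$category == "cds", ]
  gfm <- minmax_normalize(gene_feature_vectors(b, genes, "mean"))
  set.seed(71)
  gfm <- set_labels(gfm, rbinom(nrow(gfm$x), 1, 0.5))
  # tiny class sizes here make glmnet grumble; the check is the restriction
  ev <- suppressWarnings(sequence_only_baseline(model_spec_logistic(), gfm,
                                                k = 2, n_downsamples = 1,
                                                seed = 2))
  expect_s3_class(ev, "bitome_eval")
})

test_that("the L1 SVM solver honors sign, shrinkage and the objective", {
  # 1-D separable data: coefficient sign follows class ordering
  x <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1,
              dimnames = list(paste0("s", 1:6), "f1"))
  y <- c(0, 0, 0, 1, 1, 1)
  f <- fit_svm_l1(x, y, C = 10)
  expect_gt(f$w[1], 0)
  expect_equal(unname(sign(drop(x %*% f$w + f$b))), ifelse(y == 1, 1, -1))
  # strong L1 (tiny C) drives all coefficients to zero
  f0 <- fit_svm_l1(x, y, C = 1e-6)
  expect_equal(unname(f0$w), 0)
  # flipping labels flips the coefficient
  f2 <- fit_svm_l1(x, 1 - y, C = 10)
  expect_lt(f2$w[1], 0)
})

test_that("L1 SVM support agrees with L1 logistic regression on planted data", {
  set.seed(81)
  n <- 250; p <- 40
  x <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("f%02d", 1:p)))
  eta <- 8 * x[, 3] - 8 * x[, 7]
  y <- rbinom(n, 1, plogis(eta))
  sv <- fit_svm_l1(x, y, C = 0.5)
  lg <- glmnet::glmnet(x, y, family = "binomial", alpha = 1, lambda = 0.02)
  sv_top <- order(abs(sv$w), decreasing = TRUE)[1:2]
  lg_top <- order(abs(as.numeric(lg$beta)), decreasing = TRUE)[1:2]
  expect_setequal(sv_top, c(3, 7))
  expect_setequal(lg_top, c(3, 7))
  expect_gt(sv$w[3], 0); expect_lt(sv$w[7], 0)
})

test_that("lockbox evaluation reports accuracy, confusion and AUC correctly", {
  # hand-checkable 20-example lockbox
  x <- matrix(seq(-1, 1, length.out = 20), ncol = 1,
              dimnames = list(sprintf("g%02d", 1:20), "f1"))
  y <- as.integer(x[, 1] > 0)
  y[1] <- 1L # one positive deep in negative territory
  lock <- set_labels(as_gene_feature_matrix(x), y)
  model <- structure(list(
    coefficients = tibble::tibble(feature = "f1", coefficient = 1),
    intercept = 0, spec = "manual", converged = TRUE,
    fit = list(w = 1, b = 0),
    decision = function(fit, x) drop(x %*% fit$w + fit$b)), class = "bitome_model")
  ev <- evaluate_lockbox(model, lock)
  expect_equal(ev$mean_accuracy, 19 / 20)
  expect_equal(unname(ev$confusion[1, 1]), 1) # all true 0s predicted 0
  expect_equal(unname(ev$confusion[2, 2]), 10 / 11)
  # rank AUC by hand: one misranked positive below all 9 negatives
  expect_equal(ev$auc, (10 * 9 + 0) / (11 * 9), tolerance = 1e-12)

  # perfect predictions give the identity confusion matrix
  y2 <- as.integer(x[, 1] > 0)
  ev2 <- evaluate_lockbox(model, set_labels(as_gene_feature_matrix(x), y2))
  expect_equal(unname(ev2$confusion), diag(2))
  expect_equal(ev2$auc, 1)
})

test_that("feature importance ranks nonzero coefficients deterministically", {
  gfm <- random_gfm(200, 30, seed = 4)
  lab <- generate_labels(gfm, effects = c(feat005 = 9, feat020 = -9),
                         intercept = 0, seed = 7)
  gfm <- minmax_normalize(set_labels(gfm, lab$labels))
  m1 <- train_final_model(gfm, model_spec_svm_l1(C = 0.5), seed = 2)
  m2 <- train_final_model(gfm, model_spec_svm_l1(C = 0.5), seed = 2)
  expect_identical(feature_importance(m1), feature_importance(m2))
  imp <- feature_importance(m1)
  expect_setequal(head(imp$feature, 2), c("feat005", "feat020"))
  expect_gt(imp$coefficient[imp$feature == "feat005"], 0)
  # all-zero model gives an empty ranking
  z <- train_final_model(gfm, model_spec_svm_l1(C = 1e-7), seed = 2)
  expect_equal(nrow(feature_importance(z)), 0)
})

test_that("models persist to JSON and predict identically after reload", {
  gfm <- random_gfm(60, 8, seed = 6)
  gfm <- set_labels(gfm, as.integer(gfm$x[, 1] > 0.5))
  m <- train_final_model(gfm, model_spec_svm_l1(C = 1), seed = 1)
  tf <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, tf)
  m2 <- read_model_json(tf)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$decision(m2$fit, gfm$x), m$decision(m$fit, gfm$x))
})
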