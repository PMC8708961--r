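small_cfg <- function(...) {
  train_config(batch_size = 4, epochs = 1, probe_epochs = 5, seed = 1, ...)
}

small_enc_cfg <- encoder_config(conv_filters = c(2, 3, 4), fc_sizes = c(8, 4),
                                embedding_dim = 4)

test_that("one contrastive epoch on eight images runs end to end", {
  b <- tiny_batch(n = 8)
  set.seed(1)
  enc <- build_encoder(small_enc_cfg, c(16, 16, 3))
  head <- build_projection_head(4, 4)
  ph1 <- train_contrastive_phase1(enc, head, b$x, b$labels, small_cfg())
  expect_true(all(is.finite(ph1$trace$loss)))
  expect_equal(nrow(ph1$trace), 1)
  ph2 <- train_classifier_phase2(ph1$encoder, b$x, b$labels, small_cfg())
  p <- classifier_forward(ph2$classifier, encoder_forward(ph1$encoder, b$x))
  expect_true(all(p > 0 & p < 1))
})

test_that("phase 2 leaves the encoder weights bitwise untouched", {
  b <- tiny_batch(n = 8)
  set.seed(2)
  enc <- build_encoder(small_enc_cfg, c(16, 16, 3))
  before <- serialize(enc$params, NULL)
  invisible(train_classifier_phase2(enc, b$x, b$labels, small_cfg()))
  expect_identical(serialize(enc$params, NULL), before)
})

test_that("contrastive phase separates a separable toy problem", {
  # two classes of images with very different intensity structure
  set.seed(3)
  n <- 16
  x <- array(0, c(16, 16, 3, n))
  lab <- rep(0:1, each = n / 2)
  for (i in seq_len(n)) {
    base <- matrix(rnorm(256, mean = ifelse(lab[i] == 1, 0, 3)), 16)
    if (lab[i] == 1) base[4:8, 4:8] <- base[4:8, 4:8] + 6
    x[, , 1, i] <- base; x[, , 2, i] <- base; x[, , 3, i] <- base
  }
  set.seed(3)
  enc <- build_encoder(small_enc_cfg, c(16, 16, 3))
  head <- build_projection_head(4, 4)
  cfg <- train_config(batch_size = 8, epochs = 15, learning_rate = 0.01,
                      tau = 0.5, seed = 3, augment = aug_config(1, 2, 0.05))
  ph1 <- train_contrastive_phase1(enc, head, x, lab, cfg)
  z <- head_forward(ph1$head, encoder_forward(ph1$encoder, x))
  s <- tcrossprod(z)
  same <- outer(lab, lab, "==")
  diag(same) <- NA
  expect_gt(mean(s[which(same)]), mean(s[which(!same)]))
})

test_that("probe training loss is non-increasing on a separable toy set", {
  set.seed(4)
  b <- tiny_batch(n = 24, lesion_amplitude = 5)
  enc <- build_encoder(small_enc_cfg, c(16, 16, 3))
  cfg <- train_config(batch_size = 24, epochs = 1, probe_epochs = 40,
                      learning_rate = 0.05, seed = 4)
  ph2 <- train_classifier_phase2(enc, b$x, b$labels, cfg)
  # epoch-mean trace, allowing tiny optimizer noise
  expect_true(all(diff(ph2$trace$loss) < 0.01))
  expect_lt(ph2$trace$loss[40], ph2$trace$loss[1])
})

test_that("a random encoder scores near chance on balanced toy data", {
  set.seed(5)
  x <- array(runif(16 * 16 * 3 * 40), c(16, 16, 3, 40))
  lab <- rep(0:1, 20)
  enc <- build_encoder(small_enc_cfg, c(16, 16, 3))
  ph2 <- train_classifier_phase2(enc, x, lab,
                                 train_config(batch_size = 8, epochs = 1,
                                              probe_epochs = 3, seed = 5))
  p <- classifier_forward(ph2$classifier, encoder_forward(enc, x))
  expect_equal(roc_auc(lab, p)$auc, 0.5, tolerance = 0.35)
})

test_that("supervised baseline smoke run trains and predicts", {
  b <- tiny_batch(n = 12)
  model <- train_supervised_baseline(b$x, b$labels,
                                     small_cfg(method = "supervised"),
                                     encoder_cfg = small_enc_cfg)
  expect_s3_class(model, "bone_scan_model")
  p <- predict(model, b$x)
  expect_length(p, 12)
  expect_true(all(is.finite(model$trace$loss)))
  g <- glance(model)
  expect_equal(g$method, "supervised")
  expect_equal(nrow(tidy(model)), 1)
})

test_that("training is reproducible under a fixed seed", {
  b <- tiny_batch(n = 10)
  cfg <- train_config(batch_size = 4, epochs = 2, probe_epochs = 4, seed = 9)
  m1 <- train_supcon(b$x, b$labels, cfg, encoder_cfg = small_enc_cfg)
  m2 <- train_supcon(b$x, b$labels, cfg, encoder_cfg = small_enc_cfg)
  expect_identical(predict(m1, b$x), predict(m2, b$x))
  expect_identical(m1$trace, m2$trace)
})

test_that("single-class data triggers the degeneracy warning", {
  b <- tiny_batch(n = 6)
  x <- b$x
  expect_warning(train_classifier_phase2(build_encoder(small_enc_cfg, c(16, 16, 3)),
                                         x, rep(0L, 6), small_cfg()),
                 "single-class")
  expect_error(train_supervised_baseline(x, integer(0), small_cfg()), "empty")
})

test_that("stratified folds meet the exact class-count contract", {
  labels <- rep(c(1L, 0L), c(456, 5159))
  folds <- stratified_kfold(labels, k = 6, seed = 2)
  expect_setequal(unique(folds), 1:6)
  for (f in 1:6) {
    expect_equal(sum(labels == 1 & folds == f), 76)
    expect_true(sum(labels == 0 & folds == f) %in% c(859, 860))
  }
  # folds partition all records
  expect_equal(sort(unlist(lapply(1:6, function(f) which(folds == f)))),
               seq_along(labels))
})

test_that("k = 2 on a four-record set puts one of each class per fold", {
  folds <- stratified_kfold(c(0, 0, 1, 1), k = 2, seed = 1)
  for (f in 1:2) {
    expect_equal(sum(folds == f & c(0, 0, 1, 1) == 0), 1)
    expect_equal(sum(folds == f & c(0, 0, 1, 1) == 1), 1)
  }
  expect_error(stratified_kfold(c(0, 0, 0, 1), k = 2), "at least k")
})

test_that("fold balance matches an independent stratified splitter", {
  set.seed(11)
  labels <- rbinom(300, 1, 0.2)
  ours <- stratified_kfold(labels, k = 5, seed = 3)
  ref <- caret::createFolds(factor(labels), k = 5)
  our_pos <- sort(table(ours[labels == 1]))
  ref_pos <- sort(vapply(ref, function(i) sum(labels[i] == 1), numeric(1)))
  expect_equal(as.numeric(our_pos), as.numeric(ref_pos))
})
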