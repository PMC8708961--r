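#' Training configuration
#'
#' Defaults follow the reference protocol: 50 epochs, learning rate 0.001,
#' Adam, batches of 256 images. Desk-scale experiments pass smaller values
#' explicitly.
#'
#' @param batch_size Images per batch (>= 4); phase 1 contrasts two views per
#'   image, so the contrastive batch holds `2 * batch_size` embeddings.
#' @param epochs Training epochs (>= 1, fixed; no early stopping).
#' @param learning_rate Adam step size (> 0).
#' @param optimizer Only `"adam"` is implemented.
#' @param tau Contrastive temperature for phase 1 (default 0.1).
#' @param seed Integer seed controlling initialization, batching, augmentation.
#' @param method `"supcon"` (two-phase) or `"supervised"` (end-to-end).
#' @param backbone Encoder choice, see [encoder_config()].
#' @param k_folds Folds for stratified cross-validation (default 6).
#' @param threshold Decision threshold for confusion matrices (default 0.5).
#' @param balanced_batches Draw phase-1 batches with balanced classes so most
#'   anchors have positives (recommended at low prevalence).
#' @param probe_epochs Epochs for the phase-2 linear probe (default 100).
#'   The probe is a convex fit on cached frozen-encoder embeddings, so
#'   training it to convergence is cheap and is the standard linear-evaluation
#'   protocol; the representation budgets of the two arms stay matched.
#' @param proj_dim Projection-head width (default 32).
#' @param augment An [aug_config()] for the contrastive views.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 256, epochs = 50, learning_rate = 0.001,
                         optimizer = "adam", tau = 0.1, seed = 1L,
                         method = c("supcon", "supervised"),
                         backbone = "cnn_based", k_folds = 6, threshold = 0.5,
                         balanced_batches = TRUE, probe_epochs = 100,
                         proj_dim = 32, augment = aug_config()) {
  method <- match.arg(method)
  if (batch_size < 4) stop("batch_size must be at least 4", call. = FALSE)
  if (epochs < 1) stop("epochs must be at least 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (optimizer != "adam") stop("only the adam optimizer is implemented", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer, tau = tau,
                 seed = as.integer(seed), method = method, backbone = backbone,
                 k_folds = as.integer(k_folds), threshold = threshold,
                 balanced_batches = balanced_batches,
                 probe_epochs = as.integer(probe_epochs),
                 proj_dim = as.integer(proj_dim), augment = augment),
            class = "train_config")
}

# ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# batch index generator: plain shuffled epochs, or class-balanced draws
make_batches <- function(labels, batch_size, balanced) {
  n <- length(labels)
  n_batches <- max(1L, floor(n / batch_size))
  if (!balanced || length(unique(labels)) < 2) {
    ord <- sample.int(n)
    return(lapply(seq_len(n_batches), function(b) {
      ord[((b - 1) * batch_size + 1):min(b * batch_size, n)]
    }))
  }
  pos <- which(labels == 1); neg <- which(labels == 0)
  half <- batch_size %/% 2
  lapply(seq_len(n_batches), function(b) {
    sample(c(sample(pos, half, replace = length(pos) < half),
             sample(neg, batch_size - half, replace = length(neg) < batch_size - half)))
  })
}

check_trainable <- function(labels) {
  if (length(labels) == 0) stop("empty dataset", call. = FALSE)
  if (length(unique(labels)) < 2) {
    warning("single-class dataset: contrastive structure is degenerate",
            call. = FALSE)
  }
  invisible(labels)
}

#' Phase 1: contrastive training of the encoder
#'
#' Minimizes the supervised contrastive loss over two-view batches for the
#' configured number of epochs, updating the encoder and the projection head
#' with Adam. The head is detached afterwards (returned separately); only the
#' encoder proceeds to phase 2.
#'
#' @param encoder A `cnn_encoder` (from [build_encoder()]).
#' @param head A `projection_head` (from [build_projection_head()]).
#' @param x Preprocessed image batch, array `(H, W, 3, N)`.
#' @param labels Binary label per image.
#' @param cfg A [train_config()] with `method = "supcon"`.
#' @return List with `encoder`, `head`, and `trace` (tibble of per-epoch mean
#'   per-anchor loss).
#' @export
train_contrastive_phase1 <- function(encoder, head, x, labels, cfg) {
  check_trainable(labels)
  opt_enc <- adam_init(encoder$params)
  opt_head <- adam_init(head$params)
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    batches <- make_batches(labels, cfg$batch_size, cfg$balanced_batches)
    epoch_losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      views <- make_views(x[, , , idx, drop = FALSE], labels[idx], cfg$augment)
      fwd <- encoder_forward(encoder, views$x, keep_cache = TRUE)
      hfwd <- head_forward(head, fwd$emb, keep_cache = TRUE)
      batch_obj <- embedding_batch(hfwd$z, views$labels, cfg$tau, tol = 1e-6)
      l <- supcon_loss(batch_obj, per_anchor = TRUE)
      dz <- supcon_loss_grad(batch_obj)
      hb <- head_backward(head, hfwd$cache, dz)
      grads_enc <- encoder_backward(encoder, fwd$cache, hb$demb)
      st <- adam_step(encoder$params, grads_enc, opt_enc, cfg$learning_rate)
      encoder$params <- st$params; opt_enc <- st$state
      st <- adam_step(head$params, list(Wp = hb$dWp, bp = hb$dbp), opt_head,
                      cfg$learning_rate)
      head$params <- st$params; opt_head <- st$state
      epoch_losses[b] <- l$mean
    }
    trace[epoch] <- mean(epoch_losses)
  }
  list(encoder = encoder, head = head,
       trace = tibble::tibble(epoch = seq_len(cfg$epochs), loss = trace,
                              phase = "contrastive"))
}

#' Phase 2: linear probe on the frozen encoder
#'
#' The encoder is frozen (its weights are not touched); its embeddings of the
#' training images are computed once and a single affine + logistic layer is
#' trained on them with cross-entropy and Adam.
#'
#' @param encoder A trained `cnn_encoder` (left unchanged).
#' @param x,labels Training images and labels.
#' @param cfg A [train_config()].
#' @return List with `classifier` and `trace`.
#' @export
train_classifier_phase2 <- function(encoder, x, labels, cfg) {
  emb <- encoder_forward(encoder, x)   # label checks happen in the probe
  train_linear_probe(emb, labels, cfg)
}

#' Train the linear probe on fixed embeddings
#'
#' Cross-entropy training (Adam, mini-batches) of a single affine + logistic
#' layer on precomputed representations; this is the workhorse of
#' [train_classifier_phase2()] and follows the standard linear-evaluation
#' protocol.
#'
#' @param emb `N x d` embedding matrix.
#' @param labels Binary label per row.
#' @param cfg A [train_config()]; `probe_epochs` controls the budget.
#' @return List with `classifier` and `trace`.
#' @export
train_linear_probe <- function(emb, labels, cfg) {
  check_trainable(labels)
  clf <- build_linear_classifier(ncol(emb))
  opt <- adam_init(clf$params)
  n <- length(labels)
  n_epochs <- if (is.null(cfg$probe_epochs)) cfg$epochs else cfg$probe_epochs
  trace <- numeric(n_epochs)
  for (epoch in seq_len(n_epochs)) {
    batches <- make_batches(labels, min(cfg$batch_size, n), FALSE)
    epoch_losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      e <- emb[idx, , drop = FALSE]
      p <- classifier_forward(clf, e)
      y <- labels[idx]
      # d(mean CE)/d(logit) = (p - y) / n_batch
      dlogit <- matrix((p - y) / length(idx), ncol = 1)
      grads <- list(w = crossprod(e, dlogit), b = sum(dlogit))
      st <- adam_step(clf$params, grads, opt, cfg$learning_rate)
      clf$params <- st$params; opt <- st$state
      epoch_losses[b] <- cross_entropy(p, y)
    }
    trace[epoch] <- mean(epoch_losses)
  }
  list(classifier = clf,
       trace = tibble::tibble(epoch = seq_len(n_epochs), loss = trace,
                              phase = "linear_probe"))
}

#' End-to-end supervised baseline
#'
#' Trains the same backbone with a logistic head by plain cross-entropy for
#' the same budget — the comparison arm for the contrastive method.
#'
#' @param x,labels Training images and labels.
#' @param cfg A [train_config()] (method `"supervised"`).
#' @param input_shape Image shape `(H, W, C)`; taken from `x` by default.
#' @param encoder_cfg An [encoder_config()].
#' @return A `bone_scan_model` with `method = "supervised"`.
#' @export
train_supervised_baseline <- function(x, labels, cfg,
                                      input_shape = dim(x)[1:3],
                                      encoder_cfg = NULL) {
  check_trainable(labels)
  set.seed(cfg$seed)
  if (is.null(encoder_cfg)) encoder_cfg <- encoder_config(backbone = cfg$backbone)
  encoder <- build_encoder(encoder_cfg, input_shape)
  clf <- build_linear_classifier(encoder_cfg$embedding_dim)
  opt_enc <- adam_init(encoder$params)
  opt_clf <- adam_init(clf$params)
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    batches <- make_batches(labels, cfg$batch_size, FALSE)
    epoch_losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      fwd <- encoder_forward(encoder, x[, , , idx, drop = FALSE], keep_cache = TRUE)
      p <- classifier_forward(clf, fwd$emb)
      y <- labels[idx]
      dlogit <- matrix((p - y) / length(idx), ncol = 1)
      grads_clf <- list(w = crossprod(fwd$emb, dlogit), b = sum(dlogit))
      demb <- dlogit %*% t(clf$params$w)
      grads_enc <- encoder_backward(encoder, fwd$cache, demb)
      st <- adam_step(encoder$params, grads_enc, opt_enc, cfg$learning_rate)
      encoder$params <- st$params; opt_enc <- st$state
      st <- adam_step(clf$params, grads_clf, opt_clf, cfg$learning_rate)
      clf$params <- st$params; opt_clf <- st$state
      epoch_losses[b] <- cross_entropy(p, y)
    }
    trace[epoch] <- mean(epoch_losses)
  }
  new_bone_scan_model(encoder, clf, cfg, "supervised",
                      tibble::tibble(epoch = seq_len(cfg$epochs), loss = trace,
                                     phase = "supervised"))
}

#' Train the full two-phase contrastive model
#'
#' Convenience wrapper: builds the encoder and projection head, runs
#' [train_contrastive_phase1()], then [train_classifier_phase2()] on the
#' frozen encoder.
#'
#' @inheritParams train_supervised_baseline
#' @return A `bone_scan_model` with `method = "supcon"`.
#' @export
train_supcon <- function(x, labels, cfg, input_shape = dim(x)[1:3],
                         encoder_cfg = NULL) {
  set.seed(cfg$seed)
  if (is.null(encoder_cfg)) encoder_cfg <- encoder_config(backbone = cfg$backbone)
  encoder <- build_encoder(encoder_cfg, input_shape)
  head <- build_projection_head(encoder_cfg$embedding_dim, cfg$proj_dim)
  ph1 <- train_contrastive_phase1(encoder, head, x, labels, cfg)
  ph2 <- train_classifier_phase2(ph1$encoder, x, labels, cfg)
  new_bone_scan_model(ph1$encoder, ph2$classifier, cfg, "supcon",
                      rbind(ph1$trace, ph2$trace))
}

new_bone_scan_model <- function(encoder, classifier, cfg, method, trace) {
  structure(list(encoder = encoder, classifier = classifier, cfg = cfg,
                 method = method, trace = trace),
            class = "bone_scan_model")
}

#' @export
print.bone_scan_model <- function(x, ...) {
  cat(sprintf("bone_scan_model (%s, %s backbone): %d epochs, final loss %.4f\n",
              x$method, x$encoder$cfg$backbone, max(x$trace$epoch),
              x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' Predict metastasis probabilities
#'
#' @param object A `bone_scan_model`.
#' @param x Image batch `(H, W, 3, N)`.
#' @param ... Unused.
#' @return Probability vector.
#' @export
predict.bone_scan_model <- function(object, x, ...) {
  classifier_forward(object$classifier, encoder_forward(object$encoder, x))
}

#' Embed images with a trained model's encoder
#' @param model A `bone_scan_model`.
#' @param x Image batch `(H, W, 3, N)`.
#' @return `N x embedding_dim` matrix.
#' @export
embed_images <- function(model, x) {
  encoder_forward(model$encoder, x)
}

#' @rdname train_supcon
#' @param x A `bone_scan_model`.
#' @param ... Unused.
#' @export
tidy.bone_scan_model <- function(x, ...) x$trace

#' @rdname train_supcon
#' @export
glance.bone_scan_model <- function(x, ...) {
  tibble::tibble(method = x$method, backbone = x$encoder$cfg$backbone,
                 epochs = max(x$trace$epoch),
                 final_loss = x$trace$loss[nrow(x$trace)],
                 n_parameters = n_parameters(x$encoder))
}

#' Stratified k-fold assignment
#'
#' Partitions record indices into k folds so that each fold's class mix
#' matches the whole set as closely as integer counts allow: within each
#' class, shuffled indices are dealt round-robin, so per-fold class counts
#' differ by at most one.
#'
#' @param labels Binary label vector.
#' @param k Number of folds (>= 2); every class must have at least k members.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold index (1..k) per record, with attribute `k`.
#' @export
stratified_kfold <- function(labels, k = 6, seed = 1L) {
  check_binary_labels(labels)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs at least k members (smallest has ",
         min(counts), ")", call. = FALSE)
  }
  folds <- integer(length(labels))
  with_preserved_rng(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(folds, k = as.integer(k))
}
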