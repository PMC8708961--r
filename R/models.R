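#' Encoder architecture configuration
#'
#' The built-in `cnn_based` backbone is a compact convolutional encoder:
#' three 3x3 convolution + 2x2 max-pooling blocks, a flatten layer, and two
#' fully connected layers whose second output is the embedding. Larger
#' backbones (`resnet50v2`, `densenet121`) are pluggable via
#' [register_backbone()]; their internals are not reimplemented here.
#'
#' @param conv_filters Three filter counts for the convolution blocks.
#' @param kernel Convolution kernel size (square, odd).
#' @param pool Pooling window; only 2x2 max pooling is supported.
#' @param fc_sizes Two fully connected widths; the second is the embedding.
#' @param embedding_dim Representation width (>= 2); must equal `fc_sizes[2]`.
#' @param backbone `"cnn_based"`, `"resnet50v2"` or `"densenet121"`.
#' @param activation Nonlinearity; only `"relu"` is implemented.
#' @return An `encoder_config`.
#' @export
encoder_config <- function(conv_filters = c(16, 32, 64), kernel = c(3, 3),
                           pool = c(2, 2), fc_sizes = c(128, 64),
                           embedding_dim = 64,
                           backbone = c("cnn_based", "resnet50v2", "densenet121"),
                           activation = "relu") {
  backbone <- match.arg(backbone)
  if (length(conv_filters) != 3) stop("exactly three conv/pool blocks", call. = FALSE)
  if (length(fc_sizes) != 2) stop("exactly two fully connected layers", call. = FALSE)
  if (embedding_dim < 2) stop("embedding_dim must be at least 2", call. = FALSE)
  if (embedding_dim != fc_sizes[2]) {
    stop("embedding_dim must equal the second fully connected width", call. = FALSE)
  }
  if (kernel[1] != kernel[2] || kernel[1] %% 2 == 0) {
    stop("kernel must be square with odd size", call. = FALSE)
  }
  if (!identical(as.numeric(pool), c(2, 2))) stop("only 2x2 max pooling", call. = FALSE)
  if (activation != "relu") stop("only relu activation is implemented", call. = FALSE)
  structure(list(conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), fc_sizes = as.integer(fc_sizes),
                 embedding_dim = as.integer(embedding_dim), backbone = backbone,
                 activation = activation),
            class = "encoder_config")
}

.backbone_registry <- new.env(parent = emptyenv())

#' Register an external encoder backbone
#'
#' Plug-in point for larger architectures: `builder(cfg, input_shape)` must
#' return an object with the same forward contract as the built-in encoder
#' (a map from an image batch to `embedding_dim`-wide vectors).
#'
#' @param name Backbone name (e.g. `"resnet50v2"`).
#' @param builder Construction function.
#' @export
register_backbone <- function(name, builder) {
  .backbone_registry[[name]] <- builder
  invisible(name)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build the encoder
#'
#' Initializes a trainable encoder mapping a preprocessed image to a real
#' embedding vector. Weights use He-normal initialization from the current
#' RNG state (seed beforehand for reproducibility). Input height and width
#' must be divisible by 8 (three 2x pooling stages).
#'
#' @param cfg An [encoder_config()].
#' @param input_shape `(H, W, C)` of the model input, default `c(256, 256, 3)`.
#' @return A `cnn_encoder` object holding the parameter list.
#' @export
build_encoder <- function(cfg = encoder_config(), input_shape = c(256, 256, 3)) {
  if (cfg$backbone != "cnn_based") {
    builder <- .backbone_registry[[cfg$backbone]]
    if (is.null(builder)) {
      stop("backbone '", cfg$backbone, "' has no registered implementation; ",
           "use register_backbone() to plug one in", call. = FALSE)
    }
    return(builder(cfg, input_shape))
  }
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  if (H %% 8 != 0 || W %% 8 != 0) {
    stop("input height and width must be divisible by 8", call. = FALSE)
  }
  K <- cfg$kernel[1]
  f <- cfg$conv_filters
  flat <- (H / 8) * (W / 8) * f[3]
  params <- list(
    W1 = he_init(K * K * C, f[1], K * K * C), b1 = numeric(f[1]),
    W2 = he_init(K * K * f[1], f[2], K * K * f[1]), b2 = numeric(f[2]),
    W3 = he_init(K * K * f[2], f[3], K * K * f[2]), b3 = numeric(f[3]),
    Wf1 = he_init(flat, cfg$fc_sizes[1], flat), bf1 = numeric(cfg$fc_sizes[1]),
    Wf2 = he_init(cfg$fc_sizes[1], cfg$fc_sizes[2], cfg$fc_sizes[1]),
    bf2 = numeric(cfg$fc_sizes[2])
  )
  structure(list(cfg = cfg, input_shape = as.integer(input_shape), params = params),
            class = "cnn_encoder")
}

#' @export
print.cnn_encoder <- function(x, ...) {
  cat(sprintf("cnn_encoder: input %s, filters %s, fc %s, embedding %d (%d parameters)\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$cfg$conv_filters, collapse = "/"),
              paste(x$cfg$fc_sizes, collapse = "/"),
              x$cfg$embedding_dim, n_parameters(x)))
  invisible(x)
}

#' Total trainable parameter count of an encoder
#' @param enc A `cnn_encoder`.
#' @return Integer count over all weight matrices and biases.
#' @export
n_parameters <- function(enc) {
  sum(vapply(enc$params, length, numeric(1)))
}

# fixed per-image standardization at the network input: bone-scan images share
# a dominant skeleton component, and without any internal normalization that
# common mode swamps the embedding and lets the contrastive phase collapse to
# a constant representation; zero-mean/unit-variance inputs prevent this
standardize_images <- function(x) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  mu <- colMeans(xm)
  sd <- sqrt(pmax(colMeans(xm^2) - mu^2, 0)) + 1e-8
  xm <- sweep(sweep(xm, 2, mu, "-"), 2, sd, "/")
  array(xm, dim = d)
}

conv_forward <- function(x, Wmat, b, K) {
  d <- dim(x)  # (H, W, C, N)
  cols <- im2col_batch(x, d[1], d[2], d[3], d[4], K)
  y <- cols %*% Wmat
  y <- sweep(y, 2, b, "+")
  f <- ncol(Wmat)
  out <- aperm(array(y, dim = c(d[1], d[2], d[4], f)), c(1, 2, 4, 3))
  list(out = out, cols = cols, xdim = d)
}

conv_backward <- function(dout, cache, Wmat, K, need_dx = TRUE) {
  d <- cache$xdim
  f <- ncol(Wmat)
  dy <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = f)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dx <- NULL
  if (need_dx) {
    dcols <- dy %*% t(Wmat)
    dx <- array(col2im_batch(dcols, d[1], d[2], d[3], d[4], K), dim = d)
  }
  list(dW = dW, db = db, dx = dx)
}

#' Encode an image batch
#'
#' Deterministic forward pass of the encoder. With `keep_cache = TRUE` the
#' intermediate activations needed for backpropagation are returned as well.
#'
#' @param enc A `cnn_encoder`.
#' @param x Array `(H, W, C, N)` (a single `(H, W, C)` image is promoted).
#' @param keep_cache Keep activations for [encoder_backward()].
#' @return With `keep_cache = FALSE`, an `N x embedding_dim` matrix;
#'   otherwise a list `(emb, cache)`.
#' @export
encoder_forward <- function(enc, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (!is.double(x)) storage.mode(x) <- "double"
  x <- standardize_images(x)
  K <- enc$cfg$kernel[1]
  p <- enc$params
  c1 <- conv_forward(x, p$W1, p$b1, K); a1 <- pmax(c1$out, 0)
  p1 <- maxpool2_fwd(a1, dim(a1)[1], dim(a1)[2], dim(a1)[3], dim(a1)[4])
  c2 <- conv_forward(p1$out, p$W2, p$b2, K); a2 <- pmax(c2$out, 0)
  p2 <- maxpool2_fwd(a2, dim(a2)[1], dim(a2)[2], dim(a2)[3], dim(a2)[4])
  c3 <- conv_forward(p2$out, p$W3, p$b3, K); a3 <- pmax(c3$out, 0)
  p3 <- maxpool2_fwd(a3, dim(a3)[1], dim(a3)[2], dim(a3)[3], dim(a3)[4])
  n <- dim(x)[4]
  flat <- matrix(p3$out, ncol = n)            # (feat, N)
  z1 <- crossprod(flat, p$Wf1)                # (N, fc1)
  z1 <- sweep(z1, 2, p$bf1, "+")
  r1 <- pmax(z1, 0)
  emb <- sweep(r1 %*% p$Wf2, 2, p$bf2, "+")   # (N, embedding_dim)
  if (!keep_cache) return(emb)
  list(emb = emb,
       cache = list(c1 = c1, a1mask = c1$out > 0, p1 = p1, d_a1 = dim(a1),
                    c2 = c2, a2mask = c2$out > 0, p2 = p2, d_a2 = dim(a2),
                    c3 = c3, a3mask = c3$out > 0, p3 = p3, d_a3 = dim(a3),
                    flat = flat, z1mask = z1 > 0, r1 = r1, n = n))
}

#' Backpropagate through the encoder
#'
#' @param enc A `cnn_encoder`.
#' @param cache Cache from `encoder_forward(..., keep_cache = TRUE)`.
#' @param demb Gradient of the loss w.r.t. the embedding (`N x embedding_dim`).
#' @return Named list of parameter gradients matching `enc$params`.
#' @export
encoder_backward <- function(enc, cache, demb) {
  K <- enc$cfg$kernel[1]
  p <- enc$params
  dWf2 <- crossprod(cache$r1, demb)
  dbf2 <- colSums(demb)
  dr1 <- demb %*% t(p$Wf2)
  dz1 <- dr1 * cache$z1mask
  dWf1 <- cache$flat %*% dz1
  dbf1 <- colSums(dz1)
  dflat <- p$Wf1 %*% t(dz1)                   # (feat, N)
  dp3 <- array(dflat, dim = dim(cache$p3$out))
  da3 <- array(maxpool2_bwd(dp3, cache$p3$idx, prod(cache$d_a3)),
               dim = cache$d_a3)
  dc3 <- da3 * cache$a3mask
  g3 <- conv_backward(dc3, cache$c3, p$W3, K, need_dx = TRUE)
  dp2 <- g3$dx
  da2 <- array(maxpool2_bwd(dp2, cache$p2$idx, prod(cache$d_a2)),
               dim = cache$d_a2)
  dc2 <- da2 * cache$a2mask
  g2 <- conv_backward(dc2, cache$c2, p$W2, K, need_dx = TRUE)
  dp1 <- g2$dx
  da1 <- array(maxpool2_bwd(dp1, cache$p1$idx, prod(cache$d_a1)),
               dim = cache$d_a1)
  dc1 <- da1 * cache$a1mask
  g1 <- conv_backward(dc1, cache$c1, p$W1, K, need_dx = FALSE)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db, W3 = g3$dW, b3 = g3$db,
       Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2)
}

#' Projection head for the contrastive phase
#'
#' An affine layer, feature-wise batch standardization, and L2 normalization,
#' so every output lies on the unit hypersphere — the domain the supervised
#' contrastive loss assumes. The batch standardization follows the standard
#' contrastive-head design: bone-scan embeddings share a strong common
#' component, and without it the contrastive phase can collapse to a constant
#' representation (every anchor's softmax turns uniform and the loss plateaus
#' at `log(2N - 1)`). The head is used during the contrastive phase only and
#' discarded afterwards.
#'
#' @param embedding_dim Encoder output width (>= 2).
#' @param proj_dim Projection width (default 32).
#' @return A `projection_head`.
#' @export
build_projection_head <- function(embedding_dim, proj_dim = 32) {
  if (embedding_dim < 2 || proj_dim < 2) stop("dims must be >= 2", call. = FALSE)
  structure(list(params = list(Wp = he_init(embedding_dim, proj_dim, embedding_dim),
                               bp = numeric(proj_dim))),
            class = "projection_head")
}

#' @rdname build_projection_head
#' @param head A `projection_head`.
#' @param emb `N x embedding_dim` matrix.
#' @param keep_cache Keep intermediates for [head_backward()].
#' @param batch_norm Standardize each feature across the batch before the
#'   unit normalization (training mode; needs `N >= 2`).
#' @return Unit-norm `N x proj_dim` matrix (or a list with `z` and `cache`).
#' @export
head_forward <- function(head, emb, keep_cache = FALSE, batch_norm = TRUE) {
  v <- sweep(emb %*% head$params$Wp, 2, head$params$bp, "+")
  if (batch_norm && nrow(v) >= 2) {
    mu <- colMeans(v)
    sd_ <- sqrt(colMeans(sweep(v, 2, mu, "-")^2) + 1e-5)
    u <- sweep(sweep(v, 2, mu, "-"), 2, sd_, "/")
  } else {
    mu <- NULL; sd_ <- NULL; u <- v
  }
  nrm <- pmax(sqrt(rowSums(u^2)), 1e-12)
  z <- u / nrm
  if (!keep_cache) return(z)
  list(z = z, cache = list(emb = emb, u = u, sd_ = sd_, nrm = nrm, z = z,
                           batch_norm = batch_norm && nrow(v) >= 2))
}

#' Backpropagate through the projection head
#' @param head A `projection_head`.
#' @param cache Cache from `head_forward(..., keep_cache = TRUE)`.
#' @param dz Gradient w.r.t. the unit-norm outputs.
#' @return List with `dWp`, `dbp` and `demb` (gradient into the encoder).
#' @export
head_backward <- function(head, cache, dz) {
  # through u -> u/||u||: du = (dz - z (z . dz)) / ||u||
  zdot <- rowSums(cache$z * dz)
  du <- (dz - cache$z * zdot) / cache$nrm
  if (cache$batch_norm) {
    # standard batch-normalization backward (no learned scale/shift)
    n <- nrow(du)
    uhat <- cache$u
    dv <- sweep(du * n - matrix(colSums(du), n, ncol(du), byrow = TRUE) -
                  uhat * matrix(colSums(du * uhat), n, ncol(du), byrow = TRUE),
                2, n * cache$sd_, "/")
  } else {
    dv <- du
  }
  list(dWp = crossprod(cache$emb, dv), dbp = colSums(dv),
       demb = dv %*% t(head$params$Wp))
}

#' Linear probability classifier on the embedding
#'
#' A single affine layer with a logistic output. Weights start at zero, so an
#' untrained classifier returns probability 0.5 everywhere.
#'
#' @param embedding_dim Encoder output width (>= 1).
#' @return A `linear_classifier`.
#' @export
build_linear_classifier <- function(embedding_dim) {
  if (embedding_dim < 1) stop("embedding_dim must be >= 1", call. = FALSE)
  structure(list(params = list(w = matrix(0, embedding_dim, 1), b = 0)),
            class = "linear_classifier")
}

#' @rdname build_linear_classifier
#' @param clf A `linear_classifier`.
#' @param emb `N x embedding_dim` matrix.
#' @return Probability vector in (0, 1).
#' @export
classifier_forward <- function(clf, emb) {
  as.numeric(stats::plogis(emb %*% clf$params$w + clf$params$b))
}
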