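#' Batch of unit-norm embeddings for the contrastive loss
#'
#' Container for the quantities the supervised contrastive loss operates on:
#' a matrix of L2-normalized embedding vectors (conventionally two augmented
#' views per source image), their class labels, and the softmax temperature.
#'
#' @param z Numeric matrix, one unit-norm embedding per row.
#' @param labels Class label per row.
#' @param tau Temperature, strictly positive (default 0.1).
#' @param tol Allowed deviation of row norms from 1.
#' @return An `embedding_batch`.
#' @export
embedding_batch <- function(z, labels, tau = 0.1, tol = 1e-4) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("a batch needs at least 2 embeddings", call. = FALSE)
  if (nrow(z) != length(labels)) stop("one label per embedding", call. = FALSE)
  if (tau <= 0) stop("temperature must be positive", call. = FALSE)
  nrm <- sqrt(rowSums(z^2))
  if (any(abs(nrm - 1) > tol)) {
    stop("embeddings must be unit-norm (max deviation ",
         format(max(abs(nrm - 1))), ")", call. = FALSE)
  }
  structure(list(z = z, labels = labels, tau = tau), class = "embedding_batch")
}

#' Supervised contrastive (SupCon) loss
#'
#' For every anchor embedding the loss pulls all same-class batch members
#' (the anchor's positives) towards it and pushes the rest away:
#' \deqn{L = \sum_{i} \frac{-1}{|P(i)|} \sum_{p \in P(i)}
#'   \log \frac{\exp(z_i \cdot z_p / \tau)}{\sum_{a \neq i} \exp(z_i \cdot z_a / \tau)}}
#' summed over anchors, computed with a numerically stable log-sum-exp.
#' Anchors without any positive in the batch (a singleton class, common under
#' class imbalance) contribute zero rather than raising an error.
#'
#' @param batch An [embedding_batch()], or a matrix if `labels` is given.
#' @param labels,tau Used when `batch` is a plain matrix.
#' @param per_anchor If `TRUE`, also return the average over anchors that have
#'   positives (readability scale); the optimized quantity is the sum.
#' @return Nonnegative scalar (the anchor sum), or a list when `per_anchor`.
#' @examples
#' z <- matrix(rep(c(1, 0), each = 4), 4, 2)  # four identical unit vectors
#' supcon_loss(embedding_batch(z, c(0, 0, 1, 1)))  # 4 * log(3)
#' @export
supcon_loss <- function(batch, labels = NULL, tau = 0.1, per_anchor = FALSE) {
  if (!inherits(batch, "embedding_batch")) {
    batch <- embedding_batch(batch, labels, tau)
  }
  parts <- supcon_parts(batch$z, batch$labels, batch$tau)
  if (per_anchor) {
    list(sum = parts$loss,
         mean = if (parts$n_anchored > 0) parts$loss / parts$n_anchored else 0)
  } else {
    parts$loss
  }
}

# shared core: loss pieces and the softmax matrix needed for the gradient
supcon_parts <- function(z, labels, tau) {
  n <- nrow(z)
  s <- tcrossprod(z) / tau
  diag(s) <- -Inf                        # A(i) excludes the anchor itself
  m <- apply(s, 1, max)
  lse <- m + log(rowSums(exp(s - m)))
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  npos <- rowSums(same)
  anchored <- npos > 0
  pos_mean <- numeric(n)
  if (any(anchored)) {
    s0 <- s; diag(s0) <- 0               # avoid -Inf * 0 in the masked sum
    pos_sum <- rowSums(s0 * same)
    pos_mean[anchored] <- pos_sum[anchored] / npos[anchored]
  }
  loss <- sum(lse[anchored] - pos_mean[anchored])
  list(loss = loss, s = s, lse = lse, same = same, npos = npos,
       anchored = anchored, n_anchored = sum(anchored))
}

#' @rdname supcon_loss
#' @return `supcon_loss_grad()` returns the gradient of the anchor-summed loss
#'   with respect to each embedding row (same shape as `z`).
#' @export
supcon_loss_grad <- function(batch, labels = NULL, tau = 0.1) {
  if (!inherits(batch, "embedding_batch")) {
    batch <- embedding_batch(batch, labels, tau)
  }
  z <- batch$z
  parts <- supcon_parts(z, batch$labels, batch$tau)
  # dL/ds for s_ij = z_i . z_j / tau; anchors without positives contribute 0.
  # Column recycling of the length-n vectors applies them row-wise, as needed.
  g <- exp(parts$s - parts$lse)          # row-softmax over A(i); diag exp(-Inf)=0
  g <- g - parts$same / pmax(parts$npos, 1)
  g[!parts$anchored, ] <- 0
  (g + t(g)) %*% z / batch$tau
}

#' Two stochastic augmented views per image
#'
#' Produces the paired views the contrastive phase contrasts: each source
#' image yields two independently augmented copies. The augmentation set is
#' anatomy-preserving — small translation, small rotation and multiplicative
#' intensity jitter; no left-right flip, which would move lateralized
#' structures (injection site, organs) implausibly.
#'
#' @param x Image batch, array `(H, W, C, N)`.
#' @param labels Label per source image.
#' @param aug An [aug_config()]; with all ranges zero the views equal the source.
#' @param seed Optional seed for reproducible views.
#' @return List with `x` (array `(H, W, C, 2N)`, views `2i-1` and `2i` from
#'   source `i`), `labels` (length 2N) and `source` (source index per view).
#' @export
make_views <- function(x, labels, aug = aug_config(), seed = NULL) {
  if (!is.null(seed)) {
    return(with_preserved_rng(seed, make_views(x, labels, aug)))
  }
  d <- dim(x)
  if (length(d) != 4) stop("image batch must be (H, W, C, N)", call. = FALSE)
  n <- d[4]
  if (n < 1) stop("at least one image is required", call. = FALSE)
  out <- array(0, dim = c(d[1], d[2], d[3], 2 * n))
  for (i in seq_len(n)) {
    for (v in 1:2) {
      out[, , , 2 * (i - 1) + v] <- augment_image(x[, , , i, drop = FALSE], aug)
    }
  }
  list(x = out, labels = rep(labels, each = 2), source = rep(seq_len(n), each = 2))
}

#' Augmentation configuration
#'
#' @param translate_px Maximum absolute translation, pixels (default 8).
#' @param rotate_deg Maximum absolute rotation, degrees (default 5).
#' @param intensity_jitter Maximum relative multiplicative intensity change
#'   (default 0.1 = +-10%).
#' @return An `aug_config`.
#' @export
aug_config <- function(translate_px = 8, rotate_deg = 5, intensity_jitter = 0.1) {
  if (translate_px < 0 || rotate_deg < 0 || rotate_deg > 45 ||
      intensity_jitter < 0 || intensity_jitter >= 1) {
    stop("augmentation parameters outside valid ranges", call. = FALSE)
  }
  structure(list(translate_px = translate_px, rotate_deg = rotate_deg,
                 intensity_jitter = intensity_jitter), class = "aug_config")
}

augment_image <- function(img, aug) {
  d <- dim(img)
  plane <- img[, , 1, 1]
  angle <- if (aug$rotate_deg > 0) stats::runif(1, -aug$rotate_deg, aug$rotate_deg) else 0
  dr <- if (aug$translate_px > 0) sample(-aug$translate_px:aug$translate_px, 1) else 0L
  dc <- if (aug$translate_px > 0) sample(-aug$translate_px:aug$translate_px, 1) else 0L
  gain <- if (aug$intensity_jitter > 0) {
    1 + stats::runif(1, -aug$intensity_jitter, aug$intensity_jitter)
  } else 1
  plane <- warp_rigid(plane, angle, dr, dc, gain)
  array(rep(plane, d[3]), dim = c(d[1], d[2], d[3], 1))
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` with probabilities clamped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param probabilities Predicted probabilities in (0, 1).
#' @param labels Binary labels, same length.
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must have equal length", call. = FALSE)
  }
  check_binary_labels(labels)
  p <- pmin(pmax(probabilities, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
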