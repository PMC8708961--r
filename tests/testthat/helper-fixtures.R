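# shared fixtures and independent oracles, built in code at test time

tiny_spec <- function(...) {
  phantom_spec(preset = "desk", ...)
}

# small preprocessed batch for model tests
tiny_batch <- function(n = 12, seed = 11, lesion_amplitude = 3,
                       target = c(16, 16)) {
  spec <- tiny_spec(lesion_amplitude = lesion_amplitude)
  scans <- generate_scans(spec, n, seed = seed)
  preprocess_batch(scans, preproc_config(target_size = target))
}

# independent naive double-sum implementation of the supervised contrastive
# loss, written directly from the anchor/positive definition
supcon_naive <- function(z, labels, tau) {
  n <- nrow(z)
  total <- 0
  for (i in seq_len(n)) {
    A <- setdiff(seq_len(n), i)
    P <- A[labels[A] == labels[i]]
    if (length(P) == 0) next
    denom <- sum(exp(sapply(A, function(a) sum(z[i, ] * z[a, ]) / tau)))
    inner <- 0
    for (p in P) {
      inner <- inner + log(exp(sum(z[i, ] * z[p, ]) / tau) / denom)
    }
    total <- total - inner / length(P)
  }
  total
}

# pairwise InfoNCE (one positive per anchor), coded independently
infonce_pairwise <- function(z, pos_of, tau) {
  n <- nrow(z)
  total <- 0
  for (i in seq_len(n)) {
    A <- setdiff(seq_len(n), i)
    denom <- sum(exp(sapply(A, function(a) sum(z[i, ] * z[a, ]) / tau)))
    total <- total - log(exp(sum(z[i, ] * z[pos_of[i], ]) / tau) / denom)
  }
  total
}

random_unit_rows <- function(n, d) {
  z <- matrix(stats::rnorm(n * d), n, d)
  z / sqrt(rowSums(z^2))
}

# concordant-pair AUC estimator (ties counted one half)
auc_pair_counting <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# direct O(n^2) silhouette from the definition
silhouette_bruteforce <- function(x, labels) {
  n <- nrow(x)
  dmat <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    other <- which(labels != labels[i])
    a <- if (length(own)) mean(dmat[i, own]) else 0
    b <- mean(dmat[i, other])
    s[i] <- if (length(own)) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# reference test-set confusion matrices with their published metric cells
published_table2 <- function() {
  metrics <- rbind(
    c(0.943, 0.322, 0.998, 0.081, 0.930, 0.943, 0.479),
    c(0.934, 0.230, 0.996, 0.081, 0.840, 0.936, 0.361),
    c(0.957, 0.533, 0.995, 0.081, 0.900, 0.960, 0.669),
    c(0.959, 0.596, 0.991, 0.081, 0.858, 0.965, 0.704),
    c(0.960, 0.564, 0.995, 0.081, 0.908, 0.963, 0.696),
    c(0.961, 0.599, 0.993, 0.081, 0.878, 0.965, 0.712))
  colnames(metrics) <- c("accuracy", "sensitivity", "specificity",
                         "prevalence", "precision", "npv", "f1")
  cbind(reference_confusions(), tibble::as_tibble(metrics))
}
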