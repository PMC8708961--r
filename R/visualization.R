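#' Project embeddings to 2-D for cluster inspection
#'
#' Reduces encoder representations to two dimensions for visual assessment of
#' class separation. The default method is UMAP, run through the system
#' Python's `umap-learn` implementation (the algorithm itself is not
#' reimplemented here) with a fixed random state for reproducibility; `"pca"`
#' is a dependency-free deterministic alternative.
#'
#' @param embeddings `n x d` numeric matrix, `n >= 10`, `d >= 2`.
#' @param labels Binary label per row.
#' @param seed Integer seed for the projection.
#' @param method `"umap"` or `"pca"`.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 and 0.1).
#' @return A `projected_embedding`: list with `coords` (tibble `x`, `y`,
#'   `label`), `method` and `seed`.
#' @export
project_embeddings <- function(embeddings, labels, seed = 42L,
                               method = c("umap", "pca"),
                               n_neighbors = 15, min_dist = 0.1) {
  method <- match.arg(method)
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 10) stop("at least 10 points are needed for the neighbour graph", call. = FALSE)
  if (ncol(embeddings) < 2) stop("embeddings must have at least 2 dimensions", call. = FALSE)
  if (length(labels) != n) stop("one label per embedding", call. = FALSE)
  coords <- switch(method,
                   umap = umap_via_python(embeddings, seed, n_neighbors, min_dist),
                   pca = pca_2d(embeddings))
  structure(list(coords = tibble::tibble(x = coords[, 1], y = coords[, 2],
                                         label = labels),
                 method = method, seed = as.integer(seed)),
            class = "projected_embedding")
}

umap_via_python <- function(x, seed, n_neighbors, min_dist) {
  python <- Sys.which("python")
  if (python == "") stop("no python interpreter on PATH for the UMAP backend", call. = FALSE)
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(x, fin, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- paste(
    "import sys, numpy, umap",
    "x = numpy.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    sprintf(paste0("m = umap.UMAP(n_neighbors=%d, min_dist=%s, n_components=2, ",
                   "random_state=%d, n_jobs=1)"),
            as.integer(min(n_neighbors, nrow(x) - 1)), format(min_dist), as.integer(seed)),
    "numpy.savetxt(sys.argv[2], m.fit_transform(x), delimiter=',')",
    sep = "; ")
  status <- system2(python, c("-c", shQuote(script), fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout)) {
    stop("UMAP backend failed (exit status ", status, ")", call. = FALSE)
  }
  as.matrix(utils::read.table(fout, sep = ","))
}

# first two principal components with a deterministic sign convention
pca_2d <- function(x) {
  pc <- stats::prcomp(x, rank. = 2, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  for (j in 1:2) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pc$x[, 1:2, drop = FALSE]
}

#' @export
print.projected_embedding <- function(x, ...) {
  cat(sprintf("projected_embedding: %d points via %s (seed %d)\n",
              nrow(x$coords), x$method, x$seed))
  invisible(x)
}

#' Silhouette-based class separation
#'
#' Mean silhouette width (Euclidean distance, via \pkg{cluster}) of the
#' binary labeling over the given coordinates — a quantitative proxy for how
#' visibly the two classes separate in an embedding plot. Near 1: tight,
#' well-separated classes; near or below 0: intermixed.
#'
#' @param x Numeric matrix of coordinates (any dimension), or a
#'   `projected_embedding`.
#' @param labels Binary label per row (taken from the projection if omitted).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
cluster_separation <- function(x, labels = NULL) {
  if (inherits(x, "projected_embedding")) {
    labels <- x$coords$label
    x <- cbind(x$coords$x, x$coords$y)
  }
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("at least 4 points are required", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to measure separation", call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(labels) + 1L, stats::dist(x))
  mean(sil[, "sil_width"])
}

#' @rdname project_embeddings
#' @param object A `projected_embedding`.
#' @param ... Unused.
#' @export
autoplot.projected_embedding <- function(object, ...) {
  df <- object$coords
  df$class <- factor(df$label, c(0, 1), c("no metastasis", "metastasis"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8, size = 1.5) +
    ggplot2::labs(x = paste0(toupper(object$method), " 1"),
                  y = paste0(toupper(object$method), " 2"),
                  colour = NULL,
                  title = "Encoder embedding, 2-D projection") +
    ggplot2::theme_minimal()
}

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @param ... Unused.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Write an embedding scatter / ROC curve to a PNG file
#'
#' @param object A `projected_embedding` or `roc_result`.
#' @param file Output PNG path.
#' @param width,height,dpi Figure geometry.
#' @return `file`, invisibly.
#' @export
plot_embedding <- function(object, file, width = 6, height = 5, dpi = 120) {
  if (!inherits(object, "projected_embedding")) {
    stop("plot_embedding() expects a projected_embedding", call. = FALSE)
  }
  if (nrow(object$coords) == 0) stop("empty projection", call. = FALSE)
  save_png(autoplot(object), file, width, height, dpi)
}

#' @rdname plot_embedding
#' @export
plot_roc <- function(object, file, width = 6, height = 5, dpi = 120) {
  if (!inherits(object, "roc_result")) {
    stop("plot_roc() expects a roc_result", call. = FALSE)
  }
  if (nrow(object$curve) == 0) stop("empty ROC curve", call. = FALSE)
  save_png(autoplot(object), file, width, height, dpi)
}

save_png <- function(plot, file, width, height, dpi) {
  dir <- dirname(file)
  if (!dir.exists(dir)) stop("unwritable path: ", dir, call. = FALSE)
  grDevices::png(file, width = width * dpi, height = height * dpi, res = dpi)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(file)
}
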