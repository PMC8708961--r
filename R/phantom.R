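#' Parameters of the synthetic bone-scan phantom generator
#'
#' Describes the statistical model used to emulate whole-body planar bone
#' scintigraphy: a deterministic skeleton-shaped uptake template, Gaussian
#' focal hot spots for metastatic scans, benign confounders (residual-urine
#' bladder blob, injection-site spot) applied to both classes, a global
#' activity scale emulating contrast variability, and Poisson counting noise.
#'
#' @param grid_height,grid_width Per-view grid size in pixels. The faithful
#'   preset is 1024 x 256 (clinical matrix); the `"desk"` preset uses 256 x 64.
#' @param lesion_count_mean Expected number of hot spots on a positive scan;
#'   the realized count is Poisson with this mean, truncated to be >= 1.
#' @param lesion_amplitude Multiplicative peak uptake of a hot spot relative
#'   to the local skeleton uptake; must exceed 1. Controls detectability.
#' @param lesion_sigma Gaussian spot width (pixels).
#' @param p_bladder Probability of a residual-urine bladder blob (both classes).
#' @param p_injection Probability of an injection-site spot (both classes).
#' @param activity_scale_range Interval of global count multipliers emulating
#'   low/high tracer uptake; lower bound must be positive.
#' @param prevalence Fraction of positive scans in a generated dataset,
#'   strictly inside (0, 1). Default 0.081, a realistic bone-scan population.
#' @param seed Integer RNG seed for dataset generation.
#' @param preset `"full"` (1024 x 256) or `"desk"` (256 x 64, prevalence 0.2),
#'   applied before any explicitly supplied argument.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(grid_height = 1024, grid_width = 256,
                         lesion_count_mean = 3, lesion_amplitude = 2,
                         lesion_sigma = 6, p_bladder = 0.3, p_injection = 0.2,
                         activity_scale_range = c(0.5, 2), prevalence = 0.081,
                         seed = 1L, preset = c("full", "desk")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    if (missing(grid_height)) grid_height <- 256
    if (missing(grid_width)) grid_width <- 64
    if (missing(lesion_sigma)) lesion_sigma <- 2
    if (missing(prevalence)) prevalence <- 0.2
  }
  spec <- list(grid_height = as.integer(grid_height),
               grid_width = as.integer(grid_width),
               lesion_count_mean = lesion_count_mean,
               lesion_amplitude = lesion_amplitude,
               lesion_sigma = lesion_sigma,
               p_bladder = p_bladder, p_injection = p_injection,
               activity_scale_range = activity_scale_range,
               prevalence = prevalence, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$grid_height < 64 || spec$grid_width < 64) {
    stop("grid dimensions must be at least 64 pixels", call. = FALSE)
  }
  if (spec$lesion_amplitude <= 1) stop("lesion_amplitude must exceed 1", call. = FALSE)
  if (spec$prevalence <= 0 || spec$prevalence >= 1) {
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (length(spec$activity_scale_range) != 2 ||
      spec$activity_scale_range[1] <= 0 ||
      diff(spec$activity_scale_range) < 0) {
    stop("activity_scale_range must be an increasing interval with positive lower bound",
         call. = FALSE)
  }
  if (spec$lesion_count_mean <= 0 || spec$lesion_sigma <= 0) {
    stop("lesion_count_mean and lesion_sigma must be positive", call. = FALSE)
  }
  for (p in c(spec$p_bladder, spec$p_injection)) {
    if (p < 0 || p > 1) stop("artifact probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(spec)
}

#' One patient's anterior/posterior scan pair
#'
#' @param anterior,posterior Nonnegative integer count matrices of equal size.
#' @param patient_id Identifier string.
#' @param label 1 = metastasis present, 0 = absent.
#' @param meta Optional list of acquisition annotations.
#' @return A `scan_pair` object.
#' @export
scan_pair <- function(anterior, posterior, patient_id, label, meta = list()) {
  if (!identical(dim(anterior), dim(posterior))) {
    stop("anterior and posterior views must share the same shape", call. = FALSE)
  }
  for (g in list(anterior, posterior)) {
    if (any(g < 0) || any(g != round(g))) {
      stop("scan counts must be nonnegative integers", call. = FALSE)
    }
  }
  if (!label %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  structure(list(anterior = anterior, posterior = posterior,
                 patient_id = as.character(patient_id),
                 label = as.integer(label), meta = meta),
            class = "scan_pair")
}

#' @export
print.scan_pair <- function(x, ...) {
  cat(sprintf("scan_pair %s: %d x %d per view, label = %d\n",
              x$patient_id, nrow(x$anterior), ncol(x$anterior), x$label))
  invisible(x)
}

# cache templates per grid size: deterministic, so safe to reuse
.template_cache <- new.env(parent = emptyenv())

#' Deterministic skeleton-shaped uptake template
#'
#' Builds an idealized whole-body uptake map from geometric primitives: a body
#' silhouette with low soft-tissue uptake and elevated uptake along the axial
#' skeleton (skull, spine, ribs, pelvis, shoulder girdle) and long bones.
#' Anterior and posterior views differ by a fixed asymmetry: spine, pelvis and
#' scapulae are stronger posteriorly, skull and sternum anteriorly. Values are
#' mean photon counts per pixel at unit activity scale.
#'
#' @param height,width Grid size in pixels, both at least 64.
#' @return List with `anterior` and `posterior` nonnegative real matrices.
#' @export
make_skeleton_template <- function(height, width) {
  if (height < 64 || width < 64) {
    stop("template grid must be at least 64 x 64 pixels", call. = FALSE)
  }
  key <- paste(height, width, sep = "x")
  hit <- .template_cache[[key]]
  if (!is.null(hit)) return(hit)

  y <- matrix((seq_len(height) - 0.5) / height, height, width)
  x <- matrix(rep((seq_len(width) - 0.5) / width, each = height), height, width)
  band <- function(y0, y1, x0, x1) (y >= y0 & y < y1 & x >= x0 & x < x1)

  head_m <- ((y - 0.07) / 0.05)^2 + ((x - 0.5) / 0.16)^2 <= 1
  torso <- band(0.12, 0.64, 0.27, 0.73)
  leg_l <- band(0.62, 0.97, 0.28, 0.47)
  leg_r <- band(0.62, 0.97, 0.53, 0.72)
  arm_l <- band(0.15, 0.56, 0.19, 0.27)
  arm_r <- band(0.15, 0.56, 0.73, 0.81)
  silhouette <- head_m | torso | leg_l | leg_r | arm_l | arm_r

  spine <- band(0.12, 0.60, 0.46, 0.54)
  pelvis <- band(0.55, 0.64, 0.33, 0.67)
  ribs <- band(0.18, 0.42, 0.30, 0.70) &
    (floor((y - 0.18) / 0.04) %% 2 == 0)
  shoulders <- band(0.12, 0.16, 0.25, 0.75)
  femur <- band(0.64, 0.83, 0.345, 0.405) | band(0.64, 0.83, 0.595, 0.655)
  tibia <- band(0.85, 0.97, 0.355, 0.395) | band(0.85, 0.97, 0.605, 0.645)
  sternum <- band(0.18, 0.31, 0.47, 0.53)
  scapula <- band(0.17, 0.28, 0.30, 0.42) | band(0.17, 0.28, 0.58, 0.70)

  soft <- 8
  compose <- function(w) {
    soft * silhouette +
      w["skull"] * head_m + w["spine"] * spine + w["pelvis"] * pelvis +
      w["ribs"] * ribs + w["shoulders"] * shoulders + w["femur"] * femur +
      w["tibia"] * tibia + w["sternum"] * sternum + w["scapula"] * scapula
  }
  anterior <- compose(c(skull = 16, spine = 12, pelvis = 16, ribs = 10,
                        shoulders = 10, femur = 12, tibia = 10,
                        sternum = 6, scapula = 0))
  posterior <- compose(c(skull = 12, spine = 22, pelvis = 20, ribs = 8,
                         shoulders = 10, femur = 12, tibia = 10,
                         sternum = 0, scapula = 8))
  out <- list(anterior = anterior, posterior = posterior)
  .template_cache[[key]] <- out
  out
}

# pixels eligible as lesion centers: elevated (bony) uptake in either view
skeleton_mask <- function(template) {
  (template$anterior + template$posterior) > 2 * 8 + 4
}

# add a Gaussian bump of given peak at (r0, c0), windowed to +-4 sigma
add_gaussian_spot <- function(grid, r0, c0, peak, sigma) {
  h <- nrow(grid); w <- ncol(grid)
  half <- ceiling(4 * sigma)
  rr <- max(1, r0 - half):min(h, r0 + half)
  cc <- max(1, c0 - half):min(w, c0 + half)
  g <- exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * sigma^2))
  grid[rr, cc] <- grid[rr, cc] + peak * g
  grid
}

#' Generate one synthetic scan pair
#'
#' Composes the phantom intensity model and draws Poisson counts: the skeleton
#' template is scaled by a global activity factor drawn from
#' `activity_scale_range`; positive scans receive `K >= 1` Gaussian hot spots
#' (K truncated-Poisson with mean `lesion_count_mean`) centered on skeleton
#' pixels with peak `lesion_amplitude` times the local uptake; bladder and
#' injection-site artifacts are added with their probabilities regardless of
#' the label (so they cannot serve as class shortcuts); each pixel count is
#' finally Poisson with the composed intensity as mean.
#'
#' @param spec A [phantom_spec()].
#' @param label 0 or 1.
#' @param seed Optional integer; when given, generation is a pure function of
#'   `(spec, label, seed)` and the caller's RNG state is untouched.
#' @param noise If `FALSE`, the rounded composed intensity is returned instead
#'   of Poisson draws (useful for testing the noiseless limit).
#' @param patient_id Identifier stored on the scan.
#' @return A [scan_pair()].
#' @export
generate_phantom <- function(spec, label, seed = NULL, noise = TRUE,
                             patient_id = "phantom") {
  validate_phantom_spec(spec)
  if (!label %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  if (!is.null(seed)) {
    return(with_preserved_rng(seed, generate_phantom(spec, label, seed = NULL,
                                                     noise = noise,
                                                     patient_id = patient_id)))
  }
  tmpl <- make_skeleton_template(spec$grid_height, spec$grid_width)
  scale <- stats::runif(1, spec$activity_scale_range[1], spec$activity_scale_range[2])
  ant <- tmpl$anterior * scale
  post <- tmpl$posterior * scale

  n_lesions <- 0L
  if (label == 1) {
    n_lesions <- stats::rpois(1, spec$lesion_count_mean)
    while (n_lesions < 1) n_lesions <- stats::rpois(1, spec$lesion_count_mean)
    centers <- which(skeleton_mask(tmpl))
    picks <- sample(centers, n_lesions, replace = TRUE)
    for (idx in picks) {
      r0 <- ((idx - 1) %% spec$grid_height) + 1
      c0 <- ((idx - 1) %/% spec$grid_height) + 1
      ant <- add_gaussian_spot(ant, r0, c0,
                               (spec$lesion_amplitude - 1) * ant[r0, c0],
                               spec$lesion_sigma)
      post <- add_gaussian_spot(post, r0, c0,
                                (spec$lesion_amplitude - 1) * post[r0, c0],
                                spec$lesion_sigma)
    }
  }

  h <- spec$grid_height; w <- spec$grid_width
  bladder <- stats::runif(1) < spec$p_bladder
  if (bladder) {
    r0 <- round(0.615 * h); c0 <- round(0.5 * w)
    peak <- 40 * scale; sig <- 2.5 * spec$lesion_sigma
    ant <- add_gaussian_spot(ant, r0, c0, peak, sig)          # bladder is anterior-dominant
    post <- add_gaussian_spot(post, r0, c0, 0.5 * peak, sig)
  }
  injection <- stats::runif(1) < spec$p_injection
  if (injection) {
    side <- if (stats::runif(1) < 0.5) 0.23 else 0.77
    r0 <- round(0.50 * h); c0 <- round(side * w)
    peak <- 60 * scale; sig <- 0.75 * spec$lesion_sigma
    ant <- add_gaussian_spot(ant, r0, c0, peak, sig)
    post <- add_gaussian_spot(post, r0, c0, peak, sig)
  }

  draw <- function(intensity) {
    if (noise) {
      matrix(stats::rpois(length(intensity), intensity), nrow(intensity))
    } else {
      round(intensity)
    }
  }
  scan_pair(draw(ant), draw(post), patient_id, label,
            meta = list(activity_scale = scale, n_lesions = n_lesions,
                        bladder = bladder, injection = injection))
}

#' Generate a labeled set of scan pairs in memory
#'
#' Labels are Bernoulli draws at the spec's prevalence; each scan is generated
#' with [generate_phantom()]. Deterministic given `(spec, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of patients (>= 2).
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return List of [scan_pair()] objects.
#' @export
generate_scans <- function(spec, n, seed = spec$seed) {
  validate_phantom_spec(spec)
  if (n < 2) stop("at least 2 patients are required", call. = FALSE)
  with_preserved_rng(seed, {
    labels <- stats::rbinom(n, 1, spec$prevalence)
    lapply(seq_len(n), function(i) {
      generate_phantom(spec, labels[i], patient_id = sprintf("P%05d", i))
    })
  })
}

#' Generate a synthetic dataset on disk
#'
#' Draws labels at the spec's prevalence, writes every scan pair as two DICOM
#' files via [write_scan_pair()], and writes a CSV manifest.
#'
#' @param spec A [phantom_spec()].
#' @param n_patients Number of patients (>= 2).
#' @param out_dir Writable output directory (created if missing).
#' @return The manifest tibble (also written to `out_dir/manifest.csv`), with
#'   a `provenance` attribute identifying the generator spec.
#' @export
generate_dataset <- function(spec, n_patients, out_dir) {
  scans <- generate_scans(spec, n_patients)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("output directory is not writable", call. = FALSE)
  rows <- lapply(scans, function(s) {
    paths <- write_scan_pair(s, out_dir)
    tibble::tibble(patient_id = s$patient_id, anterior_path = paths[1],
                   posterior_path = paths[2], label = s$label, split = "train")
  })
  manifest <- do.call(rbind, rows)
  attr(manifest, "provenance") <- spec_hash(spec)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

spec_hash <- function(spec) {
  paste0("phantom:", paste(unlist(spec), collapse = ","))
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
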