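test_that("skeleton template is deterministic with the declared geometry", {
  t1 <- make_skeleton_template(1024, 256)
  t2 <- make_skeleton_template(1024, 256)
  expect_identical(t1, t2)
  expect_equal(dim(t1$anterior), c(1024, 256))
  expect_equal(dim(t1$posterior), c(1024, 256))
  expect_true(all(t1$anterior >= 0) && all(t1$posterior >= 0))
  # maximal uptake falls in the spine column band
  spine_cols <- floor(0.46 * 256):ceiling(0.54 * 256)
  expect_true(arrayInd(which.max(t1$posterior), dim(t1$posterior))[2] %in% spine_cols)
  # background outside the silhouette is zero
  expect_equal(t1$anterior[1, 1], 0)
  expect_equal(t1$posterior[1024, 256], 0)
  # views differ by the stated asymmetry: spine stronger posteriorly
  mid_spine <- t1$posterior[400, 128] - t1$anterior[400, 128]
  expect_gt(mid_spine, 0)
})

test_that("smallest valid template fits and undersized grids are rejected", {
  t_small <- make_skeleton_template(64, 64)
  expect_equal(dim(t_small$anterior), c(64, 64))
  expect_true(any(t_small$anterior > 0))
  expect_error(make_skeleton_template(32, 256), "at least 64")
})

test_that("phantom_spec enforces its invariants", {
  expect_s3_class(tiny_spec(), "phantom_spec")
  expect_error(phantom_spec(lesion_amplitude = 1), "exceed 1")
  expect_error(phantom_spec(prevalence = 0), "prevalence")
  expect_error(phantom_spec(prevalence = 1), "prevalence")
  expect_error(phantom_spec(activity_scale_range = c(0, 2)), "positive lower bound")
  expect_error(phantom_spec(grid_height = 32), "at least 64")
})

test_that("noiseless artifact-free negative scan equals the scaled template", {
  spec <- tiny_spec(p_bladder = 0, p_injection = 0)
  s <- generate_phantom(spec, 0, seed = 5, noise = FALSE)
  tmpl <- make_skeleton_template(spec$grid_height, spec$grid_width)
  k <- s$meta$activity_scale
  expect_identical(s$anterior, round(tmpl$anterior * k))
  expect_identical(s$posterior, round(tmpl$posterior * k))
  expect_equal(s$meta$n_lesions, 0L)
})

test_that("generation is bit-identical under equal (spec, label, seed)", {
  spec <- tiny_spec()
  expect_identical(generate_phantom(spec, 1, seed = 42),
                   generate_phantom(spec, 1, seed = 42))
  expect_identical(generate_scans(spec, 8, seed = 3),
                   generate_scans(spec, 8, seed = 3))
})

test_that("positive scans carry >= 1 lesion and label consistency holds", {
  spec <- tiny_spec(lesion_count_mean = 0.2)  # heavy truncation pressure
  for (seed in 1:20) {
    s <- generate_phantom(spec, 1, seed = seed)
    expect_gte(s$meta$n_lesions, 1)
  }
  s0 <- generate_phantom(spec, 0, seed = 1)
  expect_equal(s0$meta$n_lesions, 0L)
  expect_error(generate_phantom(spec, 2), "label")
})

test_that("lesion disks show the configured uptake elevation on average", {
  # derived check: with amplitude a, the mean intensity at the lesion centre
  # is about a times the local baseline; averaged over seeded replicates the
  # observed counts must exceed half that elevation
  spec <- tiny_spec(lesion_amplitude = 3, p_bladder = 0, p_injection = 0,
                    activity_scale_range = c(1, 1), lesion_count_mean = 3)
  tmpl <- make_skeleton_template(spec$grid_height, spec$grid_width)
  ratio <- numeric(0)
  for (seed in 1:100) {
    s <- generate_phantom(spec, 1, seed = seed)
    diff <- s$anterior - tmpl$anterior
    centre <- arrayInd(which.max(diff), dim(diff))
    base <- tmpl$anterior[centre[1], centre[2]]
    if (base > 0) ratio <- c(ratio, s$anterior[centre[1], centre[2]] / base)
  }
  expect_gt(mean(ratio), spec$lesion_amplitude / 2)
})

test_that("Poisson noise has the composed intensity as its mean", {
  spec <- tiny_spec(p_bladder = 0, p_injection = 0,
                    activity_scale_range = c(1, 1))
  tmpl <- make_skeleton_template(spec$grid_height, spec$grid_width)
  px <- cbind(c(40, 120, 200), c(30, 32, 24))  # spine / pelvis / leg pixels
  sums <- numeric(3)
  n_rep <- 1000
  set.seed(99)
  for (r in seq_len(n_rep)) {
    s <- generate_phantom(spec, 0)
    sums <- sums + s$anterior[px]
  }
  lambda <- tmpl$anterior[px]
  se <- sqrt(lambda / n_rep)
  expect_true(all(abs(sums / n_rep - lambda) <= 3 * se + 1e-9))
})

test_that("generated datasets respect prevalence within binomial bounds", {
  spec <- phantom_spec(preset = "desk", prevalence = 0.081, seed = 7)
  scans <- generate_scans(spec, 1000)
  npos <- sum(vapply(scans, function(s) s$label, integer(1)))
  expect_true(npos >= 50 && npos <= 115)  # +-4 SD around 81
})

test_that("generate_dataset writes scans plus a loadable manifest", {
  out <- withr::local_tempdir()
  spec <- tiny_spec(seed = 21)
  manifest <- generate_dataset(spec, 4, out)
  expect_equal(nrow(manifest), 4)
  expect_true(all(file.exists(manifest$anterior_path)))
  loaded <- read_manifest(file.path(out, "manifest.csv"))
  expect_equal(loaded$patient_id, manifest$patient_id)
  expect_equal(loaded$label, manifest$label)
  # round trip through DICOM reproduces the generated counts
  s1 <- generate_scans(spec, 4)[[1]]
  rt <- read_scan_pair(manifest$anterior_path[1], manifest$posterior_path[1],
                       label = manifest$label[1])
  expect_identical(rt$anterior, s1$anterior)
  expect_error(generate_dataset(spec, 1, out), "at least 2")
})
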