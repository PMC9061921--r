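checkerboard <- function(n = 4) (outer(1:n, 1:n, "+") %% 2L) + 1L

test_that("constant slices give degenerate closed-form features", {
  sl <- matrix(3L, 4, 4)
  for (d in names(inplane_directions())) {
    m <- glcm_matrix(sl, 4, d)
    expect_equal(sum(m$p), 1)
    expect_equal(m$p[3, 3], 1)            # point mass on the diagonal
    f <- glcm_features(m)
    expect_equal(unname(f["contrast"]), 0)
    expect_equal(unname(f["joint_energy"]), 1)
    expect_equal(unname(f["correlation"]), 0)  # zero-variance convention
  }
  r <- glrlm_matrix(sl, 4, "0")
  fr <- glrlm_features(r)
  # one maximal run per row: 4 runs over 16 pixels
  expect_equal(unname(fr["run_percentage"]), 4 / 16)
})

test_that("a two-level checkerboard has unit GLCM contrast at 0 degrees", {
  sl <- checkerboard(4)
  m <- glcm_matrix(sl, 2, "0")
  expect_equal(diag(m$p), c(0, 0))          # all pairs differ
  expect_equal(unname(glcm_features(m)["contrast"]), 1)
})

test_that("checkerboard zones follow 8-connectivity (2 zones of 8)", {
  sl <- checkerboard(4)
  z <- glszm_matrix(sl, 2)
  o <- oracle_glszm(sl, 2)
  expect_equal(z$counts, o)
  expect_equal(unname(z$counts[, 8]), c(1, 1))
  expect_equal(sum(z$counts), 2)
})

test_that("every family matches its brute-force transcription on random slices", {
  set.seed(20240917)
  rl_names <- paste0("f", 1:16)
  n_cases <- 200
  for (rep in seq_len(n_cases)) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    ng <- sample(2:8, 1)
    sl <- random_slice(nr, nc, ng)
    dir <- sample(names(inplane_directions()), 1)

    P <- glcm_matrix(sl, ng, dir)
    O <- oracle_glcm(sl, ng, dir)
    expect_equal(P$p, O, tolerance = 1e-12)
    if (sum(O) > 0) {
      f <- glcm_features(P); fo <- oracle_glcm_features(O, ng)
      expect_equal(f, fo[names(f)], tolerance = 1e-10)
    }

    R <- glrlm_matrix(sl, ng, dir)
    RO <- oracle_glrlm(sl, ng, dir)
    expect_equal(R$counts, RO, tolerance = 1e-12)
    fr <- glrlm_features(R)
    fro <- oracle_rl_features(RO, sum(sl > 0), rl_names)
    expect_equal(unname(fr), unname(fro), tolerance = 1e-10)

    Z <- glszm_matrix(sl, ng)
    ZO <- oracle_glszm(sl, ng)
    expect_equal(Z$counts, ZO, tolerance = 1e-12)
    fz <- glszm_features(Z)
    fzo <- oracle_rl_features(ZO, sum(sl > 0), rl_names)
    expect_equal(unname(fz), unname(fzo), tolerance = 1e-10)

    N <- ngtdm_matrix(sl, ng)
    NO <- oracle_ngtdm(sl, ng)
    expect_equal(N$n, NO$n, tolerance = 1e-12)
    expect_equal(N$s, NO$s, tolerance = 1e-10)
    if (sum(NO$n) > 0) {
      fn <- ngtdm_features(N)
      fno <- oracle_ngtdm_features(NO$n, NO$s, ng)
      expect_equal(fn, fno, tolerance = 1e-10)
    }

    D <- gldm_matrix(sl, ng)
    DO <- oracle_gldm(sl, ng)
    expect_equal(D$counts, DO, tolerance = 1e-12)
    fd <- gldm_features(D)
    fdo <- oracle_rl_features(DO, sum(DO), rl_names)
    expect_equal(unname(fd),
                 unname(fdo[c(1, 2, 3, 5, 6, 8, 9, 10, 11, 12, 13, 14, 15,
                              16)]),
                 tolerance = 1e-10)
  }
})

test_that("normalized GLCMs are symmetric with unit mass and consistent marginals", {
  set.seed(11)
  for (rep in 1:20) {
    sl <- random_slice(8, 8, 5)
    m <- glcm_matrix(sl, 5, sample(names(inplane_directions()), 1))
    if (sum(m$p) == 0) next
    expect_equal(sum(m$p), 1, tolerance = 1e-12)
    expect_equal(m$p, t(m$p), tolerance = 1e-12)
    px <- rowSums(m$p); py <- colSums(m$p)
    expect_equal(sum(1:5 * px), sum(1:5 * py), tolerance = 1e-12)
  }
})

test_that("aggregated directional features are invariant to 90-degree rotations and flips", {
  set.seed(5)
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  agg_dir <- function(fam, sl, ng) {
    vals <- lapply(names(inplane_directions()), function(d)
      compute_family_features(fam, build_texture_matrix(fam, sl, ng,
                                                        direction = d)))
    Reduce(`+`, vals) / length(vals)
  }
  for (rep in 1:15) {
    ng <- sample(3:6, 1)
    sl <- random_slice(sample(6:10, 1), sample(6:10, 1), ng)
    for (fam in c("glcm", "glrlm")) {
      base <- agg_dir(fam, sl, ng)
      expect_equal(agg_dir(fam, rot90(sl), ng), base, tolerance = 1e-10)
      expect_equal(agg_dir(fam, sl[nrow(sl):1, , drop = FALSE], ng), base,
                   tolerance = 1e-10)
      expect_equal(agg_dir(fam, sl[, ncol(sl):1, drop = FALSE], ng), base,
                   tolerance = 1e-10)
    }
  }
})

test_that("2.5D aggregation averages directions within slices, then slices", {
  one <- list(list(c(a = 1), c(a = 2), c(a = 3), c(a = 4)))
  expect_equal(aggregate_25d(one), c(a = 2.5))
  two <- list(c(a = 2), c(a = 4))
  expect_equal(aggregate_25d(two), c(a = 3))
  single <- list(c(a = 7))
  expect_equal(aggregate_25d(single), c(a = 7))
})

test_that("ADC first-order statistics follow their closed forms", {
  expect_equal(adc_first_order(rep(3, 10)),
               c(mean = 3, sd = 0, skewness = 0, kurtosis = 0))
  f <- adc_first_order(c(1, 2, 3, 4))
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["sd"]), sd(1:4), tolerance = 1e-10)
  expect_equal(unname(f["sd"]), 1.2910, tolerance = 1e-4)
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(unname(adc_first_order(sym)["skewness"]), 0, tolerance = 1e-12)
  # uncorrected kurtosis of a large normal sample is near 3
  set.seed(2)
  expect_equal(unname(adc_first_order(rnorm(2e4))["kurtosis"]), 3,
               tolerance = 0.15)
  expect_error(adc_first_order(1), "at least two")
})

test_that("case extraction emits the exact 157-name catalogue", {
  cases <- generate_cohort(cohort_spec(n_responders = 1, n_nonresponders = 1,
                                       centres = list(A = c(1, 1, 2)),
                                       seed = 3))
  fv <- extract_case_features(cases[[1]], "manual")
  cat <- feature_catalogue()
  expect_equal(names(fv), cat$name)
  expect_length(fv, 157)
  expect_equal(sum(cat$modality == "t2w"), 77)
  expect_equal(sum(cat$modality == "adc"), 80)
  expect_true(all(is.finite(fv)))
})

test_that("identical volumes in both modality slots give pairwise-equal textures", {
  cases <- generate_cohort(cohort_spec(n_responders = 1, n_nonresponders = 1,
                                       centres = list(A = c(1, 1, 2)),
                                       seed = 4))
  cs <- cases[[1]]
  cs$adc <- cs$t2w
  fv <- extract_case_features(cs, "manual")
  fam <- texture_feature_names()
  for (f in names(fam)) {
    t2 <- fv[paste0("t2w.", f, ".", fam[[f]])]
    ad <- fv[paste0("adc.", f, ".", fam[[f]])]
    expect_equal(unname(t2), unname(ad), tolerance = 1e-12)
  }
})

test_that("shifting T2w intensities leaves all T2w features unchanged", {
  cases <- generate_cohort(cohort_spec(n_responders = 1, n_nonresponders = 1,
                                       centres = list(A = c(1, 1, 2)),
                                       seed = 5))
  cs <- cases[[1]]
  fv0 <- extract_case_features(cs, "manual")
  cs$t2w <- image_volume(cs$t2w$voxels + 100, cs$t2w$spacing)
  fv1 <- extract_case_features(cs, "manual")
  t2_names <- feature_catalogue()$name[feature_catalogue()$modality == "t2w"]
  expect_equal(fv1[t2_names], fv0[t2_names], tolerance = 1e-9)
})

test_that("the catalogue arithmetic is conserved", {
  cat <- feature_catalogue()
  expect_equal(nrow(cat), 157)
  expect_equal(anyDuplicated(cat$name), 0)
  fam <- texture_feature_names()
  expect_equal(lengths(fam)[c("glcm", "glrlm", "glszm", "ngtdm", "gldm")],
               c(glcm = 25L, glrlm = 16L, glszm = 16L, ngtdm = 5L,
                 gldm = 14L))
  expect_equal(1 + 4 + 2 * sum(lengths(fam)), 157)
})
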