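test_that("SNV rows have mean 0 and SD 1, with the n-1 denominator", {
  s <- spectra_set(c(100, 104, 108), matrix(c(1, 2, 3), 1), "S1")
  out <- snv_transform(s)
  expect_equal(unname(out$absorbance[1, ]), c(-1, 0, 1)) # SD of (1,2,3) is 1
  r <- snv_transform(toy_spectra())
  expect_lt(max(abs(rowMeans(r$absorbance))), 1e-10)
  sds <- apply(r$absorbance, 1, sd)
  expect_lt(max(abs(sds - 1)), 1e-10)
  expect_identical(r$grid, toy_spectra()$grid)
  flat <- spectra_set(c(100, 104, 108), rbind(c(1, 2, 3), c(5, 5, 5)),
                      c("A", "B"))
  expect_error(snv_transform(flat), "B")
})

test_that("SG derivative of polyorder 2 is exact on quadratics", {
  grid <- seq(650, 1050, by = 4)
  y <- 3 + 2 * grid + 0.5 * grid^2
  s <- spectra_set(grid, matrix(y, 1), "S1")
  d1 <- savgol_derivative(s, 1)
  expect_equal(unname(d1$absorbance[1, ]), 2 + d1$grid,
               tolerance = 1e-9)
  d2 <- savgol_derivative(s, 2)
  expect_equal(unname(d2$absorbance[1, ]), rep(1, length(d2$grid)),
               tolerance = 1e-9)
})

test_that("SG derivative trims edges and annihilates constants", {
  s <- toy_spectra(n = 2, p = 100)
  out <- savgol_derivative(s, 1, window = 17)
  expect_equal(ncol(out$absorbance), 84L) # 100 - 16
  expect_equal(length(out$grid), 84L)
  expect_equal(out$grid[1], s$grid[9])
  const <- spectra_set(s$grid, matrix(7, 1, 100), "C1")
  expect_equal(unname(savgol_derivative(const, 1)$absorbance[1, ]),
               rep(0, 84))
  expect_equal(unname(savgol_derivative(const, 2)$absorbance[1, ]),
               rep(0, 84))
})

test_that("SG derivative is linear and grid-spacing invariant", {
  set.seed(1)
  p <- 60
  x <- runif(p); y <- runif(p)
  sx <- spectra_set(seq(0, by = 2, length.out = p), matrix(x, 1), "X")
  sy <- spectra_set(sx$grid, matrix(y, 1), "Y")
  sxy <- spectra_set(sx$grid, matrix(3 * x - 2 * y, 1), "XY")
  d <- function(s) savgol_derivative(s, 1)$absorbance[1, ]
  expect_lt(max(abs(d(sxy) - (3 * d(sx) - 2 * d(sy)))), 1e-10)
  # per-cm^-1 scaling: the same analytic curve sampled at two spacings
  # yields the same derivative values (exact for a quadratic)
  f <- function(v) 0.01 * v^2
  for (step in c(1, 2)) {
    v <- seq(100, by = step, length.out = p)
    a <- savgol_derivative(spectra_set(v, matrix(f(v), 1), "A"), 1)
    expect_equal(unname(a$absorbance[1, ]), 0.02 * a$grid,
                 tolerance = 1e-10)
  }
})

test_that("SG parameter validation", {
  s <- toy_spectra(n = 1, p = 30)
  expect_error(savgol_derivative(s, 1, window = 16), "odd")
  expect_error(savgol_derivative(s, 1, window = 3, polyorder = 4),
               "exceed")
  expect_error(savgol_derivative(toy_spectra(n = 1, p = 10), 1,
                                 window = 17), "at least 17")
  expect_error(pretreatment_spec("snv_d1", sg_window = 16), "odd")
  expect_error(pretreatment_spec("nope"), "arg")
})

test_that("autoscaling stores training statistics and applies them", {
  tr <- spectra_set(c(1, 2), rbind(c(0, 5), c(2, 5)), c("A", "B"))
  f <- autoscale_fit(tr)
  expect_equal(unname(f$means), c(1, 5))
  expect_equal(unname(f$sds), c(sqrt(2), 0))
  out <- autoscale_apply(f, tr)
  expect_equal(unname(colMeans(out$absorbance)), c(0, 0))
  # zero-variance channel maps to 0 for all samples
  expect_equal(unname(out$absorbance[, 2]), c(0, 0))
  # a test value equal to the training mean maps to 0
  te <- spectra_set(c(1, 2), matrix(c(1, 7), 1), "T")
  expect_equal(unname(autoscale_apply(f, te)$absorbance[1, 1]), 0)
  expect_error(autoscale_fit(spectra_set(c(1, 2), matrix(1:2, 1), "A")),
               "at least 2")
  expect_error(autoscale_apply(f, spectra_set(c(1, 3), tr$absorbance,
                                              c("A", "B"))),
               "mismatch")
})

test_that("the six recipes compose as documented", {
  expect_identical(names(default_pretreatments()),
                   c("autoscale", "snv", "d1", "d2", "snv_d1", "snv_d2"))
  tr <- toy_spectra(n = 6, p = 40, seed = 2)
  te <- toy_spectra(n = 3, p = 40, seed = 3)
  # autoscale spec equals explicit fit + apply
  pa <- apply_pretreatment(pretreatment_spec("autoscale"), tr, list(te))
  f <- autoscale_fit(tr)
  expect_equal(pa$train$absorbance, autoscale_apply(f, tr)$absorbance)
  expect_equal(pa$others[[1]]$absorbance,
               autoscale_apply(f, te)$absorbance)
  # snv_d1 equals manual SNV followed by derivative; the SNV step removes
  # a per-sample offset before differentiation
  pb <- apply_pretreatment(pretreatment_spec("snv_d1"), tr, list(te))
  manual <- savgol_derivative(snv_transform(te), 1)
  expect_equal(pb$others[[1]]$absorbance, manual$absorbance)
  off <- te
  off$absorbance <- off$absorbance + 5 # constant offset, changes raw d1
  off <- spectra_set(te$grid, off$absorbance, te$sample_ids)
  pb_off <- apply_pretreatment(pretreatment_spec("snv_d1"), tr, list(off))
  expect_equal(pb_off$others[[1]]$absorbance, pb$others[[1]]$absorbance)
})

test_that("sample-local steps act row by row; only autoscale is fitted", {
  s <- toy_spectra(n = 5, p = 40, seed = 4)
  perm <- c(3, 1, 5, 2, 4)
  for (nm in c("snv", "d1", "d2", "snv_d1", "snv_d2")) {
    spec <- pretreatment_spec(nm)
    a <- apply_pretreatment(spec, s)$train
    b <- apply_pretreatment(spec, subset_samples(s, perm))$train
    expect_equal(b$absorbance, a$absorbance[perm, ],
                 info = nm)
  }
  # fitted statistics never use test-set values: mutating the test set
  # leaves the transformed training set unchanged
  tr <- toy_spectra(n = 6, p = 40, seed = 5)
  te1 <- toy_spectra(n = 3, p = 40, seed = 6)
  te2 <- te1
  te2$absorbance <- te2$absorbance * 100 + 3
  te2 <- spectra_set(te1$grid, te2$absorbance, te1$sample_ids)
  for (nm in pretreatment_names()) {
    spec <- pretreatment_spec(nm)
    r1 <- apply_pretreatment(spec, tr, list(te1))
    r2 <- apply_pretreatment(spec, tr, list(te2))
    expect_identical(r1$train$absorbance, r2$train$absorbance, info = nm)
  }
})

test_that("pretreat_apply reproduces the training-time transform on new data", {
  tr <- toy_spectra(n = 6, p = 40, seed = 8)
  te <- toy_spectra(n = 3, p = 40, seed = 9)
  for (nm in pretreatment_names()) {
    r <- apply_pretreatment(pretreatment_spec(nm), tr, list(te))
    again <- pretreat_apply(r$fitted, te)
    expect_equal(again$absorbance, r$others[[1]]$absorbance, info = nm)
  }
})
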