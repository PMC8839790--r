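# Pretreatment operators, codec, the 41-combination grid, leakage safety.

lambda <- seq(1300, 1600, by = 3)

test_that("Savitzky-Golay reproduces polynomials and scales derivatives", {
  a <- 2e-4; b <- -0.5; cc <- 300
  quad <- a * lambda^2 + b * lambda + cc
  X <- rbind(quad, quad)
  interior <- 11:(length(lambda) - 10)
  # deriv 0 leaves an exact quadratic unchanged
  sm <- sgol(X, window = 21, poly_order = 2, deriv = 0, step_nm = 3)
  expect_lt(max(abs(sm[, interior] - X[, interior])), 1e-9)
  # second derivative of a*l^2 + b*l + c is the constant 2a (per nm^2)
  d2 <- sgol(X, window = 21, poly_order = 2, deriv = 2, step_nm = 3)
  expect_lt(max(abs(d2[, interior] - 2 * a)), 1e-9)
  # first derivative of a constant row is zero
  d1 <- sgol(matrix(5, 2, length(lambda)), 13, 2, 1, 3)
  expect_lt(max(abs(d1)), 1e-12)
  # window must be odd, larger than the polynomial order, smaller than p
  expect_error(sgol(X, window = 20), "odd")
  expect_error(sgol(X, window = 3, poly_order = 4), "exceed")
  expect_error(sgol(X, window = 999), "smaller")
})

test_that("SNV standardizes rows and is affine-invariant", {
  set.seed(1)
  x <- runif(length(lambda))
  X <- rbind(x, 3 * x + 7)
  out <- snv(X)
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans(out^2)) - 1)), 1e-12)
  # affine-transformed row maps to the identical output
  expect_lt(max(abs(out[1, ] - out[2, ])), 1e-12)
  # idempotence: snv of snv output is unchanged
  expect_lt(max(abs(snv(out) - out)), 1e-9)
  expect_error(snv(matrix(1, 2, 10)), "zero-variance")
})

test_that("MSC removes per-row affine scatter against the train reference", {
  set.seed(2)
  ref <- 0.5 + 0.3 * exp(-0.5 * ((lambda - 1450) / 40)^2)
  X_train <- rbind(ref, ref)  # reference = column mean = ref exactly
  fit <- msc_fit_apply(X_train, rbind(ref, 2 * ref + 5))
  # a row equal to the reference passes through; affine scatter is removed
  expect_lt(max(abs(fit$corrected[1, ] - ref)), 1e-9)
  expect_lt(max(abs(fit$corrected[2, ] - ref)), 1e-9)
  # the reference comes from the training set, not the applied set
  B <- rbind(ref + 10, ref + 10)  # very different mean level
  fit2 <- msc_fit_apply(X_train, B)
  expect_equal(fit2$reference, colMeans(X_train))
  # rows generated as m*s + a are recovered up to a common affine map of s
  s0 <- ref
  Xs <- t(vapply(1:20, function(i)
    runif(1, 0.5, 2) * s0 + runif(1, -1, 1), numeric(length(lambda))))
  corr <- msc_fit_apply(Xs)$corrected
  cors <- apply(corr, 1, function(r) cor(r, corr[1, ]))
  expect_true(all(cors > 1 - 1e-9))
})

test_that("detrending is an exact idempotent quadratic projection", {
  a <- 1e-5; b <- 0.01; cc <- 2
  quad <- a * lambda^2 + b * lambda + cc
  X <- rbind(quad, quad + exp(-0.5 * ((lambda - 1450) / 20)^2))
  out <- detrend(X, lambda)
  # a pure quadratic row vanishes
  expect_lt(max(abs(out[1, ])), 1e-9)
  # idempotence
  expect_lt(max(abs(detrend(out, lambda) - out)), 1e-9)
  # the residual band is orthogonal to the {1, l, l^2} basis
  basis <- cbind(1, lambda, lambda^2)
  proj <- crossprod(basis, out[2, ])
  expect_lt(max(abs(proj / colSums(basis^2))), 1e-9)
})

test_that("codec round-trips and rejects malformed or doubled scatter", {
  for (code in c("raw", "snv", "deTr_msc", "sgol@2-21-0_snv",
                 "sgol@2-13-0_sgol@2-13-2")) {
    expect_identical(format(parse_pretreatment(code)), code)
  }
  expect_error(parse_pretreatment("sgol@2-21"), "malformed")
  expect_error(parse_pretreatment("wavelet"), "unknown")
  expect_error(parse_pretreatment("snv_msc"), "at most one scatter")
})

test_that("the optimization grid has 41 unique members incl. all published specs", {
  grid <- enumerate_grid()
  codes <- vapply(grid, format, character(1))
  expect_length(codes, 41L)
  expect_false(anyDuplicated(codes) > 0)
  published <- c(
    # classification winners
    "sgol@2-21-0_snv", "sgol@2-13-0_sgol@2-13-2", "sgol@2-17-0",
    "sgol@2-13-0_sgol@2-17-2", "sgol@2-17-0_deTr", "sgol@2-13-0_sgol@2-21-1",
    "sgol@2-21-0_deTr_msc", "sgol@2-13-0_sgol@2-17-1", "sgol@2-13-0_msc",
    "sgol@2-13-0_deTr_msc", "sgol@2-17-0_sgol@2-21-1",
    "sgol@2-21-0_sgol@2-13-1", "sgol@2-17-0_msc",
    # display-model pretreatments from the score-plot captions
    "sgol@2-13-0_snv")
  expect_true(all(published %in% codes))
  # round-trip every grid member
  for (code in codes)
    expect_identical(format(parse_pretreatment(code)), code)
})

test_that("apply_pretreatment respects order and composes sgol passes", {
  set.seed(3)
  X <- matrix(runif(2 * length(lambda)), 2)
  # raw is the identity
  raw <- apply_pretreatment("raw", X, wavelengths = lambda)
  expect_identical(raw$train, X)
  # snv_deTr and deTr_snv differ on a sloped row
  sl <- rbind(0.001 * lambda + exp(-0.5 * ((lambda - 1400) / 30)^2),
              0.002 * lambda + exp(-0.5 * ((lambda - 1500) / 30)^2))
  o1 <- apply_pretreatment("snv_deTr", sl, wavelengths = lambda)$train
  o2 <- apply_pretreatment("deTr_snv", sl, wavelengths = lambda)$train
  expect_gt(max(abs(o1 - o2)), 1e-6)
  # chained sgol equals composing the two passes
  chained <- apply_pretreatment("sgol@2-13-0_sgol@2-13-2", X,
                                wavelengths = lambda)$train
  manual <- sgol(sgol(X, 13, 2, 0, 3), 13, 2, 2, 3)
  expect_equal(chained, manual, tolerance = 1e-12)
  # step failures carry the step index
  expect_error(
    apply_pretreatment("sgol@2-13-0_snv", matrix(1, 2, length(lambda)),
                       wavelengths = lambda),
    "step 2")
})

test_that("MSC state inside a spec is fitted on the training side only", {
  set.seed(4)
  ref <- 0.5 + 0.3 * exp(-0.5 * ((lambda - 1450) / 40)^2)
  Xt <- t(vapply(1:10, function(i) runif(1, .8, 1.2) * ref + runif(1, -.1, .1),
                 numeric(length(lambda))))
  Xv <- t(vapply(1:4, function(i) runif(1, .8, 1.2) * (ref + 3) + 1,
                 numeric(length(lambda))))
  res <- apply_pretreatment("msc", Xt, Xv, wavelengths = lambda)
  expect_equal(res$msc_reference, colMeans(Xt))
  # validation rows were corrected against the training reference:
  # correcting them against their own mean would give a different result
  own <- msc_fit_apply(Xv, Xv)$corrected
  expect_gt(max(abs(own - res$apply)), 1e-6)
})
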