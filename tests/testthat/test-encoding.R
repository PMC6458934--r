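test_that("temporal encoding maps the feature range onto the time window", {
  expect_equal(encode_feature(0, a = 0.01, b = 9, m = 0, M = 1), 0.01)
  expect_equal(encode_feature(1, a = 0.01, b = 9, m = 0, M = 1), 9)
  expect_equal(encode_feature(0.5, a = 0.01, b = 9, m = 0, M = 1), 4.505)
  # endpoint identities Y(m) = a, Y(M) = b on random windows/ranges
  set.seed(11)
  for (i in 1:200) {
    a <- runif(1, 0, 5); b <- a + runif(1, 0.1, 10)
    m <- runif(1, -10, 10); M <- m + runif(1, 0.1, 10)
    expect_equal(encode_feature(m, a, b, m, M), a, tolerance = 1e-9)
    expect_equal(encode_feature(M, a, b, m, M), b, tolerance = 1e-9)
    # strictly monotone inside the range
    f <- sort(runif(5, m, M))
    expect_true(all(diff(encode_feature(f, a, b, m, M)) > 0))
  }
  # out-of-range values clamp to the window endpoints
  expect_equal(encode_feature(-3, 0.01, 9, m = 0, M = 1), 0.01)
  expect_equal(encode_feature(42, 0.01, 9, m = 0, M = 1), 9)
  # degenerate range maps to the window midpoint
  expect_equal(encode_feature(3, 0.01, 9, m = 3, M = 3), (0.01 + 9) / 2)
})

test_that("encoding specs are fitted on the design columns only", {
  ds <- snn_dataset(cbind(c(0, 2, 4, 1), c(10, 20, 30, 40)),
                    c("a", "a", "b", "b"))
  spec <- fit_encoding(ds, a = 0.01, b = 9)
  expect_equal(unname(spec$m), c(0, 10))
  expect_equal(unname(spec$M), c(4, 40))
  expect_equal(unname(spec$r), c(4, 30))
  enc <- encode_dataset(ds, spec)
  expect_equal(dim(enc$spikes), dim(ds$x))
  # encoded design columns span exactly [a, b]
  expect_equal(unname(apply(enc$spikes, 2, min)), c(0.01, 0.01))
  expect_equal(unname(apply(enc$spikes, 2, max)), c(9, 9))
  # hand-computed cell-by-cell check of the linear map
  small <- snn_dataset(cbind(c(0, 4, 2, 1), c(10, 40, 20, 30)),
                       c("a", "b", "a", "b"))
  e2 <- encode_dataset(small, spec)
  expect_equal(e2$spikes[, 1], encode_feature(c(0, 4, 2, 1), 0.01, 9, 0, 4))
  expect_equal(e2$spikes[, 2],
               encode_feature(c(10, 40, 20, 30), 0.01, 9, 10, 40))
  # constant design column is flagged degenerate
  const <- snn_dataset(cbind(c(3, 3, 3, 3), c(1, 2, 3, 4)),
                       c("a", "a", "b", "b"))
  expect_warning(sc <- fit_encoding(const), "degenerate")
  expect_true(sc$degenerate[1] && !sc$degenerate[2])
  expect_equal(encode_dataset(const, sc)$spikes[, 1], rep(4.505, 4))
  # dimension mismatch is an error
  expect_error(encode_dataset(small, fit_encoding(snn_dataset(
    matrix(1:12, 4), c("a", "a", "b", "b")))), "dimensions")
})

test_that("stratified split halves every class and is seed-deterministic", {
  ds <- make_blobs(100, 3, 2, separation = 4, seed = 5)
  sp <- stratified_split(ds, seed = 3)
  expect_equal(nrow(sp$design$x) + nrow(sp$test$x), 100)
  expect_equal(sort(c(sp$design_idx, sp$test_idx)), 1:100)
  expect_equal(as.integer(table(sp$design$y)), c(25, 25))
  expect_equal(as.integer(table(sp$test$y)), c(25, 25))
  # odd class counts: the extra sample goes to the design half
  odd <- snn_dataset(matrix(rnorm(22), ncol = 2),
                     rep(c("u", "v"), c(7, 4)))
  so <- stratified_split(odd, seed = 1)
  expect_equal(as.integer(table(so$design$y)), c(4, 2))
  expect_equal(as.integer(table(so$test$y)), c(3, 2))
  # determinism and sensitivity to the seed
  expect_identical(stratified_split(ds, seed = 3)$design_idx, sp$design_idx)
  expect_false(identical(stratified_split(ds, seed = 4)$design_idx,
                         sp$design_idx))
})

test_that("synthetic blobs are balanced, separable and reproducible", {
  ds <- make_blobs(40, 2, 2, separation = 8, seed = 1)
  expect_s3_class(ds, "snn_dataset")
  expect_equal(as.integer(table(ds$y)), c(20, 20))
  # high separation: nearest-centroid rule scores 100%
  cents <- rbind(colMeans(ds$x[ds$y == 0, ]), colMeans(ds$x[ds$y == 1, ]))
  pred <- apply(ds$x, 1, function(r)
    which.min(colSums((t(cents) - r)^2)) - 1L)
  expect_equal(pred, ds$y)
  # separation 0: class-conditional means nearly coincide (n large)
  flat <- make_blobs(2000, 2, 2, separation = 0, seed = 2)
  mu <- colMeans(flat$x[flat$y == 0, ]) - colMeans(flat$x[flat$y == 1, ])
  expect_lt(sqrt(sum(mu^2)), 0.25)
  # same seed, same matrices; different seed, different data
  expect_identical(make_blobs(40, 2, 2, separation = 8, seed = 1)$x, ds$x)
  expect_false(identical(make_blobs(40, 2, 2, separation = 8, seed = 2)$x,
                         ds$x))
  expect_error(make_blobs(3, 2, 2), "n_samples")
})

test_that("CSV round trip preserves features and labels", {
  ds <- make_blobs(20, 3, 2, separation = 5, seed = 9)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(ds$x, label = paste0("c", ds$y)), f,
            row.names = FALSE)
  back <- read_dataset(f, label = "label")
  expect_equal(unname(back$x), unname(ds$x))
  expect_equal(back$y, ds$y)
  # label column by index
  back2 <- read_dataset(f, label = 4)
  expect_equal(back2$y, ds$y)
  unlink(f)
})
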