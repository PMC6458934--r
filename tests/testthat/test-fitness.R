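test_that("class targets follow the 12 + 3k progression", {
  t3 <- class_targets(3)
  expect_equal(t3$targets, c(12, 15, 18))
  expect_equal(t3$t_end, 20)
  t2 <- class_targets(2)
  expect_equal(t2$targets, c(12, 15))
  expect_equal(t2$t_end, 17)
  t6 <- class_targets(6)
  expect_equal(t6$targets, c(12, 15, 18, 21, 24, 27))
  expect_equal(t6$t_end, 29)
  expect_error(class_targets(1), "n_classes")
})

test_that("spike times decode to the nearest target class", {
  t2 <- class_targets(2)
  expect_equal(decode_spike_time(13.4, t2), 0L)
  expect_equal(decode_spike_time(13.5, t2), 0L)   # tie goes to the smaller id
  expect_equal(decode_spike_time(13.6, t2), 1L)
  expect_equal(decode_spike_time(NA, t2), NA_integer_)
  expect_equal(decode_spike_time(c(12, 15, NA), t2), c(0L, 1L, NA))
  # moving toward a class target never flips the prediction away from it
  t3 <- class_targets(3)
  set.seed(8)
  for (i in 1:50) {
    t0 <- runif(1, 10, 20)
    k <- decode_spike_time(t0, t3)
    closer <- t0 + 0.5 * (t3$targets[k + 1] - t0)
    expect_equal(decode_spike_time(closer, t3), k)
  }
})

test_that("fitness formulas match their hand sums", {
  expect_equal(squared_error(14, 12), 4)
  expect_equal(squared_error(c(12, 15), c(12, 15)), 0)
  expect_equal(squared_error(c(13, 16), c(12, 18)), 5)
  expect_error(squared_error(1, c(1, 2)), "length")
  expect_equal(accuracy_error(c(0L, 1L), c(0L, 1L)), 0)
  expect_equal(accuracy_error(c(1L, 0L), c(0L, 1L)), 1)
  expect_equal(accuracy_error(c(0L, 1L, 0L, NA), c(0L, 1L, 0L, 1L)), 0.25)
  # E_a only takes values in {0, 1/T, ..., 1}
  set.seed(9)
  for (i in 1:20) {
    T <- sample(1:30, 1)
    ea <- accuracy_error(sample(0:2, T, replace = TRUE),
                         sample(0:2, T, replace = TRUE))
    expect_true(ea >= 0 && ea <= 1)
    expect_equal(round(ea * T), ea * T, tolerance = 1e-12)
  }
  expect_error(accuracy_error(integer(0), integer(0)), "no predictions")
})

test_that("genotype evaluation composes mapping, parsing and simulation", {
  sg <- snn_grammar()
  enc <- tiny_encoded()
  targets <- class_targets(2)
  params <- srm_params(t_end = targets$t_end)
  # a genotype that exhausts its codons is invalid and gets the sentinel
  rec <- evaluate_genotype(integer(0), sg, enc, params, targets, "accuracy")
  expect_false(rec$valid)
  expect_equal(rec$value, sentinel_fitness("accuracy"))
  expect_equal(evaluate_genotype(integer(0), sg, enc, params, targets,
                                 "squared")$value,
               sentinel_fitness("squared"))
  # sentinel is strictly worse than any attainable valid value
  expect_gt(sentinel_fitness("accuracy"), 1)
  expect_gt(sentinel_fitness("squared"),
            length(enc$y) * params$t_end^2)
  # a valid genotype's fitness equals the topology evaluation of its word
  set.seed(14)
  repeat {
    geno <- sample(0:255, 500, replace = TRUE)
    word <- map_genotype(geno, sg)
    if (!is.na(word)) break
  }
  rec2 <- evaluate_genotype(geno, sg, enc, params, targets, "accuracy")
  expect_true(rec2$valid)
  expect_equal(rec2$word, word)
  ref <- evaluate_topology(parse_word(word, 1), enc, params, targets,
                           "accuracy")
  expect_equal(rec2$value, ref$value)
  expect_equal(rec2$output_times, ref$output_times)
  # determinism, bit for bit
  expect_identical(evaluate_genotype(geno, sg, enc, params, targets,
                                     "squared"),
                   evaluate_genotype(geno, sg, enc, params, targets,
                                     "squared"))
})

test_that("a network firing at the target time scores zero error", {
  # strong synapses fire one grid step after onset, so the output time is
  # set by the delays: 0.01 (input spike) + 0.01 + d_in + 0.01 + d_out
  targets <- class_targets(2)
  params <- srm_params(t_end = targets$t_end)
  top <- snn_topology(1, list(list(presyn = 0L, weight = 999, delay = 0.01,
                                   out_weight = 999, out_delay = 11.96)))
  enc <- list(spikes = matrix(0.01, 1, 1), y = 0L)
  rec_s <- evaluate_topology(top, enc, params, targets, "squared")
  expect_equal(rec_s$output_times, 12, tolerance = 1e-9)
  expect_equal(rec_s$value, 0, tolerance = 1e-12)
  rec_a <- evaluate_topology(top, enc, params, targets, "accuracy")
  expect_equal(rec_a$value, 0)
  expect_equal(rec_a$predictions, 0L)
  # one-pattern composition: fitness equals the hand-composed two-stage
  # first-spike search plus the squared-error formula
  h <- first_spike_time(0.01, 999, 0.01, params, search_from = 0)
  o <- first_spike_time(h, 999, 11.96, params,
                        search_from = params$decision_start)
  expect_equal(rec_s$value, squared_error(o, targets$targets[1]))
  # non-firing outputs are substituted with t_end under E_s
  silent <- snn_topology(1, list(list(presyn = 0L, weight = 0, delay = 0.01,
                                      out_weight = 0, out_delay = 1)))
  rec0 <- evaluate_topology(silent, enc, params, targets, "squared")
  expect_equal(rec0$value, (params$t_end - targets$targets[1])^2)
  expect_true(is.na(rec0$output_times))
  # ... and rejected (never correct) under E_a
  expect_equal(evaluate_topology(silent, enc, params, targets,
                                 "accuracy")$value, 1)
})
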