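test_that("Gray coding has the adjacency property over the full overlap range", {
  codes <- vapply(0:127, gray_encode, integer(7), width = 7L)
  # round trip
  expect_equal(vapply(0:127, function(k) gray_decode(gray_encode(k, 7L)), 0),
               as.numeric(0:127))
  # neighbours differ in exactly one bit
  diffs <- vapply(1:127, function(k) sum(codes[, k] != codes[, k + 1]), 0L)
  expect_true(all(diffs == 1L))
})

test_that("chromosome decoding honours channel gating and the overlap map", {
  layout <- chromosome_layout(8, 250)
  expect_equal(layout$length, 2015L)

  zero <- rep(0L, layout$length)
  ph <- decode_chromosome(zero, layout)
  expect_equal(ph$overlap_pct, 10L)          # minimum decode
  expect_equal(length(ph$active_channels), 0L)
  expect_equal(ph$total_selected, 0L)

  # feature bits all on for channel 3, but its channel bit off
  bits <- zero
  bits[7L + 8L + (2L * 250L + 1L):(3L * 250L)] <- 1L
  ph2 <- decode_chromosome(bits, layout)
  expect_equal(ph2$total_selected, 0L)
  bits[7L + 3L] <- 1L                        # switch the channel on
  ph3 <- decode_chromosome(bits, layout)
  expect_equal(ph3$active_channels, 3L)
  expect_equal(ph3$total_selected, 250L)
  expect_equal(ph3$per_channel[3L], 250)

  # encode/decode round trip over the exhaustive canonical overlap space
  small <- chromosome_layout(2, 4)
  for (pct in 10:90) {
    ch <- c(1L, 0L); fb <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L), 2, 4)
    bits <- encode_chromosome(pct, ch, fb, small)
    ph <- decode_chromosome(bits, small)
    expect_equal(ph$overlap_pct, pct)
    expect_identical(encode_chromosome(ph$overlap_pct, ch, fb, small), bits)
  }
})

test_that("uniform crossover conserves the per-position allele multiset", {
  set.seed(5)
  for (i in 1:200) {
    a <- sample(0:1, 60, replace = TRUE)
    b <- sample(0:1, 60, replace = TRUE)
    kids <- uniform_crossover(a, b, rate = 0.9)
    swapped <- mapply(function(x, y) sort(c(x, y)),
                      kids[[1]], kids[[2]])
    original <- mapply(function(x, y) sort(c(x, y)), a, b)
    expect_identical(swapped, original)
  }
  # identical parents and zero rate both give copies
  a <- sample(0:1, 30, replace = TRUE)
  expect_identical(uniform_crossover(a, a, 0.9), list(a, a))
  b <- sample(0:1, 30, replace = TRUE)
  expect_identical(uniform_crossover(a, b, 0), list(a, b))
  expect_error(uniform_crossover(a, b[-1], 0.5), "length")
})

test_that("mutation flip rate follows the linear schedule within binomial bounds", {
  cfg <- ga_config(pop_size = 10, generations = 30, seed = 1)
  L <- 500L
  eta <- L
  bits <- rep(0L, L)
  set.seed(2)
  flips_start <- replicate(2000, sum(mutate(bits, 0L, cfg, eta)))
  flips_end <- replicate(2000, sum(mutate(bits, 29L, cfg, eta)))
  # binomial oracle: mean L*p, 3-sigma band over the replicate mean
  check_band <- function(flips, p) {
    se <- sqrt(L * p * (1 - p) / length(flips))
    expect_lt(abs(mean(flips) - L * p), 3 * se)
  }
  check_band(flips_start, 10 / eta)
  check_band(flips_end, 1 / eta)
  # interior point of the line
  expect_equal(eegselect:::mutation_prob(14.5, cfg, eta),
               (10 / eta + 1 / eta) / 2)
})

test_that("binary tournament prefers fitness, then sparsity", {
  pop <- list(list(fitness = 0.2, total_selected = 10),
              list(fitness = 0.9, total_selected = 500))
  set.seed(3)
  wins <- table(replicate(400, tournament_select(pop)))
  # drawn pairs (1,2) or (2,1) must return individual 2; (2,2) returns 2;
  # only the (1,1) collision (prob 1/4) can return 1
  expect_equal(unname(wins["1"] / 400), 0.25, tolerance = 0.25)
  # equal fitness: the sparser individual wins any mixed draw, so with two
  # individuals it should be returned 3/4 of the time (only the (1,1)
  # self-draw returns the denser one)
  tie <- list(list(fitness = 0.5, total_selected = 300),
              list(fitness = 0.5, total_selected = 30))
  set.seed(4)
  frac2 <- mean(replicate(2000, tournament_select(tie)) == 2L)
  expect_equal(frac2, 0.75, tolerance = 0.05)
  expect_error(tournament_select(list()), "empty")
})

test_that("mu+lambda keeps the best and never loses the incumbent", {
  mk <- function(f, t) list(bits = NULL, fitness = f, total_selected = t)
  parents <- list(mk(1.0, 100), mk(1.0, 90))
  offspring <- list(mk(0.0, 10), mk(0.5, 10))
  kept <- mu_plus_lambda(parents, offspring, 2)
  expect_equal(vapply(kept, `[[`, 0, "fitness"), c(1.0, 1.0))
  pool4 <- list(mk(0.1, 1), mk(0.9, 1), mk(0.4, 1), mk(0.7, 1))
  top2 <- mu_plus_lambda(pool4[1:2], pool4[3:4], 2)
  expect_equal(sort(vapply(top2, `[[`, 0, "fitness")), c(0.7, 0.9))
  # fitness ties resolved toward fewer features
  tied <- mu_plus_lambda(list(mk(0.8, 500)), list(mk(0.8, 50)), 1)
  expect_equal(tied[[1]]$total_selected, 50)
  expect_error(mu_plus_lambda(parents, offspring, 0), "mu")
})

test_that("wrapper fitness is deterministic, cached, and zero for empty phenotypes", {
  rec <- generate_eeg(synth_config(duration = 24, n_events = 8, seed = 21))
  p <- preprocess(rec)
  parts <- split_by_events(p)
  layout <- chromosome_layout(8, 100)
  ctx <- fitness_context(parts$train, parts$validation, layout, seed = 7)

  empty <- rep(0L, layout$length)
  expect_equal(ga_fitness(empty, ctx), 0)

  set.seed(10)
  bits <- sample(0:1, layout$length, replace = TRUE)
  f1 <- ga_fitness(bits, ctx)
  f2 <- ga_fitness(bits, ctx)  # cache hit
  expect_identical(f1, f2)
  ctx2 <- fitness_context(parts$train, parts$validation, layout, seed = 7)
  expect_identical(suppressWarnings(ga_fitness(bits, ctx2)), f1)  # recomputed
  expect_true(f1 >= 0 && f1 <= 1)

  # fitness recomputed outside the GA from the decoded phenotype matches
  ph <- decode_chromosome(bits, layout)
  ds_t <- suppressWarnings(make_training_set(parts$train, 100, ph$overlap))
  ds_v <- make_sliding_set(parts$validation, 100, ph$overlap)
  cols <- which(as.vector(t(ph$feature_mask)))
  mseed <- (7 * 7919 + eegselect:::chromosome_hash(bits)) %% 2147483629
  m <- suppressWarnings(mlp_train(ds_t$X[, cols], ds_t$label,
                                  mlp_spec(IL = length(cols), seed = mseed)))
  expect_equal(score_windows(ds_v, predict(m, ds_v$X[, cols]))$F1, f1)
})

test_that("a seeded GA run is reproducible and monotonically improving", {
  rec <- generate_eeg(synth_config(duration = 24, n_events = 8, seed = 22))
  p <- preprocess(rec)
  parts <- split_by_events(p)
  layout <- chromosome_layout(8, 100)
  cfg <- ga_config(pop_size = 6, generations = 5, seed = 13)
  r1 <- suppressWarnings(ga_run(parts$train, parts$validation, cfg, layout))
  r2 <- suppressWarnings(ga_run(parts$train, parts$validation, cfg, layout))
  expect_identical(r1$log, r2$log)
  expect_identical(r1$best$bits, r2$best$bits)
  expect_true(all(diff(r1$log$best_f1) >= 0))  # mu+lambda elitism
  expect_equal(nrow(r1$log), 5L)
})
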