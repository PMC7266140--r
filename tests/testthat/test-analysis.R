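# Filtering, assembly identification, similarity criterion, decoders,
# voxelization.

test_that("low-pass filter matches the truncated exponential kernel", {
  sp <- data.frame(neuron = 1L, time_ms = 10)
  tr <- lowpass_traces(sp, 1, 0, 200)
  expect_equal(unname(tr["30", 1]), exp(-1)) # one spike, 20 ms later, tau 20
  expect_equal(unname(tr["10", 1]), 1)       # at the spike
  expect_equal(unname(tr["5", 1]), 0)        # before the spike
  expect_equal(unname(tr["115", 1]), 0)      # older than T_LP = 100: truncated
  # random train equals the brute-force convolution
  spr <- random_trains(3, 80, 500, seed = 2)
  tr2 <- lowpass_traces(spr, 3, 0, 500)
  grid <- as.numeric(rownames(tr2))
  brute <- vapply(grid, function(t) {
    s <- spr$time_ms[spr$neuron == 2]
    # epsilon guards the float comparison at the exact truncation boundary
    sum(exp(-(t - s[s <= t & s >= t - 100 - 1e-9]) / 20))
  }, 1.0)
  expect_equal(unname(tr2[, 2]), brute, tolerance = 1e-9)
})

test_that("assembly identification applies a strict rate threshold", {
  expect_equal(identify_assembly(integer(10), 100), integer(0))
  counts <- c(6, 5, 0, 7) # over 100 ms: 60, 50, 0, 70 Hz
  expect_equal(identify_assembly(counts, 100), c(1L, 4L))
})

test_that("similarity criterion implements the 80/20 rule", {
  ref <- 1:60
  r1 <- similarity(ref, c(1:50, 101:105))
  expect_equal(r1$retained_fraction, 50 / 60)
  expect_equal(r1$excess_count, 5)
  expect_true(r1$passes) # 0.833 >= 0.8 and 5 <= 12
  r2 <- similarity(ref, 1:47)
  expect_false(r2$passes) # 0.783 < 0.8
  r3 <- similarity(ref, ref)
  expect_true(r3$passes && r3$retained_fraction == 1 && r3$excess_count == 0)
  # boundary: exactly 20% excess still passes; one more fails
  expect_true(similarity(ref, c(ref, 101:112))$passes)
  expect_false(similarity(ref, c(ref, 101:113))$passes)
  expect_error(similarity(integer(0), 1:3), "empty")
})

test_that("similarity is monotone in correctly recalled neurons", {
  ref <- 1:50
  n_checked <- 0
  with_local_seed(31, for (i in 1:100) {
    rec <- c(sample(ref, sample(40:49, 1)), sample(51:120, sample(0:10, 1)))
    s0 <- similarity(ref, rec)
    extra <- setdiff(ref, rec)[1]
    if (!s0$passes || is.na(extra)) next
    n_checked <- n_checked + 1
    expect_true(similarity(ref, c(rec, extra))$passes)
  })
  expect_gt(n_checked, 20)
})

test_that("linear decoder separates well-separated classes and fails permuted", {
  with_local_seed(11, {
    n <- 90
    X <- rbind(matrix(rnorm(n * 20, 0), n, 20),
               matrix(rnorm(n * 20, 1.5), n, 20),
               matrix(rnorm(n * 20, -1.5), n, 20))
    y <- rep(1:3, each = n)
    dec <- train_decoder(X, y)
    expect_lt(mean(classify(dec, X) != y), 0.05)
    expect_equal(decoder_error(dec, X, 99), 1) # label absent from training
    # permuted labels: chance-level error (~2/3 for 3 classes)
    yp <- sample(y)
    decp <- train_decoder(X, yp)
    Xtest <- matrix(rnorm(60 * 20), 60, 20)
    expect_gt(mean(classify(decp, Xtest) != rep(1:3, 20)), 0.4)
  })
})

test_that("voxelization sums, averages, adds calibrated noise, and is linear", {
  part <- voxel_partition(20, 5, seed = 1)
  expect_true(all(lengths(part) == 4))
  tr <- matrix(rep(1:20, each = 10), 10, 20)
  v0 <- voxelize(tr, part, noise_var = 0)
  expect_equal(v0, vapply(part, sum, 1.0)) # time-constant traces
  expect_equal(voxelize(2 * tr, part, noise_var = 0), 2 * v0) # linearity
  expect_equal(unname(voxelize(matrix(0, 10, 20), part, noise_var = 0)), rep(0, 5))
  # noise variance calibration over repeated draws
  draws <- vapply(1:2000, function(s)
    voxelize(matrix(0, 2, 20), part, noise_var = 5, seed = s)[1], 1.0)
  expect_lt(abs(stats::var(draws) - 5), 0.5)
  # fixed partition: same seed, same grouping
  expect_identical(voxel_partition(20, 5, seed = 1), part)
})

test_that("assembly-match cost is a weighted symmetric difference", {
  expect_equal(assembly_cost(1:5, 1:5, 1:9, 1:9)$cost, 0)
  cv <- assembly_cost(1:10, c(1:8, 21, 22), 1:20, c(1:15, 31:35))
  expect_equal(cv$cost, 4 + 1e-4 * 10)
  # symmetry under swapping CREATE and RECALL
  cv2 <- assembly_cost(c(1:8, 21, 22), 1:10, c(1:15, 31:35), 1:20)
  expect_equal(cv$cost, cv2$cost)
})

test_that("spike records and weight snapshots round-trip as text", {
  sp <- data.frame(pop = c("C_E", "C_E", "X"), neuron = c(3L, 7L, 1L),
                   time_ms = c(0.1, 5.5, 9))
  f <- tempfile()
  write_spikes(sp, f)
  expect_equal(read_spikes(f), sp)
  net <- tiny_net(seed = 1)
  fw <- tempfile()
  write_weights(net, "C_EI", fw, timestamp = "t0")
  back <- read_weights(fw)
  expect_equal(attr(back, "group"), "C_EI")
  expect_equal(back$w, net$groups$C_EI$w)
  unlink(c(f, fw))
})
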