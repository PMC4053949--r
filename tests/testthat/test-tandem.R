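test_that("a perfect array is recovered exactly", {
  set.seed(1)
  m <- randomDNA(60)
  h <- detectTandem(strrep(m, 10), minPeriod = 10, maxPeriod = 300)
  expect_equal(nrow(h), 1)
  expect_equal(h$period, 60)
  expect_equal(h$copy_number, 10)
  expect_equal(h$identity, 100)
  expect_equal(c(h$start, h$end), c(0, 600))
  expect_equal(canonicalizeMonomer(h$consensus), canonicalizeMonomer(m))
})

test_that("fewer than two copies yields no hit", {
  set.seed(2)
  m <- randomDNA(200)
  read <- paste0(m, substr(m, 1, 100))        # 1.5 copies
  expect_equal(nrow(detectTandem(read, minPeriod = 50, maxPeriod = 300)), 0)
  # short reads return an empty result, not an error
  expect_equal(nrow(detectTandem("ACGTACGT", minPeriod = 50)), 0)
})

test_that("mutated arrays match the brute-force oracle", {
  set.seed(3)
  m <- randomDNA(171)
  read <- make_array_read(m, 8, rate = 0.02, seed = 4)
  h <- detectTandem(read, minPeriod = 50, maxPeriod = 900)
  mono <- h[which.min(h$period), ]
  expect_equal(mono$period, 171)
  expect_gte(mono$identity, 94)
  o <- bruteForcePeriodOracle(read, 171)
  expect_lt(abs(mono$identity - o$identity), 2.5)
})

test_that("the oracle sees multimer ambiguity and background identity", {
  set.seed(4)
  m <- randomDNA(50)
  read <- strrep(m, 8)
  expect_equal(bruteForcePeriodOracle(read, 50)$identity, 100)
  expect_equal(bruteForcePeriodOracle(read, 100)$identity, 100)
  rnd <- randomDNA(400)
  ids <- vapply(c(37, 50, 83, 120), function(p)
    bruteForcePeriodOracle(rnd, p)$identity, numeric(1))
  expect_true(all(ids > 15 & ids < 40))
})

test_that("detector period agrees with the oracle on random instances", {
  set.seed(5)
  for (i in 1:20) {
    p <- sample(20:80, 1)
    copies <- sample(5:9, 1)
    read <- make_array_read(randomDNA(p), copies, rate = 0.01, seed = 50 + i)
    h <- detectTandem(read, minPeriod = 10, maxPeriod = nchar(read))
    expect_gt(nrow(h), 0)
    # the array hit spans (nearly) the whole read; incidental micro-repeats
    # do not
    h <- h[h$end - h$start >= 0.5 * nchar(read), ]
    mono <- h[which.min(h$period), ]
    qs <- 10:min(120, floor(nchar(read) / 2))
    best_p <- oracle_fundamental(read, qs)
    expect_lte(abs(mono$period - best_p), 1)
  }
})

test_that("detection is strand symmetric", {
  set.seed(6)
  for (i in 1:5) {
    read <- make_array_read(randomDNA(80), 6, rate = 0.02, seed = 80 + i)
    h1 <- detectTandem(read, minPeriod = 20, maxPeriod = 300)
    h2 <- detectTandem(revComp(read), minPeriod = 20, maxPeriod = 300)
    m1 <- h1[which.min(h1$period), ]; m2 <- h2[which.min(h2$period), ]
    expect_equal(m1$period, m2$period)
    expect_lt(abs(m1$identity - m2$identity), 1.5)
  }
})

test_that("score never decreases when an exact unit is appended", {
  set.seed(7)
  m <- randomDNA(70)
  scores <- vapply(3:8, function(k) {
    h <- detectTandem(strrep(m, k), minPeriod = 20, maxPeriod = 300)
    max(h$score[h$period == 70])
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("soft-masked spans are not reported as repeats", {
  # a poly-AT region is periodic but should be killed by its DUST mask
  s <- paste0(randomDNA(100), strrep("AT", 150), randomDNA(100))
  masked <- softMask(s, dustMask(s))
  h <- detectTandem(masked, minPeriod = 1, maxPeriod = 200)
  expect_equal(nrow(h), 0)
})

test_that("candidate filters mirror the pipeline rules", {
  rl <- c(read1 = 1000L)
  # span: 79% removed, 85% kept
  h <- fake_hits(c("read1", "read1"), start = c(0, 0), end = c(790, 850),
                 period = c(100, 100))
  kept <- filterHits(h, rl)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$end, 850)
  # period: 49 removed, 50 kept
  h2 <- fake_hits(c("read1", "read1"), start = 0, end = 900,
                  period = c(49, 50))
  expect_equal(filterHits(h2, rl)$period, 50)
  # same span: shortest period retained
  h3 <- fake_hits(c("read1", "read1"), start = 0, end = 900,
                  period = c(171, 342))
  expect_equal(filterHits(h3, rl)$period, 171)
  # non-overlapping hits are kept independently
  h4 <- fake_hits(c("read1", "read1"), start = c(0, 820), end = c(810, 1000),
                  period = c(60, 90))
  expect_equal(sort(filterHits(h4, rl, minSpanFraction = 0.1)$period), c(60, 90))
})
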