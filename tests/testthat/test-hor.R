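test_that("a planted AB dimer array produces a dimer call", {
  set.seed(1)
  m <- randomDNA(171)
  read <- make_array_read(m, 8, rate = 0.005, hor = TRUE, nsub = 8, seed = 2)
  hits <- detectTandem(read, minPeriod = 50, maxPeriod = 900)
  calls <- detectHOR(hits)
  expect_gt(nrow(calls), 0)
  best <- calls[which.min(calls$multimer_period), ]
  expect_equal(best$multiplicity, 2L)
  expect_equal(best$monomer_period, 171)
  expect_gt(best$identity_gain, 0)
  expect_gt(best$score_gain, 0)
})

test_that("homogeneous arrays never fire the HOR detector", {
  set.seed(2)
  fired <- vapply(1:50, function(i) {
    read <- make_array_read(randomDNA(171), 8, rate = 0.01, seed = 100 + i)
    hits <- detectTandem(read, minPeriod = 50, maxPeriod = 900)
    nrow(detectHOR(hits)) > 0
  }, logical(1))
  expect_lt(mean(fired), 0.05)
})

test_that("a truncated-unit HOR is recognized with its truncation length", {
  set.seed(3)
  m <- randomDNA(175)
  # super-unit: five diverged full monomers plus a 58-bp truncated copy
  variants <- vapply(1:5, function(i) {
    v <- m
    for (e in make_sub_edits(m, 5, seed = 10 + i))
      substr(v, e$pos, e$pos) <- e$base
    v
  }, character(1))
  super_unit <- paste0(paste(variants, collapse = ""), substr(m, 1, 58))
  read <- strrep(super_unit, 3)   # 2,799 bp
  hits <- detectTandem(read, minPeriod = 50, maxPeriod = 1200)
  calls <- detectHOR(hits)
  trunc <- calls[!is.na(calls$truncated_unit_len), ]
  expect_gt(nrow(trunc), 0)
  expect_lte(abs(trunc$truncated_unit_len[1] - 58), 6)
  expect_equal(trunc$multiplicity[1], 6L)
})

test_that("instances tile the array and alternate for dimeric HORs", {
  set.seed(4)
  m <- randomDNA(171)
  read <- make_array_read(m, 10, rate = 0, hor = TRUE, nsub = 8, seed = 5)
  hits <- detectTandem(read, minPeriod = 50, maxPeriod = 900)
  mono <- hits[hits$period == 171, ][1, ]
  inst <- extractInstances(read, mono)
  expect_gte(length(inst$instances), 8)
  b <- inst$boundaries
  expect_true(all(diff(b) > 0))                      # no overlaps or gaps
  cl <- clusterInstances(inst$instances, seed = 6)
  expect_equal(length(unique(cl$labels)), 2)
  expect_true(all(abs(diff(cl$labels)) == 1))        # alternation A,B,A,B...
  expect_gte(cl$support, 90)
  # labels invariant under instance reordering (up to label swap)
  rev_cl <- clusterInstances(rev(inst$instances), seed = 6)
  agree <- mean(rev(rev_cl$labels) == cl$labels)
  expect_true(agree %in% c(0, 1))
})

test_that("a perfect array yields identical instances and no split", {
  m <- randomDNA(80)
  read <- strrep(m, 10)
  hits <- detectTandem(read, minPeriod = 20, maxPeriod = 400)
  mono <- hits[hits$period == 80, ][1, ]
  inst <- extractInstances(read, mono)
  expect_equal(length(unique(inst$instances)), 1)
  cl <- clusterInstances(inst$instances)
  expect_null(cl$tree)
  expect_equal(cl$labels, rep(1L, length(inst$instances)))
  expect_error(clusterInstances(inst$instances[1:3]), "at least 4")
})

test_that("random instances get no supported bipartition", {
  set.seed(7)
  supports <- vapply(1:10, function(i) {
    inst <- vapply(1:8, function(j) randomDNA(100), character(1))
    clusterInstances(inst, seed = i)$support
  }, numeric(1))
  expect_lt(mean(supports), 70)
})

test_that("the half-alignment test separates dimer origins from noise", {
  set.seed(8)
  s <- randomDNA(171)
  exact <- halfAlignmentTest(paste0(s, s), s)
  expect_equal(exact$identity_first, 100)
  expect_equal(exact$identity_second, 100)
  expect_length(exact$diff_columns, 0)
  mut <- .mutate_copies_for_test(s, 0.10)
  half <- halfAlignmentTest(paste0(s, mut), s)
  expect_gt(half$identity_first, 95)
  expect_lt(half$identity_second, half$identity_first)
  expect_gt(half$identity_second, 80)
  expect_gt(length(half$diff_columns), 0)
  unrel <- halfAlignmentTest(randomDNA(342), randomDNA(171))
  expect_lt(unrel$identity_first, 35)
  expect_lt(unrel$identity_second, 35)
  expect_error(halfAlignmentTest(randomDNA(300), randomDNA(171)), "ratio")
})
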