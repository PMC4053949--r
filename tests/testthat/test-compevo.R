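test_that("global identity handles identity, rotation and the credit formula", {
  set.seed(1)
  s <- randomDNA(100)
  expect_equal(globalIdentity(s, s)$identity, 100)
  expect_equal(globalIdentity(rotateSeq(s, 37), s)$identity, 100)
  expect_equal(globalIdentity(revComp(s), s)$identity, 100)
  # engineered alignment: 50 columns with 45 matches inside unalignable
  # flanks -> 100 * (45 + 0.25 * 50) / 100 = 57.5
  core <- randomDNA(50)
  mut <- core
  for (p in c(10, 18, 27, 35, 43))
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), substr(core, p, p))[1]
  a <- paste0(mut, strrep("A", 50))
  b <- paste0(core, strrep("C", 50))
  expect_equal(globalIdentity(a, b)$identity, 57.5)
})

test_that("unrelated monomers sit at the 25% background", {
  set.seed(2)
  ids <- vapply(1:60, function(i)
    globalIdentity(randomDNA(200), randomDNA(200))$identity, numeric(1))
  expect_lt(abs(mean(ids) - 25), 1)
})

test_that("identity is symmetric and the matrix is exactly symmetric", {
  set.seed(3)
  for (i in 1:5) {
    a <- randomDNA(150)
    b <- .mutate_copies_for_test(rotateSeq(a, 40), 0.2)
    expect_lt(abs(globalIdentity(a, b)$identity -
                  globalIdentity(b, a)$identity), 3)
  }
  mons <- c(sp1 = randomDNA(150), sp2 = randomDNA(170), sp3 = randomDNA(160))
  m <- identityMatrix(mons)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 100))
})

test_that("similarity groups recover a planted clade", {
  set.seed(4)
  anc <- randomDNA(180)
  tr <- ape::read.tree(text = "((A:5,B:5):5,C:10);")
  clade <- simulateMonomerDivergence(anc, tr, 0.002, seed = 5)
  mons <- c(clade, X = randomDNA(180), Y = randomDNA(180))
  m <- identityMatrix(mons)
  gr <- similarityGroups(m, 70)
  expect_equal(length(gr), 1)
  expect_equal(gr[[1]], c("A", "B", "C"))
  expect_equal(length(similarityGroups(m, 101)), 0)
  # invariant to species order
  m2 <- identityMatrix(mons[c(4, 2, 5, 1, 3)])
  gr2 <- similarityGroups(m2, 70)
  expect_equal(gr2[[1]], c("A", "B", "C"))
})

test_that("polytomy resolution is uniform, lossless and deterministic", {
  bin <- fixture_tree(8, seed = 1)
  expect_identical(resolvePolytomies(bin, seed = 2), bin)
  tri <- ape::read.tree(text = "((A:5,B:5,C:5):5,D:10);")
  # three possible resolutions of the internal trifurcation, identified by
  # which pair of A,B,C becomes sisters (inserted branches have zero length,
  # so distances cannot tell them apart)
  cherry <- vapply(1:1500, function(s) {
    r <- resolvePolytomies(tri, seed = s)
    if (!ape::is.binary(r)) return("nonbinary")
    d <- ape::cophenetic.phylo(r)
    d0 <- ape::cophenetic.phylo(tri)[rownames(d), colnames(d)]
    if (max(abs(d - d0)) > 1e-12) return("lengths-changed")
    abc <- match(c("A", "B", "C"), r$tip.label)
    parents <- r$edge[match(abc, r$edge[, 2]), 1]
    sib <- c("A", "B", "C")[parents == parents[duplicated(parents)][1]]
    paste(sort(sib), collapse = "")
  }, character(1))
  expect_true(all(cherry %in% c("AB", "AC", "BC")))
  tab <- table(cherry)
  expect_equal(length(tab), 3)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  expect_identical(ape::write.tree(resolvePolytomies(tri, seed = 9)),
                   ape::write.tree(resolvePolytomies(tri, seed = 9)))
})

test_that("node averaging partitions tip pairs by their MRCA", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  mat <- matrix(100, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mat["A", "B"] <- mat["B", "A"] <- 80
  mat["A", "C"] <- mat["C", "A"] <- 40
  mat["B", "C"] <- mat["C", "B"] <- 60
  nc <- nodeAverage(tr, mat)
  nc <- nc[order(nc$age), ]
  expect_equal(nc$mean_identity, c(80, 50))       # inner: AB; root: mean(AC, BC)
  expect_equal(nc$age, c(1, 2))
  expect_equal(nc$n_pairs, c(1L, 2L))
  # partition property on a larger random tree
  tr2 <- fixture_tree(10, seed = 2)
  m2 <- matrix(50, 10, 10, dimnames = list(tr2$tip.label, tr2$tip.label))
  nc2 <- nodeAverage(tr2, m2)
  expect_equal(sum(nc2$n_pairs), choose(10, 2))
  expect_error(nodeAverage(tr2, m2[1:5, 1:5]), "missing tips")
})

test_that("decay fit recovers exact power-law parameters", {
  t <- seq(2, 100, length.out = 30)
  H <- 90 * t^-0.5
  fit <- fitDecay(data.frame(age = t, mean_identity = H))
  expect_equal(fit$alpha, 90, tolerance = 1e-3)
  expect_equal(fit$lambda, -0.5, tolerance = 1e-3)
  expect_equal(fit$t_background, (25 / 90)^(1 / -0.5), tolerance = 1e-3)
  flat <- fitDecay(data.frame(age = t, mean_identity = rep(60, 30)))
  expect_lt(abs(flat$lambda), 1e-4)
  expect_equal(flat$t_background, Inf)
  expect_error(fitDecay(data.frame(age = c(0, 0), mean_identity = c(1, 2))),
               "at least 3")
  expect_error(fitDecay(data.frame(age = rep(5, 5), mean_identity = 1:5)),
               "constant age")
})

test_that("background time falls as substitution rate rises", {
  set.seed(5)
  anc <- randomDNA(200)
  tr <- fixture_tree(12, seed = 6, depth = 80)
  tbg <- vapply(c(0.004, 0.012, 0.03), function(rate) {
    tips <- simulateMonomerDivergence(anc, tr, rate, seed = 7)
    m <- identityMatrix(tips)
    fit <- fitDecay(nodeAverage(tr, m))
    min(fit$t_background, 1e4)
  }, numeric(1))
  expect_true(all(diff(tbg) < 0))
})

test_that("Blomberg's K agrees with an independent implementation", {
  skip_if_not_installed("picante")
  tr <- fixture_tree(15, seed = 8)
  x <- simulateBMTrait(tr, sigma2 = 2, seed = 9)
  ours <- blombergK(tr, x, nPerm = 99, seed = 10)
  ref <- picante::Kcalc(x[tr$tip.label], tr)
  expect_equal(ours$K, as.numeric(ref), tolerance = 1e-8)
  expect_error(blombergK(tr, setNames(rep(1, 15), tr$tip.label)),
               "zero-variance")
})

test_that("K is near 1 under its Brownian null and below 1 for iid traits", {
  tr <- fixture_tree(20, seed = 11)
  ks <- vapply(1:120, function(i)
    blombergK(tr, simulateBMTrait(tr, 1, seed = 300 + i), nPerm = 99,
              seed = i)$K, numeric(1))
  expect_gt(mean(ks), 0.85)
  expect_lt(mean(ks), 1.15)
  set.seed(12)
  ks_iid <- vapply(1:60, function(i) {
    x <- setNames(rnorm(20), tr$tip.label)
    blombergK(tr, x, nPerm = 99, seed = i)$K
  }, numeric(1))
  expect_lt(mean(ks_iid), mean(ks))
})

test_that("trait correlations are rank-based and order-invariant", {
  set.seed(13)
  d <- data.frame(species = sprintf("s%02d", 1:50),
                  length = sample(50:500, 50),
                  gc = runif(50, 0.2, 0.7),
                  fraction = 10^runif(50, -4, -1))
  ct <- traitCorrelations(d)
  expect_equal(nrow(ct), 3)
  expect_true(all(abs(ct$rho) < 0.5))   # independent traits
  ct2 <- traitCorrelations(d[sample(50), ])
  expect_equal(ct$rho, ct2$rho, tolerance = 1e-12)
  # a perfectly monotone pair has rho 1
  d$gc <- d$length / 1000
  ct3 <- traitCorrelations(d)
  expect_equal(ct3$rho[ct3$trait_a == "length" & ct3$trait_b == "gc"], 1)
})
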