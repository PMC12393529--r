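test_that("patristic distances match hand values and shortest-path oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- patristic_distances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ds <- patristic_distances(star)
  expect_true(all(ds[upper.tri(ds)] == 2))

  tr20 <- simulate_cophylogeny(20, switch_prob = 0.5, seed = 77)$symbiont
  d <- patristic_distances(tr20)
  o <- oracle_patristic(tr20)[rownames(d), colnames(d)]
  expect_equal(d, o, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PCoA reproduces Euclidean structure and handles corrections", {
  # three collinear points at 0, 1, 3
  d <- as.matrix(dist(c(0, 1, 3)))
  dimnames(d) <- list(letters[1:3], letters[1:3])
  xy <- pcoa_coords(d, "none")
  expect_equal(ncol(xy), 1L)
  expect_equal(as.matrix(dist(xy)), d, ignore_attr = TRUE, tolerance = 1e-9)

  withr::with_seed(5, {
    pts <- matrix(rnorm(20), 10, 2)
  })
  d2 <- as.matrix(dist(pts))
  dimnames(d2) <- list(sprintf("p%02d", 1:10), sprintf("p%02d", 1:10))
  rec <- pcoa_coords(d2, "cailliez")
  expect_equal(as.matrix(dist(rec)), d2, ignore_attr = TRUE, tolerance = 1e-6)

  # ultrametric tree distances are Euclidean-compatible: no negative axes
  ut <- upgma(d2)
  du <- patristic_distances(ut)
  expect_no_warning(pcoa_coords(du, "none"))
})

test_that("PACo attains its floor p-value on perfectly congruent trees", {
  co <- simulate_cophylogeny(8, seed = 3)
  res <- paco(patristic_distances(co$host), patristic_distances(co$symbiont),
              co$assoc, n_permutations = 999, seed = 4)
  expect_lt(res$m2, 0.05)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$r2, 1 - res$m2)
})

test_that("m2 equals the independent symmetric-Procrustes computation", {
  for (s in 1:5) {
    co <- simulate_cophylogeny(10, switch_prob = 0.4, multi_assoc_rate = 0.5,
                               seed = s)
    hd <- patristic_distances(co$host)
    sd_ <- patristic_distances(co$symbiont)
    res <- paco(hd, sd_, co$assoc, n_permutations = 9, seed = 1)
    expect_equal(res$m2, oracle_m2_vegan(hd, sd_, co$assoc), tolerance = 1e-8)
  }
})

test_that("m2 is invariant to tip order and distance rescaling", {
  co <- simulate_cophylogeny(9, switch_prob = 0.3, seed = 8)
  hd <- patristic_distances(co$host)
  sd_ <- patristic_distances(co$symbiont)
  base <- paco(hd, sd_, co$assoc, n_permutations = 9, seed = 1)$m2
  ordh <- withr::with_seed(2, sample(nrow(hd)))
  hd2 <- hd[ordh, ordh]
  scaled <- paco(hd2 * 7.3, sd_ * 0.21, co$assoc, n_permutations = 9,
                 seed = 1)$m2
  expect_equal(scaled, base, tolerance = 1e-9)
  # p-values live on the add-one grid
  r <- paco(hd, sd_, co$assoc, n_permutations = 99, seed = 3)
  expect_gte(r$p_value, 1 / 100)
  expect_lte(r$p_value, 1)
})

test_that("paco rejects degenerate inputs", {
  co <- simulate_cophylogeny(8, seed = 3)
  a <- co$assoc[, 1:2]
  a <- a[rowSums(a) > 0, , drop = FALSE]
  expect_error(paco(patristic_distances(co$host),
                    patristic_distances(co$symbiont), a, 9),
               "at least 3")
})

test_that("published m2 values imply the published R2 via r2 = 1 - m2", {
  # Faviidae-style check: m2 = 0.59 must give R2 = 0.41
  expect_equal(1 - 0.59, 0.41)
  call <- classify_phylosymbiosis(p = 0.025, r2 = 1 - 0.59)
  expect_equal(call$signal, "high")
  expect_equal(call$congruence, "weak")
})

test_that("classification follows the published decision rules", {
  c1 <- classify_phylosymbiosis(0.47, 0.14, rf = 0.93)
  expect_equal(c(c1$signal, c1$congruence), c("none", "none"))
  c2 <- classify_phylosymbiosis(0.011, 0.11, rf = 0.85)
  expect_equal(c(c2$signal, c2$congruence), c("low", "none"))
  c3 <- classify_phylosymbiosis(0.0009, 0.20)
  expect_equal(c(c3$signal, c3$congruence), c("high", "none"))
  # congruence requires signal; boundary r2 = 0.25 is not enough
  c4 <- classify_phylosymbiosis(0.01, 0.25)
  expect_equal(c4$congruence, "none")
  c5 <- classify_phylosymbiosis(0.01, 0.61)
  expect_equal(c5$congruence, "strong")
  # rf gate blocks congruence when enabled
  c6 <- classify_phylosymbiosis(0.01, 0.5, rf = 0.9, rf_gate = 0.8)
  expect_equal(c6$congruence, "none")
  expect_true(all(vapply(list(c1, c2, c3, c4),
                         function(x) x$congruence == "none" || x$signal != "none",
                         logical(1))))
})

test_that("tip mapping subsamples uniformly and respects one-to-one shortcuts", {
  co <- simulate_cophylogeny(8, seed = 3)
  trees <- map_symbiont_tips(co$symbiont, co$assoc, n_subsamples = 50, seed = 1)
  expect_length(trees, 1)     # one-to-one: single relabeled tree
  expect_setequal(trees[[1]]$tip.label, rownames(co$assoc))

  # a host with 3 linked tips: each chosen with frequency ~1/3; the
  # chosen tip is identifiable from its distinct terminal branch length
  symb <- ape::read.tree(text = "((s1:1,s2:2):1,(s3:5,s4:1):1);")
  a <- matrix(c(1L, 1L, 1L, 0L,
                0L, 0L, 0L, 1L), 2, byrow = TRUE,
              dimnames = list(c("h1", "h2"), c("s1", "s2", "s3", "s4")))
  n_sub <- 300
  trees <- map_symbiont_tips(symb, a, n_subsamples = n_sub, seed = 2)
  expect_length(trees, n_sub)
  chosen <- vapply(trees, function(tr) {
    d <- patristic_distances(tr)["h1", "h2"]
    c("4" = "s1", "5" = "s2", "6" = "s3")[[as.character(d)]]
  }, character(1))
  freq <- table(factor(chosen, levels = c("s1", "s2", "s3")))
  expect_true(all(abs(freq / n_sub - 1 / 3) < 3 * sqrt((1/3) * (2/3) / n_sub)))
  # determinism
  t1 <- map_symbiont_tips(symb, a, n_subsamples = 5, seed = 9)
  t2 <- map_symbiont_tips(symb, a, n_subsamples = 5, seed = 9)
  expect_identical(lapply(t1, ape::write.tree), lapply(t2, ape::write.tree))
})

test_that("congruence RF is 0 for identical trees and grows with switching", {
  co <- simulate_cophylogeny(10, seed = 6)
  r <- congruence_rf(co$host, co$symbiont, co$assoc, n_subsamples = 5, seed = 1)
  expect_equal(r$distance, 0, tolerance = 1e-12)
  lo <- vapply(1:20, function(s) {
    co <- simulate_cophylogeny(12, switch_prob = 0, seed = s)
    congruence_rf(co$host, co$symbiont, co$assoc, 2, seed = s)$distance
  }, numeric(1))
  hi <- vapply(1:20, function(s) {
    co <- simulate_cophylogeny(12, switch_prob = 0.8, seed = s)
    congruence_rf(co$host, co$symbiont, co$assoc, 2, seed = s)$distance
  }, numeric(1))
  expect_lt(mean(lo), mean(hi))
  small <- ape::read.tree(text = "(A:1,(B:1,C:1):1);")
  aa <- diag(3L); dimnames(aa) <- list(c("A","B","C"), c("A","B","C"))
  expect_error(congruence_rf(small, small, aa), "at least 4 tips")
})
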