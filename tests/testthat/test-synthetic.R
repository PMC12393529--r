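test_that("pure codivergence yields an isomorphic symbiont tree and a permutation association", {
  for (s in c(2, 17, 99)) {
    co <- simulate_cophylogeny(10, switch_prob = 0, loss_prob = 0,
                               multi_assoc_rate = 0, seed = s)
    expect_true(all(rowSums(co$assoc) == 1))
    expect_true(all(colSums(co$assoc) == 1))
    relab <- co$symbiont
    hosts <- apply(co$assoc, 2, function(col) rownames(co$assoc)[col == 1])
    relab$tip.label <- unname(hosts[relab$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(co$host), ape::unroot(relab)), 0,
                 ignore_attr = TRUE)
    d1 <- patristic_distances(co$host)
    d2 <- patristic_distances(relab)[rownames(d1), colnames(d1)]
    expect_equal(d1, d2, tolerance = 1e-8)   # branch lengths track host time
  }
})

test_that("heavy host switching erodes topological congruence", {
  rfs <- vapply(1:100, function(s) {
    co <- simulate_cophylogeny(16, switch_prob = 0.8, seed = s)
    congruence_rf(co$host, co$symbiont, co$assoc, n_subsamples = 1,
                  seed = s)$distance
  }, numeric(1))
  expect_gte(mean(rfs > 0), 0.95)
})

test_that("cophylogeny simulation is a pure function of its seed", {
  a <- simulate_cophylogeny(12, switch_prob = 0.3, loss_prob = 0.1,
                            multi_assoc_rate = 0.5, seed = 5)
  b <- simulate_cophylogeny(12, switch_prob = 0.3, loss_prob = 0.1,
                            multi_assoc_rate = 0.5, seed = 5)
  expect_identical(ape::write.tree(a$host), ape::write.tree(b$host))
  expect_identical(ape::write.tree(a$symbiont), ape::write.tree(b$symbiont))
  expect_identical(a$assoc, b$assoc)
  c <- simulate_cophylogeny(12, switch_prob = 0.3, loss_prob = 0.1,
                            multi_assoc_rate = 0.5, seed = 6)
  expect_false(identical(ape::write.tree(a$host), ape::write.tree(c$host)))
})

test_that("every simulated association keeps all hosts and symbionts linked", {
  for (s in 1:10) {
    co <- simulate_cophylogeny(8, switch_prob = 0.5, loss_prob = 0.3,
                               multi_assoc_rate = 1, seed = s)
    expect_true(all(rowSums(co$assoc) >= 1))
    expect_true(all(colSums(co$assoc) >= 1))
    expect_setequal(colnames(co$assoc), co$symbiont$tip.label)
    expect_setequal(rownames(co$assoc), co$host$tip.label)
  }
})

test_that("pangenome simulator plants the requested structure deterministically", {
  pg <- simulate_pangenome(n_genomes = 20, n_core = 10, n_accessory = 0,
                           unique_per_genome_mean = 0, seed = 3)
  s <- partition_gene_families(pg$matrix)
  expect_equal(c(s$n_core, s$n_accessory, s$n_unique), c(10, 0, 0))

  a <- simulate_pangenome(seed = 11)
  b <- simulate_pangenome(seed = 11)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$metadata, b$metadata)

  # planted odds ratios: realized log-OR centred on the target
  pg <- simulate_pangenome(n_genomes = 200, n_core = 0, n_accessory = 0,
                           unique_per_genome_mean = 0, n_trait_genes = 200,
                           trait_odds_ratio = 8, lifestyle_fraction = 0.5,
                           seed = 21)
  hits <- fisher_association(pg$matrix, pg$metadata)
  expect_lt(abs(median(log(hits$odds_ratio)) - log(8)), log(2))
})

test_that("ANI simulator recovers planted blocks through clustering", {
  ani <- simulate_ani(list(c(5, 0.98), c(5, 0.97)), between_sim = 0.85,
                      noise_sd = 0, seed = 1)
  cl <- ani_cluster(ani, 0.95)
  expect_equal(cl$n_phylogroups, 2L)
  expect_identical(simulate_ani(list(c(4, 0.97), c(3, 0.96)), 0.8, 0.01, seed = 2),
                   simulate_ani(list(c(4, 0.97), c(3, 0.96)), 0.8, 0.01, seed = 2))

  # 57 planted blocks of sizes 1..10 recovered exactly at low noise
  withr::with_seed(7, {
    sizes <- sample(1:10, 57, replace = TRUE)
  })
  blocks <- lapply(sizes, function(k) c(k, 0.97))
  ani <- simulate_ani(blocks, between_sim = 0.85, noise_sd = 0.005, seed = 8)
  cl <- ani_cluster(ani, 0.95)
  planted <- attr(ani, "block")
  expect_equal(cl$n_phylogroups, 57L)
  # Rand index 1 <=> identical partitions
  tab <- table(planted, cl$assignment[names(planted)])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  expect_error(simulate_ani(list(c(3, 0.9)), between_sim = 0.95),
               "must exceed")
  expect_error(simulate_ani(list(c(-2, 0.99)), 0.8), "positive integers")
})

test_that("read-count simulator hits its limit behaviors", {
  co <- simulate_cophylogeny(6, seed = 4)
  # huge enrichment, small depth: thresholded RPKM binarizes to the association
  rc <- simulate_read_counts(co$host, co$assoc, depth_mean = 0.02,
                             enrichment = 5000, seed = 5)
  prof <- compute_rpkm(rc, threshold = 0.1)
  bin <- (prof$rpkm > 0) * 1L
  expect_equal(unname(bin[paste0("sample_", rownames(co$assoc)), ]),
               unname(co$assoc))
  # zero depth: all-zero counts and RPKM
  rc0 <- simulate_read_counts(co$host, co$assoc, depth_mean = 0,
                              enrichment = 10, seed = 5)
  expect_true(all(rc0$counts == 0))
  expect_true(all(compute_rpkm(rc0)$rpkm == 0))
  expect_error(simulate_read_counts(co$host, co$assoc, enrichment = 0.5),
               "enrichment")
  # determinism
  expect_identical(simulate_read_counts(co$host, co$assoc, seed = 9)$counts,
                   simulate_read_counts(co$host, co$assoc, seed = 9)$counts)
})

test_that("clade associations share genomes between related hosts", {
  co <- simulate_cophylogeny(8, seed = 1)
  assoc <- clade_association(co$host)
  expect_true(all(rowSums(assoc) >= 2))  # every host: root clade + own genome
  d <- patristic_distances(co$host)
  h <- rownames(assoc)
  shared <- tcrossprod(assoc)
  # most-related pair shares at least as many genomes as the most distant
  close <- which(d == min(d[d > 0]), arr.ind = TRUE)[1, ]
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_gte(shared[close[1], close[2]], shared[far[1], far[2]])
})
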