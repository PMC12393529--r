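test_that("accessory filter keeps exactly the mid-prevalence accessory families", {
  m <- matrix(1L, 3, 50, dimnames = list(c("core1", "low", "mid"),
                                         sprintf("g%02d", 1:50)))
  m["low", ] <- 0L; m["low", 1:2] <- 1L      # prevalence 0.04
  m["mid", ] <- 0L; m["mid", 1:3] <- 1L      # prevalence 0.06
  s <- partition_gene_families(m)
  out <- filter_accessory(m, s, prevalence = 0.05)
  expect_identical(rownames(out), "mid")     # 0.04 dropped, 0.06 kept
  core_only <- matrix(1L, 2, 10, dimnames = list(c("a", "b"),
                                                 sprintf("g%02d", 1:10)))
  sc <- partition_gene_families(core_only)
  expect_error(filter_accessory(core_only, sc), "no accessory")

  sim <- simulate_pangenome(n_genomes = 40, seed = 19)
  s <- partition_gene_families(sim$matrix)
  kept <- rownames(filter_accessory(sim$matrix, s, 0.05))
  # oracle: set comprehension over classification and prevalence
  want <- names(s$classification)[
    s$classification == "accessory" &
      rowSums(sim$matrix)[names(s$classification)] / ncol(sim$matrix) > 0.05]
  expect_setequal(kept, want)
})

test_that("genome similarity matches set-based oracles", {
  m <- random_gene_matrix(10, 6, p = 0.4, seed = 8)
  s <- genome_similarity(m, "jaccard")
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(s[i, j], oracle_jaccard(m[, i], m[, j]), tolerance = 1e-12)
  }
  ident <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(genome_similarity(ident)["a", "b"], 1)
  disj <- cbind(a = c(1L, 0L, 1L, 0L), b = c(0L, 1L, 0L, 1L))
  rownames(disj) <- paste0("f", 1:4)
  expect_equal(genome_similarity(disj)["a", "b"], 0)
  # invariant to families absent from both genomes
  m2 <- rbind(m, zero1 = 0L, zero2 = 0L)
  m2[c("zero1", "zero2"), 1] <- 1L   # present only in genome 1
  s2 <- genome_similarity(m2, "jaccard")
  expect_equal(s2[2, 3], s[2, 3])
  # simple matching oracle on one pair
  sm <- genome_similarity(m, "simple_matching")
  expect_equal(sm[1, 2], mean(m[, 1] == m[, 2]))
})

test_that("network construction applies the edge threshold monotonically", {
  m <- random_gene_matrix(20, 8, p = 0.5, seed = 4)
  s <- genome_similarity(m)
  full <- build_network(s, edge_threshold = 0)
  expect_equal(nrow(full$edges), choose(8, 2))
  none <- build_network(s, edge_threshold = 1 + 1e-9)
  expect_equal(nrow(none$edges), 0)
  expect_equal(nrow(none$nodes), 8)          # isolated nodes retained
  mid <- build_network(s, edge_threshold = 0.5)
  want <- sum(s[upper.tri(s)] >= 0.5)
  expect_equal(nrow(mid$edges), want)
  counts <- vapply(c(0, 0.3, 0.6, 0.9),
                   function(t) nrow(build_network(s, t)$edges), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("assortativity is 1 for separated cliques and ~0 for random labels", {
  sim <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  sim[1:4, 1:4] <- 0.9; sim[5:8, 5:8] <- 0.9; diag(sim) <- 1
  net <- build_network(sim, edge_threshold = 0.5)
  cl <- stats::setNames(rep(c("A", "B"), each = 4), letters[1:8])
  expect_equal(label_assortativity(net, cl), 1)
  expect_error(label_assortativity(build_network(sim, 1.01), cl), "edgeless")

  # unweighted case agrees with igraph's nominal assortativity
  g <- as_igraph(net)
  r_ig <- igraph::assortativity_nominal(g, as.integer(factor(cl[igraph::V(g)$name])))
  expect_equal(label_assortativity(net, cl), r_ig, tolerance = 1e-12)

  # random labels on a complete graph: near zero over 50 seeds
  comp <- matrix(0.8, 12, 12, dimnames = list(sprintf("g%02d", 1:12),
                                              sprintf("g%02d", 1:12)))
  diag(comp) <- 1
  netc <- build_network(comp, 0.5)
  rs <- vapply(1:50, function(s) {
    labs <- withr::with_seed(s, stats::setNames(
      sample(c("x", "y"), 12, replace = TRUE), sprintf("g%02d", 1:12)))
    if (length(unique(labs)) < 2) return(0)
    label_assortativity(netc, labs)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("accessory content structured by planted blocks is phylogroup-assortative", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      n <- 24
      block <- rep(1:3, each = 8)
      # block-specific accessory families at high within-block prevalence
      m <- do.call(rbind, lapply(1:30, function(f) {
        b <- sample(1:3, 1)
        p <- ifelse(block == b, 0.9, 0.05)
        rbinom(n, 1L, p)
      }))
      dimnames(m) <- list(sprintf("f%02d", 1:30), sprintf("g%02d", 1:n))
      empty <- rowSums(m) == 0
      m[cbind(which(empty), sample.int(n, sum(empty), replace = TRUE))] <- 1L
      storage.mode(m) <- "integer"
      net <- build_network(genome_similarity(m), 0.3)
      pg <- stats::setNames(paste0("PG", block), colnames(m))
      rand <- stats::setNames(sample(c("host_associated", "free_living"), n,
                                     replace = TRUE), colnames(m))
      if (length(unique(rand)) < 2) return(TRUE)
      label_assortativity(net, pg) > label_assortativity(net, rand)
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("network exports write GraphML and an edge list", {
  m <- random_gene_matrix(15, 6, p = 0.5, seed = 2)
  meta <- data.frame(genome_id = colnames(m),
                     lifestyle = rep(c("host_associated", "free_living"), 3))
  net <- build_network(genome_similarity(m), 0.4, metadata = meta)
  d <- withr::local_tempdir()
  export_network(net, file.path(d, "net.graphml"), file.path(d, "edges.tsv"))
  expect_true(file.exists(file.path(d, "net.graphml")))
  edges <- read.delim(file.path(d, "edges.tsv"))
  expect_equal(nrow(edges), nrow(net$edges))
})
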