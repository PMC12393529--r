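# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (loops, enumeration, external packages) so it
# shares no code path with the implementation it checks.

sp_log_enable(FALSE)

# Brute-force Jaccard on two binary vectors via set operations
oracle_jaccard <- function(x, y) {
  sx <- which(x == 1)
  sy <- which(y == 1)
  u <- union(sx, sy)
  if (!length(u)) return(0)
  length(intersect(sx, sy)) / length(u)
}

# Loop-based Bray-Curtis
oracle_bray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  if (den == 0) 0 else unname(num / den)
}

# Pearson chi-square by explicit O/E loop
oracle_chisq <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  unname(stat)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + b           # present genomes
  nt <- a + c          # trait-positive genomes
  n <- a + b + c + d
  lo <- max(0, k - (n - nt)); hi <- min(k, nt)
  sup <- lo:hi
  pr <- dhyper(sup, nt, n - nt, k)
  obs <- dhyper(a, nt, n - nt, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Patristic distance by shortest path on the tree's edge graph
oracle_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n <- length(tree$tip.label)
  d <- igraph::distances(g, v = as.character(1:n), to = as.character(1:n))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# Symmetric Procrustes residual via vegan (independent implementation)
oracle_m2_vegan <- function(host_d, symb_d, assoc) {
  hp <- ape::pcoa(as.dist(host_d), correction = "cailliez")
  sp <- ape::pcoa(as.dist(symb_d), correction = "cailliez")
  hv <- if (is.null(hp$vectors.cor)) hp$vectors else hp$vectors.cor
  sv <- if (is.null(sp$vectors.cor)) sp$vectors else sp$vectors.cor
  rownames(hv) <- rownames(host_d); rownames(sv) <- rownames(symb_d)
  idx <- which(assoc == 1L, arr.ind = TRUE)
  X <- hv[rownames(assoc)[idx[, 1]], , drop = FALSE]
  Y <- sv[colnames(assoc)[idx[, 2]], , drop = FALSE]
  k <- max(ncol(X), ncol(Y))
  X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
  Y <- cbind(Y, matrix(0, nrow(Y), k - ncol(Y)))
  vegan::procrustes(X, Y, symmetric = TRUE)$ss
}

# Non-trivial splits as canonical "membership string" set, built
# independently of tree_splits (via phangorn's split machinery)
oracle_split_key <- function(v) {
  if (v[1]) v <- !v
  paste(as.integer(v), collapse = "")
}

oracle_splits <- function(tree, ref) {
  s <- phangorn::as.splits(ape::unroot(tree))
  labs <- attr(s, "labels")
  n <- length(ref)
  out <- list()
  for (sp in s) {
    v <- ref %in% labs[sp]
    if (sum(v) >= 2 && sum(v) <= n - 2) out[[length(out) + 1L]] <- v
  }
  if (!length(out)) return(list())
  out[!duplicated(vapply(out, oracle_split_key, character(1)))]
}

oracle_mi <- function(a, b) {
  n <- length(a)
  p <- function(x) x / n
  mi <- 0
  for (va in c(TRUE, FALSE)) {
    for (vb in c(TRUE, FALSE)) {
      pj <- p(sum(a == va & b == vb))
      if (pj > 0) mi <- mi + pj * log2(pj / (p(sum(a == va)) * p(sum(b == vb))))
    }
  }
  mi
}

oracle_entropy <- function(a) {
  p <- mean(a)
  h <- 0
  if (p > 0) h <- h - p * log2(p)
  if (p < 1) h <- h - (1 - p) * log2(1 - p)
  h
}

# Generalized RF by exhaustive enumeration over all split injections
oracle_grf <- function(t1, t2) {
  ref <- sort(t1$tip.label)
  s1 <- oracle_splits(t1, ref)
  s2 <- oracle_splits(t2, ref)
  h1 <- sum(vapply(s1, oracle_entropy, numeric(1)))
  h2 <- sum(vapply(s2, oracle_entropy, numeric(1)))
  if (h1 + h2 == 0) return(0)
  if (!length(s1) || !length(s2)) return(1)
  if (length(s1) > length(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  k1 <- length(s1); k2 <- length(s2)
  best <- 0
  perms <- gtools_permutations(k2)
  for (r in seq_len(nrow(perms))) {
    tot <- 0
    for (i in seq_len(k1)) tot <- tot + oracle_mi(s1[[i]], s2[[perms[r, i]]])
    best <- max(best, tot)
  }
  min(max(1 - 2 * best / (h1 + h2), 0), 1)
}

# all permutations of 1..n as a matrix (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# random binary family x genome matrix with no all-zero rows
random_gene_matrix <- function(n_fam, n_gen, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_fam * n_gen, 1L, p), n_fam, n_gen)
    empty <- rowSums(m) == 0
    m[cbind(which(empty), sample.int(n_gen, sum(empty), replace = TRUE))] <- 1L
    dimnames(m) <- list(sprintf("fam%03d", seq_len(n_fam)),
                        sprintf("gen%02d", seq_len(n_gen)))
    storage.mode(m) <- "integer"
    m
  })
}

random_yule <- function(n, seed) simulate_cophylogeny(n, seed = seed)$host
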