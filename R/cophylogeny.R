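#' Principal-coordinates embedding of a distance matrix
#'
#' Classical metric scaling via [ape::pcoa()], with Cailliez or Lingoes
#' correction of non-Euclidean distances (patristic distances are
#' frequently non-Euclidean, so Cailliez is the default throughout the
#' cophylogeny stage). Axes with eigenvalue above `1e-9` are retained in
#' descending order; pairwise Euclidean distances among the returned
#' rows reproduce the (corrected) input distances.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param correction `"cailliez"`, `"lingoes"` or `"none"`.
#' @return a numeric coordinate matrix, items in rows.
#' @export
pcoa_coords <- function(d, correction = c("cailliez", "lingoes", "none")) {
  correction <- match.arg(correction)
  d <- validate_square_matrix(as.matrix(d), "distance")
  res <- ape::pcoa(stats::as.dist(d),
                   correction = if (correction == "none") "none" else correction)
  if (!is.null(res$vectors.cor)) {
    vec <- res$vectors.cor
    ev <- res$values$Corr_eig[seq_len(ncol(vec))]
  } else {
    vec <- res$vectors
    ev <- res$values$Eigenvalues[seq_len(ncol(vec))]
    if (correction == "none" && any(res$values$Eigenvalues < -1e-9)) {
      warning("non-Euclidean distances; negative axes dropped", call. = FALSE)
    }
  }
  keep <- which(ev > 1e-9)
  if (!length(keep)) stop("no positive eigenvalues in PCoA", call. = FALSE)
  out <- vec[, keep, drop = FALSE]
  rownames(out) <- rownames(d)
  out
}

## Symmetric Procrustes residual: both configurations are column-centred
## and scaled to unit sum of squares, so after the optimal rotation the
## residual m^2 = 1 - (sum of singular values)^2 lies in [0, 1].
procrustes_m2 <- function(X, Y) {
  k <- max(ncol(X), ncol(Y))
  if (ncol(X) < k) X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
  if (ncol(Y) < k) Y <- cbind(Y, matrix(0, nrow(Y), k - ncol(Y)))
  X <- sweep(X, 2L, colMeans(X))
  Y <- sweep(Y, 2L, colMeans(Y))
  nx <- sqrt(sum(X^2))
  ny <- sqrt(sum(Y^2))
  if (nx < 1e-12 || ny < 1e-12) {
    stop("degenerate configuration: all coordinates identical", call. = FALSE)
  }
  d <- svd(crossprod(X / nx, Y / ny), nu = 0L, nv = 0L)$d
  min(max(1 - sum(d)^2, 0), 1)
}

#' PACo: Procrustean test of cophylogeny
#'
#' Superimposes principal-coordinate embeddings of the host and symbiont
#' tree distances over the association links. Each 1-link contributes a
#' row pairing its host's coordinates with its symbiont's coordinates;
#' both configurations are centred and scaled to unit trace (symmetric
#' scaling), the optimal rotation is found by SVD, and the residual sum
#' of squares `m2` (in \[0, 1\]) measures misfit; `r2 = 1 - m2` is the
#' goodness of fit. Significance comes from permuting the association
#' matrix: under scheme `"r0"` each host row's links are re-placed
#' uniformly among the symbionts, preserving the row's link count; under
#' `"full_shuffle"` all links are shuffled, preserving the total and the
#' at-least-one-link-per-symbiont constraint by rejection. The p-value
#' uses the add-one estimator `(1 + #\{m2_perm <= m2_obs\}) / (n + 1)`.
#'
#' @param host_d,symb_d patristic (or other) distance matrices whose
#'   labels cover the association's hosts and symbionts.
#' @param assoc binary host x symbiont association matrix with >= 3
#'   links.
#' @param n_permutations number of permutations (default 1000).
#' @param scheme permutation scheme, `"r0"` or `"full_shuffle"`.
#' @param seed RNG seed for the permutations.
#' @param correction PCoA correction, default Cailliez.
#' @return a `paco_result` with `m2`, `r2`, `p_value`,
#'   `n_permutations`, `permutation_scheme`, `seed`, `n_links`.
#' @export
paco <- function(host_d, symb_d, assoc, n_permutations = 1000,
                 scheme = c("r0", "full_shuffle"), seed = 1,
                 correction = "cailliez") {
  scheme <- match.arg(scheme)
  assoc <- validate_association(assoc)
  hosts <- rownames(assoc)
  symbs <- colnames(assoc)
  if (!all(hosts %in% rownames(host_d))) {
    stop("host distance matrix does not cover all hosts", call. = FALSE)
  }
  if (!all(symbs %in% rownames(symb_d))) {
    stop("symbiont distance matrix does not cover all symbionts", call. = FALSE)
  }
  if (sum(assoc) < 3) stop("need at least 3 association links", call. = FALSE)
  hc <- pcoa_coords(host_d[hosts, hosts, drop = FALSE], correction)
  sc <- pcoa_coords(symb_d[symbs, symbs, drop = FALSE], correction)
  m2_of <- function(links) {
    idx <- which(links == 1L, arr.ind = TRUE)
    procrustes_m2(hc[idx[, 1L], , drop = FALSE],
                  sc[idx[, 2L], , drop = FALSE])
  }
  obs <- m2_of(assoc)
  row_counts <- rowSums(assoc)
  n_h <- length(hosts)
  n_s <- length(symbs)
  one_to_one <- n_h == n_s && all(row_counts == 1L) && all(colSums(assoc) == 1L)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      p <- matrix(0L, n_h, n_s)
      if (scheme == "r0") {
        for (i in seq_len(n_h)) {
          p[i, sample.int(n_s, row_counts[i])] <- 1L
        }
      } else if (one_to_one) {
        ## the constrained set is exactly the permutation matrices:
        ## sample one uniformly (exact null for one-to-one associations)
        p[cbind(seq_len(n_h), sample.int(n_s))] <- 1L
      } else {
        total <- sum(assoc)
        ok <- FALSE
        for (try in seq_len(1000L)) {
          p[] <- 0L
          p[sample.int(length(p), total)] <- 1L
          if (all(colSums(p) > 0L) && all(rowSums(p) > 0L)) { ok <- TRUE; break }
        }
        if (!ok) stop("full_shuffle rejection failed; use scheme = 'r0'",
                      call. = FALSE)
      }
      m2_of(p)
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats <= obs + 1e-12)) / (n_permutations + 1)
  sp_log("paco: %d links, m2 = %.4f, r2 = %.4f, p = %.4g (%d perms, %s)",
         sum(assoc), obs, 1 - obs, p, n_permutations, scheme)
  structure(list(m2 = obs, r2 = 1 - obs, p_value = p,
                 n_permutations = n_permutations,
                 permutation_scheme = scheme, seed = seed,
                 n_links = sum(assoc)),
            class = "paco_result")
}

#' @export
print.paco_result <- function(x, ...) {
  cat(sprintf("PACo: m2 = %.4f, R2 = %.4f, p = %.4g (%d permutations, scheme %s, %d links)\n",
              x$m2, x$r2, x$p_value, x$n_permutations,
              x$permutation_scheme, x$n_links))
  invisible(x)
}

## ---- generalized Robinson-Foulds --------------------------------------

## Non-trivial splits of a tree as a logical matrix (one row per split)
## over `ref` tip order, canonicalized so ref[1] is always excluded.
tree_splits <- function(tr, ref) {
  pp <- ape::prop.part(ape::unroot(tr))
  labs <- attr(pp, "labels")
  n <- length(ref)
  rows <- list()
  for (s in pp) {
    v <- ref %in% labs[s]
    sz <- sum(v)
    if (sz >= 2 && sz <= n - 2) {
      if (v[1L]) v <- !v
      rows[[length(rows) + 1L]] <- v
    }
  }
  if (!length(rows)) return(matrix(logical(0), 0L, n))
  unique(do.call(rbind, rows))
}

split_entropy <- function(v) {
  p <- c(mean(v), 1 - mean(v))
  p <- p[p > 0]
  -sum(p * log2(p))
}

## Mutual information (bits) between two bipartitions of the same tip set.
split_mutual_info <- function(a, b) {
  n <- length(a)
  cnt <- c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  pa <- c(sum(a), n - sum(a)) / n
  pb <- c(sum(b), n - sum(b)) / n
  pj <- cnt / n
  ex <- c(pa[1] * pb[1], pa[1] * pb[2], pa[2] * pb[1], pa[2] * pb[2])
  keep <- pj > 0
  sum(pj[keep] * log2(pj[keep] / ex[keep]))
}

max_weight_split_matching <- function(S) {
  if (!nrow(S) || !ncol(S) || max(S) <= 0) return(0)
  g <- igraph::graph_from_biadjacency_matrix(S, weighted = TRUE)
  igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)$matching_weight
}

#' Generalized Robinson-Foulds distance (mutual clustering information)
#'
#' Scores every pair of non-trivial splits (one from each tree) by the
#' mutual information, in bits, between the two-block partitions they
#' induce on the shared tips, finds the maximum-weight bipartite
#' matching of splits, and normalizes:
#' `distance = 1 - 2 * matched_info / (entropy_t1 + entropy_t2)`, where
#' each tree's entropy is the sum of its split entropies. Identical
#' split sets give distance 0; trees sharing no split information give
#' distance 1. Trees must share at least four tips and identical tip
#' sets.
#'
#' @param t1,t2 `phylo` trees on the same tip set (>= 4 tips).
#' @return a `generalized_rf` with `distance`, `matched_info`,
#'   `entropy_t1`, `entropy_t2`.
#' @export
generalized_rf <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("tip sets differ: ",
         paste(c(setdiff(t1$tip.label, t2$tip.label),
                 setdiff(t2$tip.label, t1$tip.label)), collapse = ", "),
         call. = FALSE)
  }
  if (length(t1$tip.label) < 4) stop("need at least 4 tips", call. = FALSE)
  ref <- sort(t1$tip.label)
  s1 <- tree_splits(t1, ref)
  s2 <- tree_splits(t2, ref)
  h1 <- if (nrow(s1)) sum(apply(s1, 1L, split_entropy)) else 0
  h2 <- if (nrow(s2)) sum(apply(s2, 1L, split_entropy)) else 0
  if (h1 + h2 == 0) {
    msi <- 0
    dist <- 0   # both trees are stars: identical (empty) split sets
  } else if (!nrow(s1) || !nrow(s2)) {
    msi <- 0
    dist <- 1
  } else {
    S <- matrix(0, nrow(s1), nrow(s2))
    for (i in seq_len(nrow(s1))) {
      for (j in seq_len(nrow(s2))) {
        S[i, j] <- split_mutual_info(s1[i, ], s2[j, ])
      }
    }
    msi <- max_weight_split_matching(S)
    dist <- min(max(1 - 2 * msi / (h1 + h2), 0), 1)
  }
  structure(list(distance = dist, matched_info = msi,
                 entropy_t1 = h1, entropy_t2 = h2,
                 n_splits_t1 = nrow(s1), n_splits_t2 = nrow(s2)),
            class = "generalized_rf")
}

#' @export
print.generalized_rf <- function(x, ...) {
  cat(sprintf("Generalized RF = %.4f (matched info %.3f bits; entropies %.3f / %.3f)\n",
              x$distance, x$matched_info, x$entropy_t1, x$entropy_t2))
  invisible(x)
}

#' Subsample one-to-one host-labeled trees from a multi-tip symbiont tree
#'
#' When several symbiont tips link to one host, tree-distance statistics
#' need a tip-matching rule. For each subsample one linked symbiont tip
#' is chosen per host uniformly at random (collisions between hosts that
#' share a tip are resolved by rejection), the symbiont tree is pruned
#' to the chosen tips and the tips are relabeled by host. A one-to-one
#' association returns the single relabeled tree.
#'
#' @param symb symbiont `phylo` tree.
#' @param assoc binary host x symbiont matrix; its symbionts must match
#'   the tree's tips.
#' @param n_subsamples number of subsampled trees.
#' @param seed RNG seed.
#' @return a list of host-labeled `phylo` trees.
#' @export
map_symbiont_tips <- function(symb, assoc, n_subsamples = 100, seed = 1) {
  assoc <- validate_association(assoc)
  if (!setequal(colnames(assoc), symb$tip.label)) {
    stop("association symbionts must match symbiont tree tips", call. = FALSE)
  }
  hosts <- rownames(assoc)
  linked <- lapply(hosts, function(h) colnames(assoc)[assoc[h, ] == 1L])
  names(linked) <- hosts
  one_to_one <- all(rowSums(assoc) == 1L) && all(colSums(assoc) == 1L)
  pick <- function() {
    for (try in seq_len(100L)) {
      ch <- vapply(linked, function(v) v[sample.int(length(v), 1L)],
                   character(1))
      if (!anyDuplicated(ch)) return(ch)
    }
    stop("could not draw collision-free tip assignment", call. = FALSE)
  }
  prune <- function(ch) {
    tr <- ape::keep.tip(symb, unname(ch))
    tr$tip.label <- names(ch)[match(tr$tip.label, ch)]
    tr
  }
  if (one_to_one) {
    ch <- vapply(linked, function(v) v[1L], character(1))
    return(list(prune(ch)))
  }
  with_seed(seed, lapply(seq_len(n_subsamples), function(b) prune(pick())))
}

#' Host-symbiont congruence by subsampled generalized RF
#'
#' Mean generalized RF distance between the host tree and host-labeled
#' one-to-one subsamples of the symbiont tree (see
#' [map_symbiont_tips()]).
#'
#' @param host host `phylo` tree (>= 4 tips).
#' @param symb symbiont `phylo` tree.
#' @param assoc binary host x symbiont association matrix.
#' @param n_subsamples number of subsampled trees, default 100.
#' @param seed RNG seed.
#' @return a list with the mean `distance`, per-subsample `distances`,
#'   `n_subsamples` and `seed`.
#' @export
congruence_rf <- function(host, symb, assoc, n_subsamples = 100, seed = 1) {
  assoc <- validate_association(assoc)
  if (!all(rownames(assoc) %in% host$tip.label)) {
    stop("association hosts missing from host tree", call. = FALSE)
  }
  host <- ape::keep.tip(host, rownames(assoc))
  if (length(host$tip.label) < 4) {
    stop("host tree needs at least 4 tips for RF", call. = FALSE)
  }
  trees <- map_symbiont_tips(symb, assoc, n_subsamples, seed)
  ds <- vapply(trees, function(tr) generalized_rf(host, tr)$distance,
               numeric(1))
  sp_log("congruence_rf: mean generalized RF %.4f over %d subsample(s)",
         mean(ds), length(ds))
  structure(list(distance = mean(ds), distances = ds,
                 n_subsamples = length(ds), seed = seed),
            class = "congruence_rf")
}

#' Classify cophylogenetic signal and phylogenetic congruence
#'
#' Operationalizes the published decision rules: a cophylogenetic signal
#' exists when the PACo permutation test is significant (`p < alpha`),
#' graded `high` when `r2 >= r2_high` and `low` otherwise. Phylogenetic
#' congruence additionally requires `r2 > r2_congruence`, graded `weak`
#' up to `r2 <= 0.60` and `strong` above; an optional generalized-RF
#' gate (`rf <= rf_gate`) can be imposed on top.
#'
#' @param p PACo permutation p-value.
#' @param r2 PACo goodness of fit (1 - m2).
#' @param rf optional generalized RF distance.
#' @param alpha significance level, default 0.05.
#' @param r2_high signal grading cut, default 0.20.
#' @param r2_congruence congruence requirement (strict `>`), default 0.25.
#' @param rf_gate optional maximum RF for congruence (disabled by default).
#' @return a `phylosymbiosis_call` with `signal` and `congruence`.
#' @export
classify_phylosymbiosis <- function(p, r2, rf = NULL, alpha = 0.05,
                                    r2_high = 0.20, r2_congruence = 0.25,
                                    rf_gate = NULL) {
  stopifnot(p >= 0, p <= 1, r2 >= -1e-9, r2 <= 1 + 1e-9)
  r2 <- round(r2, 9)   # guard threshold comparisons against float residue
  signal <- if (p >= alpha) "none" else if (r2 >= r2_high) "high" else "low"
  congruence <- "none"
  if (p < alpha && r2 > r2_congruence) {
    gate_ok <- is.null(rf_gate) || (!is.null(rf) && rf <= rf_gate)
    if (gate_ok) congruence <- if (r2 <= 0.60) "weak" else "strong"
  }
  structure(list(signal = signal, congruence = congruence, p = p, r2 = r2,
                 rf = rf, alpha = alpha, r2_high = r2_high,
                 r2_congruence = r2_congruence, rf_gate = rf_gate),
            class = "phylosymbiosis_call")
}

#' @export
print.phylosymbiosis_call <- function(x, ...) {
  cat(sprintf("Cophylogenetic signal: %s | Phylogenetic congruence: %s (p = %.3g, R2 = %.3f%s)\n",
              x$signal, x$congruence, x$p, x$r2,
              if (is.null(x$rf)) "" else sprintf(", RF = %.3f", x$rf)))
  invisible(x)
}
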