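#' Compute RPKM recruitment profiles from read counts
#'
#' `RPKM = reads / ((genome_length / 1e3) * (library_size / 1e6))`,
#' normalizing recruitment for genome size and sequencing depth. Values
#' below the detection threshold are set to exactly 0 (the published
#' default of 0.1 guards against spurious low-level mapping).
#'
#' @param rc a `read_count_table`.
#' @param threshold detection threshold, default 0.1.
#' @return an `rpkm_profile` with the samples x genomes `rpkm` matrix,
#'   `detection_threshold`, and any sample-to-host mapping carried by
#'   the input.
#' @export
compute_rpkm <- function(rc, threshold = 0.1) {
  stopifnot(inherits(rc, "read_count_table"), threshold >= 0)
  if (any(rc$library_size <= 0)) stop("zero library size", call. = FALSE)
  r <- sweep(rc$counts, 2L, rc$genome_length_bp / 1e3, "/")
  r <- sweep(r, 1L, rc$library_size / 1e6, "/")
  r[r < threshold] <- 0
  sp_log("compute_rpkm: %d x %d profile, %.1f%% cells detected at threshold %g",
         nrow(r), ncol(r), 100 * mean(r > 0), threshold)
  structure(list(rpkm = r, detection_threshold = threshold,
                 sample_host = attr(rc, "sample_host")),
            class = "rpkm_profile")
}

#' Mean RPKM per host grouping
#'
#' Reporting helper: mean over all sample x genome cells for the
#' samples belonging to each group (e.g. host family).
#'
#' @param p an `rpkm_profile`.
#' @param groups named vector mapping sample IDs to group labels.
#' @return named numeric vector of group means.
#' @export
mean_rpkm_by_group <- function(p, groups) {
  stopifnot(inherits(p, "rpkm_profile"))
  g <- groups[rownames(p$rpkm)]
  if (anyNA(g)) stop("group missing for some samples", call. = FALSE)
  vapply(split(seq_len(nrow(p$rpkm)), g),
         function(idx) mean(p$rpkm[idx, , drop = FALSE]), numeric(1))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x - y| / sum (x + y)` over genomes; the distance
#' between two all-zero samples is 0 by convention.
#'
#' @param p an `rpkm_profile` or a non-negative samples x genomes matrix.
#' @return a symmetric distance matrix (zero diagonal).
#' @export
bray_curtis <- function(p) {
  m <- if (inherits(p, "rpkm_profile")) p$rpkm else as.matrix(p)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (anyNA(d)) {
    sp_log("bray_curtis: %d all-zero sample pair(s) set to distance 0",
           sum(is.na(d[upper.tri(d)])))
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  attr(d, "mode") <- "distance"
  d
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage agglomeration producing an ultrametric tree (tip
#' depth equals half the merge height). Labels are sorted before
#' clustering so the merge order, including ties, is a deterministic
#' function of the distances alone.
#'
#' @param d symmetric distance matrix.
#' @return an ultrametric `phylo` tree.
#' @export
upgma <- function(d) {
  d <- validate_square_matrix(as.matrix(d), "distance")
  if (nrow(d) < 2) stop("need at least 2 items", call. = FALSE)
  ord <- order(rownames(d))
  hc <- stats::hclust(stats::as.dist(d[ord, ord]), method = "average")
  ape::as.phylo(hc)
}

#' Concordance between a host phylogeny and RPKM profile clustering
#'
#' Builds the UPGMA dendrogram of the Bray-Curtis dissimilarities among
#' samples, takes its cophenetic distances as the "symbiont" side, links
#' every sample to its host taxon, and runs the PACo permutation test
#' against the host tree's patristic distances. Host tips without any
#' sample are dropped with a log note.
#'
#' @param host host `phylo` tree (>= 3 tips with samples).
#' @param p an `rpkm_profile` whose `sample_host` maps samples to host
#'   tips (or supply `sample_host`).
#' @param n_permutations PACo permutations, default 1000.
#' @param seed RNG seed.
#' @param sample_host optional named vector, sample -> host tip.
#' @param scheme PACo permutation scheme (see [paco()]).
#' @return a `paco_result`.
#' @export
profile_concordance <- function(host, p, n_permutations = 1000, seed = 1,
                                sample_host = NULL, scheme = "r0") {
  stopifnot(inherits(p, "rpkm_profile"))
  sample_host <- sample_host %||% p$sample_host
  if (is.null(sample_host)) stop("no sample-to-host mapping available",
                                 call. = FALSE)
  samples <- rownames(p$rpkm)
  sh <- sample_host[samples]
  if (anyNA(sh)) stop("host mapping missing for sample(s): ",
                      paste(samples[is.na(sh)], collapse = ", "), call. = FALSE)
  if (!all(sh %in% host$tip.label)) {
    stop("mapped host taxa missing from host tree: ",
         paste(setdiff(sh, host$tip.label), collapse = ", "), call. = FALSE)
  }
  unused <- setdiff(host$tip.label, sh)
  if (length(unused)) {
    sp_log("profile_concordance: dropping %d host tip(s) without samples",
           length(unused))
    host <- ape::keep.tip(host, setdiff(host$tip.label, unused))
  }
  if (length(host$tip.label) < 3) stop("need >= 3 host tips with samples",
                                       call. = FALSE)
  dend <- upgma(bray_curtis(p))
  symb_d <- patristic_distances(dend)
  assoc <- matrix(0L, length(host$tip.label), length(samples),
                  dimnames = list(host$tip.label, samples))
  assoc[cbind(match(sh, host$tip.label), seq_along(samples))] <- 1L
  paco(patristic_distances(host), symb_d, assoc,
       n_permutations = n_permutations, scheme = scheme, seed = seed)
}
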