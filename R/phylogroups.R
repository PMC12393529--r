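#' Delineate phylogroups from an ANI similarity matrix
#'
#' Hierarchical agglomerative clustering on distance `1 - ANI`, cut at
#' `1 - threshold`, so genomes joined at or above the ANI threshold fall
#' in the same phylogroup. Average linkage mirrors the secondary
#' clustering of common genome-dereplication workflows; single linkage
#' (equivalent to connected components of the at-threshold similarity
#' graph) is offered as a documented alternative. Labels `PG1..PGk` are
#' assigned by descending cluster size, breaking ties by the
#' lexicographically smallest member, so they depend only on the
#' clustering itself.
#'
#' @param ani symmetric similarity matrix (unit diagonal).
#' @param threshold ANI fraction in (0, 1), default 0.95.
#' @param linkage `"average"` or `"single"`.
#' @return a `phylogroup_assignment` with `assignment` (genome ->
#'   label), `ani_threshold`, `linkage`, `n_phylogroups`.
#' @export
ani_cluster <- function(ani, threshold = 0.95,
                        linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  ani <- validate_square_matrix(ani, "similarity")
  n <- nrow(ani)
  if (n == 1L) {
    cl <- stats::setNames(1L, rownames(ani))
  } else {
    ord <- order(rownames(ani))      # input-order invariance
    d <- stats::as.dist(1 - ani[ord, ord])
    hc <- stats::hclust(d, method = linkage)
    cl <- stats::cutree(hc, h = 1 - threshold)
  }
  ## canonical labels: size-descending, ties by smallest member label
  members <- split(names(cl), cl)
  key <- vapply(members, function(g) min(g), character(1))
  ordc <- order(-lengths(members), key)
  relabel <- stats::setNames(sprintf("PG%d", seq_along(ordc)),
                             names(members)[ordc])
  assignment <- stats::setNames(unname(relabel[as.character(cl)]), names(cl))
  assignment <- assignment[rownames(ani)]
  sp_log("ani_cluster: %d genomes at ANI >= %g (%s linkage) -> %d phylogroups",
         n, threshold, linkage, length(members))
  structure(list(assignment = assignment, ani_threshold = threshold,
                 linkage = linkage, n_phylogroups = length(members)),
            class = "phylogroup_assignment")
}

#' @export
print.phylogroup_assignment <- function(x, ...) {
  cat(sprintf("%d genomes in %d phylogroups (ANI >= %g, %s linkage)\n",
              length(x$assignment), x$n_phylogroups, x$ani_threshold,
              x$linkage))
  invisible(x)
}

#' Lifestyle composition of phylogroups
#'
#' A phylogroup is mixed when it contains both host-associated and
#' free-living genomes; otherwise it is lifestyle-specific (host-only or
#' free-only). Percentages are reported to two decimals. `n_small`
#' counts phylogroups with fewer than three genomes, where composition
#' is weakly supported.
#'
#' @param assign a `phylogroup_assignment`.
#' @param meta metadata data.frame with `genome_id` and `lifestyle`.
#' @return a `phylogroup_composition` list.
#' @export
phylogroup_composition <- function(assign, meta) {
  stopifnot(inherits(assign, "phylogroup_assignment"))
  meta <- validate_metadata(meta)
  genomes <- names(assign$assignment)
  miss <- setdiff(genomes, meta$genome_id)
  if (length(miss)) stop("missing metadata for genome(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ls <- stats::setNames(meta$lifestyle, meta$genome_id)[genomes]
  by_group <- split(ls, assign$assignment[genomes])
  kinds <- vapply(by_group, function(v) {
    has_h <- any(v == "host_associated")
    has_f <- any(v == "free_living")
    if (has_h && has_f) "mixed" else if (has_h) "host_only" else "free_only"
  }, character(1))
  n_mixed <- sum(kinds == "mixed")
  n_host <- sum(kinds == "host_only")
  n_free <- sum(kinds == "free_only")
  k <- length(kinds)
  out <- list(n_mixed = n_mixed, n_host_only = n_host, n_free_only = n_free,
              n_phylogroups = k,
              pct_mixed = round(100 * n_mixed / k, 2),
              pct_specific = round(100 * (n_host + n_free) / k, 2),
              n_small = sum(lengths(by_group) < 3),
              group_kind = kinds)
  sp_log("phylogroup_composition: %d groups -> %d mixed (%.2f%%), %d host-only, %d free-only",
         k, n_mixed, out$pct_mixed, n_host, n_free)
  structure(out, class = "phylogroup_composition")
}
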