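#' Pangenome-wide association of gene presence with a binary trait
#'
#' For every gene family, tests the 2 x 2 table of presence/absence
#' against the trait (e.g. host-associated vs free-living lifestyle)
#' with a two-sided Fisher's exact test (all tables with point
#' probability at most the observed one are summed). The odds ratio is
#' the sample `(a*d)/(b*c)`, Haldane-corrected (+0.5 to every cell)
#' whenever a cell is zero. Families constant across the (optionally
#' clade-filtered) genomes are skipped and excluded from the Bonferroni
#' denominator. A family passes when `p < alpha` and its Bonferroni
#' p-value is at most `fwer_cutoff` (mirroring the permissive FWER 0.99
#' screen of pan-GWAS workflows).
#'
#' @param m binary family x genome matrix.
#' @param trait named logical vector over genomes (TRUE = trait
#'   positive), or a metadata data.frame in which case
#'   `lifestyle == "host_associated"` is used.
#' @param clade_filter optional genome IDs to restrict the analysis
#'   (e.g. one pigmentation clade); at least 2 genomes per trait class
#'   must remain.
#' @param alpha nominal significance level, default 0.05.
#' @param fwer_cutoff Bonferroni family-wise cutoff, default 0.99.
#' @return a data.frame of hits ordered by ascending p then family ID,
#'   with columns `family_id`, `a`, `b`, `c`, `d` (the 2 x 2 counts:
#'   present/absent x trait+/trait-), `odds_ratio`, `p_value`,
#'   `p_bonferroni`, `passes`; `attr(, "n_tested")` holds the Bonferroni
#'   denominator.
#' @export
fisher_association <- function(m, trait, clade_filter = NULL, alpha = 0.05,
                               fwer_cutoff = 0.99) {
  m <- validate_gene_matrix(m)
  if (is.data.frame(trait)) {
    trait <- stats::setNames(trait$lifestyle == "host_associated",
                             trait$genome_id)
  }
  genomes <- colnames(m)
  if (!is.null(clade_filter)) {
    genomes <- intersect(genomes, clade_filter)
    m <- m[, genomes, drop = FALSE]
  }
  miss <- genomes[!genomes %in% names(trait) | is.na(trait[genomes])]
  if (length(miss)) stop("trait missing for genome(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tv <- trait[genomes]
  if (sum(tv) < 2 || sum(!tv) < 2) {
    stop("need at least 2 genomes per trait class", call. = FALSE)
  }
  n <- length(genomes)
  nt <- sum(tv)
  pres <- rowSums(m)
  a <- as.integer(m %*% tv)           # present & trait+
  keep <- pres > 0L & pres < n
  if (!any(keep)) stop("all families are constant; nothing to test", call. = FALSE)
  fam <- rownames(m)[keep]
  k <- pres[keep]
  a <- a[keep]
  b <- k - a                          # present & trait-
  cc <- nt - a                        # absent & trait+
  d <- n - nt - b                     # absent & trait-
  ## p depends only on (k, a) given fixed margins: memoize
  memo <- new.env(parent = emptyenv())
  pval <- vapply(seq_along(a), function(i) {
    key <- paste(k[i], a[i], sep = ":")
    if (is.null(memo[[key]])) {
      memo[[key]] <- stats::fisher.test(
        matrix(c(a[i], b[i], cc[i], d[i]), 2L, byrow = TRUE))$p.value
    }
    memo[[key]]
  }, numeric(1))
  or <- ifelse(a == 0 | b == 0 | cc == 0 | d == 0,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)),
               (a * d) / (b * cc))
  n_tested <- length(fam)
  p_bonf <- pmin(1, pval * n_tested)
  out <- data.frame(family_id = fam, a = a, b = b, c = cc, d = d,
                    odds_ratio = or, p_value = pval,
                    p_bonferroni = p_bonf,
                    passes = pval < alpha & p_bonf <= fwer_cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  sp_log("fisher_association: %d families tested on %d genomes (%d trait+), %d pass",
         n_tested, n, nt, sum(out$passes))
  out
}
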