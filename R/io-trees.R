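#' Read a phylogenetic tree from a Newick file
#'
#' Wraps [ape::read.tree()] with validation: tip labels must be unique,
#' branch lengths must be non-negative, and missing branch lengths
#' default to 0. Polytomies and unlabeled internal nodes are accepted;
#' rootedness is inferred from the top-level child count.
#'
#' @param path path to a Newick file (single tree).
#' @param format tree format; only `"newick"` is supported.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path, format = "newick") {
  format <- match.arg(format, "newick")
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt)
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error in ", path, call. = FALSE)
  validate_tree(tr)
}

## Cheap structural pre-check so malformed input reports a character offset.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at character offset ", i,
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth,
         " unclosed '(' by character offset ", length(chars), call. = FALSE)
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("Newick parse error: missing ';' terminator at character offset ",
         nchar(txt), call. = FALSE)
  }
  invisible(TRUE)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    dups <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip labels: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  tr
}

#' Write a tree to a Newick file
#'
#' Branch lengths are emitted with 10 significant digits so that
#' read/write round-trips preserve lengths.
#'
#' @param tree an [ape::phylo] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Patristic distances between all tip pairs
#'
#' Sums branch lengths along the tip-to-tip path for every pair,
#' yielding the distance matrix that feeds the principal-coordinates
#' step of the PACo procedure.
#'
#' @param tree an [ape::phylo] object with labeled tips.
#' @return a symmetric numeric matrix (distance mode, zero diagonal)
#'   with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  if (sum(tree$edge.length) == 0) {
    sp_log("patristic_distances: tree has total length 0; all distances 0")
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}
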