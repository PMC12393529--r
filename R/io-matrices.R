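#' Read a binary gene-family presence/absence matrix
#'
#' Reads a PIRATE-style Rtab (tab-separated) or CSV file whose first
#' column holds gene-family IDs and whose header row holds genome IDs.
#' Cells must be 0/1.
#'
#' @param path input file.
#' @param dialect `"rtab"` (tab-separated) or `"csv"`.
#' @return an integer matrix, families in rows, genomes in columns.
#' @export
read_gene_matrix <- function(path, dialect = c("rtab", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "rtab") "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("gene matrix needs >= 1 genome column", call. = FALSE)
  fam <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- fam
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("non-binary cell at family '%s', genome '%s': %s",
                 rownames(m)[i], colnames(m)[j], m[i, j]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  validate_gene_matrix(m)
}

validate_gene_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("gene matrix must carry family rownames and genome colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate family IDs", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate genome IDs", call. = FALSE)
  if (!all(m %in% c(0L, 1L))) stop("gene matrix entries must be 0/1", call. = FALSE)
  zero <- rowSums(m) == 0L
  if (any(zero)) {
    stop("all-zero family rows: ",
         paste(utils::head(rownames(m)[zero], 5L), collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Write a gene-family matrix
#'
#' @param m binary family x genome matrix.
#' @param path output file.
#' @param dialect `"rtab"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_gene_matrix <- function(m, path, dialect = c("rtab", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "rtab") "\t" else ","
  df <- data.frame(Gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square labeled matrix (ANI similarities or distances)
#'
#' Row and column labels must match. Similarity values above 1 are
#' interpreted as percentages and divided by 100. Reciprocal entries are
#' symmetrized by averaging when they agree within `tol`; larger
#' asymmetries are an error (ANI estimators are asymmetric by
#' construction; averaging follows common dereplication practice).
#'
#' @param path input TSV.
#' @param mode `"similarity"` (unit diagonal) or `"distance"` (zero diagonal).
#' @param tol symmetry tolerance after normalization.
#' @return a symmetric numeric matrix with a `mode` attribute.
#' @export
read_square_matrix <- function(path, mode = c("similarity", "distance"),
                               tol = 1e-6) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  validate_square_matrix(m, mode, tol = tol, normalize = TRUE)
}

validate_square_matrix <- function(m, mode, tol = 1e-6, normalize = FALSE) {
  if (nrow(m) != ncol(m)) stop("matrix is not square", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("square matrix must be labeled", call. = FALSE)
  }
  if (!setequal(rownames(m), colnames(m))) {
    miss <- c(setdiff(rownames(m), colnames(m)), setdiff(colnames(m), rownames(m)))
    stop("row/column labels differ: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- m[rownames(m), rownames(m), drop = FALSE]
  if (anyNA(m)) stop("missing values in square matrix", call. = FALSE)
  if (normalize && mode == "similarity" && any(m > 1 + 1e-12)) {
    m <- m / 100  # percentage convention (e.g. fastANI 0-100)
  }
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("asymmetric entries beyond tolerance at (%s, %s): %g vs %g",
                 rownames(m)[ij[1L]], colnames(m)[ij[2L]],
                 m[ij[1L], ij[2L]], m[ij[2L], ij[1L]]), call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- if (mode == "similarity") 1 else 0
  if (mode == "similarity" && (any(m < -1e-12) || any(m > 1 + 1e-12))) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "distance" && any(m < -1e-12)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  attr(m, "mode") <- mode
  m
}

#' Write a square matrix as TSV
#' @param m labeled square matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genome metadata
#'
#' Canonical columns: `genome_id`, `lifestyle` (one of `host_associated`,
#' `free_living`; required), and optional `host_phylum`, `host_taxon`,
#' `pigmentation` (`pigmented`/`nonpigmented`), `geography`.
#'
#' @param path TSV file.
#' @return a data.frame with one row per genome.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  req <- c("genome_id", "lifestyle")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$genome_id)) stop("duplicate genome_id in metadata", call. = FALSE)
  ok <- df$lifestyle %in% c("host_associated", "free_living")
  if (!all(ok)) {
    stop("invalid lifestyle values: ",
         paste(unique(df$lifestyle[!ok]), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write genome metadata
#' @param meta metadata data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary host-symbiont association matrix
#'
#' CSV with host labels in the first column and symbiont labels in the
#' header. Every host row and every symbiont column must carry at least
#' one link.
#'
#' @param path CSV file.
#' @return a binary integer matrix, hosts in rows, symbionts in columns.
#' @export
read_association <- function(path) {
  df <- utils::read.delim(path, sep = ",", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  validate_association(m)
}

validate_association <- function(m) {
  if (!all(m %in% c(0L, 1L))) stop("association entries must be 0/1", call. = FALSE)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate host or symbiont labels", call. = FALSE)
  }
  if (any(rowSums(m) == 0L)) {
    stop("hosts with no link: ",
         paste(rownames(m)[rowSums(m) == 0L], collapse = ", "), call. = FALSE)
  }
  if (any(colSums(m) == 0L)) {
    stop("symbionts with no link: ",
         paste(colnames(m)[colSums(m) == 0L], collapse = ", "), call. = FALSE)
  }
  m
}

#' Write an association matrix as CSV
#' @param assoc binary host x symbiont matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  df <- data.frame(host = rownames(assoc), assoc, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a read-recruitment count table
#'
#' @param counts non-negative integer matrix, samples in rows, genomes in
#'   columns.
#' @param genome_length_bp named positive integer vector, one per genome.
#' @param library_size named positive integer vector, one per sample.
#' @return a `read_count_table` list.
#' @export
read_count_table <- function(counts, genome_length_bp, library_size) {
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  genome_length_bp <- genome_length_bp[colnames(counts)]
  library_size <- library_size[rownames(counts)]
  if (anyNA(genome_length_bp) || any(genome_length_bp <= 0)) {
    stop("every genome needs a positive length", call. = FALSE)
  }
  if (anyNA(library_size) || any(library_size <= 0)) {
    stop("every sample needs a positive library size", call. = FALSE)
  }
  mapped <- rowSums(counts)
  if (any(library_size < mapped)) {
    stop("library_size smaller than mapped total for sample(s): ",
         paste(rownames(counts)[library_size < mapped], collapse = ", "),
         call. = FALSE)
  }
  structure(list(counts = counts, genome_length_bp = genome_length_bp,
                 library_size = library_size),
            class = "read_count_table")
}

#' Read a read-count table from three TSV files
#'
#' @param counts_path samples x genomes count TSV (first column = sample IDs).
#' @param genomes_path TSV with columns `genome_id`, `length_bp`.
#' @param samples_path TSV with columns `sample_id`, `library_size`.
#' @return a `read_count_table`.
#' @export
read_read_counts <- function(counts_path, genomes_path, samples_path) {
  cnt <- as.matrix(utils::read.delim(counts_path, sep = "\t", row.names = 1L,
                                     check.names = FALSE))
  gl <- utils::read.delim(genomes_path, sep = "\t")
  ls <- utils::read.delim(samples_path, sep = "\t")
  read_count_table(cnt,
                   stats::setNames(gl$length_bp, gl$genome_id),
                   stats::setNames(ls$library_size, ls$sample_id))
}

#' Write a read-count table to three TSV files
#' @param rc a `read_count_table`.
#' @param counts_path,genomes_path,samples_path output files.
#' @return invisibly, the three paths.
#' @export
write_read_counts <- function(rc, counts_path, genomes_path, samples_path) {
  df <- data.frame(sample = rownames(rc$counts), rc$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(genome_id = names(rc$genome_length_bp),
               length_bp = unname(rc$genome_length_bp)),
    genomes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(rc$library_size),
               library_size = unname(rc$library_size)),
    samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, genomes_path, samples_path))
}

#' Default analysis configuration
#'
#' One block per pipeline stage; thresholds default to the published
#' protocol values (core prevalence 0.95, accessory prevalence filter
#' 0.05, ANI 0.95, 1000 permutations, RPKM 0.1, alpha 0.05, congruence
#' R-squared 0.25).
#'
#' @return a nested list of stage settings.
#' @export
default_config <- function() {
  list(
    pangenome = list(core_threshold = 0.95, permutations = 100L),
    network = list(prevalence = 0.05, edge_threshold = 0.5, metric = "jaccard"),
    phylogroups = list(ani_threshold = 0.95, linkage = "average"),
    cophylogeny = list(permutations = 1000L, alpha = 0.05,
                       r2_high = 0.20, r2_congruence = 0.25,
                       scheme = "r0", rf_subsamples = 100L),
    pangwas = list(alpha = 0.05, fwer = 0.99),
    profiles = list(rpkm_threshold = 0.1, permutations = 1000L)
  )
}

#' Read a YAML pipeline configuration
#'
#' Values absent from the file fall back to [default_config()].
#'
#' @param path YAML file.
#' @return nested list of stage settings.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}
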