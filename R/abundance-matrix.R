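#' Sample-by-taxon abundance matrix
#'
#' Central container of the workflow: a numeric matrix with samples in rows
#' and taxa in columns, tagged with the data layer it came from (metagenomic
#' `"dna"` or metatranscriptomic `"rna"`) and the normalisation currently
#' applied. One instance holds genome abundances, a second instance holds
#' transcript counts mapped to the same genomes; every downstream stage
#' accepts either.
#'
#' @param values numeric matrix, samples in rows, taxa in columns; must carry
#'   unique row and column names.
#' @param layer `"dna"` or `"rna"`.
#' @param normalisation one of `"raw"`, `"tss"`, `"hellinger"`, `"clr"`.
#'
#' @return An object of class `abund_mat`.
#' @export
abundance_matrix <- function(values, layer = c("dna", "rna"),
                             normalisation = c("raw", "tss", "hellinger", "clr")) {
  layer <- match.arg(layer)
  normalisation <- match.arg(normalisation)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample rownames and taxon colnames")
  obj <- structure(list(values = values, layer = layer,
                        normalisation = normalisation),
                   class = "abund_mat")
  validate_abundance_matrix(obj)
  obj
}

#' @export
print.abund_mat <- function(x, ...) {
  cat(sprintf("<abund_mat> %d samples x %d taxa, layer=%s, normalisation=%s\n",
              nrow(x$values), ncol(x$values), x$layer, x$normalisation))
  invisible(x)
}

#' Validate the invariants of an abundance matrix
#'
#' Checks the layer-specific row constraints: non-negativity for raw, TSS and
#' Hellinger data; unit row sums under TSS; unit row sums of squares under
#' Hellinger; zero row sums under CLR; and unique sample/taxon identifiers.
#'
#' @param m an [abundance_matrix()].
#' @param tol tolerance on the row-sum identities.
#' @return `m`, invisibly; errors if an invariant is violated.
#' @export
validate_abundance_matrix <- function(m, tol = 1e-9) {
  stopifnot(inherits(m, "abund_mat"))
  v <- m$values
  if (anyDuplicated(rownames(v))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(v))) stop("duplicate taxon ids")
  if (any(!is.finite(v))) stop("non-finite values in abundance matrix")
  if (m$normalisation %in% c("raw", "tss", "hellinger") && any(v < 0))
    stop("negative entries not allowed under normalisation ", m$normalisation)
  rs <- rowSums(v)
  if (m$normalisation == "tss" && any(abs(rs - 1) > tol))
    stop("tss rows must sum to 1")
  if (m$normalisation == "hellinger" && any(abs(rowSums(v^2) - 1) > tol))
    stop("hellinger rows must have unit sum of squares")
  if (m$normalisation == "clr" && any(abs(rs) > tol))
    stop("clr rows must sum to 0")
  invisible(m)
}

#' @rdname abundance_matrix
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname abundance_matrix
#' @export
taxon_ids <- function(m) colnames(m$values)

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited abundance (or expression) table
#'
#' Accepts TSV/CSV with a header row and a first label column. MAG tables are
#' frequently written taxon-major (taxa in rows); the `orientation` flag says
#' which way the file is laid out — there is no auto-detection.
#'
#' @param path file path.
#' @param orientation `"sample_major"` (samples in rows) or `"taxon_major"`.
#' @param layer `"dna"` or `"rna"`.
#' @param sep field delimiter; defaults from the file extension
#'   (`","` for `.csv`, tab otherwise).
#' @return A raw-layer [abundance_matrix()], sample-major.
#' @export
read_abundance_table <- function(path, orientation = c("sample_major", "taxon_major"),
                                 layer = c("dna", "rna"), sep = NULL) {
  orientation <- match.arg(orientation)
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = 1, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  v <- as.matrix(df)
  if (!is.numeric(v)) stop("non-numeric cell in abundance table: ", path)
  if (orientation == "taxon_major") v <- t(v)
  if (any(v < 0)) stop("negative value in abundance table: ", path)
  abundance_matrix(v, layer = layer, normalisation = "raw")
}

#' Write an abundance matrix as a delimited table
#'
#' @param m an [abundance_matrix()].
#' @param path output path; delimiter inferred from extension unless given.
#' @param orientation layout to write (see [read_abundance_table()]).
#' @param sep field delimiter override.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(m, path,
                                  orientation = c("sample_major", "taxon_major"),
                                  sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- infer_sep(path, sep)
  v <- m$values
  if (orientation == "taxon_major") v <- t(v)
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (orientation == "sample_major") "sample_id" else "taxon_id"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
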