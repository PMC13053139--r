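#' @keywords internal
"_PACKAGE"

#' @useDynLib keystonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Continuous sonde variables carried in sample metadata.
ENV_VARIABLES <- c("depth", "wtemp", "do_sat", "do_raw", "sp_cond", "pH",
                   "chlor_rfu", "phyco_rfu", "fdom_rfu", "turb_fnu",
                   "sampling_time")

# Default predictor set for the chain graph: the nine physico-chemical
# variables typically plotted alongside the network (saturation and sampling
# time excluded).
DEFAULT_PREDICTORS <- c("depth", "wtemp", "do_raw", "sp_cond", "pH",
                        "chlor_rfu", "phyco_rfu", "fdom_rfu", "turb_fnu")

OXYGEN_LEVELS <- c("oxic", "anoxic", "oxycline")

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

#' Validate a sample metadata table
#'
#' Metadata is a plain data.frame with one row per sample: `sample_id`
#' (unique), `depth_m` (positive real), `month` (categorical), `oxygen`
#' (one of oxic/anoxic/oxycline) and the continuous environmental variables
#' used as chain-graph predictors.
#'
#' @param meta data.frame of per-sample metadata.
#' @param env_vars names of continuous variables that must be present and
#'   finite; defaults to those found among the standard sonde variables.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta, env_vars = NULL) {
  need <- c("sample_id", "depth_m", "month", "oxygen")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (any(is.na(meta$depth_m)) || any(is.na(meta$month)) || any(is.na(meta$oxygen)))
    stop("missing category value in metadata")
  if (!all(meta$oxygen %in% OXYGEN_LEVELS))
    stop("oxygen must be one of: ", paste(OXYGEN_LEVELS, collapse = ", "))
  if (is.null(env_vars)) env_vars <- intersect(ENV_VARIABLES, names(meta))
  for (v in env_vars) {
    if (!v %in% names(meta)) stop("metadata missing environmental variable: ", v)
    if (any(!is.finite(meta[[v]]))) stop("non-finite value in variable: ", v)
  }
  invisible(meta)
}

#' Read sample metadata from a delimited file
#'
#' If the table has a `date` column in ISO-8601 (`YYYY-MM-DD`) and no `month`
#' column, the month name is derived from the date.
#'
#' @param path file path (TSV/CSV, header row).
#' @param sep delimiter; inferred from extension by default.
#' @return A validated metadata data.frame.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- infer_sep(path, sep)
  meta <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"month" %in% names(meta) && "date" %in% names(meta)) {
    d <- as.Date(meta$date, format = "%Y-%m-%d")
    if (any(is.na(d))) stop("unparseable ISO-8601 date in metadata")
    meta$month <- months(d)
  }
  validate_metadata(meta)
  meta
}

#' Extract the scaled predictor matrix from metadata
#'
#' @param meta validated metadata data.frame.
#' @param predictors variable names; defaults to the nine standard sonde
#'   predictors present in `meta`.
#' @param scale min-max scale to \[0, 1\] (the convention for chain-graph
#'   predictors)?
#' @return Numeric matrix samples x predictors, rownames = sample ids.
#' @export
env_matrix <- function(meta, predictors = NULL, scale = TRUE) {
  if (is.null(predictors)) predictors <- intersect(DEFAULT_PREDICTORS, names(meta))
  miss <- setdiff(predictors, names(meta))
  if (length(miss)) stop("unknown predictor(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(meta[, predictors, drop = FALSE])
  rownames(x) <- meta$sample_id
  if (scale) x <- minmax_scale(x)
  x
}

#' Assign samples to condition groups
#'
#' Samples are categorised separately under three schemes — depth, month and
#' oxygen regime — and each observed level of each scheme forms one
#' condition. The total number of conditions is the sum of distinct levels
#' over the three schemes (11 for the reference sampling design: 4 depths +
#' 4 months + 3 oxygen regimes).
#'
#' @param meta validated metadata data.frame.
#' @return data.frame with columns `scheme`, `condition`, `sample_id`; one
#'   row per (condition, member sample).
#' @export
assign_condition_groups <- function(meta) {
  validate_metadata(meta, env_vars = character())
  schemes <- list(depth = paste0(meta$depth_m, "m"),
                  month = as.character(meta$month),
                  oxygen = as.character(meta$oxygen))
  out <- do.call(rbind, lapply(names(schemes), function(s) {
    data.frame(scheme = s, condition = paste(s, schemes[[s]], sep = ":"),
               sample_id = meta$sample_id, stringsAsFactors = FALSE)
  }))
  out[order(out$scheme, out$condition, out$sample_id), , drop = FALSE]
}

#' Count condition groups and their sizes
#'
#' @param groups output of [assign_condition_groups()].
#' @return data.frame `scheme`, `condition`, `n` ordered by scheme then
#'   condition.
#' @export
condition_sizes <- function(groups) {
  agg <- stats::aggregate(list(n = groups$sample_id),
                          by = list(scheme = groups$scheme,
                                    condition = groups$condition),
                          FUN = length)
  agg[order(agg$scheme, agg$condition), , drop = FALSE]
}

#' Parse a taxonomy table
#'
#' Accepts either GTDB-style lineage strings
#' (`d__...;p__...;c__...;o__...;f__...;g__...;s__...`) in a `taxonomy`
#' column, or one column per rank. Empty rank fields become `"UNKNOWN"`, and
#' the deepest named rank is reported as `lowest_confident_rank` (the
#' convention of reporting the lowest confident assignment).
#'
#' @param path file path.
#' @param sep delimiter; inferred from extension by default.
#' @return data.frame with `taxon_id`, the seven rank columns and
#'   `lowest_confident_rank`.
#' @export
read_taxonomy <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"taxon_id" %in% names(df)) stop("taxonomy table needs a taxon_id column")
  if ("taxonomy" %in% names(df)) {
    prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
    parts <- strsplit(df$taxonomy, ";", fixed = TRUE)
    ranks <- t(vapply(parts, function(p) {
      p <- trimws(p)
      vapply(seq_along(TAXONOMIC_RANKS), function(i) {
        hit <- p[startsWith(p, prefixes[i])]
        val <- if (length(hit)) sub(prefixes[i], "", hit[1], fixed = TRUE) else ""
        if (nzchar(val)) val else "UNKNOWN"
      }, character(1))
    }, character(length(TAXONOMIC_RANKS))))
    colnames(ranks) <- TAXONOMIC_RANKS
    out <- data.frame(taxon_id = df$taxon_id, ranks, stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(TAXONOMIC_RANKS, names(df))
    if (length(miss)) stop("taxonomy table missing rank column(s): ",
                           paste(miss, collapse = ", "))
    out <- df[, c("taxon_id", TAXONOMIC_RANKS)]
    for (r in TAXONOMIC_RANKS) {
      x <- out[[r]]
      x[is.na(x) | !nzchar(x)] <- "UNKNOWN"
      out[[r]] <- x
    }
  }
  enforce_rank_monotonicity(out)
}

# Once a rank is UNKNOWN, all deeper ranks are forced UNKNOWN, and the
# deepest named rank is recorded.
enforce_rank_monotonicity <- function(tax) {
  rk <- as.matrix(tax[, TAXONOMIC_RANKS, drop = FALSE])
  for (i in seq_len(nrow(rk))) {
    cut <- which(rk[i, ] == "UNKNOWN")
    if (length(cut)) rk[i, cut[1]:ncol(rk)] <- "UNKNOWN"
  }
  tax[, TAXONOMIC_RANKS] <- rk
  tax$lowest_confident_rank <- apply(rk, 1, function(r) {
    known <- which(r != "UNKNOWN")
    if (length(known)) TAXONOMIC_RANKS[max(known)] else "none"
  })
  tax
}
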