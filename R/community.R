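#' Screen for strongly concordant sample pairs
#'
#' Computes correlations between sample relative-abundance profiles under
#' Pearson and Spearman (average ranks for ties) and reports the pairs whose
#' correlation exceeds the threshold under *every* requested method — the
#' "shared across both metrics" rule with the conventional r > 0.8 cut.
#' Pairs involving a constant profile (undefined correlation) are skipped
#' with a warning.
#'
#' @param m tss-layer [abundance_matrix()] with >= 3 taxa.
#' @param methods subset of `c("pearson", "spearman")`.
#' @param threshold correlation cut-off (default 0.8).
#' @return data.frame `sample_a`, `sample_b` and one `r_<method>` column per
#'   method, one row per retained pair.
#' @export
sample_correlation_screen <- function(m, methods = c("pearson", "spearman"),
                                      threshold = 0.8) {
  stopifnot(inherits(m, "abund_mat"))
  if (m$normalisation != "tss")
    stop("sample_correlation_screen expects a tss-layer matrix")
  if (ncol(m$values) < 3) stop("need at least 3 taxa")
  methods <- match.arg(methods, several.ok = TRUE)
  v <- t(m$values)  # taxa x samples: correlate sample columns
  const <- apply(v, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    warning("constant profile(s) skipped: ",
            paste(colnames(v)[const], collapse = ", "))
  cors <- lapply(methods, function(me) suppressWarnings(stats::cor(v, method = me)))
  names(cors) <- methods
  ids <- colnames(v)
  out <- NULL
  for (i in seq_len(ncol(v) - 1)) for (j in seq(i + 1, ncol(v))) {
    if (const[i] || const[j]) next
    rs <- vapply(cors, function(cm) cm[i, j], numeric(1))
    if (all(rs > threshold)) {
      row <- data.frame(sample_a = ids[i], sample_b = ids[j],
                        stringsAsFactors = FALSE)
      for (me in methods) row[[paste0("r_", me)]] <- rs[[me]]
      out <- rbind(out, row)
    }
  }
  if (is.null(out)) {
    out <- data.frame(sample_a = character(0), sample_b = character(0))
    for (me in methods) out[[paste0("r_", me)]] <- numeric(0)
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) between sample rows;
#' conventionally applied to Hellinger-transformed abundances so dominant
#' taxa do not swamp the distances.
#'
#' @param m [abundance_matrix()] with non-negative entries.
#' @return A `dist_matrix`: list with `sample_ids` and the symmetric,
#'   zero-diagonal `values` matrix.
#' @export
bray_curtis <- function(m) {
  stopifnot(inherits(m, "abund_mat"))
  if (any(m$values < 0)) stop("bray_curtis needs non-negative entries")
  if (sum(rowSums(m$values) == 0) >= 2)
    stop("two all-zero samples make Bray-Curtis undefined")
  d <- as.matrix(vegan::vegdist(m$values, method = "bray"))
  if (any(!is.finite(d))) stop("undefined Bray-Curtis distance (all-zero pair?)")
  diag(d) <- 0
  structure(list(sample_ids = rownames(m$values), values = d),
            class = "dist_matrix")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared distance matrix (Gower centering) and
#' eigendecomposes it; coordinates are eigenvectors scaled by the square
#' root of the positive eigenvalues, so Euclidean input distances are
#' reproduced exactly. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities like Bray-Curtis) are reported but excluded from the
#' percentage of variance explained.
#'
#' @param d a `dist_matrix` (from [bray_curtis()] or built directly) with
#'   >= 3 samples.
#' @return An `ordination`: `coordinates` (samples x axes), `eigenvalues`
#'   (all, decreasing), `variance_explained` (% per positive axis).
#' @export
pcoa <- function(d) {
  stopifnot(inherits(d, "dist_matrix"))
  n <- nrow(d$values)
  if (n < 3) stop("need at least 3 samples")
  # cmdscale warns when trailing eigenvalues are not positive; that is the
  # expected situation for semi-metric dissimilarities and handled below
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(d$values),
                                         k = n - 1, eig = TRUE))
  eig <- cs$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)
  coords <- cs$points
  if (any(pos)) {
    coords <- coords[, seq_len(sum(pos)), drop = FALSE]
    colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
    ve <- 100 * eig[pos] / sum(eig[pos])
  } else {
    coords <- matrix(0, n, 0, dimnames = list(d$sample_ids, NULL))
    ve <- numeric(0)
  }
  rownames(coords) <- d$sample_ids
  structure(list(coordinates = coords, eigenvalues = eig,
                 variance_explained = ve),
            class = "ordination")
}

check_terms <- function(meta, vars) {
  for (v in vars) {
    if (!v %in% names(meta)) stop("unknown factor in formula: ", v)
    if (length(unique(meta[[v]])) < 2)
      stop("factor with a single level: ", v)
  }
}

#' Multi-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' sequential (Type-I) partitioning of the Gower-centred matrix in the order
#' the terms are given, pseudo-F by permutation of raw sample labels, and
#' the +1 p-value convention `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`
#' (so the smallest attainable p with 999 permutations is 0.001).
#'
#' @param d a `dist_matrix`.
#' @param meta metadata with one row per sample of `d`.
#' @param terms character vector of model terms in fitting order, e.g.
#'   `c("depth_m", "month", "oxygen")` or `c("depth_m * month")`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return A `permanova_fit`: `table` (term, Df, SumOfSqs, R2, F, p), plus
#'   `n_permutations` and `seed`.
#' @export
permanova <- function(d, meta, terms, n_perm = 999, seed = 1) {
  stopifnot(inherits(d, "dist_matrix"), n_perm >= 1)
  meta <- meta[match(d$sample_ids, meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id))) stop("metadata missing for some samples")
  vars <- unique(all.vars(stats::as.formula(paste("~", paste(terms, collapse = "+")))))
  check_terms(meta, vars)
  df <- meta
  for (v in vars) if (!is.numeric(df[[v]]) || length(unique(df[[v]])) <= 8)
    df[[v]] <- factor(df[[v]])
  fml <- stats::as.formula(paste("dmat ~", paste(terms, collapse = " + ")))
  dmat <- stats::as.dist(d$values)
  tab <- with_seed(derive_seed(seed, "permanova"), {
    vegan::adonis2(fml, data = df, permutations = n_perm, by = "terms")
  })
  out <- data.frame(term = rownames(tab), Df = tab$Df, SumOfSqs = tab$SumOfSqs,
                    R2 = tab$R2, F = tab$F, p = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(table = out, n_permutations = n_perm, seed = seed),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations)\n", x$n_permutations))
  print(x$table, digits = 4)
  invisible(x)
}

#' Pairwise PERMANOVA over the levels of one factor
#'
#' Runs a one-factor PERMANOVA on every pair of factor levels. Raw p-values
#' are what the analysis reads (pairwise tables are conventionally reported
#' uncorrected); a Benjamini-Hochberg column is emitted alongside for
#' reference. Levels with fewer than 2 samples are skipped with a warning.
#'
#' @param d a `dist_matrix`.
#' @param meta per-sample metadata.
#' @param factor_name the grouping column in `meta`.
#' @param n_perm permutations per pair.
#' @param seed integer seed.
#' @return data.frame `level_a`, `level_b`, `F`, `R2`, `p`, `p_bh`.
#' @export
pairwise_permanova <- function(d, meta, factor_name, n_perm = 999, seed = 1) {
  meta <- meta[match(d$sample_ids, meta$sample_id), , drop = FALSE]
  lv <- unique(as.character(meta[[factor_name]]))
  if (length(lv) < 2) stop("factor has fewer than 2 levels")
  sizes <- table(as.character(meta[[factor_name]]))
  out <- NULL
  for (i in seq_len(length(lv) - 1)) for (j in seq(i + 1, length(lv))) {
    a <- lv[i]; b <- lv[j]
    if (sizes[[a]] < 2 || sizes[[b]] < 2) {
      warning("skipping pair ", a, " vs ", b, ": a level has < 2 samples")
      next
    }
    keep <- meta[[factor_name]] %in% c(a, b)
    sub <- structure(list(sample_ids = d$sample_ids[keep],
                          values = d$values[keep, keep, drop = FALSE]),
                     class = "dist_matrix")
    fit <- permanova(sub, meta[keep, , drop = FALSE], factor_name,
                     n_perm = n_perm, seed = derive_seed(seed, paste(a, b)))
    row1 <- fit$table[1, ]
    out <- rbind(out, data.frame(level_a = a, level_b = b, F = row1$F,
                                 R2 = row1$R2, p = row1$p,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(level_a = character(0), level_b = character(0),
                      F = numeric(0), R2 = numeric(0), p = numeric(0),
                      p_bh = numeric(0)))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Top-k prevalence of taxa across condition groups
#'
#' Per condition, taxa are ranked by mean relative abundance over the member
#' samples (descending, ties by taxon id) and the top k recorded.
#' `Presence_Count` is the number of conditions in which a taxon makes the
#' top k, and `Bar_Percent = Presence_Count / n_conditions x 100`.
#'
#' @param m tss-layer [abundance_matrix()].
#' @param groups output of [assign_condition_groups()].
#' @param k taxa retained per condition (default 10).
#' @return List with `top_taxa` (condition, rank, taxon_id, mean_abundance)
#'   and `prevalence` (taxon_id, per-condition presence flags,
#'   Presence_Count, Bar_Percent).
#' @export
top_taxa_prevalence <- function(m, groups, k = 10) {
  stopifnot(inherits(m, "abund_mat"))
  if (m$normalisation != "tss") stop("top_taxa_prevalence expects a tss matrix")
  conds <- unique(groups$condition)
  top <- NULL
  for (cn in conds) {
    member <- groups$sample_id[groups$condition == cn]
    if (!length(member)) stop("empty condition: ", cn)
    miss <- setdiff(member, sample_ids(m))
    if (length(miss)) stop("condition members absent from matrix: ",
                           paste(miss, collapse = ", "))
    mu <- colMeans(m$values[member, , drop = FALSE])
    ord <- order(-mu, names(mu))
    kk <- min(k, length(mu))
    if (kk < length(mu) && mu[ord[kk]] == mu[ord[kk + 1]])
      message("tie at rank ", kk, " in condition ", cn,
              "; resolved by taxon id")
    sel <- ord[seq_len(kk)]
    top <- rbind(top, data.frame(condition = cn, rank = seq_len(kk),
                                 taxon_id = names(mu)[sel],
                                 mean_abundance = unname(mu[sel]),
                                 stringsAsFactors = FALSE))
  }
  hit_taxa <- sort(unique(top$taxon_id))
  flags <- sapply(conds, function(cn)
    as.integer(hit_taxa %in% top$taxon_id[top$condition == cn]))
  flags <- matrix(flags, nrow = length(hit_taxa),
                  dimnames = list(hit_taxa, conds))
  prev <- data.frame(taxon_id = hit_taxa, flags,
                     Presence_Count = rowSums(flags),
                     check.names = FALSE, stringsAsFactors = FALSE)
  prev$Bar_Percent <- prev$Presence_Count / length(conds) * 100
  prev <- prev[order(-prev$Presence_Count, prev$taxon_id), , drop = FALSE]
  rownames(prev) <- NULL
  list(top_taxa = top, prevalence = prev, n_conditions = length(conds), k = k)
}
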