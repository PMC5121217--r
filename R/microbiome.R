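#' OTU count helpers
#'
#' Throughout the package an OTU count table is a tibble with an `otu_id`
#' column and one numeric column per sample (the layout of
#' `otu_counts.tsv`).  `otu_matrix()` converts it to the samples-by-OTUs
#' integer matrix used internally.
#'
#' @param counts An OTU count tibble (`otu_id` + one column per sample) or
#'   an already-converted samples-by-OTUs matrix.
#' @return A samples-by-OTUs numeric matrix with dimnames.
#' @keywords internal
otu_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
  } else {
    stopifnot(is.data.frame(counts), "otu_id" %in% names(counts))
    m <- t(as.matrix(counts[setdiff(names(counts), "otu_id")]))
    colnames(m) <- counts$otu_id
  }
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("sample ids must be unique", call. = FALSE)
  m
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples is exactly one, the
#' usual pre-filter before community analysis of short-read OTU tables.
#'
#' @param counts An OTU count tibble (see [otu_matrix()]).
#' @return The count tibble without singleton OTUs.
#' @export
remove_singletons <- function(counts) {
  m <- otu_matrix(counts)
  keep <- colSums(m) != 1
  counts[counts$otu_id %in% colnames(m)[keep], , drop = FALSE]
}

#' Relative OTU abundances
#'
#' Scales each sample to proportions; every sample column sums to 1.
#'
#' @param counts An OTU count tibble (`otu_id` + sample columns).
#' @return A tibble of the same shape holding per-sample proportions.
#' @examples
#' tab <- tibble::tibble(otu_id = c("a", "b", "c"),
#'                       s1 = c(10, 30, 60), s2 = c(1, 1, 2))
#' relative_abundance(tab)
#' @export
relative_abundance <- function(counts) {
  m <- otu_matrix(counts)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(rownames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  p <- m / totals
  out <- counts
  out[setdiff(names(out), "otu_id")] <- as.data.frame(t(p))
  out
}

#' OTUs above a relative-abundance threshold
#'
#' Returns the OTUs whose relative abundance reaches the threshold in at
#' least one sample.  The boundary is inclusive by default
#' (`abundance >= threshold`); set `strict = TRUE` for a strict
#' "exceeds" rule.
#'
#' @param counts An OTU count tibble.
#' @param threshold Relative-abundance threshold (default 0.01, the
#'   conventional 1% screen).
#' @param strict Use `>` instead of `>=` at the boundary.
#' @return Character vector of OTU ids, in table order.
#' @export
abundant_otus <- function(counts, threshold = 0.01, strict = FALSE) {
  m <- otu_matrix(relative_abundance(counts))
  peak <- apply(m, 2, max)
  hit <- if (strict) peak > threshold else peak >= threshold
  colnames(m)[hit]
}

#' Shannon diversity index
#'
#' `shannon_index()` computes the Shannon entropy of one proportion
#' vector, `-sum(p * log(p))` with zero proportions excluded; the log base
#' defaults to 2 (so a community of S equally abundant OTUs scores
#' log2(S)).  `shannon_diversity()` maps it over every sample of a count
#' table.
#'
#' @param p Proportions for one sample (non-negative; normalised if they
#'   do not sum to one).
#' @param base Logarithm base (default 2; use `exp(1)` for nats).
#' @return A single diversity value, or for `shannon_diversity()` a tibble
#'   `(sample_id, shannon)`.
#' @examples
#' shannon_index(rep(1 / 16, 16)) # 4 bits
#' @export
shannon_index <- function(p, base = 2) {
  if (any(p < 0)) stop("proportions must be non-negative", call. = FALSE)
  if (sum(p) <= 0) stop("proportions must have a positive sum", call. = FALSE)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' @rdname shannon_index
#' @param counts An OTU count tibble.
#' @export
shannon_diversity <- function(counts, base = 2) {
  m <- otu_matrix(counts)
  tibble::tibble(
    sample_id = rownames(m),
    shannon = unname(apply(m, 1, shannon_index, base = base))
  )
}

#' Critical Pearson correlation at a given sample size
#'
#' The smallest |r| that is significant at level `alpha` in a two-sided
#' test with `n` paired observations:
#' `t / sqrt(t^2 + n - 2)` with `t = qt(1 - alpha/2, n - 2)`.
#' At `n = 7` and `alpha = 0.05` this is 0.754, the gate used to call an
#' OTU's relative abundance positively correlated with MCC productivity.
#'
#' @param n Number of paired observations (>= 3).
#' @param alpha Significance level (default 0.05).
#' @param two_sided Use the two-sided critical value (default `TRUE`).
#' @return Critical r in (0, 1), strictly decreasing in `n`.
#' @examples
#' critical_pearson_r(7) # 0.754
#' @export
critical_pearson_r <- function(n, alpha = 0.05, two_sided = TRUE) {
  if (any(n < 3)) stop("n must be at least 3", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  p_tail <- if (two_sided) 1 - alpha / 2 else 1 - alpha
  t_crit <- stats::qt(p_tail, df = n - 2)
  t_crit / sqrt(t_crit^2 + n - 2)
}

#' Correlate OTU abundances with productivity
#'
#' For every OTU passing the relative-abundance screen, computes the
#' Pearson correlation between its relative abundance and the per-sample
#' MCC productivity, the two-sided p-value from the t-transform
#' (`stats::cor.test`), and a positive-direction significance flag:
#' an OTU is called significant when `r > critical_pearson_r(n, alpha)`.
#' No multiple-testing correction is applied by default; `adjust = "BH"`
#' adds Benjamini-Hochberg adjusted p-values.
#'
#' @param counts An OTU count tibble.
#' @param metadata A tibble with `sample_id` and `productivity` (g
#'   COD/L-d); only samples present in both the counts and the metadata
#'   (with non-missing productivity) enter the correlation.
#' @param alpha Significance level for the gate (default 0.05).
#' @param threshold,strict Passed to [abundant_otus()] (screen computed on
#'   the correlated samples); `threshold = 0` keeps every OTU.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble `(otu_id, r, p_value, significant, note)`, one row per
#'   screened OTU.  Zero-variance abundance vectors get `r = NA` and
#'   `note = "undefined-r"` instead of propagating NaN.
#' @examples
#' sim <- simulate_otu_table(otu_sim_config(seed = 1))
#' correlate_otus(sim$counts, sim$metadata)
#' @export
correlate_otus <- function(counts, metadata, alpha = 0.05, threshold = 0.01,
                           strict = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "productivity") %in% names(metadata)))
  meta <- metadata[!is.na(metadata$productivity), ]
  keep_samples <- intersect(names(counts), meta$sample_id)
  if (length(keep_samples) < 3) {
    stop("at least 3 samples with productivity metadata are required",
         call. = FALSE)
  }
  sub <- counts[c("otu_id", keep_samples)]
  prod <- meta$productivity[match(keep_samples, meta$sample_id)]
  screened <- abundant_otus(sub, threshold = threshold, strict = strict)
  p_mat <- otu_matrix(relative_abundance(sub))
  n <- length(keep_samples)
  r_crit <- critical_pearson_r(n, alpha)
  out <- purrr::map_dfr(screened, function(otu) {
    x <- p_mat[, otu]
    if (stats::sd(x) == 0 || stats::sd(prod) == 0) {
      return(tibble::tibble(otu_id = otu, r = NA_real_, p_value = NA_real_,
                            significant = FALSE, note = "undefined-r"))
    }
    ct <- stats::cor.test(x, prod, method = "pearson",
                          alternative = "two.sided")
    r <- unname(ct$estimate)
    tibble::tibble(otu_id = otu, r = r, p_value = ct$p.value,
                   significant = r > r_crit, note = NA_character_)
  })
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  attr(out, "n") <- n
  attr(out, "critical_r") <- r_crit
  out
}

#' Bray-Curtis dissimilarity and UPGMA ordering
#'
#' Computes pairwise Bray-Curtis dissimilarities on relative abundances
#' and clusters them with average linkage (UPGMA), returning the
#' dendrogram leaf order used to arrange heat maps.  Rows are sorted
#' lexicographically by id before clustering so equal-height merges
#' resolve deterministically.
#'
#' @param counts An OTU count tibble.
#' @param margin Cluster `"samples"` (default) or `"otus"`.
#' @return A list of class `bc_cluster`: `distance` (a `dist`, values in
#'   `[0, 1]`), `hclust` (average linkage), and `order` (leaf ids in
#'   dendrogram order).
#' @examples
#' tab <- tibble::tibble(otu_id = c("a", "b"),
#'                       s1 = c(10, 0), s2 = c(0, 10), s3 = c(5, 5))
#' bray_curtis_cluster(tab)$order
#' @export
bray_curtis_cluster <- function(counts, margin = c("samples", "otus")) {
  margin <- match.arg(margin)
  p <- otu_matrix(relative_abundance(counts))
  if (margin == "otus") p <- t(p)
  p <- p[order(rownames(p)), , drop = FALSE]
  if (nrow(p) < 2) stop("at least 2 units are required to cluster", call. = FALSE)
  d <- vegan::vegdist(p, method = "bray")
  hc <- stats::hclust(d, method = "average")
  structure(
    list(distance = d, hclust = hc, order = rownames(p)[hc$order]),
    class = "bc_cluster"
  )
}

#' @export
print.bc_cluster <- function(x, ...) {
  cat("Bray-Curtis / UPGMA clustering of", attr(x$distance, "Size"),
      "units\n  leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical (metric) multidimensional scaling of a dissimilarity matrix:
#' eigen-decomposition of the double-centred squared-distance matrix.
#' For Euclidean input the configuration is recovered exactly (up to
#' rotation/reflection); for semimetrics such as Bray-Curtis, negative
#' eigenvalues can occur and are reported, never hidden.  Variance
#' explained is each positive eigenvalue over the sum of positive
#' eigenvalues.
#'
#' @param d A `dist` object or symmetric zero-diagonal matrix.
#' @param k Number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return An object of class `pcoa_ordination`: `points` (tibble with
#'   `sample_id` and `Axis.1 ... Axis.k`), `eigenvalues` (all, including
#'   negatives), `variance_explained` (fractions, nonincreasing), and
#'   `negative_eigenvalues`.
#' @examples
#' xy <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' ord <- pcoa(dist(xy))
#' ord$variance_explained
#' @export
pcoa <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m)) || any(diag(m) != 0)) {
      stop("d must be symmetric with a zero diagonal", call. = FALSE)
    }
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  # cmdscale warns when the dissimilarity is non-Euclidean; the negative
  # eigenvalues it refers to are returned explicitly below
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(eig) * 1e-9
  n_axes <- min(sum(pos), ncol(fit$points))
  if (is.null(k)) k <- n_axes else k <- min(k, n_axes)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis.", seq_len(k))
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  structure(
    list(
      points = dplyr::bind_cols(tibble::tibble(sample_id = labels),
                                tibble::as_tibble(coords)),
      eigenvalues = eig,
      variance_explained = eig[pos] / sum(eig[pos]),
      negative_eigenvalues = eig[eig < 0]
    ),
    class = "pcoa_ordination"
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  ve <- round(100 * x$variance_explained[seq_len(min(2, length(x$variance_explained)))])
  cat("Principal coordinates analysis:", nrow(x$points), "samples\n")
  cat("  first axes explain:", paste0(ve, "%", collapse = ", "), "\n")
  if (length(x$negative_eigenvalues) > 0) {
    cat("  negative eigenvalues:", length(x$negative_eigenvalues),
        "(min", signif(min(x$negative_eigenvalues), 3), ")\n")
  }
  invisible(x)
}
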