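# Correlation structure between model predictions and hierarchical
# grouping of GCMs on the correlation distance d = 1 - r.

#' Pairwise between-model correlation for one variable
#'
#' Pearson correlation between every pair of models, computed across
#' all grid cells where both models are unmasked (cells weighted
#' uniformly). A model with zero variance has undefined correlations:
#' its entries are masked and the model is flagged.
#'
#' @param cube an [ensemble_cube()].
#' @param variable a bioclim variable name.
#' @param min_shared minimum shared unmasked cells per pair (default 3).
#' @return symmetric model x model correlation matrix (diagonal 1) of
#'   class `correlation_matrix`, with attributes `variable` and
#'   `flagged` (zero-variance model ids).
#' @export
pairwise_model_correlation <- function(cube, variable, min_shared = 3) {
  stopifnot(inherits(cube, "ensemble_cube"))
  x <- cube_slice(cube, variable)
  models <- colnames(x)
  m <- ncol(x)
  r <- matrix(NA_real_, m, m, dimnames = list(models, models))
  diag(r) <- 1
  sds <- apply(x, 2, sd, na.rm = TRUE)
  flagged <- models[!is.na(sds) & sds == 0]
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ok <- is.finite(x[, i]) & is.finite(x[, j])
      if (sum(ok) < min_shared) {
        stop("models ", models[i], " and ", models[j], " share fewer than ",
             min_shared, " unmasked cells")
      }
      if (sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) next
      r[i, j] <- r[j, i] <- cor(x[ok, i], x[ok, j])
    }
  }
  structure(r, variable = variable, flagged = flagged,
            class = c("correlation_matrix", "matrix", "array"))
}

#' Group models by hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of models on the distance d = 1 - r, with
#' the tree cut into `k` groups (k = 4 by default, the ensemble-audit
#' convention). Given a list of per-variable correlation matrices, the
#' distance is the mean of the per-variable distance matrices — the
#' all-variable consensus grouping. Group labels are renumbered by
#' order of first member appearance in the model roster, so the
#' labelling is reproducible.
#'
#' @param corr a `correlation_matrix` (or plain symmetric matrix), or a
#'   list of them for the consensus grouping.
#' @param k number of groups (default 4); must not exceed the number of
#'   models.
#' @param linkage agglomeration method (default `"complete"`).
#' @return an object of class `cluster_result`: list with `labels`
#'   (named integer vector), `hclust` (the dendrogram), `k`, `linkage`,
#'   and `degenerate` (`TRUE` when all pairwise distances are 0, ties
#'   then broken by model order).
#' @export
cluster_models <- function(corr, k = 4, linkage = "complete") {
  if (is.list(corr) && !is.data.frame(corr)) {
    dmats <- lapply(corr, function(m) 1 - unclass(m))
    d <- Reduce(`+`, dmats) / length(dmats)
  } else {
    d <- 1 - unclass(corr)
  }
  n <- nrow(d)
  if (k > n) stop("k = ", k, " exceeds the number of models (", n, ")")
  if (anyNA(d)) stop("distance matrix has masked entries")
  degenerate <- all(d[upper.tri(d)] < 1e-12)
  hc <- hclust(as.dist(d), method = linkage)
  raw <- cutree(hc, k = k)
  # renumber groups by first appearance in the roster
  first <- match(unique(raw), raw)
  remap <- setNames(order(order(first)), unique(raw))
  labels <- setNames(as.integer(remap[as.character(raw)]), names(raw))
  structure(list(labels = labels, hclust = hc, k = k, linkage = linkage,
                 degenerate = degenerate),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, %s linkage%s\n", x$k, x$linkage,
              if (x$degenerate) " [degenerate: all distances 0]" else ""))
  print(x$labels)
  invisible(x)
}

#' Per-variable group table for an ensemble
#'
#' Runs [pairwise_model_correlation()] and [cluster_models()] for every
#' bioclim variable and assembles the models x variables table of group
#' ids (1-`k`), the layout used to choose a spanning subset of models
#' per variable.
#'
#' @inheritParams cluster_models
#' @param cube an [ensemble_cube()].
#' @return data.frame with one row per model and columns
#'   `BIO1`...`BIO19` holding group ids.
#' @export
cluster_table <- function(cube, k = 4, linkage = "complete") {
  cols <- lapply(bio_names(), function(v) {
    cluster_models(pairwise_model_correlation(cube, v), k, linkage)$labels
  })
  out <- as.data.frame(setNames(cols, bio_names()))
  rownames(out) <- dimnames(cube)[[2]]
  out
}

#' Long-format correlation summary across variables
#'
#' Assembles every between-model correlation into a long table
#' (variable, model pair, r, variable family) and the per-model /
#' per-variable boxplot-style summaries, with outliers by the 1.5 x IQR
#' rule. Temperature family: BIO1-BIO11; precipitation family:
#' BIO12-BIO19.
#'
#' @param matrices named list of per-variable `correlation_matrix`
#'   objects covering all 19 variables.
#' @return list with `pairs` (long data.frame: `variable`, `model_i`,
#'   `model_j`, `r`, `family`), `by_model` (per model and family:
#'   quartiles, whisker bounds and outlier count) and `by_variable`
#'   (per variable: quartiles and outlier count).
#' @export
correlation_summary <- function(matrices) {
  missing_vars <- setdiff(bio_names(), names(matrices))
  if (length(missing_vars)) {
    stop("missing correlation matrices for: ",
         paste(missing_vars, collapse = ", "))
  }
  pairs <- do.call(rbind, lapply(bio_names(), function(v) {
    r <- unclass(matrices[[v]])
    ij <- which(upper.tri(r), arr.ind = TRUE)
    data.frame(variable = v,
               model_i = rownames(r)[ij[, 1]],
               model_j = colnames(r)[ij[, 2]],
               r = r[ij],
               family = bio_family(v))
  }))

  box_stats <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    c(q1 = q[1], median = q[2], q3 = q[3], lower = lo, upper = hi,
      n_outliers = sum(v < lo | v > hi, na.rm = TRUE))
  }

  models <- unique(c(pairs$model_i, pairs$model_j))
  by_model <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(c("temperature", "precipitation"), function(fam) {
      v <- pairs$r[(pairs$model_i == m | pairs$model_j == m) &
                     pairs$family == fam]
      cbind(data.frame(model = m, family = fam), t(box_stats(v)))
    }))
  }))
  by_variable <- do.call(rbind, lapply(bio_names(), function(vn) {
    v <- pairs$r[pairs$variable == vn]
    cbind(data.frame(variable = vn, family = bio_family(vn)),
          t(box_stats(v)))
  }))
  rownames(by_model) <- rownames(by_variable) <- NULL
  list(pairs = pairs, by_model = by_model, by_variable = by_variable)
}

#' Export a model dendrogram as a Newick tree
#'
#' Writes the clustering dendrogram with branch lengths given by the
#' merge heights, for use in standard tree viewers.
#'
#' @param result a [cluster_models()] result.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to `file`.
#' @export
dendrogram_newick <- function(result, file = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  tree <- ape::as.phylo(result$hclust)
  if (is.null(file)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = file)
    invisible(ape::write.tree(tree))
  }
}
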