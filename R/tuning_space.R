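#' PCA of z-scored tuning profiles
#'
#' Principal component analysis of per-sensillum tuning profiles
#' (covariance PCA of the already z-scored responses, no re-scaling).
#' Sensilla with any missing odor value are dropped before fitting
#' (complete-case). The sign of PC1 is fixed so that the loading of
#' `orient_odor` (butyric acid, C4, by default) is non-negative: a larger
#' PC1 score means a more C4-tuned sensillum.
#'
#' @param z_matrix A [response_matrix()] of z-scored responses, or a plain
#'   numeric matrix with odor column names.
#' @param orient_odor Odor whose PC1 loading is forced `>= 0` (default
#'   `"C4"`); ignored with a message if absent from the columns.
#' @return An object of class `tuning_pca`: list with `loadings` (odors x
#'   components, orthonormal columns), `scores` (complete rows x
#'   components), `center` (fitted column means), `variance_fraction`
#'   (non-increasing, sums to 1), `odors`, `rows_used`, and `genotype`
#'   (labels of the rows used, when available).
#' @export
run_pca <- function(z_matrix, orient_odor = "C4") {
  x <- unclass(as.matrix(z_matrix))
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) stop("'z_matrix' must have odor column names")
  complete <- stats::complete.cases(x)
  if (sum(complete) < 2L) {
    stop("need at least 2 complete rows for PCA (got ", sum(complete), ")")
  }
  xc <- x[complete, , drop = FALSE]
  if (all(abs(sweep(xc, 2L, colMeans(xc))) < 1e-12)) {
    stop("zero total variance: all complete rows are identical")
  }
  fit <- stats::prcomp(xc, center = TRUE, scale. = FALSE)
  varfrac <- fit$sdev^2 / sum(fit$sdev^2)
  loadings <- fit$rotation
  scores <- fit$x
  if (orient_odor %in% rownames(loadings)) {
    if (loadings[orient_odor, 1L] < 0) {
      loadings[, 1L] <- -loadings[, 1L]
      scores[, 1L] <- -scores[, 1L]
    }
  } else {
    message("orientation odor '", orient_odor,
            "' not among columns; PC1 sign left as fitted")
  }
  gt <- attr(z_matrix, "genotype")
  structure(list(loadings = loadings, scores = scores, center = fit$center,
                 variance_fraction = stats::setNames(varfrac, colnames(loadings)),
                 odors = colnames(x), rows_used = rownames(x)[complete],
                 genotype = if (!is.null(gt)) gt[complete] else NULL),
            class = "tuning_pca")
}

#' @export
print.tuning_pca <- function(x, ...) {
  cat(sprintf("Tuning-space PCA: %d sensilla x %d odors\n",
              nrow(x$scores), length(x$odors)))
  vf <- round(100 * x$variance_fraction, 1)
  cat("Variance explained (%):",
      paste(names(vf), vf, sep = "=", collapse = ", "), "\n")
  cat("PC1 loadings:\n")
  print(round(x$loadings[, 1L], 3))
  invisible(x)
}

#' Project a tuning profile onto PC1
#'
#' The scalar tuning phenotype: the projection of one sensillum's z-scored
#' response profile onto the first principal component,
#' `(row - center) . pc1`. With the default orientation, larger values mean
#' stronger C4 (and C5) tuning and weaker C2 tuning.
#'
#' @param row Named numeric vector of z-scored responses covering all
#'   fitted odors; a missing odor value is an error.
#' @param result A [run_pca()] fit.
#' @return Scalar PC1 score.
#' @export
project_pc1 <- function(row, result) {
  if (!inherits(result, "tuning_pca")) stop("'result' must be a tuning_pca")
  if (!is.null(names(row))) {
    missing <- setdiff(result$odors, names(row))
    if (length(missing)) {
      stop("row lacks fitted odor(s): ", paste(missing, collapse = ", "))
    }
    row <- row[result$odors]
  } else if (length(row) != length(result$odors)) {
    stop("unnamed row must have one value per fitted odor")
  }
  if (anyNA(row)) stop("row has missing values over the fitted odors")
  drop(sum((row - result$center) * result$loadings[, 1L]))
}

#' PC1 scores for every complete row of a matrix
#'
#' @param mat A z-scored [response_matrix()] (or plain matrix).
#' @param result A [run_pca()] fit on the same odors.
#' @return Named numeric vector of PC1 scores for rows complete over the
#'   fitted odors; incomplete rows are omitted.
#' @export
project_pc1_rows <- function(mat, result) {
  x <- unclass(as.matrix(mat))
  x <- x[, result$odors, drop = FALSE]
  complete <- stats::complete.cases(x)
  scores <- apply(x[complete, , drop = FALSE], 1L, project_pc1, result = result)
  stats::setNames(scores, rownames(x)[complete])
}

#' C2-max vs C4-max cluster assignment
#'
#' Classifies sensilla (or their per-genotype means) in the z-scored C2 vs
#' C4 plane: `"C2-max"` if the acetic acid (C2) z-score exceeds the butyric
#' acid (C4) z-score, `"C4-max"` if the reverse. An exact tie is
#' unclassified (`NA`).
#'
#' @param zC2,zC4 Numeric vectors of z-scored C2 and C4 responses (finite).
#' @return Character vector of labels `"C2-max"`/`"C4-max"`, `NA` for ties.
#' @export
assign_cluster <- function(zC2, zC4) {
  if (length(zC2) != length(zC4)) stop("zC2 and zC4 must have equal length")
  if (any(!is.finite(zC2)) || any(!is.finite(zC4))) {
    stop("z-scores must be finite")
  }
  out <- rep(NA_character_, length(zC2))
  out[zC2 > zC4] <- "C2-max"
  out[zC4 > zC2] <- "C4-max"
  out
}

#' Write PCA results to disk
#'
#' Writes the loadings and scores tables as CSV and a JSON summary with the
#' per-component variance fractions.
#'
#' @param result A [run_pca()] fit.
#' @param prefix Output path prefix; writes `<prefix>_loadings.csv`,
#'   `<prefix>_scores.csv` and `<prefix>_summary.json`.
#' @return The three paths, invisibly.
#' @export
write_pca <- function(result, prefix) {
  if (!inherits(result, "tuning_pca")) stop("'result' must be a tuning_pca")
  paths <- paste0(prefix, c("_loadings.csv", "_scores.csv", "_summary.json"))
  utils::write.csv(data.frame(odor = rownames(result$loadings),
                              result$loadings, check.names = FALSE),
                   paths[1], row.names = FALSE)
  utils::write.csv(data.frame(row = rownames(result$scores),
                              genotype = result$genotype %||% NA,
                              result$scores, check.names = FALSE),
                   paths[2], row.names = FALSE)
  jsonlite::write_json(list(variance_fraction = as.list(result$variance_fraction),
                            n_rows = nrow(result$scores),
                            odors = result$odors),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
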