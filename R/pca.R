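#' Principal component analysis of standardised genotypes
#'
#' Samples are rows, variants columns. Each variant is standardised to zero
#' mean and unit variance (monomorphic variants are excluded first), and
#' scores are taken from the singular value decomposition, as `prcomp()`
#' with `scale. = TRUE` would produce. Because the SVD sign is arbitrary,
#' each component's sign is fixed so that its largest-magnitude variant
#' loading is positive, making scores reproducible across runs and
#' platforms.
#'
#' @param gm a [genotype_matrix()] with no missing calls (filter or impute
#'   first), or set `impute_mean = TRUE`.
#' @param k number of components to return (default
#'   `min(n - 1, m)`).
#' @param impute_mean replace missing calls by the variant mean before
#'   standardisation (default FALSE: missing data are an error).
#' @return An object of class `pca_result`: `scores` (n x k), `loadings`
#'   (m x k), `percent_variance` (length k), `center`, `scale`,
#'   `sample_ids`, `variant_ids`.
#' @export
pca <- function(gm, k = NULL, impute_mean = FALSE) {
  x <- gm$calls
  if (anyNA(x)) {
    if (!impute_mean)
      stop("missing calls present; filter to complete variants ",
           "(e.g. filter_variants with max_missing_rate = 0) ",
           "or set impute_mean = TRUE")
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  v <- apply(x, 2, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("all variants monomorphic")
  x <- x[, keep, drop = FALSE]
  n <- nrow(x); m <- ncol(x)
  kmax <- min(n - 1L, m)
  if (is.null(k)) k <- kmax
  if (k > kmax) stop("k exceeds min(n - 1, m) = ", kmax)
  ctr <- colMeans(x)
  scl <- sqrt(v[keep])
  xs <- scale(x, center = ctr, scale = scl)
  sv <- svd(xs, nu = k, nv = k)
  ev <- sv$d^2 / (n - 1)
  # sign convention: largest-|loading| coordinate positive per component
  load <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(gm$samples$id, paste0("PC", seq_len(k)))
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = load,
                 percent_variance = 100 * ev[seq_len(k)] / sum(ev),
                 center = ctr, scale = scl,
                 sample_ids = gm$samples$id, variant_ids = colnames(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("pca_result: %d samples, %d variants, %d components\n",
              nrow(x$scores), nrow(x$loadings), k))
  cat("percent variance:",
      paste(sprintf("%.2f", utils::head(x$percent_variance, 5)),
            collapse = ", "),
      if (k > 5) "..." else "", "\n")
  invisible(x)
}

#' Select samples by a predicate over principal-component scores
#'
#' Evaluates `predicate` in an environment where each component is available
#' by name (`PC1`, `PC2`, ...), e.g.
#' `select_by_pc(res, PC1 < -40 & PC2 > 20)`. Comparisons are exactly as
#' written: strict operators exclude boundary samples.
#'
#' @param result a `pca_result`.
#' @param predicate an expression over component names.
#' @return Character vector of sample ids satisfying the predicate.
#' @export
select_by_pc <- function(result, predicate) {
  stopifnot(inherits(result, "pca_result"))
  expr <- substitute(predicate)
  vars <- all.vars(expr)
  unknown <- setdiff(vars[grepl("^PC[0-9]+$", vars)], colnames(result$scores))
  if (length(unknown)) stop("unknown component name: ",
                            paste(unknown, collapse = ", "))
  env <- as.data.frame(result$scores)
  sel <- eval(expr, envir = env, enclos = parent.frame())
  if (!is.logical(sel) || length(sel) != nrow(result$scores))
    stop("predicate must evaluate to one logical per sample")
  result$sample_ids[which(sel)]
}
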