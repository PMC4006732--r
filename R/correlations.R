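#' Pairwise correlation structure across tissues
#'
#' Computes the symmetric matrix of pairwise Spearman (default) or Pearson
#' correlations between tissue columns — e.g. FPKM expression values per
#' gene, or allelic ratios per site — with pairwise-complete handling of
#' missing entries, plus a deterministic leaf order from average-linkage
#' hierarchical clustering on the correlation distance `1 - r`.
#'
#' @param mat A numeric matrix or data frame, rows = genes/sites,
#'   columns = tissues. A `site_id`/`gene_id`/rowname-like first character
#'   column of a data frame is used as rownames.
#' @param method `"spearman"` (rank-based, invariant under monotone
#'   transforms) or `"pearson"`.
#' @return A list of class `ase_cor` with `cor` (correlation matrix, unit
#'   diagonal), `order` (clustering leaf order of the column names) and
#'   `method`. Column pairs with fewer than 3 complete observations get
#'   `NA` with a warning.
#' @export
pairwise_correlations <- function(mat, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.data.frame(mat)) {
    chr <- vapply(mat, is.character, logical(1))
    if (any(chr)) {
      rn <- mat[[which(chr)[1]]]
      mat <- as.matrix(mat[!chr])
      rownames(mat) <- rn
    } else {
      mat <- as.matrix(mat)
    }
  }
  if (ncol(mat) < 2) abort("need at least two tissue columns")

  cc <- cor(mat, use = "pairwise.complete.obs", method = method)
  # columns sharing < 3 complete pairs are unreliable: blank them out
  p <- ncol(mat)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      n_ok <- sum(complete.cases(mat[, c(i, j)]))
      if (n_ok < 3) {
        cc[i, j] <- cc[j, i] <- NA_real_
        warn(sprintf("columns %s and %s share %d complete pair(s) (< 3); correlation set to NA",
                     colnames(mat)[i], colnames(mat)[j], n_ok))
      }
    }
  }
  diag(cc) <- 1

  ord <- colnames(cc)
  if (!anyNA(cc)) {
    hc <- hclust(as.dist(1 - cc), method = "average")
    ord <- colnames(cc)[hc$order]
  }
  structure(list(cor = cc, order = ord, method = method), class = "ase_cor")
}

#' @exportS3Method tidy ase_cor
tidy.ase_cor <- function(x, ...) {
  cc <- x$cor
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  tibble::tibble(
    tissue_a = rownames(cc)[idx[, 1]],
    tissue_b = colnames(cc)[idx[, 2]],
    estimate = cc[idx],
    method = x$method
  )
}

#' @exportS3Method autoplot ase_cor
autoplot.ase_cor <- function(object, ...) {
  df <- tidy(object)
  lv <- object$order
  df$tissue_a <- factor(df$tissue_a, levels = lv)
  df$tissue_b <- factor(df$tissue_b, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$tissue_a, .data$tissue_b,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-1, 1),
                                  name = paste0(object$method, " r")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
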