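#' Principal component analysis of haplogroup spectra
#'
#' Column-centered, unscaled PCA (via [stats::prcomp()]) of a
#' populations-by-classes frequency matrix, as conventional for haplogroup
#' frequency data. Correlation-mode (unit-variance scaling) is available
#' behind `scale.`.
#'
#' @param x a numeric matrix, or a data frame whose first column may be a
#'   population label (`population` or row names) followed by frequency
#'   columns; at least three rows.
#' @param scale. scale columns to unit variance before the decomposition?
#' @return an object of class `mt_pca` with tibble components `scores`
#'   (`label`, `PC1`, ...), `loadings` (`class`, `PC1`, ...) and `variance`
#'   (`component`, `sdev`, `variance`, `fraction`, `cumulative`); fractions
#'   sum to one. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
pca_spectra <- function(x, scale. = FALSE) {
  if (is.data.frame(x)) {
    label_col <- intersect(c("population", "label"), names(x))[1]
    if (!is.na(label_col)) {
      labels <- as.character(x[[label_col]])
      x <- x[setdiff(names(x), label_col)]
    } else {
      labels <- rownames(x) %||% as.character(seq_len(nrow(x)))
    }
    x <- as.matrix(x)
  } else {
    labels <- rownames(x) %||% as.character(seq_len(nrow(x)))
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) abort("frequency matrix must be numeric.")
  if (nrow(x) < 3) abort("PCA needs at least three populations (rows).")
  if (all(abs(sweep(x, 2, colMeans(x))) < 1e-12)) {
    abort("zero-variance frequency matrix: all rows identical.")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  comp <- paste0("PC", seq_along(fit$sdev))
  var <- fit$sdev^2
  scores <- tibble::as_tibble(fit$x)
  scores <- dplyr::bind_cols(tibble::tibble(label = labels), scores)
  loadings <- tibble::as_tibble(fit$rotation)
  loadings <- dplyr::bind_cols(tibble::tibble(class = rownames(fit$rotation)),
                               loadings)
  structure(
    list(
      scores = scores,
      loadings = loadings,
      variance = tibble::tibble(
        component = comp, sdev = fit$sdev, variance = var,
        fraction = var / sum(var), cumulative = cumsum(var) / sum(var)
      ),
      prcomp = fit
    ),
    class = "mt_pca"
  )
}

#' @export
print.mt_pca <- function(x, ...) {
  cat(sprintf("<mt_pca> %d populations, %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  v <- x$variance
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of total variance\n",
              100 * v$fraction[1], 100 * v$fraction[min(2, nrow(v))]))
  invisible(x)
}

#' @export
tidy.mt_pca <- function(x, matrix = c("scores", "loadings", "variance"), ...) {
  matrix <- match.arg(matrix)
  x[[matrix]]
}

#' @export
glance.mt_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    p = nrow(x$loadings),
    var_pc1 = x$variance$fraction[1],
    var_pc2 = if (nrow(x$variance) >= 2) x$variance$fraction[2] else NA_real_
  )
}

#' @export
autoplot.mt_pca <- function(object, arrows = TRUE, arrow_scale = NULL, ...) {
  v <- object$variance
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * v$fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * v$fraction[2])
    ) +
    ggplot2::theme_minimal()
  if (arrows) {
    sc <- arrow_scale %||%
      (0.8 * max(abs(unlist(object$scores[c("PC1", "PC2")]))) /
         max(abs(unlist(object$loadings[c("PC1", "PC2")]))))
    ld <- object$loadings
    p <- p +
      ggplot2::geom_segment(
        data = ld,
        ggplot2::aes(x = 0, y = 0, xend = sc * .data$PC1,
                     yend = sc * .data$PC2),
        inherit.aes = FALSE, colour = "grey55",
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
      ) +
      ggplot2::geom_text(
        data = ld,
        ggplot2::aes(x = 1.07 * sc * .data$PC1, y = 1.07 * sc * .data$PC2,
                     label = .data$class),
        inherit.aes = FALSE, colour = "grey40", size = 2.8
      )
  }
  p
}
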