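#' Genetic distance profile of an ancient spectrum against modern pools
#'
#' Computes a per-pool genetic distance between one haplogroup frequency
#' spectrum and each row of a pool frequency matrix sharing the same pooled
#' variables. The default is Nei's standard genetic distance
#' `D = -log( J_xy / sqrt(J_x * J_y) )` on haplogroup frequencies, with
#' Euclidean distance available as an alternative. The distance to an
#' identical spectrum is 0 and the measure is symmetric; spectra with no
#' shared haplogroup class have infinite Nei distance.
#'
#' @param ancient a named frequency vector, a one-row frequency data frame,
#'   or a spectrum tibble from [haplogroup_spectrum()].
#' @param pools a frequency matrix/data frame (one row per pool) with the
#'   same variables; a `population`/`label` column supplies pool names.
#' @param method `"nei"` (default) or `"euclidean"`.
#' @return a tibble with columns `pool`, `distance`, ordered as `pools`.
#' @export
distance_profile <- function(ancient, pools, method = c("nei", "euclidean")) {
  method <- match.arg(method)
  a <- as_freq_vector(ancient)
  p <- as_freq_matrix(pools)
  if (!setequal(names(a), colnames(p))) {
    abort("mismatched haplogroup variable sets between `ancient` and `pools`.")
  }
  p <- p[, names(a), drop = FALSE]
  d <- apply(p, 1, function(row) spectrum_distance(a, row, method))
  tibble::tibble(pool = rownames(p), distance = unname(d))
}

spectrum_distance <- function(x, y, method) {
  if (method == "euclidean") return(sqrt(sum((x - y)^2)))
  jxy <- sum(x * y)
  jx <- sum(x^2)
  jy <- sum(y^2)
  if (jxy <= 0) return(Inf)
  -log(jxy / sqrt(jx * jy))
}

as_freq_vector <- function(x) {
  if (is.data.frame(x) && all(c("class", "freq") %in% names(x))) {
    return(stats::setNames(x$freq, x$class))
  }
  if (is.data.frame(x)) {
    label_col <- intersect(c("population", "label"), names(x))
    x <- x[setdiff(names(x), label_col)]
    if (nrow(x) != 1) abort("`ancient` must describe a single spectrum.")
    return(unlist(x[1, , drop = TRUE]))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  abort("cannot interpret spectrum input.")
}

as_freq_matrix <- function(x) {
  if (is.data.frame(x)) {
    label_col <- intersect(c("population", "label"), names(x))[1]
    labels <- if (!is.na(label_col)) as.character(x[[label_col]]) else
      rownames(x) %||% as.character(seq_len(nrow(x)))
    m <- as.matrix(x[setdiff(names(x), label_col)])
    rownames(m) <- labels
    return(m)
  }
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m
}
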