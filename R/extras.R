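#' Bar plot of haplotype-sharing percentages
#'
#' @param data a tibble with columns `pool` (or `to`) and `percent`, e.g.
#'   accumulated [percent_shared()] results.
#' @return a ggplot object.
#' @export
plot_sharing <- function(data) {
  stopifnot(is.data.frame(data), "percent" %in% names(data))
  lab <- intersect(c("pool", "to", "population"), names(data))[1]
  if (is.na(lab)) abort("no pool label column found.")
  d <- tibble::tibble(pool = factor(data[[lab]], levels = data[[lab]]),
                      percent = data$percent)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pool, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = NULL, y = "shared haplotypes (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Read and write pool recipes as YAML
#'
#' @param path YAML file path.
#' @return for the reader, a list of [pool_recipe()]s.
#' @export
read_pool_recipes <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is required for recipe files.")
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    pool_recipe(
      label = r$label, n = r$n,
      hg_composition = unlist(r$hg_composition),
      diversity_target = r$diversity_target,
      planted = if (!is.null(r$planted)) {
        dplyr::bind_rows(lapply(r$planted, tibble::as_tibble))
      },
      seed = r$seed %||% 1
    )
  })
}

#' @rdname read_pool_recipes
#' @param recipes a list of [pool_recipe()]s.
#' @export
write_pool_recipes <- function(recipes, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is required for recipe files.")
  }
  if (inherits(recipes, "mt_pool_recipe")) recipes <- list(recipes)
  yaml::write_yaml(lapply(recipes, function(r) {
    list(label = r$label, n = r$n,
         hg_composition = as.list(r$hg_composition),
         diversity_target = r$diversity_target,
         planted = if (!is.null(r$planted)) {
           lapply(seq_len(nrow(r$planted)), function(i) {
             list(motif = r$planted$motif[i], count = r$planted$count[i])
           })
         },
         seed = r$seed)
  }), path)
  invisible(path)
}
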