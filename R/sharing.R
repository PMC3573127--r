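#' Build a standard 500-member comparison pool
#'
#' Pools one or more modern population tables and, when the combined size
#' exceeds `target_size`, draws `target_size` members uniformly without
#' replacement using an explicit seed (reproducible; the caller's RNG stream
#' is left untouched). A combined size below `target_size` is an error; a
#' table of exactly `target_size` members is returned unchanged.
#'
#' @param data a data frame of members (rows) from one or more populations,
#'   with a `population` column and a `key` or `motif` column.
#' @param target_size pool size, default 500.
#' @param seed integer seed for the subsampling draw; required whenever
#'   subsampling happens.
#' @param label pool label recorded in the result.
#' @return a tibble of `target_size` members with attributes `label`,
#'   `source_populations` and `seed` (class `mt_pool`).
#' @export
build_pool <- function(data, target_size = 500, seed = NULL, label = NULL) {
  stopifnot(is.data.frame(data))
  target_size <- stopifnot_scalar_count(target_size, "target_size")
  n <- nrow(data)
  if (n < target_size) {
    abort(sprintf(
      "combined population size %d is %d short of the pool size %d",
      n, target_size - n, target_size))
  }
  sources <- if ("population" %in% names(data)) {
    unique(as.character(data$population))
  } else {
    character(0)
  }
  out <- if (n == target_size) {
    tibble::as_tibble(data)
  } else {
    if (is.null(seed)) {
      abort("subsampling requires an explicit `seed`.")
    }
    idx <- with_seed(seed, sample.int(n, target_size))
    tibble::as_tibble(data[idx, , drop = FALSE])
  }
  structure(out,
            label = label %||% paste(sources, collapse = "+"),
            source_populations = sources,
            seed = seed,
            class = c("mt_pool", class(out)))
}

#' Percentage of pool members matching an ancient population's haplotypes
#'
#' Counts the pool members whose haplotype exactly matches at least one
#' distinct haplotype of the ancient population (matching on resolved
#' variants, see [hvr_match()]), divided by the pool size, times 100.
#' Duplicating ancient haplotypes does not change the result: matching is
#' against the distinct ancient haplotype set.
#'
#' @param ancient ancient population: data frame with `key`/`motif` or a
#'   character vector.
#' @param pool comparison pool (e.g. from [build_pool()]), same forms.
#' @return a single percentage in `[0, 100]`.
#' @export
percent_shared <- function(ancient, pool) {
  ak <- unique(population_keys(ancient))
  pk <- population_keys(pool)
  if (!length(pk)) abort("empty pool.")
  if (!length(ak)) abort("empty ancient population.")
  100 * sum(pk %in% ak) / length(pk)
}

#' Haplotype sharing between two ancient populations
#'
#' Directional exact sharing: the percentage of `pop_b` members whose
#' haplotype matches any haplotype present in `pop_a`. Both directions of a
#' comparison are generally different; [shared_between_ancient_both()]
#' reports the full pair.
#'
#' @param pop_a,pop_b populations (data frame with `key`/`motif`, or
#'   character vector of keys).
#' @return a single percentage in `[0, 100]`.
#' @export
shared_between_ancient <- function(pop_a, pop_b) {
  ka <- unique(population_keys(pop_a))
  kb <- population_keys(pop_b)
  if (!length(ka) || !length(kb)) abort("empty population.")
  100 * sum(kb %in% ka) / length(kb)
}

#' @rdname shared_between_ancient
#' @param label_a,label_b labels used in the output table.
#' @return for the `_both` variant, a tibble with one row per direction
#'   (`from`, `to`, `percent`).
#' @export
shared_between_ancient_both <- function(pop_a, pop_b, label_a = "pop_a",
                                        label_b = "pop_b") {
  tibble::tibble(
    from = c(label_a, label_b),
    to = c(label_b, label_a),
    percent = c(shared_between_ancient(pop_a, pop_b),
                shared_between_ancient(pop_b, pop_a))
  )
}

#' Drop redundant haplotypes (kinship filter)
#'
#' Identical haplotypes observed in more than one individual of the same
#' population unit may reflect close maternal kinship; this filter keeps each
#' distinct haplotype once per grouping unit. Idempotent.
#'
#' @param data a data frame of members with a `key` or `motif` column.
#' @param group name of the grouping column (default `"population"`, the
#'   pooled analysis unit; pass `"site"` to deduplicate per burial site).
#' @return the filtered tibble, first occurrence of each haplotype kept.
#' @export
dedupe_redundant <- function(data, group = "population") {
  stopifnot(is.data.frame(data))
  if (!nrow(data)) return(tibble::as_tibble(data))
  keys <- population_keys(data)
  g <- if (group %in% names(data)) as.character(data[[group]]) else ""
  keep <- !duplicated(paste(g, keys, sep = "\r"))
  tibble::as_tibble(data[keep, , drop = FALSE])
}
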