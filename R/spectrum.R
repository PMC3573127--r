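#' The 19 pooled haplogroup-frequency variables
#'
#' Seventeen named haplogroup classes plus the pooled `EAS` group (hgs A, B,
#' E, F, G, Y) and the `misc` group (L, M*, N*, U1, U6, U7, U8), in canonical
#' order.
#'
#' @return a character vector of length 19.
#' @export
spectrum_classes <- function() SPECTRUM_CLASSES

# roll a (possibly sub-)haplogroup label up to its pooled spectrum class
hg_to_class <- function(hg, motif_table = load_hg_motifs()) {
  cls <- motif_table$class[match(hg, motif_table$hg)]
  # labels not in the motif table: strip trailing sub-clade decoration and
  # match on the leading class name (e.g. "U5a2a" -> "U5a", "C4" -> "C")
  miss <- is.na(cls)
  if (any(miss)) {
    pooled <- c(stats::setNames(SPECTRUM_CLASSES, SPECTRUM_CLASSES),
                A = "EAS", B = "EAS", E = "EAS", F = "EAS", G = "EAS",
                Y = "EAS", L = "misc", U1 = "misc", U6 = "misc",
                U7 = "misc", U8 = "misc", "M*" = "misc", "N*" = "misc",
                U5 = "U5a")
    cand <- names(pooled)[order(nchar(names(pooled)), decreasing = TRUE)]
    for (i in which(miss)) {
      hit <- cand[startsWith(hg[i], cand)]
      if (length(hit)) cls[i] <- pooled[[hit[1]]]
    }
  }
  if (anyNA(cls)) {
    abort(sprintf("cannot pool haplogroup label(s): %s",
                  paste(unique(hg[is.na(cls)]), collapse = ", ")))
  }
  cls
}

#' Haplogroup frequency spectrum of a population sample
#'
#' Counts haplogroup labels and converts to frequencies. With `pooling = TRUE`
#' (the default) sub-haplogroups roll up into the 19 pooled variables of
#' [spectrum_classes()] (e.g. C1, C*, C5 to C; U4a1 to U4; Z1a to Z), and all
#' 19 classes are reported, including zeros. With `pooling = FALSE` the raw
#' labels are tabulated.
#'
#' @param data a data frame of population members with a haplogroup column,
#'   or a character vector of haplogroup labels.
#' @param hg name of the haplogroup column when `data` is a data frame.
#' @param pooling pool into the 19 spectrum classes?
#' @param motif_table motif/class table used for pooling.
#' @return a tibble with columns `class`, `count`, `freq` (and attribute
#'   `n`, the sample size). Frequencies sum to one.
#' @examples
#' pops <- load_ancient_fixture()
#' haplogroup_spectrum(pops[pops$population == "aUzPo", ])
#' @export
haplogroup_spectrum <- function(data, hg = "hg_hvr", pooling = TRUE,
                                motif_table = load_hg_motifs()) {
  labels <- if (is.data.frame(data)) {
    col <- if (hg %in% names(data)) hg else intersect(c("hg", "hg_hvr"),
                                                      names(data))[1]
    if (is.na(col) || is.null(col)) {
      abort("no haplogroup column found in `data`.")
    }
    data[[col]]
  } else {
    as.character(data)
  }
  if (!length(labels)) abort("empty population: no haplogroup labels.")
  if (anyNA(labels)) abort("missing haplogroup label(s).")
  n <- length(labels)
  if (pooling) {
    cls <- hg_to_class(labels, motif_table)
    counts <- table(factor(cls, levels = SPECTRUM_CLASSES))
  } else {
    counts <- table(labels)
  }
  out <- tibble::tibble(class = names(counts),
                        count = as.integer(counts),
                        freq = as.integer(counts) / n)
  attr(out, "n") <- n
  out
}

#' Spectrum matrix for several populations
#'
#' Convenience wrapper building the populations-by-19-classes frequency
#' matrix consumed by [pca_spectra()] and [distance_profile()].
#'
#' @param data a data frame of members with a population and a haplogroup
#'   column.
#' @param group name of the population column.
#' @inheritParams haplogroup_spectrum
#' @return a tibble with a `population` column followed by the 19 class
#'   frequency columns (rows sum to one).
#' @export
spectrum_matrix <- function(data, group = "population", hg = "hg_hvr",
                            motif_table = load_hg_motifs()) {
  stopifnot(is.data.frame(data), group %in% names(data))
  data %>%
    dplyr::group_by(population = .data[[group]]) %>%
    dplyr::group_modify(function(d, key) {
      haplogroup_spectrum(d, hg = hg, motif_table = motif_table)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::select("population", "class", "freq") %>%
    tidyr::pivot_wider(names_from = "class", values_from = "freq")
}

#' Integer percentages of a spectrum
#'
#' Frequencies times 100, rounded half-up to whole percent -- the convention
#' used when quoting haplogroup percentages in text.
#'
#' @param spectrum output of [haplogroup_spectrum()].
#' @return the spectrum tibble with an extra `percent` column.
#' @export
spectrum_percent <- function(spectrum) {
  stopifnot(is.data.frame(spectrum), "freq" %in% names(spectrum))
  spectrum$percent <- round_half_up(100 * spectrum$freq)
  spectrum
}

#' 'European' versus 'Central/East Siberian' pooled totals
#'
#' Sums the pooled spectrum into the two macro-regional ancestry components
#' conventionally contrasted for these data: European (H, HV, I, J, K, N1, T,
#' U2, U4, U5a, U5b, V, W, X) and Central/East Siberian (C, D, Z, EAS).
#'
#' @param spectrum output of [haplogroup_spectrum()] with 19-class pooling.
#' @return a tibble with columns `region`, `freq`, `percent`.
#' @export
spectrum_region_totals <- function(spectrum) {
  stopifnot(is.data.frame(spectrum),
            all(c("class", "freq") %in% names(spectrum)))
  eur <- sum(spectrum$freq[spectrum$class %in% EUROPEAN_CLASSES])
  sib <- sum(spectrum$freq[spectrum$class %in% SIBERIAN_CLASSES])
  tibble::tibble(
    region = c("European", "Siberian"),
    freq = c(eur, sib),
    percent = round_half_up(100 * c(eur, sib))
  )
}
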