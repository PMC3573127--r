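#' Assign a haplogroup from HVR-I variants
#'
#' Walks the motif table in order (most-derived haplogroups first) and returns
#' the first haplogroup whose defining variants -- position *and* base -- are
#' all present among the haplotype's resolved variants. The shipped table ends
#' with a zero-variant root row, so a reference-identical haplotype receives
#' that root label; with a table lacking such a row, `fallback` is returned
#' when nothing matches.
#'
#' @param hap an `hvr_haplotype` or a motif string.
#' @param motif_table a motif table as returned by [load_hg_motifs()].
#' @param fallback label returned when no haplogroup matches.
#' @return a single haplogroup label.
#' @examples
#' assign_haplogroup("223T-298C-327T")   # "C*"
#' @export
assign_haplogroup <- function(hap, motif_table = load_hg_motifs(),
                              fallback = "unassigned") {
  if (is.character(hap)) hap <- parse_motif(hap)
  stopifnot(inherits(hap, "hvr_haplotype"))
  if (!is.data.frame(motif_table) || nrow(motif_table) == 0) {
    abort("`motif_table` must be a non-empty motif definition table.")
  }
  if (!"variants" %in% names(motif_table)) {
    motif_table$variants <- lapply(motif_table$motif,
                                   function(m) parse_motif(m)$variants)
  }
  v <- hap$variants
  v <- v[!v$ambiguous, ]
  carried <- paste0(v$position, v$base)
  for (i in seq_len(nrow(motif_table))) {
    def <- motif_table$variants[[i]]
    if (all(paste0(def$position, def$base) %in% carried)) {
      return(motif_table$hg[[i]])
    }
  }
  fallback
}

#' Assign haplogroups to every row of a haplotype table
#'
#' Tidy wrapper around [assign_haplogroup()]: parses the `motif` column and
#' adds (or overwrites) an `hg` column.
#'
#' @param data a data frame with a `motif` column.
#' @param motif_table,fallback passed to [assign_haplogroup()].
#' @param column name of the output column.
#' @return `data` with the haplogroup column added, as a tibble.
#' @export
add_haplogroups <- function(data, motif_table = load_hg_motifs(),
                            fallback = "unassigned", column = "hg") {
  stopifnot(is.data.frame(data), "motif" %in% names(data))
  data <- tibble::as_tibble(data)
  data[[column]] <- vapply(
    data$motif, assign_haplogroup, character(1),
    motif_table = motif_table, fallback = fallback, USE.NAMES = FALSE
  )
  data
}

#' Check HVR-I versus coding-region haplogroup consistency
#'
#' An HVR-I haplogroup call is consistent with a coding-region SNP call when
#' its coding-level class (via the correspondence table) equals the coding
#' call, e.g. `U2e` vs `U`, or `Z1a` vs `M`.
#'
#' @param hg_hvr,hg_coding character vectors of equal length (recycled if one
#'   is scalar).
#' @param mapping correspondence table as from [load_hg_coding_map()].
#' @return a logical vector.
#' @examples
#' check_hg_consistency("U2e", "U")   # TRUE
#' check_hg_consistency("C1", "U")    # FALSE
#' @export
check_hg_consistency <- function(hg_hvr, hg_coding,
                                 mapping = load_hg_coding_map()) {
  idx <- match(hg_hvr, mapping$hg_hvr)
  if (anyNA(idx)) {
    abort(sprintf("haplogroup label(s) absent from mapping: %s",
                  paste(unique(hg_hvr[is.na(idx)]), collapse = ", ")))
  }
  mapping$hg_coding[idx] == hg_coding
}
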