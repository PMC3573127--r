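#' Parse an HVR-I motif string into a haplotype
#'
#' Motifs list variant positions relative to the rCRS with 16000 subtracted,
#' e.g. `"129c-189C-362C"`. Upper-case letters denote transitions, lower-case
#' letters transversions. Parenthesised tokens with an IUPAC ambiguity code,
#' e.g. `"(390R)"`, mark sites that could not be resolved; they are kept on the
#' haplotype but excluded from all comparisons. The empty string is the
#' reference-identical haplotype.
#'
#' @param motif a single motif string (possibly `""`).
#' @param offset coordinate offset added to each token position (default
#'   16000, matching the shorthand).
#' @param window length-2 vector of 1-based rCRS coordinates bounding the
#'   sequenced window (closed interval).
#' @return an object of class `hvr_haplotype`: a list with `variants`
#'   (a tibble with columns `position`, `base`, `kind`, `ambiguous`) and
#'   `window`.
#' @examples
#' parse_motif("129c-189C-362C")
#' parse_motif("")
#' @export
parse_motif <- function(motif, offset = 16000L,
                        window = c(HVR1_START, HVR1_END)) {
  if (length(motif) != 1 || is.na(motif)) {
    abort("`motif` must be a single non-missing string.")
  }
  motif <- trimws(motif)
  if (motif == "") {
    return(new_hvr_haplotype(empty_variants(), window))
  }
  tokens <- strsplit(motif, "-", fixed = TRUE)[[1]]
  rows <- lapply(tokens, parse_motif_token, offset = offset, window = window)
  variants <- dplyr::bind_rows(rows)
  dup <- duplicated(variants$position)
  if (any(dup)) {
    abort(sprintf("duplicate position in motif: token '%s'",
                  tokens[dup][[1]]))
  }
  new_hvr_haplotype(variants, window)
}

# letters with an unambiguous complement-class reading
IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

parse_motif_token <- function(token, offset, window) {
  raw <- token
  ambiguous <- grepl("^\\(.+\\)$", token)
  if (ambiguous) token <- sub("^\\((.+)\\)$", "\\1", token)
  if (!grepl("^[0-9]{1,5}[A-Za-z]$", token)) {
    abort(sprintf("malformed motif token: '%s'", raw))
  }
  pos <- as.integer(sub("[A-Za-z]$", "", token)) + as.integer(offset)
  letter <- sub("^[0-9]+", "", token)
  base <- toupper(letter)
  if (base %in% IUPAC_AMBIGUITY) {
    ambiguous <- TRUE
  } else if (!base %in% c("A", "C", "G", "T")) {
    abort(sprintf("malformed motif token: '%s' (unknown base)", raw))
  }
  if (pos < window[1] || pos > window[2]) {
    abort(sprintf(
      "position %d from token '%s' outside sequenced window [%d, %d]",
      pos, raw, window[1], window[2]))
  }
  tibble::tibble(
    position = pos,
    base = base,
    kind = if (ambiguous) {
      NA_character_
    } else if (letter == base) "transition" else "transversion",
    ambiguous = ambiguous
  )
}

empty_variants <- function() {
  tibble::tibble(position = integer(), base = character(),
                 kind = character(), ambiguous = logical())
}

new_hvr_haplotype <- function(variants, window) {
  window <- as.integer(window)
  if (length(window) != 2 || any(is.na(window)) || window[1] > window[2]) {
    abort("`window` must be two ordered rCRS coordinates.")
  }
  structure(list(variants = variants, window = window),
            class = "hvr_haplotype")
}

#' @export
print.hvr_haplotype <- function(x, ...) {
  cat(sprintf("<hvr_haplotype> window %d-%d: %s\n", x$window[1], x$window[2],
              if (nrow(x$variants)) format_motif(x) else "(reference)"))
  invisible(x)
}

#' Format a haplotype back into motif shorthand
#'
#' Inverse of [parse_motif()]: reproduces the printed string exactly
#' (letter case encodes transition/transversion; ambiguous sites are
#' parenthesised).
#'
#' @param hap an `hvr_haplotype`.
#' @param offset coordinate offset subtracted from positions.
#' @return a single string (empty for the reference-identical haplotype).
#' @export
format_motif <- function(hap, offset = 16000L) {
  stopifnot(inherits(hap, "hvr_haplotype"))
  v <- hap$variants
  if (!nrow(v)) return("")
  letter <- ifelse(!v$ambiguous & v$kind == "transversion",
                   tolower(v$base), v$base)
  tok <- sprintf("%03d%s", v$position - as.integer(offset), letter)
  tok <- ifelse(v$ambiguous, paste0("(", tok, ")"), tok)
  paste(tok, collapse = "-")
}

#' Canonical comparison key of a haplotype
#'
#' The key is the sorted list of resolved (unambiguous) variants restricted to
#' `window`; two haplotypes are treated as identical when their keys over the
#' intersection of their sequenced windows agree. Ambiguous sites never enter
#' a key.
#'
#' @param hap an `hvr_haplotype`, or a character motif string (parsed first).
#' @param window optional length-2 restriction window (defaults to the
#'   haplotype's own window).
#' @return a single string, `""` when no resolved variant falls in the window.
#' @export
hvr_key <- function(hap, window = NULL) {
  if (is.character(hap)) hap <- parse_motif(hap)
  stopifnot(inherits(hap, "hvr_haplotype"))
  window <- window %||% hap$window
  v <- hap$variants
  v <- v[!v$ambiguous & v$position >= window[1] & v$position <= window[2], ]
  if (!nrow(v)) return("")
  ord <- order(v$position)
  paste(paste0(v$position[ord], v$base[ord]), collapse = "-")
}

#' Test two haplotypes for an exact match
#'
#' Matching compares resolved variant sets over the intersection of the two
#' sequenced windows; a haplotype observed over a narrower window can
#' therefore match another only where both were sequenced, and the absence of
#' a listed variant inside a shared window is informative.
#'
#' @param a,b `hvr_haplotype` objects (or motif strings).
#' @return `TRUE`/`FALSE`; `FALSE` when the windows do not overlap.
#' @export
hvr_match <- function(a, b) {
  if (is.character(a)) a <- parse_motif(a)
  if (is.character(b)) b <- parse_motif(b)
  lo <- max(a$window[1], b$window[1])
  hi <- min(a$window[2], b$window[2])
  if (lo > hi) return(FALSE)
  identical(hvr_key(a, c(lo, hi)), hvr_key(b, c(lo, hi)))
}

# vectorised keys for a motif column; the workhorse behind diversity, F_ST and
# sharing when all records share the standard window
motif_keys <- function(motif) {
  vapply(motif, function(m) hvr_key(parse_motif(m)), character(1),
         USE.NAMES = FALSE)
}
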