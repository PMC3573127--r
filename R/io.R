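HAPLOTYPE_SCHEMA <- c("sample_id", "population", "age_generations", "motif", "hg")

#' Read a haplotype table from CSV
#'
#' The documented schema is a UTF-8 CSV with header columns `sample_id`,
#' `population`, `age_generations`, `motif`, `hg`. Every motif is parsed and
#' validated against the sequenced window; schema violations and malformed
#' motifs are reported with their row number.
#'
#' @param path file path.
#' @return a tibble in the schema above plus a `key` comparison-key column.
#' @export
read_haplotype_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  missing <- setdiff(HAPLOTYPE_SCHEMA, names(tab))
  if (length(missing)) {
    abort(sprintf("haplotype table %s lacks required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  tab <- tibble::as_tibble(tab)[HAPLOTYPE_SCHEMA]
  tab$age_generations <- as.numeric(tab$age_generations)
  if (anyNA(tab$age_generations) | any(tab$age_generations < 0)) {
    bad <- which(is.na(tab$age_generations) | tab$age_generations < 0)[1]
    abort(sprintf("row %d: `age_generations` must be a non-negative number",
                  bad))
  }
  tab$motif[is.na(tab$motif)] <- ""
  keys <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    keys[i] <- tryCatch(hvr_key(parse_motif(tab$motif[i])), error = function(e) {
      abort(sprintf("row %d: %s", i, conditionMessage(e)))
    })
  }
  tab$key <- keys
  tab
}

#' Write a haplotype table to CSV
#'
#' @param data a data frame holding at least the schema columns of
#'   [read_haplotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(data, path) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(HAPLOTYPE_SCHEMA, names(data))
  if (length(missing)) {
    abort(sprintf("data lacks required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(data[HAPLOTYPE_SCHEMA], path)
  invisible(path)
}

#' Write haplotypes as full window sequences in FASTA
#'
#' Reconstructs each 354-nt window sequence by applying the motif's variants
#' to the packaged reference window ([rcrs_window()]); ambiguous sites are
#' written as their IUPAC code.
#'
#' @param data a data frame with `sample_id` and `motif` columns.
#' @param path output FASTA path.
#' @param reference named base vector to mutate, defaulting to
#'   [rcrs_window()].
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, reference = rcrs_window()) {
  stopifnot(is.data.frame(data),
            all(c("sample_id", "motif") %in% names(data)))
  lines <- character(0)
  for (i in seq_len(nrow(data))) {
    hap <- parse_motif(data$motif[i])
    bases <- reference
    v <- hap$variants
    if (nrow(v)) bases[as.character(v$position)] <- v$base
    seq <- paste(bases, collapse = "")
    starts <- seq(1, nchar(seq), 60)
    lines <- c(lines, paste0(">", data$sample_id[i]),
               substring(seq, starts, pmin(starts + 59, nchar(seq))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read window sequences from FASTA back into motif form
#'
#' Inverse of [write_fasta()] for resolved variants: sites differing from the
#' reference become transition/transversion variants (case inferred by
#' purine/pyrimidine class change), IUPAC codes become ambiguous sites.
#'
#' @param path FASTA path.
#' @param reference named base vector the sequences were built from.
#' @return a tibble with `sample_id`, `motif`, `key`.
#' @export
read_fasta_haplotypes <- function(path, reference = rcrs_window()) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) abort(sprintf("no FASTA records in %s", path))
  ends <- c(hdr[-1] - 1, length(lines))
  out <- vector("list", length(hdr))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  pos_all <- as.integer(names(reference))
  for (k in seq_along(hdr)) {
    id <- sub("^>\\s*", "", lines[hdr[k]])
    id <- sub("\\s.*$", "", id)
    seq <- toupper(paste(lines[(hdr[k] + 1):ends[k]], collapse = ""))
    bases <- strsplit(seq, "")[[1]]
    if (length(bases) != length(reference)) {
      abort(sprintf("record '%s': expected %d bases, found %d",
                    id, length(reference), length(bases)))
    }
    diff <- which(bases != reference)
    tok <- character(length(diff))
    for (j in seq_along(diff)) {
      i <- diff[j]
      b <- bases[i]
      if (b %in% IUPAC_AMBIGUITY) {
        tok[j] <- sprintf("(%03d%s)", pos_all[i] - 16000L, b)
      } else if (b %in% c("A", "C", "G", "T")) {
        letter <- if (purine[[b]] == purine[[reference[[i]]]]) b else tolower(b)
        tok[j] <- sprintf("%03d%s", pos_all[i] - 16000L, letter)
      } else {
        abort(sprintf("record '%s': invalid base '%s'", id, b))
      }
    }
    motif <- paste(tok, collapse = "-")
    out[[k]] <- tibble::tibble(sample_id = id, motif = motif,
                               key = hvr_key(parse_motif(motif)))
  }
  dplyr::bind_rows(out)
}
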