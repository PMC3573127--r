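#' Load the packaged ancient HVR-I genotypes
#'
#' Returns the 34 ancient mitochondrial genotypes from the three northwest
#' Russian sites (Yuzhnyy Oleni Ostrov `aUz`, Popovo `aPo`, Bol'shoy Oleni
#' Ostrov `aBOO`), transcribed verbatim from the published typing table.
#' `aUz` and `aPo` are pooled into the analysis population `aUzPo`.
#'
#' @param sites optional character vector of site labels (`"aUz"`, `"aPo"`,
#'   `"aBOO"`) to keep.
#' @return a tibble with columns `sample_id`, `site`, `population`,
#'   `age_generations`, `motif`, `hg_hvr`, `hg_coding`, plus `key`
#'   (the resolved-variant comparison key, see [hvr_key()]).
#' @examples
#' nrow(load_ancient_fixture())            # 34
#' nrow(load_ancient_fixture(c("aUz", "aPo")))  # 11
#' @export
load_ancient_fixture <- function(sites = NULL) {
  path <- system.file("extdata", "ancient_hvr1.csv", package = "mtabc",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", site = "c", population = "c",
    age_generations = "d", motif = "c", hg_hvr = "c", hg_coding = "c"
  ))
  tab$motif[is.na(tab$motif)] <- ""
  if (!is.null(sites)) {
    known <- unique(tab$site)
    bad <- setdiff(sites, known)
    if (length(bad)) {
      abort(sprintf("unknown site label(s): %s (known: %s)",
                    paste(bad, collapse = ", "),
                    paste(known, collapse = ", ")))
    }
    tab <- tab[tab$site %in% sites, ]
  }
  tab$key <- motif_keys(tab$motif)
  tab
}

#' Load the observed population statistics fixture
#'
#' Sample sizes, sampling ages in generations, haplotype diversities and
#' pairwise fixation indices for the seven populations entering the coalescent
#' simulation analyses (modern NEE, Saami, CE; ancient aHG, aUzPo, aBOO,
#' aPWC). These printed values are the observed summary statistics for ABC;
#' note that the printed ancient diversities are fixture inputs and are not
#' recomputed from the genotype table (see the methods vignette).
#'
#' @return a list with two tibbles: `populations` (`label`, `n`,
#'   `age_generations`, `age_min`, `age_max`, `haplotype_diversity`) and
#'   `fst` (`pop_a`, `pop_b`, `fst`; `NA` where no value was reported).
#' @export
load_observed_stats <- function() {
  pdir <- system.file("extdata", package = "mtabc", mustWork = TRUE)
  pops <- readr::read_csv(file.path(pdir, "observed_populations.csv"),
                          col_types = readr::cols(
                            label = "c", n = "i", age_generations = "d",
                            age_min = "d", age_max = "d",
                            haplotype_diversity = "d"
                          ))
  fst <- readr::read_csv(file.path(pdir, "observed_fst.csv"),
                         col_types = readr::cols(pop_a = "c", pop_b = "c",
                                                 fst = "d"))
  list(populations = pops, fst = fst)
}

#' Load the haplogroup motif definition table
#'
#' Maps haplogroup labels to their defining HVR-I variants (most-derived
#' first: assignment returns the first haplogroup whose defining variants are
#' all carried) and to the pooled 19-variable spectrum class. The table is an
#' editable artifact: pass your own table of the same shape to
#' [assign_haplogroup()] to change the nomenclature.
#'
#' @return a tibble with columns `hg`, `motif`, `class` and a list-column
#'   `variants` of parsed defining variants.
#' @export
load_hg_motifs <- function() {
  path <- system.file("extdata", "haplogroup_motifs.csv", package = "mtabc",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    hg = "c", motif = "c", class = "c"
  ))
  tab$motif[is.na(tab$motif)] <- ""
  tab$variants <- lapply(tab$motif, function(m) parse_motif(m)$variants)
  tab
}

#' Load the HVR-I to coding-region haplogroup correspondence
#'
#' @return a tibble with columns `hg_hvr`, `hg_coding`.
#' @export
load_hg_coding_map <- function() {
  path <- system.file("extdata", "hg_coding_map.csv", package = "mtabc",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(hg_hvr = "c", hg_coding = "c"))
}

#' The packaged reference window sequence
#'
#' A synthetic 354-nt stand-in for the rCRS HVR-I segment (np 16056-16409)
#' used as the root sequence for FASTA reconstruction and coalescent
#' simulation. It is *not* the true rCRS: every computation in the package
#' depends only on variant positions and base changes relative to this
#' window, never on its absolute base identities.
#'
#' @return a character vector of 354 single bases, named by rCRS coordinate.
#' @export
rcrs_window <- function() {
  path <- system.file("extdata", "rcrs_window_synthetic.fa",
                      package = "mtabc", mustWork = TRUE)
  lines <- readLines(path)
  seq <- paste(lines[!startsWith(lines, ">")], collapse = "")
  bases <- strsplit(seq, "")[[1]]
  stopifnot(length(bases) == HVR1_LENGTH)
  names(bases) <- as.character(seq.int(HVR1_START, HVR1_END))
  bases
}

#' Export a haplotype table as JSON
#'
#' Row-wise JSON export of any haplotype table (fixture or generated pool),
#' for interchange with non-R tooling.
#'
#' @param data a data frame of haplotype records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_json <- function(data, path) {
  stopifnot(is.data.frame(data))
  jsonlite::write_json(data, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
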