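test_that("motif parsing handles case, ambiguity codes and the empty motif", {
  h <- parse_motif("129c-189C-362C")
  expect_equal(h$variants$position, c(16129L, 16189L, 16362L))
  expect_equal(h$variants$base, c("C", "C", "C"))
  expect_equal(h$variants$kind, c("transversion", "transition", "transition"))
  expect_false(any(h$variants$ambiguous))

  empty <- parse_motif("")
  expect_s3_class(empty, "hvr_haplotype")
  expect_equal(nrow(empty$variants), 0)
  expect_identical(hvr_key(empty), "")

  amb <- parse_motif("093C-129A-134T-311C-356C-(390R)")
  expect_equal(sum(!amb$variants$ambiguous), 5)
  expect_true(amb$variants$ambiguous[amb$variants$position == 16390])
  # ambiguous sites never enter the comparison key
  expect_identical(hvr_key(amb),
                   hvr_key(parse_motif("093C-129A-134T-311C-356C")))
})

test_that("malformed or out-of-range motifs raise named errors", {
  expect_error(parse_motif("999X"), "999X")
  expect_error(parse_motif("129c-129A"), "duplicate")
  expect_error(parse_motif("001A"), "window")
  expect_error(parse_motif("189Q"), "189Q")
})

test_that("every fixture motif round-trips through parse/format verbatim", {
  fx <- load_ancient_fixture()
  rt <- vapply(fx$motif, function(m) format_motif(parse_motif(m)),
               character(1), USE.NAMES = FALSE)
  expect_identical(rt, fx$motif)
})

test_that("matching respects the intersection of sequenced windows", {
  full_with93 <- parse_motif("093C-356C")
  full_plain <- parse_motif("356C")
  # both windows cover 16093: the absence of 093C in one motif is
  # informative, so these are different haplotypes
  expect_false(hvr_match(full_plain, full_with93))
  # a haplotype observed over a window starting at 16100 says nothing about
  # 16093: over the shared window the two agree
  narrow <- parse_motif("356C", window = c(16100, 16409))
  expect_true(hvr_match(narrow, full_with93))
  expect_true(hvr_match(narrow, full_plain))
  expect_true(hvr_match(full_plain, full_plain))
})

test_that("the ancient fixture loads with site filtering and counts", {
  expect_equal(nrow(load_ancient_fixture()), 34)
  expect_equal(nrow(load_ancient_fixture(c("aUz", "aPo"))), 11)
  expect_equal(nrow(load_ancient_fixture("aBOO")), 23)
  expect_error(load_ancient_fixture("aXYZ"), "unknown site")
})

test_that("haplotype tables round-trip through CSV with row-level errors", {
  fx <- load_ancient_fixture(c("aUz", "aPo"))
  tab <- tibble::tibble(sample_id = fx$sample_id, population = fx$population,
                        age_generations = fx$age_generations,
                        motif = fx$motif, hg = fx$hg_hvr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_haplotype_table(tab, path)
  back <- read_haplotype_table(path)
  expect_equal(as.data.frame(back[names(tab)]), as.data.frame(tab))

  bad <- tab
  bad$motif[3] <- "999X"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_haplotype_table(bad, path2)
  expect_error(read_haplotype_table(path2), "row 3")
})

test_that("FASTA reconstruction differs from the reference exactly at
           variant positions", {
  ref <- rcrs_window()
  tab <- tibble::tibble(sample_id = c("empty", "var"),
                        motif = c("", "223T-298C-327T"))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tab, path)
  lines <- readLines(path)
  seqs <- tapply(lines[!startsWith(lines, ">")],
                 cumsum(startsWith(lines, ">"))[!startsWith(lines, ">")],
                 paste, collapse = "")
  expect_identical(seqs[[1]], paste(ref, collapse = ""))
  bases2 <- strsplit(seqs[[2]], "")[[1]]
  diff <- which(bases2 != ref)
  expect_setequal(16055L + diff, c(16223L, 16298L, 16327L))
  # read back: keys identical for resolved variants
  back <- read_fasta_haplotypes(path)
  expect_identical(back$key, c("", hvr_key(parse_motif("223T-298C-327T"))))
})

test_that("haplogroup assignment reproduces the fixture and is
           table-driven", {
  fx <- load_ancient_fixture()
  hg <- vapply(fx$motif, assign_haplogroup, character(1), USE.NAMES = FALSE)
  expect_identical(hg, fx$hg_hvr)
  expect_identical(assign_haplogroup("223T-298C-327T"), "C*")
  expect_identical(assign_haplogroup("129A-185T-223T-224C-260T-298C"), "Z1a")
  # the reference-identical haplotype falls through to the table root
  expect_identical(assign_haplogroup(""), "H")
  expect_error(assign_haplogroup("223T", motif_table = data.frame()),
               "non-empty")
  small <- tibble::tibble(hg = "X", motif = "189C-223T-278T")
  expect_identical(assign_haplogroup("", motif_table = small,
                                     fallback = "none"), "none")
})

test_that("HVR-I / coding-region consistency checks the fixture and flags
           contradictions", {
  fx <- load_ancient_fixture()
  expect_true(all(check_hg_consistency(fx$hg_hvr, fx$hg_coding)))
  expect_true(check_hg_consistency("U2e", "U"))
  expect_true(check_hg_consistency("Z1a", "M"))
  expect_false(check_hg_consistency("C1", "U"))
  expect_error(check_hg_consistency("QQ9", "U"), "absent")
})

test_that("fixture JSON export writes one record per individual", {
  fx <- load_ancient_fixture("aBOO")
  path <- withr::local_tempfile(fileext = ".json")
  write_fixture_json(fx, path)
  back <- jsonlite::read_json(path)
  expect_length(back, 23)
  expect_identical(back[[1]]$sample_id, fx$sample_id[1])
})
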