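# A vector-genome-sized sanity case: a 4,001 nt insert between two 145 nt
# ITRs assembles to 4,291 nt.
test_that("assembly length equals the sum of segment lengths", {
  set.seed(21)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  cds <- paste(c("ATG", sample(sense, 1331, replace = TRUE), "TAA"),
               collapse = "")
  expect_identical(nchar(cds), 3999L)
  x <- construct("aav_insert",
                 list(segment("itr5", "itr", random_seq(145)),
                      segment("cds", "orf", cds),
                      segment("pad", "other", "CC"),
                      segment("itr3", "itr", random_seq(145))),
                 intended_stop = 145L + 3996L)
  asm <- assemble(x)
  expect_identical(nchar(asm$seq), 4291L)
  expect_identical(nchar(asm$seq),
                   sum(vapply(x$segments, function(s) nchar(s$seq), 0L)))
})

test_that("coordinate map tiles the assembly and round-trips positions", {
  x <- construct("tiles",
                 list(segment("a", "promoter", random_seq(10)),
                      segment("b", "orf", "ATGAAATGA"),
                      segment("c", "utr", random_seq(30))),
                 intended_stop = 16L)
  expect_identical(x$map$start, c(0L, 10L, 19L))
  expect_identical(x$map$end, c(10L, 19L, 49L))
  pos <- 0:48
  loc <- locate(x, pos)
  back <- x$map$start[match(loc$label, x$map$label)] + loc$offset
  expect_identical(back, pos)
  lens <- table(loc$label)[x$map$label]
  expect_identical(as.integer(lens), c(10L, 9L, 30L))
  expect_error(locate(x, 49), "out of bounds")
})

test_that("construct invariants are enforced", {
  orf <- "ATGAAATGA"
  expect_error(segment("i", "intron", "GAAAAG", canonical = TRUE),
               "start GT and end AG")
  expect_error(segment("x", "widget", "ACGT"), "arg")
  # frame violation
  expect_error(construct("f", list(segment("o", "orf", orf)),
                         intended_stop = 5L), "divisible by 3")
  # intended_stop not a stop codon
  expect_error(construct("f", list(segment("o", "orf", "ATGAAAAAATGA")),
                         intended_stop = 3L), "stop codon")
  # annotated donor must sit on GT
  expect_error(construct("f", list(segment("o", "orf", orf)),
                         intended_stop = 6L, donors = 0L), "GT dinucleotide")
  # duplicate labels
  expect_error(construct("f", list(segment("o", "orf", orf),
                                   segment("o", "utr", "AAAA")),
                         intended_stop = 6L), "duplicate")
})

test_that("canonical introns derive one donor and one acceptor each", {
  x <- construct("ivs",
                 list(segment("o", "orf", "ATGCCCTAA"),
                      segment("u", "utr", "CCCTTC"),
                      segment("i1", "intron", "GTAAGCCCCAG", canonical = TRUE),
                      segment("e2", "exon", "TTTCCC")),
                 intended_stop = 6L)
  expect_identical(x$annotated_donors, 15L)
  expect_identical(x$annotated_acceptors, 26L)

  y <- construct("no_ivs", list(segment("o", "orf", "ATGCCCTAA")),
                 intended_stop = 6L)
  expect_length(y$annotated_acceptors, 0L)
})

test_that("construct spec TSV round-trips field for field", {
  x <- make_model_construct()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_construct_spec(x, path)
  y <- read_construct_spec(path)
  expect_identical(y$name, x$name)
  expect_identical(y$seq, x$seq)
  expect_identical(y$map, x$map)
  expect_identical(y$orf_start, x$orf_start)
  expect_identical(y$intended_stop, x$intended_stop)
  expect_identical(y$annotated_donors, x$annotated_donors)
  expect_identical(y$annotated_acceptors, x$annotated_acceptors)

  # explicit donor/acceptor flags survive the round trip too
  z <- construct("flagged",
                 list(segment("o", "orf", "ATGCCCTAA"),
                      segment("u", "utr", "CCGTAAGCCCCAGTT")),
                 intended_stop = 6L, donors = 11L, acceptors = 22L)
  write_construct_spec(z, path)
  z2 <- read_construct_spec(path)
  expect_identical(z2$annotated_donors, 11L)
  expect_identical(z2$annotated_acceptors, 22L)
})

test_that("construct spec reader rejects bad specs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\trole\tsequence\tflags",
               "o\twidget\tATGTAA\tstop=3"), path)
  expect_error(read_construct_spec(path), "unknown role")
  writeLines(c("label\trole\tsequence\tflags",
               "o\torf\tATGTAA\t"), path)
  expect_error(read_construct_spec(path), "stop=K")
  writeLines(c("label\trole\tsequence\tflags",
               "o\torf\tATGTAA\tstop=3",
               "i\tintron\tGAAAAG\tcanonical"), path)
  expect_error(read_construct_spec(path), "start GT and end AG")
})

test_that("BED export mirrors the coordinate map (0-based half-open)", {
  x <- make_model_construct()
  bed <- construct_bed(x)
  expect_identical(bed$chromStart, x$map$start)
  expect_identical(bed$chromEnd, x$map$end)
  expect_identical(bed$name, x$map$label)
})
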