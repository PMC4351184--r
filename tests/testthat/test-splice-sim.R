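test_that("apply_splice removes half-open intervals and records provenance", {
  set.seed(41)
  seq100 <- random_seq(100)
  iso0 <- apply_splice(seq100, NULL)
  expect_identical(iso0$mature, seq100)
  expect_identical(iso0$provenance, data.frame(start = 0L, end = 100L))

  # remove [40, 70) from a 100-mer
  s <- strrep("C", 100)
  substr(s, 41, 42) <- "GT"
  substr(s, 69, 70) <- "AG"
  iso <- apply_splice(s, splice_events(40L, 70L))
  expect_identical(nchar(iso$mature), 70L)
  expect_identical(iso$provenance, data.frame(start = c(0L, 70L),
                                              end = c(40L, 100L)))
})

test_that("splice events must be non-overlapping GT...AG intervals", {
  s <- strrep("C", 60)
  substr(s, 11, 12) <- "GT"; substr(s, 29, 30) <- "AG"
  substr(s, 21, 22) <- "GT"; substr(s, 49, 50) <- "AG"
  expect_error(apply_splice(s, splice_events(c(10L, 20L), c(30L, 50L))),
               "overlapping")
  expect_error(splice_events(30L, 10L), "precede")
  # non-GT...AG removal: error normally, warning for a bare-GT (CORE) donor
  expect_error(apply_splice(s, splice_events(12L, 30L)), "not GT")
  expect_warning(apply_splice(s, splice_events(12L, 30L, tier = "CORE")),
                 "not GT")
})

test_that("length conservation and provenance concatenation hold on random instances", {
  set.seed(42)
  for (i in 1:20) {
    inst <- planted_instance(sample(0:4, 1), sample(0:3, 1))
    isoforms <- enumerate_isoforms(inst$seq, donors = inst$donors,
                                   acceptors = inst$acceptors)
    for (iso in isoforms) {
      removed <- sum(iso$events$acceptor - iso$events$donor)
      expect_identical(nchar(iso$mature) + removed, nchar(inst$seq))
      pieces <- substring(inst$seq, iso$provenance$start + 1L,
                          iso$provenance$end)
      expect_identical(paste(pieces, collapse = ""), iso$mature)
    }
  }
})

test_that("enumeration counts simple instances correctly", {
  # 1 donor before 1 acceptor: unspliced + spliced
  inst <- list(seq = strrep("C", 60))
  s <- inst$seq
  substr(s, 11, 16) <- "GGTAAG"; substr(s, 41, 42) <- "AG"
  expect_length(enumerate_isoforms(s, donors = 11L, acceptors = 42L), 2L)
  # 2 donors before 1 acceptor, max_events = 1: 3 isoforms
  substr(s, 21, 26) <- "GGTAAG"
  expect_length(enumerate_isoforms(s, donors = c(11L, 21L), acceptors = 42L,
                                   max_events = 1L), 3L)
})

test_that("enumeration equals brute-force subset enumeration (<=4 donors, <=3 acceptors)", {
  set.seed(43)
  for (nd in 0:4) {
    for (na in 0:3) {
      inst <- planted_instance(nd, na)
      isoforms <- enumerate_isoforms(inst$seq, donors = inst$donors,
                                     acceptors = inst$acceptors,
                                     max_events = 3L)
      got <- sort(vapply(isoforms, `[[`, "", "mature"))
      want <- oracle_enumerate_matures(inst$seq, inst$donors, inst$acceptors,
                                       max_events = 3L)
      expect_identical(got, want)
      # deterministic order: event count, then leftmost removed start
      nev <- vapply(isoforms, function(i) nrow(i$events), 0L)
      expect_true(!is.unsorted(nev))
    }
  }
})

test_that("enumeration caps explode loudly, never silently", {
  inst <- planted_instance(4, 3, len = 600)
  expect_error(enumerate_isoforms(inst$seq, donors = inst$donors,
                                  acceptors = inst$acceptors, cap = 5L),
               "cap")
})

test_that("the model fixture enumerates both observed mis-splicing products", {
  x <- make_model_construct()
  lm <- attr(x, "landmarks")
  isoforms <- enumerate_isoforms(x)
  keys <- vapply(isoforms, function(iso) {
    paste(iso$events$donor, iso$events$acceptor, sep = "-", collapse = "_")
  }, "")
  acc <- x$annotated_acceptors
  # tag-excision product: junction donor -> intron-1 acceptor, plus intron 2
  tag_excised <- paste0(lm$junction_cut, "-", acc[1], "_",
                        lm$intron2_cut, "-", acc[2])
  # linker-splice product: linker donor -> intron-1 acceptor, plus intron 2
  linker_spliced <- paste0(lm$linker_cut, "-", acc[1], "_",
                           lm$intron2_cut, "-", acc[2])
  expect_true(tag_excised %in% keys)
  expect_true(linker_spliced %in% keys)

  # the tag-excision mature mRNA joins the ORF's terminal CTT (plus the
  # retained junction G) directly onto exon 2
  iso <- isoforms[[which(keys == tag_excised)]]
  exon2 <- x$segments[[which(x$map$label == "exon2")]]$seq
  exon3 <- x$segments[[which(x$map$label == "exon3")]]$seq
  expect_true(grepl(paste0("CTTG", substr(exon2, 1, 20)), iso$mature,
                    fixed = TRUE))
  expect_true(grepl(paste0(exon2, exon3), iso$mature, fixed = TRUE))
})

test_that("consequence calling reproduces the tag-excision arithmetic", {
  x <- make_model_construct()
  lm <- attr(x, "landmarks")
  v5 <- tag_spec("V5_methods")
  acc <- x$annotated_acceptors

  mis <- apply_splice(x, splice_events(c(lm$junction_cut, lm$intron2_cut),
                                       acc))
  cc <- call_consequence(mis, x, v5)
  expect_identical(cc$klass, "TAG_LOST_EXTENDED")
  expect_identical(cc$native_retained, 424L)
  expect_identical(cc$appended_missense, 55L)
  expect_identical(cc$total_length, 479L)
  expect_false(cc$tag_retained)

  intended <- apply_splice(x, splice_events(x$annotated_donors, acc))
  ci <- call_consequence(intended, x, v5)
  expect_identical(ci$klass, "INTENDED")
  expect_identical(ci$appended_missense, 0L)
  expect_true(ci$tag_retained)
  expect_identical(ci$total_length, 424L + 14L)
})

test_that("splices downstream of the stop are UTR_ONLY; losing the ORF start is distinct", {
  x <- make_model_construct()
  lm <- attr(x, "landmarks")
  v5 <- tag_spec("V5_methods")
  acc <- x$annotated_acceptors

  utr <- apply_splice(x, splice_events(c(lm$linker_cut, lm$intron2_cut), acc))
  cu <- call_consequence(utr, x, v5)
  expect_identical(cu$klass, "UTR_ONLY")
  expect_true(cu$tag_retained)
  expect_identical(cu$protein,
                   call_consequence(apply_splice(x, NULL), x, v5)$protein)

  # an artificial removal spanning the ORF start (CORE-tier events only warn
  # about non-GT...AG boundaries, so the geometry can be forced)
  ev <- splice_events(0L, acc[1], tier = "CORE")
  iso <- suppressWarnings(apply_splice(x$seq, ev))
  cc <- call_consequence(iso, x, v5)
  expect_identical(cc$klass, "ORF_START_LOST")
  expect_identical(cc$total_length, 0L)
})
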