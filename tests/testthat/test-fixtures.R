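test_that("fixture generation is deterministic per seed", {
  a <- make_model_construct(model_params(seed = 9))
  b <- make_model_construct(model_params(seed = 9))
  expect_identical(a$seq, b$seq)
  expect_identical(attr(a, "landmarks"), attr(b, "landmarks"))
  c <- make_model_construct(model_params(seed = 10))
  expect_false(identical(a$seq, c$seq))
})

test_that("the model fixture contains exactly the planted signal sites", {
  x <- make_model_construct()
  lm <- attr(x, "landmarks")
  sites <- scan_donors(x$seq)
  expect_identical(sites$cut, sort(c(lm$junction_cut, lm$linker_cut,
                                     lm$intron1_cut, lm$intron2_cut)))
  # the junction forms the TTGGTAAG site
  expect_identical(sites$context8[sites$cut == lm$junction_cut], "TTGGTAAG")
  # exactly one diagnostic restriction site, in the excisable linker
  bsa <- find_sites(x$seq, restriction_site("BsaAI_iupac"))
  expect_identical(bsa, lm$bsaai_site)
  expect_identical(locate(x, bsa)$label, "linker")
  # linker donor is 47 nt upstream of the exon-1 3' end
  exon1_end <- x$map$end[x$map$label == "exon1_utr"]
  expect_identical(lm$linker_cut, exon1_end - 47L)
  # annotated introns
  expect_identical(x$annotated_donors, c(lm$intron1_cut, lm$intron2_cut))
  expect_length(x$annotated_acceptors, 2L)
})

test_that("the appended-residue arithmetic follows the planted stop offset", {
  v5 <- tag_spec("V5_methods")
  for (off in c(168L, 120L)) {
    x <- make_model_construct(model_params(exon3_stop_offset = off, seed = 2))
    lm <- attr(x, "landmarks")
    mis <- apply_splice(x, splice_events(c(lm$junction_cut, lm$intron2_cut),
                                         x$annotated_acceptors))
    cc <- call_consequence(mis, x, v5)
    expect_identical(cc$klass, "TAG_LOST_EXTENDED")
    expect_identical(cc$appended_missense, off %/% 3L - 1L)
    expect_identical(cc$total_length, 424L + off %/% 3L - 1L)
  }
})

test_that("the repaired fixture has no junction donor and splices only in the UTR", {
  r <- make_repaired_construct()
  lm <- attr(r, "landmarks")
  x <- make_model_construct()
  # GGT -> GGG repair: same junction position now classifies as no donor
  jcut <- attr(x, "landmarks")$junction_cut
  expect_identical(classify_window(substr(r$seq, jcut - 2, jcut + 5)),
                   NA_character_)
  expect_true(is.na(lm$junction_cut))
  sites <- scan_donors(r$seq)
  expect_identical(sites$cut, c(lm$linker_cut, lm$intron1_cut, lm$intron2_cut))
  # fusion protein unchanged by the wobble repair
  v5 <- tag_spec("V5_methods")
  p_model <- translate_cds(x$seq, x$orf_start)$protein
  p_rep <- translate_cds(r$seq, r$orf_start)$protein
  expect_identical(p_rep, p_model)
  # the preferred linker-donor isoform keeps the tag: UTR_ONLY
  iso <- apply_splice(r, splice_events(c(lm$linker_cut, lm$intron2_cut),
                                       r$annotated_acceptors))
  cc <- call_consequence(iso, r, v5)
  expect_identical(cc$klass, "UTR_ONLY")
  expect_true(cc$tag_retained)
})

test_that("dropping the linker donor leaves only the annotated splice sites", {
  r <- make_repaired_construct(linker_donor = FALSE)
  sites <- scan_donors(r$seq)
  expect_identical(sites$cut, r$annotated_donors)
  isoforms <- enumerate_isoforms(r)
  klasses <- vapply(isoforms, function(i) {
    call_consequence(i, r, tag_spec("V5_methods"))$klass
  }, "")
  expect_identical(sort(unique(klasses)), c("INTENDED", "UTR_ONLY"))
  # the fully annotated splice is the INTENDED one
  nev <- vapply(isoforms, function(i) nrow(i$events), 0L)
  expect_identical(klasses[nev == 2L], "INTENDED")
})

test_that("random CDS sets honour structure, distribution, and determinism", {
  # point masses reproduce the toy screen set's terminal dinucleotides
  pm <- setNames(rep(0, 16), as.vector(outer(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T"), paste0)))
  pm[c("CA", "TT", "GG", "AC")] <- 0.25
  cds <- make_random_cds_set(400, pm, seed = 5)
  stripped <- vapply(cds, strip_stop, "", USE.NAMES = FALSE)
  dn <- substring(stripped, nchar(stripped) - 1L, nchar(stripped))
  expect_identical(sort(unique(dn)), c("AC", "CA", "GG", "TT"))

  # structure: ATG start, stop end, no internal in-frame stop
  expect_true(all(startsWith(cds, "ATG")))
  expect_true(all(substring(cds, nchar(cds) - 2L) %in% STOP_CODONS))
  expect_true(all(nchar(cds) %% 3L == 0L))

  # byte-identical FASTA for a fixed seed
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(make_random_cds_set(100, seed = 8), f1)
  write_fasta(make_random_cds_set(100, seed = 8), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(make_random_cds_set(5, length_range = c(20, 8)), "infeasible")
  expect_error(make_random_cds_set(5, setNames(rep(0.5, 2), c("AA", "XX"))),
               "dinucleotides")
})

test_that("fixture parameter validation catches impossible geometries", {
  expect_error(model_params(exon3_stop_offset = 167L), "multiple of 3")
  expect_error(model_params(exon3_stop_offset = 600L), "within exon 3")
  expect_error(model_params(linker_len = 10L), "does not fit")
  expect_error(model_params(tag = tag_spec("ha", "TACCCATACGATGTTCCAGATTACGCT",
                                           "TAA")), "starting with G")
})
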