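# Deterministic synthetic fixtures.
#
# The model construct reproduces the geometry of a tagged ORF sitting
# upstream of a natural two-intron 3' region: promoter, a 424-codon ORF
# ending in a leucine CTT codon, an in-frame V5 tag plus stop, a 40-nt
# linker (N40), an 11-nt exon-1 UTR, intron 1, exon 2, intron 2, and exon 3
# carrying the first in-frame stop of the mis-spliced reading frame 168 nt
# downstream of the ORF-tag junction plus a non-canonical ATTAAA polyA
# signal. Background sequence is uniform over ACGT and rejection-sampled so
# the construct contains exactly the planted donor sites (tier >= MINIMAL)
# and exactly one restriction diagnostic site.

SENSE_CODONS <- local({
  cods <- NULL
  function() {
    if (is.null(cods)) {
      gc <- Biostrings::GENETIC_CODE
      cods <<- names(gc)[!names(gc) %in% STOP_CODONS]
    }
    cods
  }
})

clean_random_dna <- function(n, forbid = c("GTAAG", "[CT]ACGT[AG]"),
                             max_tries = 1000L) {
  if (n <= 0L) return("")
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    if (!any(vapply(forbid, grepl, NA, x = s))) return(s)
  }
  stop("rejection sampling failed for a clean random segment of length ", n)
}

clean_random_codons <- function(k, first = NULL, last = NULL,
                                max_tries = 1000L) {
  sense <- SENSE_CODONS()
  k_rand <- k - length(first) - length(last)
  for (i in seq_len(max_tries)) {
    s <- paste(c(first, sample(sense, k_rand, replace = TRUE), last),
               collapse = "")
    if (!grepl("GTAAG", s) && !grepl("[CT]ACGT[AG]", s)) return(s)
  }
  stop("rejection sampling failed for a clean ", k, "-codon ORF")
}

#' Parameters for the model construct fixtures
#'
#' Defaults reproduce the geometry underlying the tag-excision mis-splicing
#' arithmetic: a 424-codon native ORF whose final codon is the leucine CTT,
#' the V5 tag, a 40-nt linker, an 11-nt exon-1 UTR, two canonical introns,
#' and a first in-frame stop on the mis-spliced reading frame exactly 168 nt
#' downstream of the ORF-tag junction (55 appended residues, 479 aa total).
#' A second cryptic donor is planted in the linker 47 nt before the 3' end
#' of exon 1, and a single TACGTG restriction diagnostic site is planted in
#' the excisable linker.
#'
#' @param native_orf_codons native ORF length in codons (stop excluded);
#'   the final codon is fixed to CTT, the first to ATG.
#' @param tag a [tag_spec()] fused in frame to the ORF.
#' @param linker_len,exon1_utr_len,intron1_len,intron2_len,exon2_len,exon3_len
#'   segment lengths (nt).
#' @param exon3_stop_offset nt from the ORF-tag junction to the end of the
#'   first in-frame stop codon along the mis-spliced mature mRNA (must be a
#'   multiple of 3; the stop codon's 3 nt are included, so the appended
#'   missense peptide has `exon3_stop_offset/3 - 1` residues).
#' @param promoter_len promoter stuffer length (nt).
#' @param seed RNG seed for the background sequence.
#' @return a `model_params` list.
#' @export
model_params <- function(native_orf_codons = 424L,
                         tag = tag_spec("V5_methods"),
                         linker_len = 40L, exon1_utr_len = 11L,
                         intron1_len = 200L, intron2_len = 150L,
                         exon2_len = 100L, exon3_len = 120L,
                         exon3_stop_offset = 168L,
                         promoter_len = 60L, seed = 1L) {
  stopifnot(inherits(tag, "tag_spec"))
  p <- list(native_orf_codons = as.integer(native_orf_codons), tag = tag,
            linker_len = as.integer(linker_len),
            exon1_utr_len = as.integer(exon1_utr_len),
            intron1_len = as.integer(intron1_len),
            intron2_len = as.integer(intron2_len),
            exon2_len = as.integer(exon2_len),
            exon3_len = as.integer(exon3_len),
            exon3_stop_offset = as.integer(exon3_stop_offset),
            promoter_len = as.integer(promoter_len), seed = as.integer(seed))
  if (p$exon3_stop_offset %% 3L != 0L) {
    stop("exon3_stop_offset must be a multiple of 3 (junction frame)")
  }
  if (p$native_orf_codons < 3L) stop("ORF too short")
  if (!startsWith(p$tag$coding, "G")) {
    stop("fixture geometry requires a tag starting with G ",
         "(the retained junction nucleotide)")
  }
  p$linker_cut_rel <- p$linker_len + p$exon1_utr_len - 47L
  if (p$linker_cut_rel < 3L || p$linker_cut_rel + 5L > p$linker_len) {
    stop("linker donor (47 nt before exon-1 end) does not fit in the linker")
  }
  p$bsaai_rel <- p$linker_cut_rel + 8L
  if (p$bsaai_rel + 6L > p$linker_len) {
    stop("restriction diagnostic site does not fit in the linker")
  }
  # stop placement within exon 3 along the mis-spliced path (1 retained
  # junction nt + exon 2 + exon 3)
  p$exon3_stop_rel <- p$exon3_stop_offset - 3L - 1L - p$exon2_len
  if (p$exon3_stop_rel < 0L || p$exon3_stop_rel + 3L > p$exon3_len) {
    stop("first in-frame stop does not fall within exon 3; adjust ",
         "exon3_stop_offset / exon2_len / exon3_len")
  }
  if (p$intron1_len < 10L || p$intron2_len < 10L) stop("introns too short")
  structure(p, class = "model_params")
}

plant <- function(seq, at, motif) {
  # 0-based in-place overwrite
  substr(seq, at + 1L, at + nchar(motif)) <- motif
  seq
}

build_fixture <- function(params, repaired, linker_donor,
                          max_tries = 200L) {
  stopifnot(inherits(params, "model_params"))
  p <- params
  tag_coding <- p$tag$coding
  if (repaired) {
    # wobble repair of the tag's first glycine codon: GGT -> GGG
    if (substr(tag_coding, 1L, 3L) != "GGT") {
      stop("repaired fixture expects a tag starting with the GGT codon")
    }
    tag_coding <- plant(tag_coding, 2L, "G")
  }

  result <- with_seed(p$seed, {
    out <- NULL
    for (attempt in seq_len(max_tries)) {
      promoter <- clean_random_dna(p$promoter_len)
      orf <- clean_random_codons(p$native_orf_codons,
                                 first = "ATG", last = "CTT")
      linker <- clean_random_dna(p$linker_len)
      linker <- plant(linker, p$linker_cut_rel - 3L, "CTG")
      if (linker_donor) {
        linker <- plant(linker, p$linker_cut_rel, "GTAAG")
      }
      linker <- plant(linker, p$bsaai_rel, "TACGTG")
      utr <- plant(clean_random_dna(p$exon1_utr_len),
                   p$exon1_utr_len - 1L, "C")
      intron1 <- paste0("GTAAG", clean_random_dna(p$intron1_len - 7L), "AG")
      intron2 <- paste0("GTAAG", clean_random_dna(p$intron2_len - 7L), "AG")

      # exon 2 / exon 3: the mis-spliced reading frame (1 retained junction
      # nt + exon 2 + exon 3) must reach its first in-frame stop exactly at
      # the planted position
      ok_path <- FALSE
      for (i in seq_len(max_tries)) {
        exon2 <- plant(clean_random_dna(p$exon2_len), p$exon2_len - 1L, "C")
        exon3 <- clean_random_dna(p$exon3_len)
        exon3 <- plant(exon3, p$exon3_stop_rel, "TAA")
        exon3 <- plant(exon3, p$exon3_len - 16L, "ATTAAA")
        path <- paste0(substr(tag_coding, 1L, 1L), exon2, exon3)
        cod <- codons_of(path)
        hit <- which(cod %in% STOP_CODONS)
        if (length(hit) && hit[1L] * 3L == p$exon3_stop_offset) {
          ok_path <- TRUE
          break
        }
      }
      if (!ok_path) next

      segs <- list(
        segment("promoter", "promoter", promoter),
        segment("orf", "orf", orf),
        segment("tag_stop", "tag", paste0(tag_coding, p$tag$default_stop)),
        segment("linker", "linker", linker),
        segment("exon1_utr", "utr", utr),
        segment("intron1", "intron", intron1, canonical = TRUE),
        segment("exon2", "exon", exon2),
        segment("intron2", "intron", intron2, canonical = TRUE),
        segment("exon3", "exon", exon3))
      name <- if (repaired) {
        if (linker_donor) "repaired_d4z4" else "repaired_d4z4_nolinker"
      } else "model_d4z4"
      orf_start <- p$promoter_len
      orf_len <- 3L * p$native_orf_codons
      x <- construct(name, segs, orf_start = orf_start,
                     intended_stop = orf_start + orf_len + nchar(tag_coding))

      # planted landmarks (0-based cuts on the assembled sequence)
      junction_cut <- orf_start + orf_len + 1L
      linker_start <- orf_start + orf_len + nchar(tag_coding) + 3L
      linker_cut <- linker_start + p$linker_cut_rel
      intron1_cut <- x$map$start[x$map$label == "intron1"]
      intron2_cut <- x$map$start[x$map$label == "intron2"]
      expected <- sort(c(if (!repaired) junction_cut,
                         if (linker_donor) linker_cut,
                         intron1_cut, intron2_cut))

      found <- scan_donors(x$seq, "MINIMAL")$cut
      if (!identical(as.integer(found), as.integer(expected))) next
      bsa <- find_sites(x$seq, restriction_site("BsaAI_iupac"))
      if (!identical(bsa, linker_start + p$bsaai_rel)) next

      attr(x, "landmarks") <- list(
        junction_cut = if (repaired) NA_integer_ else junction_cut,
        linker_cut = if (linker_donor) linker_cut else NA_integer_,
        intron1_cut = intron1_cut, intron2_cut = intron2_cut,
        acceptors = x$annotated_acceptors,
        bsaai_site = bsa, seed = p$seed)
      out <- x
      break
    }
    out
  })
  if (is.null(result)) {
    stop("fixture rejection sampling failed after ", max_tries, " attempts")
  }
  result
}

#' Generate the model construct fixture
#'
#' A deterministic synthetic construct (not a real vector sequence) whose
#' junction forms the cryptic `TTGGTAAG` donor, with two canonical annotated
#' introns, a second cryptic donor in the linker, and a single restriction
#' diagnostic site in the excisable linker. The background is uniform random
#' ACGT, rejection-sampled so that donor scans at tier `MINIMAL` report
#' exactly the planted sites.
#'
#' @param params a [model_params()] list.
#' @return a `construct` with a `landmarks` attribute giving the planted
#'   0-based cut offsets.
#' @export
make_model_construct <- function(params = model_params()) {
  build_fixture(params, repaired = FALSE, linker_donor = TRUE)
}

#' Generate the repaired construct fixture
#'
#' Same geometry as [make_model_construct()] but with the tag's first
#' glycine codon wobble-repaired (GGT to GGG), destroying the junction
#' donor. The linker donor 47 nt before the exon-1 3' end remains planted
#' unless `linker_donor = FALSE`.
#'
#' @param params a [model_params()] list.
#' @param linker_donor keep the second cryptic donor in the linker.
#' @return a `construct` with a `landmarks` attribute.
#' @export
make_repaired_construct <- function(params = model_params(),
                                    linker_donor = TRUE) {
  build_fixture(params, repaired = TRUE, linker_donor = linker_donor)
}

#' Generate a random CDS library
#'
#' Each CDS starts with ATG, contains no internal in-frame stop, ends with a
#' sense codon whose final two nucleotides are drawn from
#' `terminal_dinuc_distribution`, and is terminated by a stop codon.
#' Deterministic for a fixed seed.
#'
#' @param n number of CDSs.
#' @param terminal_dinuc_distribution named probability vector over the 16
#'   dinucleotides (default uniform). Point masses are allowed.
#' @param length_range CDS length range in nucleotides (including the stop
#'   codon); lengths are rounded down to codon multiples.
#' @param seed RNG seed.
#' @return named character vector of CDS sequences.
#' @export
make_random_cds_set <- function(n, terminal_dinuc_distribution = NULL,
                                length_range = c(120L, 300L), seed = 1L) {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  if (is.null(terminal_dinuc_distribution)) {
    terminal_dinuc_distribution <- setNames(rep(1 / 16, 16L), dinucs)
  }
  d <- terminal_dinuc_distribution
  if (is.null(names(d)) || !all(names(d) %in% dinucs) || any(d < 0) ||
      abs(sum(d)) < 1e-9) {
    stop("terminal_dinuc_distribution must be a named non-negative vector ",
         "over the 16 dinucleotides")
  }
  if (abs(sum(d) - 1) > 1e-6) stop("distribution must sum to 1")
  length_range <- as.integer(length_range)
  kmin <- max(3L, length_range[1L] %/% 3L)
  kmax <- length_range[2L] %/% 3L
  if (kmax < kmin) stop("infeasible length range")
  sense <- SENSE_CODONS()

  with_seed(seed, {
    k <- sample(kmin:kmax, n, replace = TRUE)      # codons incl. stop
    term <- sample(names(d), n, replace = TRUE, prob = d)
    first_nt <- vapply(term, function(dn) {
      allowed <- c("A", "C", "G", if (!dn %in% c("AA", "AG", "GA")) "T")
      sample(allowed, 1L)
    }, "", USE.NAMES = FALSE)
    stops <- sample(STOP_CODONS, n, replace = TRUE)
    n_interior <- k - 3L                            # ATG + last + stop
    interior <- sample(sense, sum(n_interior), replace = TRUE)
    grp <- rep.int(seq_len(n), n_interior)
    mid <- character(n)
    mid[unique(grp)] <- vapply(split(interior, grp), paste, "",
                               collapse = "", USE.NAMES = FALSE)
    seqs <- paste0("ATG", mid, first_nt, term, stops)
    setNames(seqs, sprintf("cds_%05d", seq_len(n)))
  })
}
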