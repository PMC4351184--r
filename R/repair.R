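# Synonymous repair of cryptic splice donors.
#
# The repair search mirrors the wobble fix that removes a tag-junction donor
# (e.g. GGT -> GGG, both glycine, destroying the invariant GT): every codon
# overlapping the donor 8-mer window is tested against all synonymous
# alternatives, candidate edits must strictly lower the donor tier, and each
# candidate is rescanned in a flanking window so edits that create a new
# donor are rejected.

SYNONYMOUS_CODONS <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::GENETIC_CODE
      code <<- split(names(gc), unname(gc))
    }
    code
  }
})

#' Suggest synonymous repairs for a splice-donor site
#'
#' For a donor inside the coding span of a frame-0 fused CDS, evaluates all
#' synonymous substitutions of the codons overlapping the donor window
#' `[cut-3, cut+5)`. A suggestion is kept when it strictly lowers the donor
#' tier at `cut` and creates no new donor at or above `MINIMAL` within
#' `flank` nucleotides of the window. Suggestions are sorted by fewest
#' nucleotides changed, then tier-destroying (`none`) first, then 5'-most
#' codon. Stop-codon swaps (e.g. TAA -> TGA) are considered synonymous.
#'
#' For a donor downstream of the coding span (UTR/linker), unconstrained
#' single-nucleotide edits of the GT dinucleotide are returned instead, with
#' `codon_index = NA` and attribute `noncoding = TRUE`.
#'
#' @param fused_cds frame-0 fused CDS (coding span runs to the first
#'   in-frame stop; any trailing sequence is treated as noncoding).
#' @param cut donor cut (0-based offset of the G of GT), e.g. from
#'   [scan_donors()].
#' @param flank rescan margin (nt) on each side of the donor window.
#' @return data frame of suggestions: `codon_index` (0-based), `old_codon`,
#'   `new_codon`, `residue`, `tier_before`, `tier_after` (`NA` = no donor
#'   left), `nt_changed`. Empty with a `diagnostic` attribute when no
#'   synonymous escape exists.
#' @export
suggest_repairs <- function(fused_cds, cut, flank = 24L) {
  fused_cds <- as_dna(fused_cds)
  if (is.data.frame(cut)) {
    if (nrow(cut) != 1L) stop("supply a single donor site")
    cut <- cut$cut
  }
  cut <- as.integer(cut)
  n <- nchar(fused_cds)
  if (cut < 3L || cut + 5L > n) {
    stop("donor window [cut-3, cut+5) out of sequence bounds")
  }
  tier_before <- classify_window(subseq0(fused_cds, cut - 3L, cut + 5L))
  if (is.na(tier_before)) {
    stop("no splice donor at cut ", cut, " (window ",
         subseq0(fused_cds, cut - 3L, cut + 5L), ")")
  }

  cod <- codons_of(fused_cds)
  stop_idx <- which(cod %in% STOP_CODONS)
  coding_end <- if (length(stop_idx)) stop_idx[1L] * 3L else n - n %% 3L

  region <- c(max(0L, cut - 3L - flank), min(n, cut + 5L + flank))
  orig_cuts <- scan_donors(fused_cds, "MINIMAL", region)$cut
  evaluate <- function(candidate) {
    tier_after <- classify_window(subseq0(candidate, cut - 3L, cut + 5L))
    if (!is.na(tier_after) && tier_rank(tier_after) >= tier_rank(tier_before)) {
      return(NULL)
    }
    new_cuts <- setdiff(scan_donors(candidate, "MINIMAL", region)$cut,
                        orig_cuts)
    if (length(new_cuts)) return(NULL)
    tier_after
  }

  empty <- data.frame(codon_index = integer(), old_codon = character(),
                      new_codon = character(), residue = character(),
                      tier_before = character(), tier_after = character(),
                      nt_changed = integer(), stringsAsFactors = FALSE)

  if (cut + 2L > coding_end) {
    # donor outside the coding span: free single-nt edits of the GT
    rows <- list()
    for (p in c(cut, cut + 1L)) {
      for (b in setdiff(c("A", "C", "G", "T"),
                        substr(fused_cds, p + 1L, p + 1L))) {
        candidate <- fused_cds
        substr(candidate, p + 1L, p + 1L) <- b
        tier_after <- evaluate(candidate)
        if (is.null(tier_after)) next
        rows[[length(rows) + 1L]] <- data.frame(
          codon_index = NA_integer_, old_codon = NA_character_,
          new_codon = paste0(p, substr(fused_cds, p + 1L, p + 1L), ">", b),
          residue = NA_character_, tier_before = tier_before,
          tier_after = tier_after, nt_changed = 1L, stringsAsFactors = FALSE)
      }
    }
    res <- if (length(rows)) do.call(rbind, rows) else empty
    res <- res[order(!is.na(res$tier_after), tier_rank(res$tier_after)), ,
               drop = FALSE]
    rownames(res) <- NULL
    attr(res, "noncoding") <- TRUE
    return(res)
  }

  syn <- SYNONYMOUS_CODONS()
  gc <- Biostrings::GENETIC_CODE
  lo <- max(0L, (cut - 3L) %/% 3L)
  hi <- min(coding_end %/% 3L - 1L, (cut + 4L) %/% 3L)
  rows <- list()
  for (ci in lo:hi) {
    old <- cod[ci + 1L]
    if (grepl("N", old, fixed = TRUE)) next
    aa <- unname(gc[old])
    for (alt in setdiff(syn[[aa]], old)) {
      candidate <- fused_cds
      substr(candidate, 3L * ci + 1L, 3L * ci + 3L) <- alt
      tier_after <- evaluate(candidate)
      if (is.null(tier_after)) next
      rows[[length(rows) + 1L]] <- data.frame(
        codon_index = ci, old_codon = old, new_codon = alt, residue = aa,
        tier_before = tier_before, tier_after = tier_after,
        nt_changed = sum(strsplit(old, "")[[1]] != strsplit(alt, "")[[1]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(res) == 0L) {
    attr(res, "diagnostic") <- paste0(
      "no synonymous substitution removes or weakens the donor at cut ", cut)
    return(res)
  }
  res <- res[order(res$nt_changed, !is.na(res$tier_after),
                   tier_rank(res$tier_after), res$codon_index), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Apply a repair suggestion
#'
#' @param fused_cds the sequence passed to [suggest_repairs()].
#' @param suggestion one row of the suggestion data frame.
#' @return the repaired sequence.
#' @export
apply_repair <- function(fused_cds, suggestion) {
  fused_cds <- as_dna(fused_cds)
  if (is.data.frame(suggestion)) {
    if (nrow(suggestion) < 1L) stop("empty suggestion")
    suggestion <- suggestion[1L, ]
  }
  if (is.na(suggestion$codon_index)) {
    m <- regmatches(suggestion$new_codon,
                    regexec("^([0-9]+)([ACGT])>([ACGT])$",
                            suggestion$new_codon))[[1]]
    if (length(m) != 4L) stop("malformed noncoding suggestion")
    p <- as.integer(m[2L])
    if (substr(fused_cds, p + 1L, p + 1L) != m[3L]) {
      stop("suggestion does not match sequence at position ", p)
    }
    substr(fused_cds, p + 1L, p + 1L) <- m[4L]
    return(fused_cds)
  }
  ci <- suggestion$codon_index
  if (subseq0(fused_cds, 3L * ci, 3L * ci + 3L) != suggestion$old_codon) {
    stop("suggestion does not match sequence at codon ", ci)
  }
  substr(fused_cds, 3L * ci + 1L, 3L * ci + 3L) <- suggestion$new_codon
  fused_cds
}

#' Verify a repair
#'
#' Asserts that `original` and `repaired` encode the same protein from
#' `orf_start` (a changed translation is a hard failure) and reports all
#' donor sites lost and gained sequence-wide -- not only at the repaired
#' cut, since a repaired construct can still carry (or newly expose) other
#' functional donors.
#'
#' @param original,repaired equal-length sequences.
#' @param orf_start 0-based translation start.
#' @param min_tier weakest donor tier audited.
#' @return a `repair_report`: `protein_identical` (always `TRUE` on return),
#'   `lost` and `gained` donor-site data frames.
#' @export
verify_repair <- function(original, repaired, orf_start = 0L,
                          min_tier = "MINIMAL") {
  original <- as_dna(original)
  repaired <- as_dna(repaired)
  if (nchar(original) != nchar(repaired)) stop("sequences differ in length")
  p0 <- translate_cds(original, orf_start)
  p1 <- translate_cds(repaired, orf_start)
  if (p0$protein != p1$protein || p0$stopped != p1$stopped) {
    stop("repair changed the translation from orf_start ", orf_start)
  }
  before <- scan_donors(original, min_tier)
  after <- scan_donors(repaired, min_tier)
  structure(list(protein_identical = TRUE,
                 lost = before[!before$cut %in% after$cut, , drop = FALSE],
                 gained = after[!after$cut %in% before$cut, , drop = FALSE]),
            class = "repair_report")
}

#' @export
print.repair_report <- function(x, ...) {
  cat("<repair_report> protein identical: ", x$protein_identical,
      "\n  donors lost: ", nrow(x$lost),
      if (nrow(x$lost)) paste0(" (cut ", paste(x$lost$cut, collapse = ", "),
                               ")") else "",
      "\n  donors gained: ", nrow(x$gained),
      if (nrow(x$gained)) paste0(" (cut ", paste(x$gained$cut, collapse = ", "),
                                 ")") else "",
      "\n", sep = "")
  invisible(x)
}
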