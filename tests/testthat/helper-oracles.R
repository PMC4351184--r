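# Independent oracles and fixture builders shared across test files. These
# deliberately use different machinery than the implementation (regexes with
# lookahead, combn-based subset enumeration, character-vector splicing) so
# that agreement is evidence, not tautology.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- donor classification / scanning oracle --------------------------------

TIER_PATTERNS <- c(
  CONSENSUS = "[AC]AGGTAAG",
  GGTAAG_CLASS = "[ACGT][ACGT]GGTAAG",
  MINIMAL = "[ACGT][ACGT][ACGT]GTAAG",
  CORE = "[ACGT][ACGT][ACGT]GT[ACGT][ACGT][ACGT]")

oracle_classify <- function(w) {
  for (tier in names(TIER_PATTERNS)) {
    if (grepl(paste0("^", TIER_PATTERNS[[tier]], "$"), w)) return(tier)
  }
  NA_character_
}

oracle_scan <- function(seq, min_tier = "MINIMAL") {
  ranks <- c(CORE = 1, MINIMAL = 2, GGTAAG_CLASS = 3, CONSENSUS = 4)
  hits <- list()
  for (tier in names(TIER_PATTERNS)) {
    m <- gregexpr(paste0("(?=", TIER_PATTERNS[[tier]], ")"), seq,
                  perl = TRUE)[[1]]
    if (m[1] == -1) next
    hits[[tier]] <- as.integer(m) - 1L + 3L    # 0-based cut
  }
  cut2tier <- list()
  for (tier in rev(names(TIER_PATTERNS))) {    # weakest first, strongest wins
    for (cut in hits[[tier]]) cut2tier[[as.character(cut)]] <- tier
  }
  cuts <- as.integer(names(cut2tier))
  tiers <- unlist(cut2tier, use.names = FALSE)
  keep <- ranks[tiers] >= ranks[[min_tier]]
  ord <- order(cuts[keep])
  data.frame(cut = cuts[keep][ord], tier = tiers[keep][ord],
             stringsAsFactors = FALSE)
}

# --- IUPAC pattern matching oracle ------------------------------------------

iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(pattern, "")[[1]]], collapse = "")
}

oracle_find_sites <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  as.integer(m) - 1L
}

# --- brute-force isoform enumeration oracle ---------------------------------

oracle_enumerate_matures <- function(seq, donors, acceptors, max_events = 3) {
  chars <- strsplit(seq, "")[[1]]
  pairs <- expand.grid(d = donors, a = acceptors)
  pairs <- pairs[pairs$d < pairs$a, , drop = FALSE]
  np <- nrow(pairs)
  sets <- list(integer())
  for (k in seq_len(min(max_events, np))) {
    sets <- c(sets, combn(np, k, simplify = FALSE))
  }
  ok <- vapply(sets, function(idx) {
    if (length(idx) < 2) return(TRUE)
    iv <- pairs[idx, ]
    iv <- iv[order(iv$d), ]
    all(iv$d[-1] >= iv$a[-nrow(iv)])
  }, NA)
  matures <- vapply(sets[ok], function(idx) {
    if (!length(idx)) return(seq)
    removed <- unlist(lapply(idx, function(i) {
      (pairs$d[i] + 1):pairs$a[i]       # 1-based positions removed
    }))
    paste(chars[-removed], collapse = "")
  }, "")
  sort(unique(matures))
}

# Planted-signal sequence on a GT/AG-free background: donors are GGTAAG
# plants (cut = offset + 1), acceptors are AG plants (cut = offset + 2).
planted_instance <- function(n_donors, n_acceptors, len = 400, gap = 12) {
  seq <- strrep("C", len)
  n_sites <- n_donors + n_acceptors
  if (n_sites == 0) {
    return(list(seq = seq, donors = integer(), acceptors = integer()))
  }
  offsets <- sort(sample(seq(10, len - 10, by = gap), n_sites))
  which_d <- sort(sample(n_sites, n_donors))
  donors <- integer()
  acceptors <- integer()
  for (i in seq_len(n_sites)) {
    if (i %in% which_d) {
      substr(seq, offsets[i] + 1, offsets[i] + 6) <- "GGTAAG"
      donors <- c(donors, offsets[i] + 1L)
    } else {
      substr(seq, offsets[i] + 1, offsets[i] + 2) <- "AG"
      acceptors <- c(acceptors, offsets[i] + 2L)
    }
  }
  list(seq = seq, donors = donors, acceptors = acceptors)
}

# --- misc -------------------------------------------------------------------

random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[!gc %in% "*"]
  paste(c("ATG", sample(sense, n_codons - 2, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

# Biostrings-based translation oracle (frame 0, stops removed at the end)
oracle_translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  p <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1, n))))
  sub("\\*.*$", "", p)
}
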