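# Seeded synthetic genomes with planted promoter/enhancer grammars and
# confusable decoy loci. The grammar is honest: every planted element is
# recoverable by exact motif match at its planted offsets, so training,
# scanning, evaluation and interpretation are all testable offline.

#' Specify a synthetic regulatory grammar
#'
#' Defaults emulate a FANTOM5-style truth set at reduced scale: point-like
#' promoter TSSs with strand, bidirectional enhancer midpoints, planted
#' core-promoter motifs (TATA box ~30 bp upstream, Initiator over the TSS),
#' GC-elevated cores, and decoy loci that resemble positives — the
#' substrate that hard-negative mining must learn to reject.
#'
#' @param background_gc genome background GC fraction.
#' @param promoter list: `tata_consensus` (IUPAC), `tata_offset` (bp
#'   upstream of the TSS), `tata_jitter` (+/- bp), `inr_consensus` (IUPAC,
#'   planted with its fourth base on the TSS), `core_gc_boost` (added GC
#'   fraction over +/-100 bp), `tata_fraction` (fraction of promoters
#'   carrying a TATA box).
#' @param enhancer list: `center_motif` (literal string planted at the
#'   midpoint), `motif_fraction`, `flank_gc_boost`.
#' @param decoys list of per-megabase rates: `tata_only_rate` (TATA box,
#'   background GC, no Initiator), `gc_island_rate` (promoter-level GC core,
#'   no motifs), `shuffled_promoter_rate` (full promoter cassette,
#'   base-shuffled: same composition, motifs destroyed).
#' @param pair_dependency optional list(d1, d2, rule) tying two TSS-relative
#'   offsets to a correlated nucleotide pair in every promoter (see
#'   [plant_pair_dependency()]).
#' @return an object of class `grammar_spec`.
#' @export
grammar_spec <- function(background_gc = 0.41,
                         promoter = list(),
                         enhancer = list(),
                         decoys = list(),
                         pair_dependency = NULL) {
  prom <- utils::modifyList(list(
    tata_consensus = "TATAWAWR", tata_offset = 30L, tata_jitter = 2L,
    inr_consensus = "BBCABW", core_gc_boost = 0.12, tata_fraction = 0.5
  ), promoter)
  enh <- utils::modifyList(list(
    center_motif = "CCGACC", motif_fraction = 0.8, flank_gc_boost = 0.08
  ), enhancer)
  dec <- utils::modifyList(list(
    tata_only_rate = 20, gc_island_rate = 20, shuffled_promoter_rate = 10
  ), decoys)
  fracs <- c(background_gc, prom$core_gc_boost, prom$tata_fraction,
             enh$motif_fraction, enh$flank_gc_boost)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (background_gc <= 0 || background_gc >= 1) {
    stop("background_gc must lie in (0, 1)")
  }
  if (any(unlist(dec) < 0)) stop("decoy rates must be >= 0")
  if (prom$tata_offset + prom$tata_jitter > 500L) {
    stop("TATA offset must stay within 500 bp of the TSS")
  }
  structure(list(background_gc = background_gc, promoter = prom,
                 enhancer = enh, decoys = dec,
                 pair_dependency = pair_dependency),
            class = "grammar_spec")
}

# Sample k positions in [lo, hi], pairwise >= gap apart (uniform over the
# feasible sorted configurations). Errors stating the achievable maximum.
sample_spaced_positions <- function(k, lo, hi, gap) {
  if (k == 0L) return(integer())
  span <- (hi - lo) - (k - 1L) * gap
  if (span < 0) {
    max_k <- (hi - lo) %/% gap + 1L
    stop("cannot place ", k, " elements with ", gap,
         " bp spacing; achievable maximum is ", max(max_k, 0L))
  }
  u <- sort(sample.int(span + 1L, k, replace = FALSE) - 1L)
  as.integer(lo + u + (seq_len(k) - 1L) * gap)
}

sample_gc_chars <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = c((1 - gc) / 2, gc / 2,
                                            gc / 2, (1 - gc) / 2))
}

# Build a promoter cassette as a character vector of width 2*half+1 with
# the TSS at index half+1. Plus-strand grammar; the caller reverse
# complements for '-' elements.
promoter_cassette <- function(spec, gc, half = 120L) {
  p <- spec$promoter
  chars <- sample_gc_chars(2L * half + 1L, gc)
  core <- (half + 1L - 100L):(half + 1L + 100L)
  chars[core] <- sample_gc_chars(length(core),
                                 min(gc + p$core_gc_boost, 0.95))
  center <- half + 1L
  inr <- instantiate_iupac(p$inr_consensus)
  # fourth symbol of the Initiator consensus sits on the TSS
  inr_start <- center - 3L
  chars[inr_start:(inr_start + length(inr) - 1L)] <- inr
  has_tata <- stats::runif(1) < p$tata_fraction
  if (has_tata) {
    off <- p$tata_offset + sample.int(2L * p$tata_jitter + 1L, 1L) -
      p$tata_jitter - 1L
    tata <- instantiate_iupac(p$tata_consensus)
    start <- center - off
    chars[start:(start + length(tata) - 1L)] <- tata
  }
  chars
}

enhancer_cassette <- function(spec, gc, half = 120L) {
  e <- spec$enhancer
  chars <- sample_gc_chars(2L * half + 1L, gc)
  core <- (half + 1L - 100L):(half + 1L + 100L)
  chars[core] <- sample_gc_chars(length(core),
                                 min(gc + e$flank_gc_boost, 0.95))
  if (stats::runif(1) < e$motif_fraction) {
    motif <- strsplit(e$center_motif, "", fixed = TRUE)[[1]]
    start <- half + 1L - length(motif) %/% 2L
    chars[start:(start + length(motif) - 1L)] <- motif
  }
  chars
}

decoy_cassette <- function(kind, spec, gc, half = 120L) {
  p <- spec$promoter
  if (kind == "tata_only") {
    chars <- sample_gc_chars(2L * half + 1L, gc)
    off <- p$tata_offset + sample.int(2L * p$tata_jitter + 1L, 1L) -
      p$tata_jitter - 1L
    tata <- instantiate_iupac(p$tata_consensus)
    start <- half + 1L - off
    chars[start:(start + length(tata) - 1L)] <- tata
    chars
  } else if (kind == "gc_island") {
    chars <- sample_gc_chars(2L * half + 1L, gc)
    core <- (half + 1L - 100L):(half + 1L + 100L)
    chars[core] <- sample_gc_chars(length(core),
                                   min(gc + p$core_gc_boost, 0.95))
    chars
  } else if (kind == "shuffled_promoter") {
    sample(promoter_cassette(spec, gc, half))
  } else {
    stop("unknown decoy kind: ", kind)
  }
}

#' Generate a synthetic genome with planted regulatory elements
#'
#' Deterministic for a fixed seed. Planted elements (truth and decoys
#' together) are at least 2000 bp apart and at least 1000 bp from
#' chromosome edges, so that true-positive/false-positive matching under
#' the 500 bp evaluation margin is unambiguous. Promoters are planted on a
#' random strand; minus-strand promoters carry the reverse complement of
#' the grammar cassette.
#'
#' @param spec a [grammar_spec()].
#' @param n_chroms number of chromosomes (named chr1, chr2, ...).
#' @param chrom_len chromosome length in bp (>= 10000).
#' @param n_promoters,n_enhancers total element counts across chromosomes.
#' @param seed integer seed.
#' @return a list of class `sim_result` with elements `genome` ([genome]),
#'   `truth` ([annotation_set]), `decoys` (data frame chrom/pos/kind),
#'   `seed`, and `spec`.
#' @export
generate_genome <- function(spec = grammar_spec(), n_chroms = 1L,
                            chrom_len = 100000L, n_promoters = 10L,
                            n_enhancers = 5L, seed = 1L) {
  stopifnot(inherits(spec, "grammar_spec"))
  if (chrom_len < 10000L) stop("chrom_len must be >= 10000 bp")
  set.seed(seed)
  half <- 120L
  gc <- spec$background_gc
  # per-megabase decoy rates -> deterministic per-chromosome counts
  dec_rates <- unlist(spec$decoys)
  n_dec_per_chrom <- round(dec_rates * chrom_len / 1e6)
  # spread promoters/enhancers across chromosomes as evenly as possible
  split_counts <- function(n) {
    base <- n %/% n_chroms
    extra <- n %% n_chroms
    base + (seq_len(n_chroms) <= extra)
  }
  prom_counts <- split_counts(n_promoters)
  enh_counts <- split_counts(n_enhancers)

  chroms <- character(n_chroms)
  names(chroms) <- paste0("chr", seq_len(n_chroms))
  truth_rows <- list()
  decoy_rows <- list()
  for (ci in seq_len(n_chroms)) {
    chars <- sample_gc_chars(chrom_len, gc)
    kinds <- c(rep("promoter", prom_counts[ci]),
               rep("enhancer", enh_counts[ci]),
               rep(names(n_dec_per_chrom), n_dec_per_chrom))
    kinds <- sub("_rate$", "", kinds)
    k <- length(kinds)
    pos <- sample_spaced_positions(k, 1000L, chrom_len - 1001L, 2000L)
    kinds <- sample(kinds)  # random interleaving of element kinds
    for (j in seq_len(k)) {
      p <- pos[j]
      idx <- (p - half):(p + half) + 1L  # 1-based slice, TSS at center
      if (kinds[j] == "promoter") {
        strand <- sample(c("+", "-"), 1L)
        cas <- promoter_cassette(spec, gc, half)
        if (strand == "-") cas <- revcomp_chars(cas)
        chars[idx] <- cas
        truth_rows[[length(truth_rows) + 1L]] <-
          list(chrom = names(chroms)[ci], pos = p, class = "promoter",
               strand = strand)
      } else if (kinds[j] == "enhancer") {
        chars[idx] <- enhancer_cassette(spec, gc, half)
        truth_rows[[length(truth_rows) + 1L]] <-
          list(chrom = names(chroms)[ci], pos = p, class = "enhancer",
               strand = ".")
      } else {
        chars[idx] <- decoy_cassette(kinds[j], spec, gc, half)
        decoy_rows[[length(decoy_rows) + 1L]] <-
          list(chrom = names(chroms)[ci], pos = p, kind = kinds[j])
      }
    }
    chroms[ci] <- paste(chars, collapse = "")
  }
  truth <- if (length(truth_rows)) {
    annotation_set(
      chrom = vapply(truth_rows, `[[`, "", "chrom"),
      pos = vapply(truth_rows, function(r) r$pos, numeric(1)),
      class = vapply(truth_rows, `[[`, "", "class"),
      strand = vapply(truth_rows, `[[`, "", "strand"),
      id = paste0(ifelse(vapply(truth_rows, `[[`, "", "class") == "promoter",
                         "prom_", "enh_"),
                  seq_along(truth_rows)))
  } else annotation_set()
  decoys <- if (length(decoy_rows)) {
    data.frame(chrom = vapply(decoy_rows, `[[`, "", "chrom"),
               pos = as.integer(vapply(decoy_rows, function(r) r$pos,
                                       numeric(1))),
               kind = vapply(decoy_rows, `[[`, "", "kind"),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), pos = integer(), kind = character())
  g <- genome(chroms)
  res <- structure(list(genome = g, truth = truth, decoys = decoys,
                        seed = seed, spec = spec),
                   class = "sim_result")
  if (!is.null(spec$pair_dependency)) {
    pd <- spec$pair_dependency
    res <- plant_genome_pair_dependency(res, pd$d1, pd$d2,
                                        pd$rule %||% "equal")
  }
  res
}

pair_rule_set <- function(rule) {
  if (is.matrix(rule)) {
    if (nrow(rule) == 0L) stop("pair rule has an empty satisfying set")
    return(rule)
  }
  if (identical(rule, "equal")) {
    return(cbind(BASES, BASES))
  }
  if (identical(rule, "complement")) {
    return(cbind(BASES, c("T", "G", "C", "A")))
  }
  stop("unknown pair rule: supply 'equal', 'complement', or a 2-column ",
       "matrix of allowed base pairs")
}

#' Plant a pairwise nucleotide dependency into positive windows
#'
#' In every sequence, the bases at offsets `d1` and `d2` from the window
#' center are jointly re-drawn to satisfy `rule` (for the built-in rules
#' each single position keeps a uniform marginal over the four bases, so
#' the dependency is invisible to any single-position statistic).
#'
#' @param seqs character vector of odd-length windows centered on the TSS.
#' @param d1,d2 distinct center-relative offsets (0 = the TSS base).
#' @param rule `"equal"` (AA/CC/GG/TT), `"complement"`, or a 2-column
#'   character matrix of allowed base pairs sampled uniformly.
#' @param seed integer seed.
#' @return the modified character vector.
#' @export
plant_pair_dependency <- function(seqs, d1, d2, rule = "equal", seed = 1L) {
  if (d1 == d2) stop("offsets d1 and d2 must be distinct")
  pairs <- pair_rule_set(rule)
  set.seed(seed)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("all sequences must have equal length")
  if (L %% 2L == 0L) stop("windows must have odd length")
  center <- (L + 1L) %/% 2L
  i1 <- center + d1
  i2 <- center + d2
  if (any(c(i1, i2) < 1L) || any(c(i1, i2) > L)) {
    stop("offsets fall outside the sequence")
  }
  draw <- sample.int(nrow(pairs), length(seqs), replace = TRUE)
  substr(seqs, i1, i1) <- pairs[draw, 1L]
  substr(seqs, i2, i2) <- pairs[draw, 2L]
  seqs
}

# Apply plant_pair_dependency in-genome to every planted promoter.
plant_genome_pair_dependency <- function(sim, d1, d2, rule) {
  pairs <- pair_rule_set(rule)
  proms <- sim$truth[sim$truth$class == "promoter", , drop = FALSE]
  chroms <- sim$genome$chroms
  for (r in seq_len(nrow(proms))) {
    chrom <- proms$chrom[r]
    p <- proms$pos[r]
    dd1 <- d1; dd2 <- d2
    if (proms$strand[r] == "-") { dd1 <- -d1; dd2 <- -d2 }
    draw <- sample.int(nrow(pairs), 1L)
    b1 <- pairs[draw, 1L]; b2 <- pairs[draw, 2L]
    if (proms$strand[r] == "-") {
      b1 <- chartr("ACGT", "TGCA", b1); b2 <- chartr("ACGT", "TGCA", b2)
    }
    substr(chroms[chrom], p + dd1 + 1L, p + dd1 + 1L) <- b1
    substr(chroms[chrom], p + dd2 + 1L, p + dd2 + 1L) <- b2
  }
  sim$genome <- genome(chroms)
  sim
}
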