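# Shared fixtures: tiny genomes, stub scorers, and PWM builders.

random_seq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

tiny_genome <- function(lens = c(chrA = 5000, chrB = 3000), seed = 1) {
  set.seed(seed)
  genome(vapply(lens, function(L) random_seq(L), character(1)))
}

# A near-deterministic PWM for a fixed consensus (probability `p` on the
# consensus base, the rest spread uniformly).
consensus_pwm <- function(consensus, name = consensus, p = 0.97) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  m <- matrix((1 - p) / 3, 4, length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- p
  pwm(name, m)
}

# Position-oracle stub scorers for scan_genome: score 1 within `radius`
# bp of any target position on the chromosome, else 0.
oracle_scorer <- function(targets, radius = 0) {
  function(chrom, centers) {
    tp <- targets$pos[targets$chrom == chrom]
    if (length(tp) == 0L) return(numeric(length(centers)))
    as.numeric(vapply(centers, function(c) min(abs(tp - c)),
                      numeric(1)) <= radius)
  }
}

# Sequence-stub models for the interpretation suite.
stub_gc_model <- function(seqs) {
  vapply(seqs, function(s) {
    mean(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# Linear (additive) model over the one-hot encoding with fixed weights.
make_linear_model <- function(L, seed = 99) {
  set.seed(seed)
  w <- matrix(rnorm(4 * L, 0, 0.05), 4, L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  function(seqs) {
    vapply(seqs, function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      idx <- match(chars, rownames(w))
      keep <- !is.na(idx)
      0.5 + sum(w[cbind(idx[keep], which(keep))])
    }, numeric(1), USE.NAMES = FALSE)
  }
}

# Small model configuration used in engine-level tests.
tiny_model_config <- function(L = 21L, seed = 42L, ...) {
  model_config(n_res_blocks = 2L, channels = c(3L, 4L), kernel = 3L,
               pool = 2L, dropout_keep = 1, weight_decay = 0,
               window_len = L, seed = seed, ...)
}
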