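# Model-analysis suite: PWM scanning, motif-replacement effects,
# window-substitution profiles, mutation maps with matrix clustering,
# pair dependency maps, and the motif-pair independence test.
#
# Every routine accepts either a trained scorer or a plain function
# `f(character vector of sequences) -> numeric scores`; the latter is the
# stub interface used to verify each analysis against closed forms.

model_scores <- function(model, seqs) {
  if (length(seqs) == 0L) return(numeric())
  if (is.function(model)) return(model(seqs))
  if (inherits(model, "scorer")) return(score_batch(model, seqs))
  stop("model must be a scorer or a scoring function")
}

seq_to_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Scan a sequence with a position weight matrix
#'
#' Log-odds scoring `sum(log(p_col(base) / bg(base)))` on both strands
#' (the reverse strand scans the reverse-complemented PWM). A position
#' matches when its log-odds reaches `score_fraction` of the maximum
#' achievable log-odds. Overlapping matches are allowed.
#'
#' @param seq DNA string (length >= PWM width).
#' @param pwm a [pwm] object.
#' @param background base frequencies for A, C, G, T (must be positive).
#' @param score_fraction fraction of the maximum achievable log-odds
#'   required for a match.
#' @return data frame with columns `start` (0-based), `strand`, `score`.
#' @export
scan_pwm <- function(seq, pwm, background = rep(0.25, 4),
                     score_fraction = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  if (any(background <= 0)) stop("background frequencies must be > 0")
  background <- background / sum(background)
  W <- ncol(pwm$matrix)
  codes <- seq_codes(seq)
  L <- length(codes)
  if (L < W) stop("sequence shorter than the PWM width")
  score_strand <- function(mat) {
    logodds <- rbind(log(mat / background), -Inf)  # row 5: N never matches
    n_start <- L - W + 1L
    sc <- numeric(n_start)
    for (w in seq_len(W)) {
      sc <- sc + logodds[cbind(codes[w:(w + n_start - 1L)], w)]
    }
    sc
  }
  maxscore <- sum(apply(log(pwm$matrix / background), 2, max))
  thr <- score_fraction * maxscore
  fwd <- score_strand(pwm$matrix)
  rc_mat <- pwm$matrix[4:1, W:1, drop = FALSE]
  rev <- score_strand(rc_mat)
  strand_df <- function(sc, strand) {
    hit <- which(sc >= thr)
    data.frame(start = hit - 1L, strand = rep(strand, length(hit)),
               score = sc[hit])
  }
  out <- rbind(strand_df(fwd, "+"), strand_df(rev, "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_bases <- function(n) sample(BASES, n, replace = TRUE)

replace_span <- function(chars, start0, width, replacement) {
  chars[(start0 + 1L):(start0 + width)] <- replacement
  chars
}

#' Effect of replacing motif occurrences with random bases
#'
#' Each PWM match in each sequence is replaced by `n_random` independent
#' uniform-random base draws; the relative score change
#' `(orig - new) / orig` is averaged over draws, then over occurrences.
#' Occurrences in sequences with non-positive original score are skipped
#' (the relative change is undefined there).
#'
#' @param model scorer or scoring function.
#' @param seqs character vector of positive windows.
#' @param pwm a [pwm].
#' @param n_random random replacement draws per occurrence.
#' @param seed integer seed.
#' @param score_fraction PWM match threshold (see [scan_pwm()]).
#' @return list of class `motif_effect`: `motif`, `n` (occurrences
#'   tested), `mean_change` (NA when `n` is 0), `per_occurrence` data
#'   frame.
#' @export
motif_effect <- function(model, seqs, pwm, n_random = 8L, seed = 1L,
                         score_fraction = 0.8) {
  set.seed(seed)
  W <- ncol(pwm$matrix)
  orig <- model_scores(model, seqs)
  occ <- list()
  mutants <- character(0)
  mut_of <- integer(0)
  for (si in seq_along(seqs)) {
    matches <- scan_pwm(seqs[[si]], pwm, score_fraction = score_fraction)
    if (nrow(matches) == 0L) next
    chars <- seq_to_chars(seqs[[si]])
    for (mi in seq_len(nrow(matches))) {
      occ[[length(occ) + 1L]] <- list(seq = si, start = matches$start[mi],
                                      strand = matches$strand[mi])
      for (r in seq_len(n_random)) {
        mut <- replace_span(chars, matches$start[mi], W, random_bases(W))
        mutants <- c(mutants, paste(mut, collapse = ""))
        mut_of <- c(mut_of, length(occ))
      }
    }
  }
  if (length(occ) == 0L) {
    return(structure(list(motif = pwm$name, n = 0L, mean_change = NA_real_,
                          per_occurrence = data.frame()),
                     class = "motif_effect"))
  }
  new_scores <- model_scores(model, mutants)
  per <- vapply(seq_along(occ), function(k) {
    o <- orig[occ[[k]]$seq]
    if (o <= 0) return(NA_real_)
    mean((o - new_scores[mut_of == k]) / o)
  }, numeric(1))
  df <- data.frame(seq = vapply(occ, function(o) o$seq, integer(1)),
                   start = vapply(occ, function(o) o$start, numeric(1)),
                   strand = vapply(occ, function(o) o$strand, ""),
                   change = per)
  ok <- !is.na(per)
  structure(list(motif = pwm$name, n = sum(ok),
                 mean_change = if (any(ok)) mean(per[ok]) else NA_real_,
                 per_occurrence = df),
            class = "motif_effect")
}

#' Sliding-window substitution profile
#'
#' At every start position, a `w` bp window is replaced by random bases
#' (`n_random` draws averaged) and the mean relative score change over
#' sequences is recorded. Profile length is `L - w + 1`.
#'
#' @param model scorer or scoring function.
#' @param seqs character vector of equal-length windows.
#' @param w substitution window width in bp.
#' @param n_random random draws per (sequence, start).
#' @param seed integer seed.
#' @return numeric vector of mean relative score changes, one per start.
#' @export
window_substitution_profile <- function(model, seqs, w = 7L, n_random = 4L,
                                        seed = 1L) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("all sequences must have equal length")
  if (w < 1L || w > L) stop("w must lie in [1, window length]")
  set.seed(seed)
  orig <- model_scores(model, seqs)
  ok <- orig > 0
  n_start <- L - w + 1L
  profile <- numeric(n_start)
  chars_list <- lapply(seqs, seq_to_chars)
  for (s0 in seq_len(n_start) - 1L) {
    mutants <- character(0)
    of <- integer(0)
    for (si in which(ok)) {
      for (r in seq_len(n_random)) {
        mut <- replace_span(chars_list[[si]], s0, w, random_bases(w))
        mutants <- c(mutants, paste(mut, collapse = ""))
        of <- c(of, si)
      }
    }
    if (length(mutants) == 0L) next
    new_scores <- model_scores(model, mutants)
    rel <- (orig[of] - new_scores) / orig[of]
    profile[s0 + 1L] <- mean(tapply(rel, of, mean))
  }
  profile
}

#' Single-nucleotide mutation map
#'
#' For each position `i` and each base `b` different from the reference,
#' `map[b, i] = score(seq with b at i) - score(seq)`; entries where `b`
#' equals the reference base are 0. Exactly `3 * L` model evaluations
#' (plus one reference).
#'
#' @param model scorer or scoring function.
#' @param seq a window sequence.
#' @return list of class `mutation_map` with the 4 x L `matrix` (rows
#'   A, C, G, T), the reference `score`, and the sequence.
#' @export
mutation_map <- function(model, seq) {
  chars <- seq_to_chars(seq)
  L <- length(chars)
  mutants <- character(0)
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(L)) {
    for (b in seq_len(4L)) {
      if (BASES[b] == chars[i]) next
      mut <- chars
      mut[i] <- BASES[b]
      mutants <- c(mutants, paste(mut, collapse = ""))
      rows <- c(rows, b); cols <- c(cols, i)
    }
  }
  scores <- model_scores(model, c(seq, mutants))
  m <- matrix(0, 4L, L, dimnames = list(BASES, NULL))
  m[cbind(rows, cols)] <- scores[-1L] - scores[1L]
  structure(list(matrix = m, score = scores[1L], seq = seq,
                 n_sequences = 1L),
            class = "mutation_map")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      remaining <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
      centers[j] <- remaining[sample.int(length(remaining), 1L)]
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    nd <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[centers, , drop = FALSE]
}

#' Cluster mutation (or dependency) matrices
#'
#' k-means under Frobenius distance (Euclidean on flattened matrices)
#' with seeded k-means++ initialization. Clusters are relabeled by
#' decreasing size, so cluster 1 is the largest.
#'
#' @param maps list of equal-shape numeric matrices.
#' @param k number of clusters.
#' @param seed integer seed.
#' @return list with `labels` (size-ranked cluster per map), `sizes`,
#'   and `cluster_means` (averaged matrix per cluster, largest first).
#' @export
cluster_maps <- function(maps, k = 10L, seed = 1L) {
  if (length(maps) < k) {
    stop("need at least k = ", k, " matrices, got ", length(maps))
  }
  shape <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), shape), logical(1)))) {
    stop("all matrices must have identical shape")
  }
  X <- t(vapply(maps, as.vector, numeric(prod(shape))))
  set.seed(seed)
  centers <- kmeanspp_init(X, k)
  centers <- centers + stats::rnorm(length(centers), 0, 1e-9)  # break exact duplicates
  km <- stats::kmeans(X, centers = centers, iter.max = 100L)
  sizes <- tabulate(km$cluster, k)
  ord <- order(-sizes, seq_len(k))
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  means <- lapply(ord, function(cl) {
    mm <- colMeans(X[km$cluster == cl, , drop = FALSE])
    dim(mm) <- shape
    rownames(mm) <- rownames(maps[[1]])
    mm
  })
  list(labels = labels, sizes = sizes[ord], cluster_means = means)
}

#' Pairwise position-dependency map
#'
#' For positions `i`, `j` in `region`, `delta(i)` is the mean score change
#' over the 3 alternative bases at `i`, `delta(i, j)` the mean over the 9
#' alternative base pairs, and `V(i, j) = delta(i, j) - delta(i) -
#' delta(j)`. For a model that is additive over positions the map is
#' identically zero; off-diagonal structure reveals non-additive
#' (epistatic) interactions learned by the model. Symmetric, zero
#' diagonal.
#'
#' @param model scorer or scoring function.
#' @param seq a window sequence.
#' @param region integer vector of 0-based positions within the window
#'   (default: 81 positions centered on the window midpoint, i.e. TSS
#'   +/- 40).
#' @return list of class `dependency_map` with `V` (m x m), `positions`,
#'   `delta1` (per-position single effects), and the reference score.
#' @export
pair_dependency_map <- function(model, seq, region = NULL) {
  chars <- seq_to_chars(seq)
  L <- length(chars)
  if (is.null(region)) {
    center <- (L + 1L) %/% 2L - 1L
    region <- (center - 40L):(center + 40L)
  }
  region <- as.integer(region)
  if (any(region < 0L) || any(region >= L)) {
    stop("region positions fall outside the window")
  }
  m <- length(region)
  alt <- lapply(region, function(p) setdiff(BASES, chars[p + 1L]))
  # single substitutions
  singles <- character(0); s_of <- integer(0)
  for (a in seq_len(m)) {
    for (b in alt[[a]]) {
      mut <- chars; mut[region[a] + 1L] <- b
      singles <- c(singles, paste(mut, collapse = ""))
      s_of <- c(s_of, a)
    }
  }
  # pair substitutions
  pairs_i <- integer(0); pairs_j <- integer(0)
  doubles <- character(0); d_of <- integer(0)
  pair_idx <- 0L
  for (a in seq_len(m - 1L)) {
    for (bdx in (a + 1L):m) {
      pair_idx <- pair_idx + 1L
      pairs_i <- c(pairs_i, a); pairs_j <- c(pairs_j, bdx)
      for (ba in alt[[a]]) {
        for (bb in alt[[bdx]]) {
          mut <- chars
          mut[region[a] + 1L] <- ba
          mut[region[bdx] + 1L] <- bb
          doubles <- c(doubles, paste(mut, collapse = ""))
          d_of <- c(d_of, pair_idx)
        }
      }
    }
  }
  scores <- model_scores(model, c(seq, singles, doubles))
  s0 <- scores[1L]
  sc_single <- scores[1L + seq_along(singles)]
  sc_double <- scores[1L + length(singles) + seq_along(doubles)]
  delta1 <- as.numeric(tapply(sc_single - s0, s_of, mean))
  delta2 <- as.numeric(tapply(sc_double - s0, d_of, mean))
  V <- matrix(0, m, m)
  for (pidx in seq_along(pairs_i)) {
    v <- delta2[pidx] - delta1[pairs_i[pidx]] - delta1[pairs_j[pidx]]
    V[pairs_i[pidx], pairs_j[pidx]] <- v
    V[pairs_j[pidx], pairs_i[pidx]] <- v
  }
  structure(list(V = V, positions = region, delta1 = delta1, score = s0),
            class = "dependency_map")
}

#' Dependency between two regions
#'
#' `D = delta(A union B) - delta(A) - delta(B)`, where `delta(span)` is
#' the mean score change over `n_random` random-replacement draws of the
#' span. `D` is near zero for models additive over the two regions.
#'
#' @param model scorer or scoring function.
#' @param seq a window sequence.
#' @param regionA,regionB disjoint spans `c(start, end)`, 0-based
#'   inclusive.
#' @param n_random replacement draws per delta.
#' @param seed integer seed.
#' @return scalar `D`.
#' @export
region_dependency <- function(model, seq, regionA, regionB,
                              n_random = 8L, seed = 1L) {
  a <- as.integer(regionA); b <- as.integer(regionB)
  if (max(a[1], b[1]) <= min(a[2], b[2])) {
    stop("regions must be disjoint")
  }
  set.seed(seed)
  chars <- seq_to_chars(seq)
  wa <- a[2] - a[1] + 1L
  wb <- b[2] - b[1] + 1L
  mk <- function(spans) {
    vapply(seq_len(n_random), function(r) {
      mut <- chars
      for (sp in spans) {
        wd <- sp[2] - sp[1] + 1L
        mut <- replace_span(mut, sp[1], wd, random_bases(wd))
      }
      paste(mut, collapse = "")
    }, character(1))
  }
  muts <- c(mk(list(a)), mk(list(b)), mk(list(a, b)))
  scores <- model_scores(model, c(seq, muts))
  s0 <- scores[1L]
  dA <- mean(scores[1L + seq_len(n_random)]) - s0
  dB <- mean(scores[1L + n_random + seq_len(n_random)]) - s0
  dAB <- mean(scores[1L + 2L * n_random + seq_len(n_random)]) - s0
  dAB - dA - dB
}

#' Test whether two motifs act independently under the model
#'
#' In every sequence where both PWMs match (non-overlapping best
#' matches), the dependency `D` between the two matched spans is compared
#' with the dependency between the first motif's span and a random span
#' of the second motif's width (avoiding both matches), by a Welch
#' two-sample t-test. A small p-value means the model treats the motif
#' pair as interacting beyond chance.
#'
#' @param model scorer or scoring function.
#' @param seqs character vector of windows.
#' @param pwmA,pwmB [pwm] objects.
#' @param n_random replacement draws per dependency evaluation.
#' @param seed integer seed.
#' @param score_fraction PWM match threshold.
#' @return list with `t`, `p_value`, `n` (co-occurrences used),
#'   `mean_dependency`, `mean_null`, and the per-sequence samples.
#' @export
independence_test <- function(model, seqs, pwmA, pwmB, n_random = 8L,
                              seed = 1L, score_fraction = 0.8) {
  set.seed(seed)
  WB <- ncol(pwmB$matrix)
  d_pair <- numeric(0)
  d_null <- numeric(0)
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    L <- nchar(s)
    ma <- scan_pwm(s, pwmA, score_fraction = score_fraction)
    mb <- scan_pwm(s, pwmB, score_fraction = score_fraction)
    if (nrow(ma) == 0L || nrow(mb) == 0L) next
    ma <- ma[which.max(ma$score), ]
    mb <- mb[which.max(mb$score), ]
    WA <- ncol(pwmA$matrix)
    spanA <- c(ma$start, ma$start + WA - 1L)
    spanB <- c(mb$start, mb$start + WB - 1L)
    if (max(spanA[1], spanB[1]) <= min(spanA[2], spanB[2])) next
    overlaps <- function(s1, s2) max(s1[1], s2[1]) <= min(s1[2], s2[2])
    rand_span <- NULL
    for (try in 1:50) {
      st <- sample.int(L - WB + 1L, 1L) - 1L
      cand <- c(st, st + WB - 1L)
      if (!overlaps(cand, spanA) && !overlaps(cand, spanB)) {
        rand_span <- cand
        break
      }
    }
    if (is.null(rand_span)) next
    d_pair <- c(d_pair,
                region_dependency(model, s, spanA, spanB, n_random,
                                  seed = derive_seed(seed, 2L * si)))
    d_null <- c(d_null,
                region_dependency(model, s, spanA, rand_span, n_random,
                                  seed = derive_seed(seed, 2L * si + 1L)))
  }
  if (length(d_pair) < 3L) {
    stop("fewer than 3 sequences with non-overlapping matches of both ",
         "motifs; the test is undefined")
  }
  tt <- stats::t.test(d_pair, d_null)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       n = length(d_pair), mean_dependency = mean(d_pair),
       mean_null = mean(d_null), sample_pair = d_pair,
       sample_null = d_null)
}
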