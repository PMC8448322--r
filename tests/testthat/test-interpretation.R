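test_that("PWM scanning finds exact motifs on both strands", {
  p <- consensus_pwm("TATAAA")
  seq <- paste0(random_seq(30, seed = 1), "TATAAA", random_seq(30))
  hits <- scan_pwm(seq, p)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, 30)
  # hand-computed log-odds of a perfect match: 6 * log(0.97 / 0.25)
  expect_equal(fwd$score, 6 * log(0.97 / 0.25), tolerance = 1e-9)

  rc <- revcomp(seq)
  hits_rc <- scan_pwm(rc, p)
  rev <- hits_rc[hits_rc$strand == "-", ]
  expect_equal(rev$start, nchar(seq) - 30 - 6)

  # a fully degenerate threshold on a non-optimal sequence finds nothing
  expect_equal(nrow(scan_pwm(strrep("G", 40), p, score_fraction = 1)), 0)
  expect_error(scan_pwm(seq, p, background = c(0, 0.5, 0.25, 0.25)), "> 0")
  expect_error(scan_pwm("ACG", p), "shorter")
})

test_that("motif replacement effects match indicator-model closed forms", {
  p <- consensus_pwm("TATAAA")
  # model scores 1 iff the sequence still contains TATAAA
  model <- function(seqs) as.numeric(grepl("TATAAA", seqs))
  set.seed(2)
  seqs <- vapply(1:12, function(i) {
    s <- random_seq(60)
    s <- sub("TATAAA", "CGCGCG", s)  # avoid accidental second copy
    paste0(substr(s, 1, 25), "TATAAA", substr(s, 32, 60))
  }, "")
  eff <- motif_effect(model, seqs, p, n_random = 6, seed = 3)
  expect_gte(eff$n, 12)
  # replacement destroys the motif almost surely (recreation prob 4^-6)
  expect_gt(eff$mean_change, 0.95)

  # a sequence-blind model sees no effect
  eff0 <- motif_effect(function(s) rep(0.8, length(s)), seqs, p,
                       n_random = 4, seed = 3)
  expect_equal(eff0$mean_change, 0, tolerance = 1e-12)

  # no matches -> n = 0 and undefined mean
  none <- motif_effect(model, strrep("G", 50), p, seed = 1)
  expect_equal(none$n, 0)
  expect_true(is.na(none$mean_change))
})

test_that("window substitution profile localizes an indicator motif", {
  L <- 40
  off <- 15  # 0-based offset of a planted 3-mer
  model <- function(seqs) as.numeric(substr(seqs, off + 1, off + 3) == "CGA")
  set.seed(4)
  seqs <- vapply(1:10, function(i) {
    s <- random_seq(L)
    paste0(substr(s, 1, off), "CGA", substr(s, off + 4, L))
  }, "")
  prof <- window_substitution_profile(model, seqs, w = 7, n_random = 8,
                                      seed = 5)
  expect_length(prof, L - 7 + 1)
  overlap <- (off - 6):(off + 2) + 1  # starts whose window touches the 3-mer
  expect_true(all(prof[overlap] > 0.5))
  expect_true(all(abs(prof[-overlap]) < 0.1))

  # constant model -> all-zero profile
  prof0 <- window_substitution_profile(function(s) rep(1, length(s)),
                                       seqs, w = 7, n_random = 2, seed = 6)
  expect_equal(prof0, rep(0, L - 6))
})

test_that("mutation maps obey the closed form of a G-counting model", {
  L <- 30
  model <- function(seqs) {
    vapply(seqs, function(s) {
      sum(strsplit(s, "", fixed = TRUE)[[1]] == "G") / nchar(s)
    }, numeric(1), USE.NAMES = FALSE)
  }
  seq <- random_seq(L, seed = 7)
  mm <- mutation_map(model, seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(L)) {
    if (chars[i] == "G") {
      expect_equal(unname(mm$matrix["A", i]), -1 / L)
      expect_equal(unname(mm$matrix["G", i]), 0)
    } else {
      expect_equal(unname(mm$matrix["G", i]), 1 / L)
      expect_equal(unname(mm$matrix[chars[i], i]), 0)
    }
  }
  # constant model gives the zero matrix
  mz <- mutation_map(function(s) rep(0.5, length(s)), seq)
  expect_equal(mz$matrix, matrix(0, 4, L,
                                 dimnames = list(c("A", "C", "G", "T"),
                                                 NULL)))
  # exactly 3L evaluations plus one reference
  counter <- local({
    n <- 0L
    function(seqs) {
      n <<- n + length(seqs)
      assign("eval_count", n, envir = globalenv())
      rep(0.5, length(seqs))
    }
  })
  mutation_map(counter, seq)
  expect_equal(get("eval_count", envir = globalenv()), 3L * L + 1L)
  rm("eval_count", envir = globalenv())
})

test_that("k-means clustering separates distinct map families", {
  set.seed(8)
  M1 <- matrix(rnorm(40), 4)
  M2 <- M1 + 10
  maps <- c(replicate(25, M1 + matrix(rnorm(40, 0, 0.01), 4),
                      simplify = FALSE),
            replicate(15, M2 + matrix(rnorm(40, 0, 0.01), 4),
                      simplify = FALSE))
  cl <- cluster_maps(maps, k = 2, seed = 9)
  expect_equal(cl$sizes, c(25, 15))
  expect_equal(sum(cl$sizes), length(maps))
  expect_true(all(cl$labels[1:25] == 1))
  expect_true(all(cl$labels[26:40] == 2))
  expect_equal(cl$cluster_means[[1]], M1, tolerance = 0.02)
  expect_equal(cl$cluster_means[[2]], M2, tolerance = 0.02)

  cl2 <- cluster_maps(maps, k = 2, seed = 9)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_maps(maps[1:5], k = 10), "at least k")
})

test_that("pair dependency maps vanish for additive models", {
  L <- 25
  model <- make_linear_model(L)
  seq <- random_seq(L, seed = 10)
  dm <- pair_dependency_map(model, seq, region = 5:19)
  expect_lt(max(abs(dm$V)), 1e-8)
  expect_equal(dm$V, t(dm$V))
  expect_equal(diag(dm$V), rep(0, 15))
  expect_error(pair_dependency_map(model, seq, region = c(5, 30)),
               "outside")
})

test_that("pair dependency maps expose a planted equality interaction", {
  L <- 25
  p1 <- 8L; p2 <- 17L  # 0-based positions
  model <- function(seqs) {
    as.numeric(substr(seqs, p1 + 1, p1 + 1) == substr(seqs, p2 + 1, p2 + 1))
  }
  seq <- paste0(random_seq(L - 1, seed = 11), "A")
  substr(seq, p1 + 1, p1 + 1) <- "C"
  substr(seq, p2 + 1, p2 + 1) <- "C"
  dm <- pair_dependency_map(model, seq, region = c(5:19))
  V <- abs(dm$V)
  idx <- which(V == max(V), arr.ind = TRUE)[1, ]
  got <- sort(dm$positions[idx])
  expect_equal(got, c(p1, p2))
  # brute-force oracle for the planted pair's V entry:
  # delta(i) = mean over 3 alts of score change = -1 each (score 1 -> 0)
  # delta(i,j) = mean over 9 pairs: 3 of 9 keep equality -> -6/9
  i <- which(dm$positions == p1)
  j <- which(dm$positions == p2)
  expect_equal(dm$V[i, j], (-6 / 9) - (-1) - (-1), tolerance = 1e-12)
})

test_that("pair-map single deltas agree with mutation-map column means", {
  L <- 21
  model <- stub_gc_model
  seq <- random_seq(L, seed = 12)
  dm <- pair_dependency_map(model, seq, region = 3:10)
  mm <- mutation_map(model, seq)
  for (k in seq_along(dm$positions)) {
    col <- dm$positions[k] + 1L
    expect_equal(dm$delta1[k], sum(mm$matrix[, col]) / 3, tolerance = 1e-10)
  }
})

test_that("region dependency detects joint motif requirements", {
  L <- 60
  # additive model: D within Monte-Carlo noise of zero
  add <- make_linear_model(L, seed = 13)
  seq <- random_seq(L, seed = 14)
  D <- region_dependency(add, seq, c(5, 10), c(30, 35), n_random = 64,
                         seed = 15)
  expect_lt(abs(D), 0.06)  # ~3x the Monte-Carlo standard error here

  # conjunctive model: score 1 iff both spans keep their planted motifs
  s2 <- paste0(substr(seq, 1, 5), "AACCG",
               substr(seq, 11, 30), "GGTAT", substr(seq, 36, L))
  conj <- function(seqs) {
    as.numeric(substr(seqs, 6, 10) == "AACCG" &
                 substr(seqs, 31, 35) == "GGTAT")
  }
  D2 <- region_dependency(conj, s2, c(5, 9), c(30, 34), n_random = 32,
                          seed = 16)
  expect_gt(D2, 0.9)  # removing either span alone already zeroes the score
  D2r <- region_dependency(conj, s2, c(30, 34), c(5, 9), n_random = 32,
                           seed = 16)
  expect_equal(D2, D2r, tolerance = 0.1)
  expect_error(region_dependency(conj, s2, c(5, 9), c(8, 12)), "disjoint")
})

test_that("independence test separates interacting from additive models", {
  set.seed(17)
  pa <- consensus_pwm("TTAACC", "A")
  pb <- consensus_pwm("GGATTA", "B")
  L <- 80
  seqs <- vapply(1:25, function(i) {
    s <- random_seq(L)
    s <- paste0(substr(s, 1, 10), "TTAACC", substr(s, 17, 44), "GGATTA",
                substr(s, 51, L))
    s
  }, "")
  inter <- function(seqs) {
    as.numeric(grepl("TTAACC", seqs) & grepl("GGATTA", seqs))
  }
  res <- independence_test(inter, seqs, pa, pb, n_random = 6, seed = 18)
  expect_lt(res$p_value, 0.01)
  expect_gte(res$n, 3)

  add <- make_linear_model(L, seed = 19)
  res0 <- independence_test(add, seqs, pa, pb, n_random = 6, seed = 18)
  expect_gt(res0$p_value, 1e-4)

  expect_error(independence_test(inter, seqs[1:2], pa, pb),
               "fewer than 3")
})
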