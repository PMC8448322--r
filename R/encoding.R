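# Window extraction, one-hot encoding, shift augmentation, and the
# dynamic negative-set store.

#' One-hot encode a DNA sequence
#'
#' A/C/G/T map to unit columns (row order A, C, G, T); N maps to an
#' all-zero column so that padding never imitates real signal.
#'
#' @param seq string over A, C, G, T, N.
#' @return a 4 x nchar(seq) numeric matrix with rownames A, C, G, T.
#' @export
one_hot <- function(seq) {
  codes <- seq_codes(seq)
  if (any(!codes %in% 1:5) ||
      grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  L <- length(codes)
  m <- matrix(0, 4L, L, dimnames = list(BASES, NULL))
  keep <- codes <= 4L
  m[cbind(codes[keep], which(keep))] <- 1
  m
}

#' Extract a fixed-length window centered on a position
#'
#' Returns `genome[center - (L-1)/2 .. center + (L-1)/2]` (0-based,
#' inclusive); overhang beyond the chromosome is padded with N.
#'
#' @param g a [genome].
#' @param chrom chromosome name.
#' @param center 0-based center position.
#' @param L odd window length in bp.
#' @return a string of length `L`.
#' @export
extract_window <- function(g, chrom, center, L = 1001L) {
  stopifnot(inherits(g, "genome"))
  if (L %% 2L == 0L) stop("window length must be odd")
  if (!chrom %in% names(g$chroms)) stop("unknown chromosome: ", chrom)
  len <- g$lengths[[chrom]]
  half <- (L - 1L) %/% 2L
  lo <- center - half
  hi <- center + half
  lo_c <- max(lo, 0L)
  hi_c <- min(hi, len - 1L)
  body <- if (lo_c <= hi_c) substr(g$chroms[[chrom]], lo_c + 1L, hi_c + 1L) else ""
  paste0(strrep("N", lo_c - lo), body, strrep("N", hi - hi_c))
}

# Fast path used by the scanner and trainer: one-hot encode many windows
# of a pre-coded chromosome (integer codes from seq_codes()) into a single
# (4*L) x B matrix, N/overhang as zero columns.
encode_centers <- function(codes, centers, L) {
  half <- (L - 1L) %/% 2L
  B <- length(centers)
  idx <- outer(seq.int(-half, half), as.integer(centers), "+") + 1L  # L x B
  inb <- idx >= 1L & idx <= length(codes)
  cval <- matrix(5L, L, B)
  cval[inb] <- codes[idx[inb]]
  X <- matrix(0, 4L * L, B)
  keep <- which(cval <= 4L)
  if (length(keep)) {
    rowpos <- (keep - 1L) %/% L + 1L      # batch column
    lpos <- (keep - 1L) %% L + 1L         # position within window
    X[cbind(cval[keep] + 4L * (lpos - 1L), rowpos)] <- 1
  }
  X
}

encode_seqs <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("all windows must have equal length")
  X <- matrix(0, 4L * L, length(seqs))
  for (j in seq_along(seqs)) {
    codes <- seq_codes(seqs[[j]])
    keep <- which(codes <= 4L)
    X[codes[keep] + 4L * (keep - 1L), j] <- 1
  }
  X
}

#' Randomly shift a window center
#'
#' Draws a fresh uniform integer offset in `[-max_shift, max_shift]` each
#' call; re-drawn every epoch during training, this virtually enlarges the
#' negative set so it cannot be memorized.
#'
#' @param center 0-based center position(s).
#' @param max_shift maximum absolute shift in bp (>= 0).
#' @return shifted center(s).
#' @export
shift_sample <- function(center, max_shift) {
  if (max_shift < 0L) stop("max_shift must be >= 0")
  if (max_shift == 0L) return(center)
  center + sample.int(2L * max_shift + 1L, length(center),
                      replace = TRUE) - max_shift - 1L
}

#' Create a negative-set store
#'
#' @param entries data frame with columns `chrom`, `pos`, `iteration`
#'   (mining iteration at which the position was found; 0 for the initial
#'   random draw).
#' @param margin exclusion margin around truth elements in bp.
#' @return an object of class `negative_set`.
#' @export
negative_set <- function(entries = data.frame(chrom = character(),
                                              pos = integer(),
                                              iteration = integer()),
                         margin = 500L) {
  stopifnot(is.data.frame(entries),
            all(c("chrom", "pos", "iteration") %in% names(entries)))
  structure(list(entries = entries, margin = as.integer(margin)),
            class = "negative_set")
}

#' @export
print.negative_set <- function(x, ...) {
  cat("negative_set:", nrow(x$entries), "position(s), margin",
      x$margin, "bp\n")
  if (nrow(x$entries)) {
    print(table(iteration = x$entries$iteration))
  }
  invisible(x)
}

# Minimum distance from each query position to any truth element on the
# same chromosome (Inf when the chromosome carries no truth).
min_truth_distance <- function(chrom, pos, truth) {
  out <- rep(Inf, length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    tp <- sort(truth$pos[truth$chrom == cn])
    if (length(tp) == 0L) next
    p <- pos[sel]
    i <- findInterval(p, tp)
    d_lo <- ifelse(i >= 1L, p - tp[pmax(i, 1L)], Inf)
    d_hi <- ifelse(i < length(tp), tp[pmin(i + 1L, length(tp))] - p, Inf)
    out[sel] <- pmin(abs(d_lo), abs(d_hi))
  }
  out
}

#' Draw the initial random negative set
#'
#' Uniform random genomic positions at least `margin` bp from every truth
#' element; deterministic per seed.
#'
#' @param g a [genome].
#' @param truth an [annotation_set].
#' @param n number of negatives to draw.
#' @param margin exclusion margin in bp.
#' @param seed integer seed.
#' @return a [negative_set].
#' @export
build_initial_negatives <- function(g, truth, n, margin = 500L, seed = 1L) {
  stopifnot(inherits(g, "genome"))
  if (margin < 0L) stop("margin must be >= 0")
  set.seed(seed)
  lens <- g$lengths
  chrom_names <- names(g$chroms)
  acc_chrom <- character(0)
  acc_pos <- integer(0)
  tries <- 0L
  while (length(acc_pos) < n && tries < 60L) {
    tries <- tries + 1L
    m <- 2L * n
    ci <- sample.int(length(lens), m, replace = TRUE,
                     prob = lens / sum(lens))
    p <- floor(stats::runif(m) * lens[ci])
    keep <- min_truth_distance(chrom_names[ci], p, truth) > margin
    acc_chrom <- c(acc_chrom, chrom_names[ci][keep])
    acc_pos <- c(acc_pos, as.integer(p[keep]))
    dup <- duplicated(paste(acc_chrom, acc_pos))
    acc_chrom <- acc_chrom[!dup]
    acc_pos <- acc_pos[!dup]
  }
  if (length(acc_pos) < n) {
    stop("cannot place ", n, " negatives outside the ", margin,
         " bp margin; only ", length(acc_pos), " positions found")
  }
  negative_set(data.frame(chrom = acc_chrom[seq_len(n)],
                          pos = acc_pos[seq_len(n)],
                          iteration = 0L, stringsAsFactors = FALSE),
               margin = margin)
}

#' Add mined hard negatives to a negative set
#'
#' Positions within `margin` of a truth element are excluded; positions
#' within 25 bp of an existing entry are collapsed onto that entry, so the
#' set grows monotonically and stays duplicate-free across iterations.
#'
#' @param negset a [negative_set].
#' @param fps data frame of false-positive positions with columns `chrom`
#'   and `pos` (typically scanner output).
#' @param truth an [annotation_set].
#' @param margin exclusion margin in bp.
#' @param iteration mining iteration tag recorded with the new entries.
#' @param dedupe_radius collapse radius in bp.
#' @return the updated [negative_set].
#' @export
add_hard_negatives <- function(negset, fps, truth, margin = 500L,
                               iteration = 1L, dedupe_radius = 25L) {
  stopifnot(inherits(negset, "negative_set"))
  if (nrow(fps) == 0L) return(negset)
  keep <- min_truth_distance(fps$chrom, fps$pos, truth) > margin
  fps <- fps[keep, , drop = FALSE]
  existing <- negset$entries
  added <- list()
  for (r in seq_len(nrow(fps))) {
    cn <- fps$chrom[r]
    p <- fps$pos[r]
    near_old <- any(existing$chrom == cn & abs(existing$pos - p) <= dedupe_radius)
    if (near_old) next
    near_new <- length(added) > 0L &&
      any(vapply(added, function(a) a$chrom == cn &&
                   abs(a$pos - p) <= dedupe_radius, logical(1)))
    if (near_new) next
    added[[length(added) + 1L]] <- list(chrom = cn, pos = as.integer(p))
  }
  if (length(added)) {
    new_df <- data.frame(
      chrom = vapply(added, `[[`, "", "chrom"),
      pos = vapply(added, function(a) a$pos, integer(1)),
      iteration = as.integer(iteration), stringsAsFactors = FALSE)
    negset$entries <- rbind(negset$entries, new_df)
  }
  negset
}

#' Specify a chromosome-held-out train/validation split
#'
#' Test chromosomes are excluded entirely; the remaining positives are
#' split 90/10 into training and validation by default.
#'
#' @param test_chroms character vector of held-out chromosome names.
#' @param train_fraction fraction of non-test elements used for training.
#' @param seed integer seed for the split.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(test_chroms, train_fraction = 0.9, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  structure(list(test_chroms = test_chroms,
                 train_fraction = train_fraction,
                 val_fraction = 1 - train_fraction, seed = seed),
            class = "split_spec")
}

# Split row indices of a data frame into train/val per a split_spec.
split_indices <- function(n, split) {
  set.seed(split$seed)
  n_train <- max(1L, floor(split$train_fraction * n))
  if (n < 2L) return(list(train = seq_len(n), val = integer()))
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[(n_train + 1L):n]))
}

#' Write a negative set as BED with a JSON iteration sidecar
#'
#' @param negset a [negative_set].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_negatives_bed <- function(negset, path) {
  e <- negset$entries
  lines <- if (nrow(e)) {
    sprintf("%s\t%d\t%d\tneg_%d\t0\t.", e$chrom, e$pos, e$pos + 1L,
            seq_len(nrow(e)))
  } else character()
  writeLines(lines, path)
  jsonlite::write_json(list(margin = negset$margin,
                            iteration = e$iteration),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
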