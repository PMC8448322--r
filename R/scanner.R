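# Genome-wide two-stage prediction: coarse sliding-window scan, fine
# position-specific refinement, distance filtering, strand assignment.

#' Configure the genome scanner
#'
#' @param stride coarse scan step in bp.
#' @param scan_threshold stage-1 trigger threshold (inclusive).
#' @param refine_span width of the region re-scanned at single-base step
#'   around each stage-1 hit.
#' @param refine_step refinement step (1 bp).
#' @param pred_threshold stage-2 acceptance threshold (inclusive).
#' @param min_separation minimum genomic distance between two retained
#'   predictions (non-maximum suppression radius).
#' @param window_len model window length in bp.
#' @param batch_size windows scored per forward pass.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(stride = 50L, scan_threshold = 0.5,
                        refine_span = 100L, refine_step = 1L,
                        pred_threshold = 0.5, min_separation = 500L,
                        window_len = 1001L, batch_size = 128L) {
  if (refine_span < stride) stop("refine_span must be >= stride")
  if (scan_threshold <= 0 || scan_threshold >= 1 ||
      pred_threshold <= 0 || pred_threshold >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  if (min_separation <= 0L) stop("min_separation must be > 0")
  structure(list(stride = as.integer(stride),
                 scan_threshold = scan_threshold,
                 refine_span = as.integer(refine_span),
                 refine_step = as.integer(refine_step),
                 pred_threshold = pred_threshold,
                 min_separation = as.integer(min_separation),
                 window_len = as.integer(window_len),
                 batch_size = as.integer(batch_size)),
            class = "scan_config")
}

# Score a set of centers on one chromosome with either a trained scorer
# (windows are encoded from pre-computed integer codes) or a stub function
# f(chrom, centers) -> scores, which tests use as a position oracle.
score_centers <- function(model, chrom, centers, codes, config,
                          fparams = NULL, prep = NULL) {
  if (is.function(model)) return(model(chrom, centers))
  n <- length(centers)
  out <- numeric(n)
  bs <- config$batch_size
  fparams <- fparams %||% nn_fold_eval(model$geom, model$params)
  use_fast <- !is.null(prep) && config$window_len > 2L * prep$ein
  for (s in seq(1L, n, by = bs)) {
    e <- min(s + bs - 1L, n)
    if (use_fast) {
      out[s:e] <- nn_scan_score(model$geom, fparams, model$config, prep,
                                codes, centers[s:e])[1L, ]
    } else {
      X <- encode_centers(codes, centers[s:e], config$window_len)
      out[s:e] <- nn_predict(model$geom, model$params, model$config, X,
                             fparams = fparams)[1L, ]
    }
  }
  out
}

#' Greedy distance filtering (non-maximum suppression)
#'
#' Candidates are sorted by score descending (ties: smaller position
#' first) and accepted greedily if at least `min_separation` bp from every
#' already-accepted candidate.
#'
#' @param candidates data frame with columns `pos` and `score`
#'   (one chromosome).
#' @param min_separation minimum retained distance in bp.
#' @return the accepted subset, sorted by position.
#' @export
distance_filter <- function(candidates, min_separation = 500L) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(-candidates$score, candidates$pos)
  cand <- candidates[ord, , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(accepted) == 0L ||
        all(abs(cand$pos[accepted] - cand$pos[i]) >= min_separation)) {
      accepted <- c(accepted, i)
    }
  }
  out <- cand[accepted, , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}

merge_intervals <- function(lo, hi) {
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  out_lo <- lo[1]; out_hi <- hi[1]
  if (length(lo) > 1L) {
    for (i in 2:length(lo)) {
      if (lo[i] <= out_hi[length(out_hi)] + 1L) {
        out_hi[length(out_hi)] <- max(out_hi[length(out_hi)], hi[i])
      } else {
        out_lo <- c(out_lo, lo[i])
        out_hi <- c(out_hi, hi[i])
      }
    }
  }
  cbind(out_lo, out_hi)
}

#' Scan a genome for regulatory elements
#'
#' Stage 1 slides the scan model at `stride` spacing across each
#' chromosome; around every hit, stage 2 re-scores each single-base center
#' in a `refine_span` window with the position-specific prediction model.
#' Candidates passing `pred_threshold` go through distance filtering, and
#' the survivors receive a strand call. Edge windows are N-padded;
#' chromosomes shorter than the model window are skipped with a warning.
#'
#' @param scan,prediction trained scorers (or stub functions
#'   `f(chrom, centers) -> scores`, used in tests).
#' @param strand a strand-role scorer, a stub function
#'   `f(chrom, centers) -> strand characters`, or `NULL` (all strands
#'   reported as `"."`).
#' @param g a [genome].
#' @param config a [scan_config()].
#' @param chroms optional subset of chromosome names to scan.
#' @return data frame with columns `chrom`, `pos`, `score`, `strand`,
#'   sorted by (chrom, pos); score is always the prediction-model score at
#'   that exact center.
#' @export
scan_genome <- function(scan, prediction, strand = NULL, g,
                        config = scan_config(), chroms = NULL) {
  stopifnot(inherits(g, "genome"))
  L <- config$window_len
  half <- (L - 1L) %/% 2L
  use <- chroms %||% names(g$chroms)
  fold_scan <- if (!is.function(scan)) {
    nn_fold_eval(scan$geom, scan$params)
  }
  fold_pred <- if (!is.function(prediction)) {
    nn_fold_eval(prediction$geom, prediction$params)
  }
  out <- list()
  for (chrom in use) {
    len <- g$lengths[[chrom]]
    if (is.null(len)) stop("unknown chromosome: ", chrom)
    if (len < L) {
      warning("chromosome ", chrom, " (", len,
              " bp) is shorter than the model window; skipped")
      next
    }
    codes <- if (is.function(scan) && is.function(prediction) &&
                 (is.null(strand) || is.function(strand))) {
      NULL
    } else {
      seq_codes(g$chroms[[chrom]])
    }
    prep_scan <- if (!is.function(scan) && len >= 2L * L) {
      nn_scan_prepare(scan$geom, fold_scan, scan$config, codes)
    }
    centers1 <- seq.int(half, len - 1L - half, by = config$stride)
    s1 <- score_centers(scan, chrom, centers1, codes, config,
                        fparams = fold_scan, prep = prep_scan)
    hits <- centers1[s1 >= config$scan_threshold]
    if (length(hits) == 0L) next
    span <- config$refine_span %/% 2L
    regions <- merge_intervals(pmax(hits - span, 0L),
                               pmin(hits + span, len - 1L))
    centers2 <- unlist(lapply(seq_len(nrow(regions)), function(i) {
      seq.int(regions[i, 1], regions[i, 2], by = config$refine_step)
    }))
    prep_pred <- if (!is.function(prediction) && len >= 2L * L) {
      nn_scan_prepare(prediction$geom, fold_pred, prediction$config, codes)
    }
    s2 <- score_centers(prediction, chrom, centers2, codes, config,
                        fparams = fold_pred, prep = prep_pred)
    keep <- s2 >= config$pred_threshold
    if (!any(keep)) next
    cand <- data.frame(pos = centers2[keep], score = s2[keep])
    cand <- distance_filter(cand, config$min_separation)
    str <- if (is.null(strand)) {
      rep(".", nrow(cand))
    } else if (is.function(strand)) {
      strand(chrom, cand$pos)
    } else {
      bs <- config$batch_size
      Ls <- strand$config$window_len  # the strand model has its own window
      calls <- character(nrow(cand))
      for (s in seq(1L, nrow(cand), by = bs)) {
        e <- min(s + bs - 1L, nrow(cand))
        X <- encode_centers(codes, cand$pos[s:e], Ls)
        calls[s:e] <- strand_call(strand, X)
      }
      calls
    }
    out[[chrom]] <- data.frame(chrom = chrom, pos = cand$pos,
                               score = cand$score, strand = str,
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[order(match(names(out), names(g$chroms)))])
  rownames(res) <- NULL
  res
}
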