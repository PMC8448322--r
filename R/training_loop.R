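# The iterative dynamic-negative-set training procedure: train the
# scan/prediction/strand models, scan the training chromosomes, feed
# confident false positives back into the negative set, repeat.

#' Configure training
#'
#' @param max_epochs maximum training epochs per model.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement); 0 stops after the first non-improving epoch.
#' @param batch_size minibatch size.
#' @param neg_ratio negatives sampled per positive in each epoch.
#' @param pos_repeats times each training positive appears per epoch
#'   (each appearance with a fresh shift draw); lifts the number of
#'   gradient steps per epoch when the positive set is small.
#' @param pos_shift_scan max random shift (bp) applied to positives when
#'   training the scan model: half the scan stride, so a stride-aligned
#'   window always has the TSS within the trained tolerance.
#' @param pos_shift_pred max shift for positives of the position-specific
#'   prediction model; a few bp of jitter preserves augmentation
#'   diversity while keeping calls within a few bp of the true TSS.
#' @param neg_shift max random shift applied to random-pool negatives
#'   every epoch, which makes the negative set effectively impossible to
#'   memorize.
#' @param hard_neg_shift max per-epoch shift for mined hard negatives; a
#'   small jitter that defeats memorization without moving the
#'   confusable locus out of the window.
#' @param margin exclusion margin (bp) between any training negative and
#'   any truth element, enforced after shifting.
#' @param neg_cap_ratio per-iteration cap on newly mined negatives, as a
#'   multiple of the positive count (sampled proportional to score when
#'   over the cap).
#' @param seed integer seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(max_epochs = 30L, patience = 5L, batch_size = 32L,
                         neg_ratio = 2, pos_repeats = 3L,
                         pos_shift_scan = 25L,
                         pos_shift_pred = 5L, neg_shift = 250L,
                         hard_neg_shift = 50L,
                         margin = 500L, neg_cap_ratio = 2, seed = 1L) {
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 neg_ratio = neg_ratio,
                 pos_repeats = as.integer(pos_repeats),
                 pos_shift_scan = as.integer(pos_shift_scan),
                 pos_shift_pred = as.integer(pos_shift_pred),
                 neg_shift = as.integer(neg_shift),
                 hard_neg_shift = as.integer(hard_neg_shift),
                 margin = as.integer(margin),
                 neg_cap_ratio = neg_cap_ratio,
                 seed = as.integer(seed)),
            class = "train_config")
}

subset_genome <- function(g, chroms) {
  genome(g$chroms[chroms])
}

# Default strand-model geometry: the transcription-orientation signal
# lives in the core promoter, so a 201 bp window with gentle pooling
# beats the wide, heavily pooled detection geometry.
default_strand_config <- function(mconfig) {
  cfg <- mconfig
  cfg$window_len <- min(201L, mconfig$window_len)
  cfg$pool <- rep_len(c(4L, 2L, 2L), mconfig$n_res_blocks)
  cfg$lr <- max(mconfig$lr, 3e-3)
  cfg$n_outputs <- 3L
  cfg
}

# Encode windows at (chrom, center) pairs from cached integer codes.
encode_positions <- function(codes_list, chrom, centers, L) {
  X <- matrix(0, 4L * L, length(centers))
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    X[, sel] <- encode_centers(codes_list[[cn]], centers[sel], L)
  }
  X
}

# Shift negatives, redrawing when a shift lands within the margin of a
# truth element (so no training negative ever violates the margin).
shift_negatives <- function(chrom, pos, max_shift, truth, margin) {
  if (max_shift == 0L) return(pos)
  shifted <- shift_sample(pos, max_shift)
  for (try in 1:10) {
    bad <- min_truth_distance(chrom, shifted, truth) <= margin
    if (!any(bad)) break
    shifted[bad] <- shift_sample(pos[bad], max_shift)
  }
  bad <- min_truth_distance(chrom, shifted, truth) <= margin
  shifted[bad] <- pos[bad]
  shifted
}

#' Train the scan, prediction and strand models
#'
#' Positives are the truth elements outside the held-out test
#' chromosomes, split train/validation per `split`. Each epoch re-draws
#' the shift augmentation and re-samples negatives at `neg_ratio` per
#' positive. Early stopping is on validation loss; the best-validation
#' checkpoint is returned. The strand model is trained on positives only,
#' with labels +, -, . (enhancers).
#'
#' @param g a [genome].
#' @param truth an [annotation_set].
#' @param split a [split_spec()].
#' @param negset a [negative_set].
#' @param mconfig a [model_config()] (2 outputs; the strand model reuses
#'   it with 3 outputs).
#' @param tconfig a [train_config()].
#' @param strand_model optional pre-trained strand scorer to reuse
#'   (its training data does not change across mining iterations).
#' @param init_models optional list with `scan` and/or `prediction`
#'   scorers whose parameters warm-start this round of training
#'   (retraining against the updated negative set continues from them).
#' @param train_strand set `FALSE` to skip the strand model (runs that
#'   only need detection, e.g. mining-efficacy experiments).
#' @param strand_config optional [model_config()] for the strand model.
#'   The default uses a 201 bp window with finer pooling: the orientation
#'   signal (TATA side, Initiator direction) is local and fine-grained,
#'   and survives a high-resolution head far better than the coarse
#'   detection geometry.
#' @param verbose print per-epoch progress.
#' @return list with trained scorers `scan`, `prediction`, `strand` and a
#'   `report` of per-model validation metrics.
#' @export
train_models <- function(g, truth, split, negset, mconfig = model_config(),
                         tconfig = train_config(), strand_model = NULL,
                         init_models = NULL, train_strand = TRUE,
                         strand_config = NULL, verbose = FALSE) {
  stopifnot(inherits(g, "genome"), inherits(split, "split_spec"),
            inherits(negset, "negative_set"))
  if (!all(split$test_chroms %in% names(g$chroms))) {
    stop("test chromosome(s) not in genome: ",
         paste(setdiff(split$test_chroms, names(g$chroms)), collapse = ", "))
  }
  L <- mconfig$window_len
  pos <- truth[!truth$chrom %in% split$test_chroms, , drop = FALSE]
  neg <- negset$entries[!negset$entries$chrom %in% split$test_chroms, ,
                        drop = FALSE]
  if (nrow(pos) == 0L) stop("empty positive set after removing test chromosomes")
  if (nrow(neg) == 0L) stop("empty negative set after removing test chromosomes")
  psp <- split_indices(nrow(pos), split)
  nsplit <- split; nsplit$seed <- derive_seed(split$seed, 17L)
  nsp <- split_indices(nrow(neg), nsplit)
  pos_tr <- pos[psp$train, , drop = FALSE]
  pos_va <- pos[psp$val, , drop = FALSE]
  neg_tr <- neg[nsp$train, , drop = FALSE]
  neg_va <- neg[nsp$val, , drop = FALSE]
  train_chroms <- setdiff(names(g$chroms), split$test_chroms)
  codes <- lapply(g$chroms[train_chroms], seq_codes)

  margin <- tconfig$margin
  make_data_fn <- function(pos_shift) {
    function(epoch) {
      # RNG state is seeded per epoch by nn_fit
      reps <- max(1L, tconfig$pos_repeats)
      pchrom <- rep(pos_tr$chrom, reps)
      pc <- rep(pos_tr$pos, reps)
      if (pos_shift > 0L) pc <- shift_sample(pc, pos_shift)
      n_pos <- length(pc)
      n_neg <- max(1L, round(tconfig$neg_ratio * n_pos))
      # mined hard negatives are always in the epoch (they are the point
      # of the method); random-pool draws fill the remainder so easy
      # background stays covered
      hard <- which(neg_tr$iteration > 0L)
      rand <- which(neg_tr$iteration == 0L)
      n_hard <- min(length(hard), max(0L, n_neg - ceiling(n_neg / 3)))
      take_hard <- if (n_hard > 0L) sample(hard, n_hard) else integer()
      n_rand <- n_neg - n_hard
      take_rand <- if (n_rand > 0L && length(rand)) {
        sample(rand, n_rand, replace = n_rand > length(rand))
      } else integer()
      take <- c(take_hard, take_rand)
      nchrom <- neg_tr$chrom[take]
      # hard negatives keep a small jitter so the confusable locus stays
      # in view; random negatives roam widely
      sh <- c(rep(tconfig$hard_neg_shift, length(take_hard)),
              rep(tconfig$neg_shift, length(take_rand)))
      npos <- neg_tr$pos[take]
      for (s_ in unique(sh)) {
        sel <- sh == s_
        npos[sel] <- shift_negatives(nchrom[sel], npos[sel], s_,
                                     truth, margin)
      }
      X <- cbind(encode_positions(codes, pchrom, pc, L),
                 encode_positions(codes, nchrom, npos, L))
      list(X = X, y = c(rep(1L, n_pos), rep(2L, n_neg)))
    }
  }
  # validation uses every held-out negative (capped): with few positives
  # the early-stopping signal would otherwise be far too noisy to select
  # a well-calibrated checkpoint
  set.seed(derive_seed(tconfig$seed, 23L))
  vtake <- sample.int(nrow(neg_va), min(200L, nrow(neg_va)))
  val_X <- cbind(encode_positions(codes, pos_va$chrom, pos_va$pos, L),
                 encode_positions(codes, neg_va$chrom[vtake],
                                  neg_va$pos[vtake], L))
  val_y <- c(rep(1L, nrow(pos_va)), rep(2L, length(vtake)))
  val <- list(X = val_X, y = val_y, w = class_balanced_weights(val_y))

  fit_role <- function(role, pos_shift, seed_off) {
    cfg <- mconfig
    cfg$seed <- derive_seed(tconfig$seed, seed_off)
    scorer <- build_model(cfg, role = role)
    init <- init_models[[role]]
    if (!is.null(init)) {
      if (!identical(init$config$window_len, cfg$window_len)) {
        stop("init model window length does not match the configuration")
      }
      scorer$params <- init$params
    }
    fit <- nn_fit(scorer$geom, scorer$params, scorer$config,
                  make_data_fn(pos_shift), val,
                  max_epochs = tconfig$max_epochs,
                  patience = tconfig$patience,
                  batch_size = tconfig$batch_size,
                  seed = derive_seed(tconfig$seed, seed_off + 1L),
                  verbose = verbose)
    scorer$params <- fit$params
    scorer$trained <- TRUE
    attr(scorer, "history") <- fit$history
    attr(scorer, "best_val_loss") <- fit$best_val_loss
    scorer
  }
  scan <- fit_role("scan", tconfig$pos_shift_scan, 101L)
  prediction <- fit_role("prediction", tconfig$pos_shift_pred, 202L)

  if (is.null(strand_model) && !train_strand) {
    strand <- NULL
  } else if (is.null(strand_model)) {
    scfg <- strand_config %||% default_strand_config(mconfig)
    scfg$n_outputs <- 3L
    scfg$seed <- derive_seed(tconfig$seed, 303L)
    Ls <- scfg$window_len
    strand_labels <- function(strand) match(strand, c("+", "-", "."))
    strand_data <- function(epoch) {
      # jitter augmentation; orientation features are fine-grained, so
      # the strand model needs the same diversity lift as the others
      reps <- max(1L, tconfig$pos_repeats)
      idx <- rep(seq_len(nrow(pos_tr)), reps)
      ctr <- shift_sample(pos_tr$pos[idx], max(tconfig$pos_shift_pred, 5L))
      list(X = encode_positions(codes, pos_tr$chrom[idx], ctr, Ls),
           y = strand_labels(pos_tr$strand[idx]))
    }
    sval <- if (nrow(pos_va)) {
      list(X = encode_positions(codes, pos_va$chrom, pos_va$pos, Ls),
           y = strand_labels(pos_va$strand))
    } else {
      list(X = encode_positions(codes, pos_tr$chrom, pos_tr$pos, Ls),
           y = strand_labels(pos_tr$strand))
    }
    sval$w <- class_balanced_weights(sval$y)
    strand <- build_model(scfg, role = "strand")
    sfit <- nn_fit(strand$geom, strand$params, strand$config, strand_data,
                   sval, max_epochs = tconfig$max_epochs,
                   patience = tconfig$patience,
                   batch_size = tconfig$batch_size,
                   seed = derive_seed(tconfig$seed, 304L),
                   verbose = verbose)
    strand$params <- sfit$params
    strand$trained <- TRUE
    attr(strand, "history") <- sfit$history
  } else {
    strand <- strand_model
  }
  report <- list(
    scan_val_loss = attr(scan, "best_val_loss"),
    pred_val_loss = attr(prediction, "best_val_loss"),
    scan_val_acc = utils::tail(attr(scan, "history")$val_acc, 1),
    pred_val_acc = utils::tail(attr(prediction, "history")$val_acc, 1),
    n_pos_train = nrow(pos_tr), n_neg_pool = nrow(neg_tr))
  list(scan = scan, prediction = prediction, strand = strand,
       report = report)
}

#' Mine hard negatives from a genome scan
#'
#' Runs the two-stage scanner over the training chromosomes; every
#' prediction farther than `margin` from all truth elements is a
#' confident false positive and is added to the negative set (capped and
#' deduplicated; see [add_hard_negatives()]).
#'
#' @param models list with trained `scan` and `prediction` scorers (stub
#'   functions also accepted, as in [scan_genome()]).
#' @param g a [genome].
#' @param truth an [annotation_set].
#' @param negset the current [negative_set].
#' @param threshold prediction-model decision threshold for mining.
#' @param margin truth exclusion margin in bp.
#' @param chroms chromosomes to scan (training chromosomes).
#' @param sconfig a [scan_config()].
#' @param cap maximum number of negatives added this iteration (`Inf` to
#'   disable); when exceeded, kept with probability proportional to score.
#' @param iteration iteration tag stored with new entries.
#' @param seed seed for the over-cap subsample.
#' @return list with the updated `negset` and a `report` (iteration,
#'   negatives_added, n_flagged).
#' @export
mine_hard_negatives <- function(models, g, truth, negset, threshold = 0.5,
                                margin = 500L, chroms = NULL,
                                sconfig = scan_config(), cap = Inf,
                                iteration = 1L, seed = 1L) {
  sconfig$pred_threshold <- threshold
  preds <- scan_genome(models$scan, models$prediction, NULL, g,
                       sconfig, chroms)
  fps <- preds[min_truth_distance(preds$chrom, preds$pos, truth) > margin, ,
               drop = FALSE]
  n_flagged <- nrow(fps)
  if (is.finite(cap) && nrow(fps) > cap) {
    set.seed(seed)
    take <- sample.int(nrow(fps), cap, prob = fps$score)
    fps <- fps[sort(take), , drop = FALSE]
  }
  before <- nrow(negset$entries)
  negset <- add_hard_negatives(negset, fps, truth, margin, iteration)
  list(negset = negset,
       report = list(iteration = iteration,
                     negatives_added = nrow(negset$entries) - before,
                     n_flagged = n_flagged))
}

#' Run the full iterative hard-negative training loop
#'
#' Alternates model training and hard-negative mining for `n_iterations`
#' rounds, evaluating each round's models on the held-out test
#' chromosomes. With `n_iterations = 1` this reduces to plain training on
#' the initial random negative set.
#'
#' @param g a [genome].
#' @param truth an [annotation_set].
#' @param n_iterations number of train/mine rounds (>= 1).
#' @param split a [split_spec()] naming the held-out chromosomes.
#' @param mconfig,tconfig,sconfig model / training / scanner
#'   configurations.
#' @param n_initial_negatives size of the iteration-0 random negative set
#'   (default: 10 per training positive).
#' @param evaluate_iterations `TRUE` to evaluate held-out performance at
#'   every iteration, `FALSE` for the final iteration only, or an integer
#'   vector of iterations to evaluate (the final iteration is always
#'   evaluated).
#' @param train_strand passed to [train_models()]; `FALSE` skips the
#'   strand model.
#' @param verbose print progress.
#' @return list with `models` (final iteration), `negset`, and `reports`
#'   (one per iteration: training report, mining report, held-out
#'   `eval_report`).
#' @export
run_iterative_training <- function(g, truth, n_iterations = 3L,
                                   split, mconfig = model_config(),
                                   tconfig = train_config(),
                                   sconfig = scan_config(),
                                   n_initial_negatives = NULL,
                                   evaluate_iterations = TRUE,
                                   train_strand = TRUE,
                                   verbose = FALSE) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  train_chroms <- setdiff(names(g$chroms), split$test_chroms)
  if (length(train_chroms) == 0L) stop("no training chromosomes left")
  n_pos <- sum(!truth$chrom %in% split$test_chroms)
  n_init <- n_initial_negatives %||% (10L * n_pos)
  g_train <- subset_genome(g, train_chroms)
  negset <- build_initial_negatives(g_train, truth, n_init,
                                    margin = tconfig$margin,
                                    seed = derive_seed(tconfig$seed, 7L))
  test_span <- sum(g$lengths[split$test_chroms])
  truth_test <- truth[truth$chrom %in% split$test_chroms, , drop = FALSE]
  reports <- vector("list", n_iterations)
  models <- NULL
  for (i in seq_len(n_iterations)) {
    tcfg_i <- tconfig
    tcfg_i$seed <- derive_seed(tconfig$seed, 1000L * i)
    if (verbose) message("iteration ", i, ": training (",
                         nrow(negset$entries), " negatives in pool)")
    models <- train_models(g, truth, split, negset, mconfig, tcfg_i,
                           strand_model = models$strand,
                           init_models = models[c("scan", "prediction")],
                           train_strand = train_strand,
                           verbose = verbose)
    rep_i <- list(iteration = i, train = models$report,
                  negatives_pool = nrow(negset$entries))
    eval_this <- if (is.logical(evaluate_iterations)) {
      isTRUE(evaluate_iterations)
    } else {
      i %in% evaluate_iterations
    }
    if (eval_this || i == n_iterations) {
      if (verbose) message("iteration ", i, ": held-out evaluation")
      preds <- scan_genome(models$scan, models$prediction, models$strand,
                           g, sconfig, chroms = split$test_chroms)
      rep_i$eval <- evaluate_predictions(preds, truth_test, test_span,
                                         margin = tconfig$margin)
      rep_i$heldout_predictions <- preds
    }
    if (i < n_iterations) {
      if (verbose) message("iteration ", i, ": mining hard negatives")
      mined <- mine_hard_negatives(
        models, g, truth, negset, threshold = sconfig$pred_threshold,
        margin = tconfig$margin, chroms = train_chroms, sconfig = sconfig,
        cap = ceiling(tconfig$neg_cap_ratio * n_pos), iteration = i,
        seed = derive_seed(tconfig$seed, 2000L + i))
      negset <- mined$negset
      rep_i$mining <- mined$report
    } else {
      rep_i$mining <- list(iteration = i, negatives_added = 0L,
                           n_flagged = NA_integer_)
    }
    reports[[i]] <- rep_i
  }
  list(models = models, negset = negset, reports = reports)
}
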