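# Training-loop behavior is verified with stub scorers where possible;
# the end-to-end mining-efficacy experiment lives in the acceptance
# suite.

mk_sim <- function(seed = 3) {
  generate_genome(grammar_spec(), n_chroms = 2, chrom_len = 40000,
                  n_promoters = 8, n_enhancers = 2, seed = seed)
}

test_that("mining with oracle stubs flags exactly the unannotated decoys", {
  sim <- mk_sim()
  negset <- negative_set()
  # stubs that fire precisely on planted decoys
  scan_stub <- oracle_scorer(sim$decoys, radius = 25)
  pred_stub <- oracle_scorer(sim$decoys, radius = 0)
  mined <- mine_hard_negatives(list(scan = scan_stub,
                                    prediction = pred_stub),
                               sim$genome, sim$truth, negset)
  expect_equal(mined$report$negatives_added, nrow(sim$decoys))
  got <- mined$negset$entries
  expect_setequal(paste(got$chrom, got$pos),
                  paste(sim$decoys$chrom, sim$decoys$pos))
  d <- regscan:::min_truth_distance(got$chrom, got$pos, sim$truth)
  expect_true(all(d > 500))

  # a second identical pass adds nothing (dedupe)
  mined2 <- mine_hard_negatives(list(scan = scan_stub,
                                     prediction = pred_stub),
                                sim$genome, sim$truth, mined$negset,
                                iteration = 2)
  expect_equal(mined2$report$negatives_added, 0)

  # silent models add nothing
  silent <- function(chrom, centers) numeric(length(centers))
  mined3 <- mine_hard_negatives(list(scan = silent, prediction = silent),
                                sim$genome, sim$truth, negset)
  expect_equal(mined3$report$negatives_added, 0)
})

test_that("mining respects the per-iteration cap", {
  sim <- mk_sim(seed = 5)
  mined <- mine_hard_negatives(
    list(scan = oracle_scorer(sim$decoys, 25),
         prediction = oracle_scorer(sim$decoys, 0)),
    sim$genome, sim$truth, negative_set(), cap = 3, seed = 2)
  expect_equal(mined$report$negatives_added, 3)
  expect_equal(mined$report$n_flagged, nrow(sim$decoys))
})

test_that("train_models validates inputs and produces working scorers", {
  sim <- mk_sim(seed = 7)
  split <- split_spec("chr1", seed = 1)
  negset <- build_initial_negatives(regscan:::subset_genome(sim$genome, "chr2"),
                                    sim$truth, 60, seed = 2)
  mcfg <- model_config(window_len = 101L, n_res_blocks = 2L,
                       channels = c(4L, 8L), pool = c(4L, 4L), seed = 1)
  tcfg <- train_config(max_epochs = 2, patience = 0, seed = 4)
  models <- train_models(sim$genome, sim$truth, split, negset, mcfg, tcfg)
  expect_s3_class(models$scan, "scorer")
  expect_s3_class(models$prediction, "scorer")
  expect_equal(models$strand$config$n_outputs, 3L)
  expect_true(models$scan$trained)
  s <- score_batch(models$scan, replicate(3, random_seq(101)))
  expect_true(all(s >= 0 & s <= 1))

  expect_error(train_models(sim$genome, sim$truth,
                            split_spec("nope"), negset, mcfg, tcfg),
               "not in genome")
  expect_error(train_models(sim$genome, sim$truth,
                            split_spec(c("chr1", "chr2")), negset, mcfg,
                            tcfg),
               "empty positive set")
  expect_error(train_models(sim$genome, sim$truth, split, negative_set(),
                            mcfg, tcfg),
               "empty negative set")
})

test_that("training is reproducible for a fixed seed", {
  sim <- mk_sim(seed = 9)
  split <- split_spec("chr1", seed = 1)
  negset <- build_initial_negatives(regscan:::subset_genome(sim$genome, "chr2"),
                                    sim$truth, 40, seed = 2)
  mcfg <- model_config(window_len = 101L, n_res_blocks = 1L,
                       channels = 4L, pool = 4L, seed = 1)
  tcfg <- train_config(max_epochs = 2, patience = 0, seed = 4)
  m1 <- train_models(sim$genome, sim$truth, split, negset, mcfg, tcfg)
  m2 <- train_models(sim$genome, sim$truth, split, negset, mcfg, tcfg)
  expect_identical(m1$scan$params, m2$scan$params)
  expect_identical(m1$report, m2$report)
})

test_that("the iterative loop produces one report per iteration", {
  sim <- mk_sim(seed = 11)
  split <- split_spec("chr1", seed = 1)
  mcfg <- model_config(window_len = 101L, n_res_blocks = 1L,
                       channels = 4L, pool = 4L, seed = 1)
  tcfg <- train_config(max_epochs = 2, patience = 0, seed = 4)
  scfg <- scan_config(window_len = 101L, stride = 200L, refine_span = 200L)
  run <- run_iterative_training(sim$genome, sim$truth, n_iterations = 2,
                                split = split, mconfig = mcfg,
                                tconfig = tcfg, sconfig = scfg,
                                n_initial_negatives = 40)
  expect_length(run$reports, 2)
  expect_equal(vapply(run$reports, `[[`, 0L, "iteration"), 1:2)
  expect_s3_class(run$reports[[2]]$eval, "eval_report")
  # negative pool is non-decreasing across iterations
  pools <- vapply(run$reports, `[[`, 0L, "negatives_pool")
  expect_true(all(diff(pools) >= 0))
  expect_error(run_iterative_training(sim$genome, sim$truth, 0, split),
               ">= 1")
})

test_that("the strand model learns transcription orientation on held-out loci", {
  # strong-TATA grammar so orientation carries an 8-mer signature; the
  # strand model trains on chr2 and is probed on chr1 elements
  sim <- generate_genome(grammar_spec(promoter = list(tata_fraction = 1)),
                         n_chroms = 2, chrom_len = 300000,
                         n_promoters = 80, n_enhancers = 20, seed = 6)
  split <- split_spec("chr1", seed = 7)
  negset <- build_initial_negatives(
    regscan:::subset_genome(sim$genome, "chr2"), sim$truth, 200, seed = 8)
  mcfg <- model_config(window_len = 201L, pool = c(4L, 2L, 2L), seed = 9)
  tcfg <- train_config(max_epochs = 25, patience = 6, seed = 10)
  models <- train_models(sim$genome, sim$truth, split, negset, mcfg, tcfg)
  expect_equal(models$strand$config$window_len, 201L)
  truth1 <- sim$truth[sim$truth$chrom == "chr1", ]
  codes <- regscan:::seq_codes(sim$genome$chroms[["chr1"]])
  X <- regscan:::encode_centers(codes, truth1$pos,
                                models$strand$config$window_len)
  calls <- strand_call(models$strand, X)
  prom <- truth1$class == "promoter"
  acc <- mean(calls[prom] == truth1$strand[prom])
  # well above random orientation assignment; desk-scale training data
  # bounds how far above (see the methods vignette)
  expect_gte(acc, 0.55)
})
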