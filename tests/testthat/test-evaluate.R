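test_that("roc_score matches hand-computed and degenerate cases", {
  expect_identical(roc_score(c(2, 1, 0), c(1, 1, -1)), 1)
  expect_identical(roc_score(c(0, 1, 2), c(1, -1, 1)), 0.5)  # neg outranks one pos
  # one concordant pair of two
  expect_identical(roc_score(c(0.9, 0.7, 0.8), c(1, 1, -1)), 0.5)
  # ties count half
  expect_identical(roc_score(c(1, 1), c(1, -1)), 0.5)
  expect_error(roc_score(1:3, c(1, 1, 1)), "both")
})

test_that("roc and roc50 agree with brute-force curve construction", {
  set.seed(61)
  for (rep in 1:100) {
    n <- sample(10:120, 1)
    scores <- if (rep %% 3 == 0) sample(1:6, n, replace = TRUE)  # heavy ties
              else stats::rnorm(n)
    labels <- sample(c(1, -1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(1, -1)
    expect_equal(roc_score(scores, labels), brute_roc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(roc50_score(scores, labels), brute_roc50(scores, labels),
                 tolerance = 1e-12)
    expect_lte(roc50_score(scores, labels), 1)
  }
})

test_that("roc50 truncates at the 50th false positive", {
  # perfect separation and total failure
  expect_identical(roc50_score(c(5, 4, 3, 2, 1), c(1, 1, -1, -1, -1)), 1)
  expect_identical(roc50_score(c(5, 4, 3, 2, 1), c(-1, -1, -1, 1, 1)), 0)
  # vacuous truncation: roc50 == roc exactly whenever n_neg <= 50
  set.seed(62)
  for (rep in 1:20) {
    n_pos <- sample(3:30, 1)
    n_neg <- sample(2:50, 1)
    scores <- stats::rnorm(n_pos + n_neg)
    labels <- c(rep(1, n_pos), rep(-1, n_neg))
    expect_identical(roc50_score(scores, labels), roc_score(scores, labels))
  }
  # positives buried after 50 negatives contribute nothing
  scores <- c(seq(200, 1))  # strictly decreasing
  labels <- c(rep(-1, 60), rep(1, 20), rep(-1, 120))
  expect_identical(roc50_score(scores, labels), 0)
  # truncation matters: same ranking is penalised less by the full ROC
  expect_gt(roc_score(scores, labels), 0)
})

test_that("roc_score agrees with an established AUC implementation", {
  set.seed(65)
  for (rep in 1:10) {
    n <- sample(30:150, 1)
    scores <- stats::rnorm(n)
    labels <- sample(c(1, -1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(1, -1)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(-1, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_score(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("roc is invariant under strictly increasing transforms", {
  set.seed(63)
  scores <- stats::rnorm(200)
  labels <- sample(c(1, -1), 200, replace = TRUE)
  r <- roc_score(scores, labels)
  expect_equal(roc_score(exp(scores), labels), r, tolerance = 1e-12)
  expect_equal(roc_score(2 * scores + 7, labels), r, tolerance = 1e-12)
  expect_equal(roc50_score(exp(scores), labels),
               roc50_score(scores, labels), tolerance = 1e-12)
})

test_that("shuffled labels calibrate the null at ROC 0.5", {
  set.seed(64)
  rocs <- vapply(1:20, function(i) {
    scores <- stats::rnorm(10000)
    labels <- sample(rep(c(1, -1), 5000))
    roc_score(scores, labels)
  }, numeric(1))
  expect_lt(abs(mean(rocs) - 0.5), 0.02)
})

test_that("family_split enforces disjointness and file round trip works", {
  expect_error(family_split("f", "a", "a", "b", "c"), "disjoint")
  sp <- family_split("f1", c("a", "b"), "c", c("d", "e"), "f")
  expect_s3_class(sp, "family_split")
  path <- withr::local_tempfile(fileext = ".split")
  write_family_split(sp, path)
  back <- read_family_split(path)
  expect_identical(back, sp)
  writeLines(c("family: f2", "x1 pos-train", "x2 bad-role"), path)
  expect_error(read_family_split(path), "unknown role")
})

test_that("run_benchmark scores families and reports unweighted averages", {
  cfgs <- lapply(c(71, 72), function(s) synthetic_family_config(
    n_pos_train = 10, n_neg_train = 10, n_pos_test = 6, n_neg_test = 6,
    length_range = c(50L, 80L), insertions = 4L, seed = s))
  fams <- lapply(seq_along(cfgs), function(i)
    generate_family(cfgs[[i]], family_id = paste0("fam", i)))
  seqs <- do.call(c, lapply(fams, `[[`, "sequences"))
  profs <- do.call(c, lapply(fams, `[[`, "profiles"))
  splits <- lapply(fams, `[[`, "split")

  res <- run_benchmark(splits, sequences = seqs, profiles = profs,
                       mode = "dt", d_max = 8)
  expect_s3_class(res, "benchmark_result")
  expect_identical(nrow(res), 2L)
  expect_true(all(res$roc >= 0 & res$roc <= 1))
  expect_equal(attr(res, "mean_roc"), mean(res$roc))
  # strong planted signal separates the classes essentially perfectly
  expect_gte(attr(res, "mean_roc"), 0.95)

  # single family: averages equal that family's scores
  res1 <- run_benchmark(splits[[1]], sequences = seqs, profiles = profs,
                        mode = "dr", d_max = 8)
  expect_identical(attr(res1, "mean_roc"), res1$roc[1])
  expect_identical(attr(res1, "mean_roc50"), res1$roc50[1])

  # determinism: identical configs give identical results
  res2 <- run_benchmark(splits, sequences = seqs, profiles = profs,
                        mode = "dt", d_max = 8)
  expect_identical(res$roc, res2$roc)

  # missing id is reported with family and id
  bad <- family_split("famX", "nosuch", splits[[1]]$positive_test,
                      splits[[1]]$negative_train, splits[[1]]$negative_test)
  expect_error(run_benchmark(bad, sequences = seqs, profiles = profs,
                             mode = "dr", d_max = 4),
               "famX.*nosuch")

  # TSV export carries a summary row
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark_tsv(res, tsv)
  tab <- utils::read.delim(tsv)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$family_id[3], "summary")
  expect_equal(tab$roc[3], attr(res, "mean_roc"), tolerance = 1e-6)
})
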