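test_that("feature_index is the documented bijection onto 1..20+400*d_max", {
  expect_identical(feature_index("unigram", "A"), 1L)
  expect_identical(feature_index("unigram", "V"), 20L)
  expect_identical(feature_index("pair", "A", "A", d = 1), 21L)
  d_max <- 7L
  expect_identical(feature_index("pair", "V", "V", d = d_max),
                   feature_dimension(d_max))
  # bijectivity: all pair indices at all distances cover the range exactly once
  idx <- c(1:20, as.vector(outer(1:400, 0:(d_max - 1), function(k, d) {
    a <- (k - 1) %/% 20 + 1; b <- (k - 1) %% 20 + 1
    feature_index("pair", a, b, d = d + 1)
  })))
  expect_identical(sort(idx), seq_len(feature_dimension(d_max)))

  expect_error(feature_index("pair", "A", "A", d = 0), ">= 1")
  expect_error(feature_index("pair", "A", "A", d = 3, d_max = 2), "d_max")
  expect_error(feature_index("unigram", "J"), "alphabet")
})

test_that("feature dimension follows 20 + 400 * d_max", {
  for (d_max in c(0L, 1L, 2L, 150L)) {
    expect_identical(feature_dimension(d_max), 20L + 400L * d_max)
    expect_length(build_feature_vector("AG", d_max), 20L + 400L * d_max)
  }
  expect_identical(feature_dimension(150L), 60020L)
})

test_that("count_distance_block counts ordered pairs at one offset", {
  b1 <- count_distance_block("KFFK", 1)
  expect_identical(b1["K", "F"], 1L)
  expect_identical(b1["F", "F"], 1L)
  expect_identical(b1["F", "K"], 1L)
  expect_identical(sum(b1), 3L)

  b2 <- count_distance_block("KFFK", 2)
  expect_identical(b2["K", "F"], 1L)
  expect_identical(b2["F", "K"], 1L)
  expect_identical(sum(b2), 2L)

  expect_identical(sum(count_distance_block("KFFK", 4)), 0L)
  expect_identical(sum(count_distance_block("KFFK", 9)), 0L)
  expect_error(count_distance_block("KFFK", 0), ">= 1")
})

test_that("the worked KFFK example has the documented block contents", {
  v <- build_feature_vector("KFFK", d_max = 2)
  expect_length(v, 820L)
  expect_identical(sum(v != 0), 7L)
  expect_identical(sum(v), 9L)  # 4 unigrams + 3 pairs at d=1 + 2 at d=2
  expect_identical(v[feature_index("unigram", "K")], 2L)
  expect_identical(v[feature_index("unigram", "F")], 2L)
  for (p in list(c("K", "F", 1), c("F", "F", 1), c("F", "K", 1),
                 c("K", "F", 2), c("F", "K", 2))) {
    expect_identical(v[feature_index("pair", p[1], p[2], d = as.integer(p[3]))], 1L)
  }
  expect_identical(as.integer(v), as.integer(naive_feature_vector("KFFK", 2)))
})

test_that("d_max = 0 gives composition; lone symbols give no pairs", {
  v <- build_feature_vector("KFFK", 0)
  expect_length(v, 20L)
  expect_identical(v[feature_index("unigram", "K")], 2L)
  expect_identical(sum(v), 4L)

  v <- build_feature_vector("A", 5)
  expect_length(v, 2020L)
  expect_identical(which(v != 0), 1L)
  expect_identical(v[1], 1L)
})

test_that("dr_features counts residue pairs and masks invalid positions", {
  v <- dr_features("AGLP", d_max = 2)
  for (u in c("A", "G", "L", "P")) {
    expect_identical(v[feature_index("unigram", u)], 1L)
  }
  for (p in list(c("A", "G", 1), c("G", "L", 1), c("L", "P", 1),
                 c("A", "L", 2), c("G", "P", 2))) {
    expect_identical(v[feature_index("pair", p[1], p[2], d = as.integer(p[3]))], 1L)
  }
  expect_identical(sum(v), 4L + 3L + 2L)

  v <- dr_features("AAAA", d_max = 1)
  expect_identical(v[feature_index("unigram", "A")], 4L)
  expect_identical(v[feature_index("pair", "A", "A", d = 1)], 3L)
  expect_identical(sum(v), 7L)

  # X masked: no unigram, and pairs spanning it are dropped, not bridged
  v <- dr_features("AXGA", d_max = 1)
  expect_identical(v[feature_index("unigram", "A")], 2L)
  expect_identical(v[feature_index("unigram", "G")], 1L)
  expect_identical(sum(v[1:20]), 3L)
  expect_identical(v[feature_index("pair", "G", "A", d = 1)], 1L)
  expect_identical(sum(v[-(1:20)]), 1L)
})

test_that("dt_features equals feature construction on the Top-1-gram sequence", {
  prof <- fixture_profile("KFFK")
  expect_identical(as.integer(dt_features(prof, 2)),
                   as.integer(build_feature_vector("KFFK", 2)))
  expect_length(dt_features(prof, 150), 60020L)

  set.seed(41)
  for (rep in 1:5) {
    seq <- paste(sample(aa_alphabet(), sample(10:50, 1), replace = TRUE),
                 collapse = "")
    prof <- synthetic_profile(seq, concentration = 1)
    expect_identical(as.integer(dt_features(prof, 5)),
                     as.integer(dr_features(seq, 5)))
  }
})

test_that("fast construction matches the naive O(L^2) oracle exactly", {
  set.seed(42)
  cases <- 0L
  for (d_max in c(0L, 1L, 5L, 20L)) {
    for (rep in 1:50) {
      L <- sample(2:300, 1)
      s <- random_symbol_sequence(L, p_invalid = ifelse(rep %% 5 == 0, 0.15, 0))
      expect_identical(as.integer(build_feature_vector(s, d_max)),
                       as.integer(naive_feature_vector(s, d_max)))
      cases <- cases + 1L
    }
  }
  expect_identical(cases, 200L)
})

test_that("counts are conserved, nested across d_max, and shift-covariant", {
  set.seed(43)
  for (rep in 1:20) {
    L <- sample(3:120, 1)
    s <- random_symbol_sequence(L)
    d_max <- sample(0:12, 1)
    v <- build_feature_vector(s, d_max)
    expect_true(all(v >= 0))
    expected_total <- L + sum(pmax(0, L - seq_len(d_max)))
    expect_identical(sum(v), as.integer(expected_total))
    # monotone nesting: F_k is a prefix of F_dmax
    k <- sample(0:d_max, 1)
    expect_identical(as.integer(v[seq_len(feature_dimension(k))]),
                     as.integer(build_feature_vector(s, k)))
    # prepending a valid symbol never decreases any count
    s2 <- symbol_sequence(c(sample.int(20L, 1), s$symbols), id = "shift")
    v2 <- build_feature_vector(s2, d_max)
    expect_true(all(v2 >= v))
  }
})

test_that("sparse feature files round-trip and validate consistency", {
  f <- withr::local_tempfile(fileext = ".svml")
  v <- structure(c(2L, integer(19)), d_max = 0L)
  write_sparse_features(list(v), labels = 1, f)
  lines <- readLines(f)
  expect_identical(lines[2], "+1 1:2")

  write_sparse_features(list(), labels = numeric(0), f)
  expect_identical(length(readLines(f)), 0L)

  set.seed(44)
  vecs <- lapply(1:6, function(i)
    build_feature_vector(random_symbol_sequence(sample(5:60, 1)), 3))
  labels <- c(1, 1, 1, -1, -1, -1)
  write_sparse_features(vecs, labels, f)
  back <- read_sparse_features(f)
  expect_identical(back$d_max, 3L)
  expect_identical(back$labels, labels)
  expect_equal(back$x, do.call(rbind, lapply(vecs, as.numeric)))

  bad <- list(build_feature_vector("AG", 1), build_feature_vector("AG", 2))
  expect_error(write_sparse_features(bad, c(1, -1), f), "inconsistent d_max")
  expect_error(write_sparse_features(vecs, c(1, 0, 1, -1, -1, -1), f), "\\+1 or -1")
})
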