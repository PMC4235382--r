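# Instance construction and cross-validated SVM discrimination.

# genome laid out as [300 G][300 A] blocks: each ORI is the A block, its
# upstream negative window the G block -> perfectly separable by GC
separable_fixture <- function(n = 40L) {
  block <- paste0(strrep("G", 300), strrep("A", 300))
  genome <- c(cs = paste0(strrep("A", 300), strrep(block, n), strrep("A", 300)))
  starts <- 300L + (seq_len(n) - 1L) * 600L + 300L
  list(genome = genome, oris = intervals(rep("cs", n), starts, starts + 300L))
}

test_that("instance windows are centred on the midpoint with an abutting upstream negative", {
  genome <- c(c1 = strrep("ACGT", 7000))
  ori <- intervals(rep("c1", 25), 4700L + (0:24) * 700L, 5300L + (0:24) * 700L)
  inst <- build_instance_sets(genome, ori, "gc_profile")
  i <- which(inst$labels == "positive")[1]
  expect_equal(inst$intervals$start[i], 4850L)  # midpoint 5000
  expect_equal(inst$intervals$end[i], 5150L)
  j <- which(inst$labels == "negative")[1]
  expect_equal(inst$intervals$start[j], 4550L)
  expect_equal(inst$intervals$end[j], 4850L)
})

test_that("feature dimensions per family match the window arithmetic", {
  b <- generate_bundle(small_spec())
  inst <- suppressWarnings(build_instance_sets(b$genome, b$oris, "gc_profile"))
  expect_equal(ncol(inst$features), 251L)
  inst <- suppressWarnings(build_instance_sets(b$genome, b$oris, "d2"))
  expect_equal(ncol(inst$features), 151L)
  inst <- suppressWarnings(build_instance_sets(b$genome, b$oris, "nucleosome",
                                               track = b$track))
  expect_equal(ncol(inst$features), 300L)
  expect_error(build_instance_sets(b$genome, b$oris, "nucleosome"),
               "track required")
  expect_error(build_instance_sets(b$genome, b$oris[1:5, ], "gc_profile"),
               "fewer than 20")
})

test_that("a perfectly separable composition contrast is classified exactly", {
  fx <- separable_fixture(40L)
  inst <- build_instance_sets(fx$genome, fx$oris, "gc_profile")
  rep <- suppressWarnings(cross_validate_svm(inst, folds = 10, seed = 1))
  expect_equal(rep$Acc, 1.0)
  expect_equal(rep$Sn, 1.0)
  expect_equal(rep$Sp, 1.0)
})

test_that("fold assignment partitions instances and stratifies classes", {
  labels <- factor(rep(c("positive", "negative"), each = 55),
                   levels = c("positive", "negative"))
  fold <- oriseq:::stratified_folds(labels, 10L, seed = 3L)
  expect_equal(sort(unique(fold)), 1:10)
  expect_length(fold, 110L)
  per_fold <- table(fold, labels)
  expect_true(all(abs(per_fold[, 1] - per_fold[, 2]) <= 1))
  # every instance in exactly one fold is implied by fold being a vector of
  # single assignments; check per-class totals conserve
  expect_equal(sum(per_fold), 110)
})

test_that("standardization parameters depend on the training fold only", {
  set.seed(19)
  x <- matrix(rnorm(200), nrow = 20)
  x[1, 3] <- NA
  tr <- 1:12
  std1 <- oriseq:::fit_standardizer(x[tr, ])
  x_corrupt <- x
  x_corrupt[13:20, ] <- x_corrupt[13:20, ] * 1000 + 77
  std2 <- oriseq:::fit_standardizer(x_corrupt[tr, ])
  expect_identical(std1, std2)
  # applying to test data imputes missing with the training mean (0 centred)
  xt <- x[13:20, ]
  xt[2, 5] <- NA
  z <- oriseq:::apply_standardizer(std1, xt)
  expect_false(anyNA(z))
})

test_that("report metrics recompute from confusion totals; table formats 4 decimals", {
  r <- structure(list(family = "gc_profile", folds = 10L, seed = 1L,
                      TP = 8L, FN = 2L, TN = 7L, FP = 3L,
                      Sn = 0.8, Sp = 0.7, Acc = 0.75),
                 class = "ori_cv_report")
  expect_equal(r$Sn, r$TP / (r$TP + r$FN), tolerance = 1e-12)
  tab <- report_table(list(r, r, r, r))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$Sn[1], 0.8)
  expect_equal(tab$Acc[1], 0.75)
})

test_that("cross-validation is reproducible given the seed", {
  b <- generate_bundle(small_spec())
  inst <- suppressWarnings(build_instance_sets(b$genome, b$oris, "gc_profile"))
  r1 <- suppressWarnings(cross_validate_svm(inst, folds = 5, seed = 42))
  r2 <- suppressWarnings(cross_validate_svm(inst, folds = 5, seed = 42))
  expect_identical(r1, r2)
  expect_equal(r1$Sn, r1$TP / (r1$TP + r1$FN), tolerance = 1e-12)
  expect_equal(r1$Acc, (r1$TP + r1$TN) / (r1$TP + r1$TN + r1$FP + r1$FN),
               tolerance = 1e-12)
})
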