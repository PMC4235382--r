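# Intergenic orientation classes, ORI positional categories, TSS distances.

test_that("gene-pair orientation follows the promoter/terminator logic", {
  expect_equal(classify_gene_pair("-", "+"), "divergent")
  expect_equal(classify_gene_pair("+", "-"), "convergent")
  expect_equal(classify_gene_pair("+", "+"), "tandem")
  expect_equal(classify_gene_pair("-", "-"), "tandem")
  expect_error(classify_gene_pair("+", "*"))
})

test_that("intergenic regions form between consecutive non-overlapping genes", {
  g <- intervals(rep("c", 2), c(100L, 300L), c(200L, 400L), c("+", "+"))
  r <- build_intergenic_regions(g)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 200L)
  expect_equal(r$end, 300L)
  expect_equal(r$cls, "tandem")

  g <- intervals(rep("c", 3), c(100L, 300L, 500L), c(200L, 400L, 600L),
                 c("+", "-", "+"))
  r <- build_intergenic_regions(g)
  expect_equal(r$cls, c("convergent", "divergent"))
  expect_equal(r$start, c(200L, 400L))
  expect_equal(r$end, c(300L, 500L))

  # abutting genes leave no gap; overlapping genes are merged out
  g <- intervals(rep("c", 2), c(100L, 200L), c(200L, 300L), c("+", "+"))
  expect_equal(nrow(build_intergenic_regions(g)), 0L)
  g <- intervals(rep("c", 3), c(100L, 150L, 500L), c(200L, 400L, 600L),
                 c("+", "-", "+"))
  expect_equal(nrow(build_intergenic_regions(g)), 0L)

  expect_equal(nrow(build_intergenic_regions(
    intervals("c", 100L, 200L, "+"))), 0L)
})

test_that("region counts equal consecutive non-overlapping gene pairs with gaps", {
  set.seed(41)
  for (rep_i in 1:10) {
    n <- 20
    starts <- sort(sample.int(20000, n)) * 5L
    lens <- sample(50:600, n, replace = TRUE)
    g <- intervals(rep("c", n), starts, starts + lens,
                   sample(c("+", "-"), n, replace = TRUE))
    r <- build_intergenic_regions(g)
    # oracle: walk sorted genes, count singleton-cluster adjacent pairs
    o <- g[order(g$start), ]
    hi <- cummax(o$end)
    cl <- cumsum(!c(FALSE, o$start[-1] < hi[-n]))
    sizes <- tabulate(cl)
    expected <- 0L
    for (i in seq_len(max(cl) - 1)) {
      if (sizes[i] == 1L && sizes[i + 1L] == 1L &&
          min(o$start[cl == i + 1L]) > max(o$end[cl == i])) {
        expected <- expected + 1L
      }
    }
    expect_equal(nrow(r), expected)
    expect_true(all(r$end > r$start))
  }
})

test_that("coordinate mirroring swaps divergent and convergent; adding a strand flip restores them", {
  set.seed(43)
  n <- 12
  starts <- sort(sample.int(5000, n)) * 4L
  g <- intervals(rep("c", n), starts, starts + sample(40:200, n, TRUE),
                 sample(c("+", "-"), n, TRUE))
  r <- build_intergenic_regions(g)
  L <- max(g$end) + 100L
  # mirror only: reading the locus from the other end swaps the classes
  gm <- intervals(rep("c", n), L - g$end, L - g$start, g$strand)
  rm1 <- build_intergenic_regions(gm)
  map <- c(tandem = "tandem", divergent = "convergent",
           convergent = "divergent")
  expect_equal(sort(unname(map[r$cls])), sort(rm1$cls))
  # mirror + strand flip: the biological reverse complement, class-preserving
  gmf <- intervals(rep("c", n), L - g$end, L - g$start,
                   ifelse(g$strand == "+", "-", "+"))
  rm2 <- build_intergenic_regions(gmf)
  expect_equal(sort(r$cls), sort(rm2$cls))
})

test_that("ORI categories follow the midpoint rule, strand-aware head/tail", {
  genes <- intervals(rep("c", 2), c(100L, 300L), c(200L, 400L), c("+", "+"))
  ig <- build_intergenic_regions(genes)

  ori <- intervals("c", 230L, 270L)      # midpoint 250 in [200, 300)
  loc <- assign_ori_location(ori, genes, ig)
  expect_equal(loc$category, "tandem")

  ori <- intervals("c", 100L, 120L)      # midpoint 110, + gene 100-200
  loc <- assign_ori_location(ori, genes, ig)
  expect_equal(loc$category, "coding_head")

  genes_m <- intervals(rep("c", 2), c(100L, 300L), c(200L, 400L), c("-", "+"))
  loc <- assign_ori_location(ori, genes_m, build_intergenic_regions(genes_m))
  expect_equal(loc$category, "coding_tail")

  # terminal gap -> coding_internal with a warning
  ori <- intervals("c", 0L, 50L)
  expect_warning(loc <- assign_ori_location(ori, genes, ig), "excluded")
  expect_equal(loc$category, "coding_internal")

  expect_error(assign_ori_location(intervals("z", 0L, 10L), genes, ig),
               "absent")
})

test_that("every ORI receives exactly one category and fractions sum to 1", {
  b <- generate_bundle(small_spec())
  ig <- build_intergenic_regions(b$genes)
  loc <- suppressWarnings(assign_ori_location(b$oris, b$genes, ig))
  expect_equal(nrow(loc), nrow(b$oris))
  expect_true(all(loc$category %in% c("tandem", "divergent", "convergent",
                                      "coding_head", "coding_tail",
                                      "coding_internal")))
  fr <- table(loc$category) / nrow(loc)
  expect_equal(sum(fr), 1.0)
})

test_that("ORI-TSS distance uses the midpoint and a strict threshold", {
  oris <- intervals(rep("c", 2), c(900L, 900L), c(1100L, 1102L))
  tss <- intervals(rep("c", 2), c(1400L, 5000L), c(1401L, 5001L))
  d <- ori_tss_distances(oris[1, ], tss, 500L)
  expect_equal(d$distances$distance, 400)
  expect_equal(d$fraction, 1.0)

  tss2 <- intervals("c", 1500L, 1501L)
  d <- ori_tss_distances(oris[1, ], tss2, 500L)
  expect_equal(d$distances$distance, 500)
  expect_equal(d$fraction, 0.0)   # "< 500" is strict

  oris2 <- intervals(c("c", "other"), c(900L, 10L), c(1100L, 30L))
  expect_warning(d <- ori_tss_distances(oris2, tss, 500L), "without TSS")
  expect_true(is.na(d$distances$distance[2]))
  expect_equal(d$fraction, 1.0)
})
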