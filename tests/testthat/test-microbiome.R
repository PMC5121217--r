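toy_counts <- function() {
  tibble::tibble(
    otu_id = c("a", "b", "c"),
    s1 = c(10, 30, 60),
    s2 = c(100, 0, 0),
    s3 = c(25, 25, 50)
  )
}

test_that("relative abundances are per-sample proportions", {
  p <- relative_abundance(toy_counts())
  expect_equal(p$s1, c(0.1, 0.3, 0.6), tolerance = 1e-15)
  expect_equal(p$s2, c(1, 0, 0), tolerance = 1e-15)
  m <- chainelongr:::otu_matrix(p)
  expect_equal(unname(rowSums(m)), rep(1, 3), tolerance = 1e-12)
  empty <- tibble::tibble(otu_id = "a", s1 = 0)
  expect_error(relative_abundance(empty), "zero total")
})

test_that("abundance screen keeps OTUs reaching the threshold in any sample", {
  # plant exactly 5 OTUs at >= 1% in at least one sample, 15 below
  set.seed(5)
  n_samp <- 6
  deep <- 1e5
  m <- matrix(0, nrow = 20, ncol = n_samp)
  m[1:5, ] <- 40                       # 5 planted: spike one sample each
  m[cbind(1:5, 1:5)] <- 0.05 * deep
  m[6:20, ] <- 10                      # rare: ~1e-4 everywhere
  filler <- deep - colSums(m)
  counts <- tibble::as_tibble(as.data.frame(rbind(m, filler)))
  names(counts) <- paste0("s", seq_len(n_samp))
  counts <- dplyr::bind_cols(
    tibble::tibble(otu_id = c(sprintf("otu%02d", 1:20), "dominant")), counts)
  hits <- abundant_otus(counts, threshold = 0.01)
  expect_setequal(hits, c(sprintf("otu%02d", 1:5), "dominant"))
  # threshold 0 keeps everything with nonzero counts; threshold 1 only
  # OTUs that monopolise a sample
  expect_length(abundant_otus(counts, threshold = 0), 21)
  expect_identical(abundant_otus(toy_counts(), threshold = 1), "a")
})

test_that("inclusive vs strict boundary handling at the 1% screen", {
  tab <- tibble::tibble(otu_id = c("x", "y"), s1 = c(1, 99))
  expect_setequal(abundant_otus(tab, 0.01), c("x", "y"))
  expect_identical(abundant_otus(tab, 0.01, strict = TRUE), "y")
})

test_that("singleton OTUs are removable", {
  tab <- tibble::tibble(otu_id = c("a", "b", "c"), s1 = c(5, 1, 0),
                        s2 = c(5, 0, 1))
  expect_identical(remove_singletons(tab)$otu_id, "a")
})

test_that("Shannon index has the right extremes and matches vegan", {
  expect_identical(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(rep(1 / 16, 16)), 4, tolerance = 1e-12)
  # uniform over S is the maximum over random distributions on S OTUs
  set.seed(11)
  for (S in c(4, 9, 25)) {
    expect_equal(shannon_index(rep(1 / S, S)), log2(S), tolerance = 1e-12)
    for (i in 1:10) {
      p <- rgamma(S, 1); p <- p / sum(p)
      expect_lte(shannon_index(p), log2(S) + 1e-12)
    }
  }
  # cross-check against vegan's natural-log implementation
  tab <- toy_counts()
  ours <- shannon_diversity(tab, base = exp(1))
  veg <- vegan::diversity(chainelongr:::otu_matrix(tab), index = "shannon")
  expect_equal(ours$shannon, unname(veg[ours$sample_id]), tolerance = 1e-12)
})

test_that("critical Pearson r reproduces the n = 7 gate and is monotone", {
  expect_equal(round(critical_pearson_r(7), 3), 0.754)
  # t(0.975, df = 1) = 12.706 -> 12.706/sqrt(161.44 + 1)
  expect_equal(round(critical_pearson_r(3), 3), 0.997)
  n <- c(3:12, 20, 50, 200, 1000)
  r <- critical_pearson_r(n)
  expect_true(all(diff(r) < 0))
  expect_lt(critical_pearson_r(1e6), 0.01)
  expect_gt(critical_pearson_r(7, alpha = 0.01), critical_pearson_r(7, alpha = 0.05))
  expect_error(critical_pearson_r(2), "at least 3")
})

test_that("OTU-productivity correlation flags and degenerate cases", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:5), day = 1:5,
                         productivity = c(1, 2, 3, 4, 5))
  depth <- 1000
  tracker <- round(seq(0.05, 0.25, length.out = 5) * depth)
  tab <- tibble::as_tibble(as.data.frame(rbind(
    tracker, rep(200, 5), depth - tracker - 200)))
  names(tab) <- meta$sample_id
  tab <- dplyr::bind_cols(tibble::tibble(otu_id = c("track", "flat", "rest")), tab)
  res <- correlate_otus(tab, meta, threshold = 0)
  expect_equal(res$r[res$otu_id == "track"], 1, tolerance = 1e-9)
  expect_true(res$significant[res$otu_id == "track"])
  expect_identical(res$note[res$otu_id == "flat"], "undefined-r")
  expect_false(res$significant[res$otu_id == "flat"])
  # gate matches the closed-form critical value
  expect_equal(attr(res, "critical_r"), critical_pearson_r(5))
  expect_error(correlate_otus(tab[1:2], meta[1:2, ]), "at least 3 samples")
})

test_that("Pearson r is invariant under affine rescaling of either variable", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    r0 <- cor(x, y)
    expect_equal(cor(3.2 * x + 7, y), r0, tolerance = 1e-12)
    expect_equal(cor(x, -2 * y + 1), -r0, tolerance = 1e-12)
  }
})

test_that("Bray-Curtis/UPGMA reproduces the hand-computed 3-sample example", {
  tab <- tibble::tibble(otu_id = c("o1", "o2"),
                        s1 = c(10, 0), s2 = c(0, 10), s3 = c(5, 5))
  cl <- bray_curtis_cluster(tab)
  d <- as.matrix(cl$distance)
  # hand computation on proportions (1,0)/(0,1)/(.5,.5):
  # BC(s1,s2) = 1, BC(s1,s3) = BC(s2,s3) = 0.5
  expect_equal(d["s1", "s2"], 1, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0.5, tolerance = 1e-12)
  expect_equal(d["s2", "s3"], 0.5, tolerance = 1e-12)
  # the two nearest samples merge first, at height 0.5
  expect_equal(cl$hclust$height[1], 0.5, tolerance = 1e-12)
  expect_identical(sort(cl$order), c("s1", "s2", "s3"))
})

test_that("Bray-Curtis is a bounded symmetric semimetric", {
  set.seed(31)
  for (i in 1:5) {
    counts <- tibble::as_tibble(as.data.frame(
      matrix(rpois(8 * 6, 20), nrow = 8)))
    names(counts) <- paste0("s", 1:6)
    counts <- dplyr::bind_cols(tibble::tibble(otu_id = paste0("o", 1:8)), counts)
    d <- as.matrix(bray_curtis_cluster(counts)$distance)
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_equal(unname(diag(d)), rep(0, 6))
    # independent hand formula: sum|x-y| / sum(x+y) on proportions
    p <- chainelongr:::otu_matrix(relative_abundance(counts))
    expect_equal(d["s1", "s2"],
                 sum(abs(p["s1", ] - p["s2", ])) / sum(p["s1", ] + p["s2", ]),
                 tolerance = 1e-12)
  }
  ident <- tibble::tibble(otu_id = c("a", "b"), s1 = c(3, 7), s2 = c(30, 70))
  expect_equal(max(as.matrix(bray_curtis_cluster(ident)$distance)), 0,
               tolerance = 1e-12)
  disjoint <- tibble::tibble(otu_id = c("a", "b"), s1 = c(5, 0), s2 = c(0, 9))
  expect_equal(max(as.matrix(bray_curtis_cluster(disjoint)$distance)), 1,
               tolerance = 1e-12)
})

test_that("PCoA recovers Euclidean configurations exactly", {
  set.seed(41)
  xy <- cbind(rnorm(7), rnorm(7))
  rownames(xy) <- paste0("p", 1:7)
  ord <- pcoa(dist(xy))
  rec <- as.matrix(ord$points[, c("Axis.1", "Axis.2")])
  # Procrustes-align the recovered configuration onto the original
  xy_c <- scale(xy, scale = FALSE)
  sol <- svd(t(xy_c) %*% rec)
  err <- max(abs(rec %*% sol$v %*% t(sol$u) - xy_c))
  expect_lt(err, 1e-9)
  expect_true(all(diff(ord$variance_explained) <= 1e-12))
  # 2 points: one axis carrying all variance
  two <- pcoa(dist(c(0, 3)))
  expect_identical(ncol(two$points) - 1L, 1L)
  expect_equal(two$variance_explained, 1, tolerance = 1e-12)
})

test_that("equilateral triangle yields two equal positive eigenvalues", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  ord <- pcoa(d)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  expect_equal(sum(pos), 1, tolerance = 1e-9) # centred Gram trace, side 1
})

test_that("negative PCoA eigenvalues are reported, not hidden", {
  # triangle-inequality violation: no Euclidean embedding exists
  m <- matrix(c(0, 10, 1,
                10, 0, 1,
                1, 1, 0), 3, 3)
  ord <- pcoa(m)
  expect_true(length(ord$negative_eigenvalues) > 0)
})
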