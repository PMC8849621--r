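test_that("crown ratios are computed, rounded, and scale-invariant", {
  expect_equal(derive_tooth_ratios(10, 10, 20)$CBR, 1)
  r <- derive_tooth_ratios(10, 6, 25)
  expect_equal(r$CBR, 0.6)
  expect_equal(r$CHR, 2.5)
  expect_equal(r$CBR_2, 0.6)
  # mm vs cm give identical ratios
  r_cm <- derive_tooth_ratios(1.0, 0.6, 2.5)
  expect_equal(r_cm$CBR, r$CBR)
  expect_equal(r_cm$CHR, r$CHR)
  expect_error(derive_tooth_ratios(0, 6, 25), "> 0")
  expect_error(derive_tooth_ratios(10, NA, 25), "> 0")
})

test_that("drop_incomplete filters, counts and is idempotent", {
  df <- data.frame(specimen_id = paste0("s", 1:5),
                   CBL = c(1, 2, 3, 4, 5),
                   AL = c(1, NA, 3, NA, 5))
  expect_identical(nrow(drop_incomplete(df, "CBL")), 5L)
  f <- drop_incomplete(df, "AL")
  expect_equal(nrow(f), 3L)
  expect_equal(unname(attr(f, "removed")["AL"]), 2L)
  f2 <- drop_incomplete(f, "AL")
  expect_equal(f2$specimen_id, f$specimen_id)
  expect_error(drop_incomplete(df, "nope"), "unknown fields")
})

test_that("run_pca handles rank-1 data and matches closed-form 2x2 eigenvalues", {
  # perfectly collinear pair -> PC1 fraction 1
  df <- data.frame(specimen_id = paste0("s", 1:6),
                   x = 1:6, y = 2 * (1:6))
  p <- run_pca(df, c("x", "y"))
  expect_equal(p$variance_fraction[1], 1)
  # closed-form 2x2: cov eigenvalues (a+c ± sqrt((a-c)^2+4b^2))/2
  set.seed(71)
  df2 <- data.frame(specimen_id = paste0("s", 1:20),
                    x = rnorm(20, 10, 2), y = rnorm(20, 5, 1))
  df2$y <- df2$y + 0.4 * df2$x
  cv <- stats::cov(df2[, c("x", "y")])
  a <- cv[1, 1]; b <- cv[1, 2]; c2 <- cv[2, 2]
  ev <- sort(c((a + c2 + sqrt((a - c2)^2 + 4 * b^2)) / 2,
               (a + c2 - sqrt((a - c2)^2 + 4 * b^2)) / 2), decreasing = TRUE)
  p2 <- run_pca(df2, c("x", "y"))
  expect_equal(p2$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(p2$variance_fraction, ev / sum(ev), tolerance = 1e-10)
  expect_error(run_pca(df2[1, ], c("x", "y")), ">= 2")
  df2$z <- 1
  expect_error(run_pca(df2, c("x", "y", "z"), scaling = "correlation"),
               "zero-variance")
})

test_that("PCA invariants: fractions sum to 1, scores uncorrelated, order
           invariance, covariance scaling law", {
  set.seed(72)
  df <- data.frame(specimen_id = paste0("s", 1:25),
                   a = rlnorm(25, 2, .3), b = rlnorm(25, 1, .2),
                   c = rlnorm(25, 3, .4))
  p <- run_pca(df, c("a", "b", "c"))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  sc_cov <- stats::cov(p$scores)
  off <- max(abs(sc_cov[upper.tri(sc_cov)]))
  expect_lt(off, 1e-9 * p$eigenvalues[1])
  # row and column order invariance (up to the sign convention)
  p_perm <- run_pca(df[sample(25), ], c("c", "a", "b"))
  expect_equal(sort(p_perm$eigenvalues), sort(p$eigenvalues), tolerance = 1e-9)
  expect_equal(p_perm$variance_fraction, p$variance_fraction, tolerance = 1e-9)
  # uniform rescaling multiplies eigenvalues by k^2, fractions unchanged
  dfk <- df
  dfk[, c("a", "b", "c")] <- dfk[, c("a", "b", "c")] * 10
  pk <- run_pca(dfk, c("a", "b", "c"))
  expect_equal(pk$eigenvalues, 100 * p$eigenvalues, tolerance = 1e-8)
  expect_equal(pk$variance_fraction, p$variance_fraction, tolerance = 1e-10)
})

test_that("loading signs follow the construction", {
  df <- data.frame(specimen_id = paste0("s", 1:6), x = 1:6, y = 2 * (1:6))
  p <- run_pca(df, c("x", "y"))
  rep1 <- loading_sign_report(p, 1)
  expect_true(all(rep1$sign == "positive"))
  # one anti-correlated variable flips sign on PC1
  set.seed(73)
  t <- rnorm(40)
  df2 <- data.frame(specimen_id = paste0("s", 1:40),
                    u = 10 + t, v = 10 + 0.9 * t, w = 10 - t)
  p2 <- run_pca(df2, c("u", "v", "w"))
  r2 <- loading_sign_report(p2, 1)
  # the anti-correlated variable loads opposite to the correlated pair
  # (absolute direction is fixed only by the largest-loading convention)
  expect_length(unique(r2$sign[r2$variable %in% c("u", "v")]), 1)
  expect_false(r2$sign[r2$variable == "w"] ==
                 r2$sign[r2$variable == "u"])
  expect_error(loading_sign_report(p2, 9), "out of range")
})

test_that("hull membership: trivial cases and the half-plane example", {
  scores <- rbind(c(0, 0), c(2, 0), c(0, 2), c(0.5, 0.5), c(2, 2))
  rownames(scores) <- paste0("s", 1:5)
  groups <- c("G", "G", "G", "q", "q")
  # hull {(0,0),(2,0),(0,2)}: (0.5,0.5) inside, (2,2) outside
  expect_true(hull_membership(scores, groups, "G", "s4")$inside)
  expect_false(hull_membership(scores, groups, "G", "s5")$inside)
  # a group member queried against its own hull is inside (boundary counts)
  scores2 <- rbind(scores, s6 = c(0, 0))
  groups2 <- c(groups, "q")
  expect_true(hull_membership(scores2, groups2, "G", "s6")$inside)
  # degenerate (collinear) group falls back to a PC1 interval, flagged
  sc3 <- rbind(a = c(0, 0), b = c(1, 0), c = c(2, 0), q = c(1.5, 5))
  g3 <- c("G", "G", "G", "q")
  r <- hull_membership(sc3, g3, "G", "q")
  expect_equal(r$method, "pc1-interval")
  expect_true(r$inside)
})

test_that("hull membership agrees with the triangle-decomposition oracle
           (property, 100 point sets)", {
  set.seed(74)
  for (r in 1:100) {
    k <- sample(4:9, 1)
    hx <- runif(k); hy <- runif(k)
    px <- runif(1, -0.2, 1.2); py <- runif(1, -0.2, 1.2)
    scores <- rbind(cbind(hx, hy), c(px, py))
    rownames(scores) <- c(paste0("g", 1:k), "q")
    groups <- c(rep("G", k), "q")
    got <- hull_membership(scores, groups, "G", "q")
    if (got$method != "hull") next
    expect_equal(got$inside, brute_in_hull(px, py, hx, hy),
                 label = paste("rep", r))
  }
})

test_that("alveolus profiles compute ratios and mean heights per position", {
  rec <- data.frame(
    specimen_id = "d1", position = c(2, 1, 3),
    mesiodistal = c(10, 8, 12), labiolingual = c(10, 6, 6),
    height_labial = c(10, 9, 12), height_lingual = c(14, 11, 12))
  p <- alveolus_profiles(rec, "d1")
  expect_equal(p$position, 1:3)
  expect_equal(p$compression_ratio, c(6 / 8, 1, 0.5))
  expect_equal(p$mean_height, c(10, 12, 12))
  expect_error(alveolus_profiles(rec, "nope"), "no alveoli")
  rec2 <- rbind(rec, rec[1, ])
  expect_error(alveolus_profiles(rec2, "d1"), "duplicate")
})

test_that("the most compressed alveolus lands at the same position across
           synthetic jaw tables with a shared profile", {
  # three specimens sharing a dentary profile whose 5th socket is the most
  # mesiodistally compressed, at different absolute sizes
  base_ratio <- c(0.95, 0.9, 0.8, 0.62, 0.45, 0.7, 0.8, 0.85)
  make <- function(id, scale) data.frame(
    specimen_id = id, position = seq_along(base_ratio),
    mesiodistal = scale * rep(10, length(base_ratio)),
    labiolingual = scale * 10 * base_ratio,
    height_labial = scale * (20 + seq_along(base_ratio)),
    height_lingual = scale * (22 + seq_along(base_ratio)))
  tab <- rbind(make("jawA", 1), make("jawB", 2.4), make("jawC", 0.7))
  for (id in c("jawA", "jawB", "jawC")) {
    p <- alveolus_profiles(tab, id)
    expect_equal(p$position[which.min(p$compression_ratio)], 5)
  }
})

test_that("nearest specimen uses standardized distance with stable ties", {
  ds <- data.frame(specimen_id = c("A", "B", "C"),
                   curvature = c(30, 40, 50), length = c(100, 200, 300))
  # query equal to a dataset point -> that point
  expect_equal(nearest_specimen(ds, c(curvature = 40, length = 200))$specimen_id,
               "B")
  # hand-computed: z-scores make curvature and length commensurable
  q <- c(curvature = 33, length = 290)
  cz <- (ds$curvature - mean(ds$curvature)) / sd(ds$curvature)
  lz <- (ds$length - mean(ds$length)) / sd(ds$length)
  qc <- (33 - mean(ds$curvature)) / sd(ds$curvature)
  ql <- (290 - mean(ds$length)) / sd(ds$length)
  d <- sqrt((cz - qc)^2 + (lz - ql)^2)
  expect_equal(nearest_specimen(ds, q)$specimen_id,
               ds$specimen_id[which.min(d)])
  # tie -> smaller index
  ds2 <- data.frame(specimen_id = c("A", "B"),
                    curvature = c(30, 50), length = c(100, 300))
  expect_equal(nearest_specimen(ds2, c(curvature = 40, length = 200))$specimen_id,
               "A")
  expect_error(nearest_specimen(ds[0, ], q), "empty dataset")
  expect_error(nearest_specimen(ds, c(curvature = 40)), "both")
})
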