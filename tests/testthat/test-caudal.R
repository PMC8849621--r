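test_that("facet area models and the ellipse/rectangle identity", {
  expect_equal(facet_area(2, 2, "ellipse"), pi)
  expect_equal(facet_area(3, 4, "rectangle"), 12)
  set.seed(81)
  for (r in 1:20) {
    dv <- runif(1, 1, 80); ml <- runif(1, 1, 80)
    expect_equal(facet_area(dv, ml, "ellipse"),
                 (pi / 4) * facet_area(dv, ml, "rectangle"))
  }
  expect_error(facet_area(0, 2), "> 0")
})

test_that("ASI is dimensionless and unit-invariant (property)", {
  expect_equal(asi(100, 10), 1)
  set.seed(82)
  for (r in 1:25) {
    a <- runif(1, 10, 4000); l <- runif(1, 5, 120)
    k <- runif(1, 0.01, 100) # arbitrary unit conversion
    expect_equal(asi(a * k^2, l * k), asi(a, l), tolerance = 1e-12)
  }
  expect_error(asi(-1, 10), "> 0")
})

test_that("ASI profile: anchor at 100, geometric series exact, rounding", {
  sim <- simulate_caudal_series(n = 8, asi_decay = 0.5, noise_sd = 0, seed = 1)
  s <- sim$series[match(sim$true_order, sim$series$vertebra_id), ]
  prof <- asi_profile(s)
  expect_equal(prof$pct_asi, 100 * 0.5^(0:7), tolerance = 1e-12)
  expect_equal(prof$pct_asi_int[1], 100)
  expect_error(asi_profile(transform(s, anchor = FALSE)), "anchor")
})

test_that("%ASI profiles are invariant to the facet-area model and to
           uniform skeletal scaling", {
  sim <- simulate_caudal_series(n = 10, noise_sd = 0.08, seed = 83)
  s <- sim$series
  p_ell <- asi_profile(s, model = "ellipse")
  p_rec <- asi_profile(s, model = "rectangle")
  expect_equal(p_ell$pct_asi, p_rec$pct_asi, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(p_ell$asi, p_rec$asi))) # raw ASI does shift
  s2 <- s
  s2$length <- s$length * 3.7
  s2$dv_diameter <- s$dv_diameter * 3.7
  s2$ml_diameter <- s$ml_diameter * 3.7
  expect_equal(asi_profile(s2)$pct_asi, p_ell$pct_asi, tolerance = 1e-9)
})

test_that("length profile is a simple percentage of the anchor", {
  s <- data.frame(vertebra_id = c("v1", "v2", "v3"),
                  length = c(50, 45, 40),
                  dv_diameter = 10, ml_diameter = 10,
                  has_diapophysis = FALSE,
                  anchor = c(TRUE, FALSE, FALSE))
  expect_equal(length_profile(s)$pct_length, c(100, 90, 80))
})

test_that("order_series recovers shuffled monotone series and documents ties", {
  sim <- simulate_caudal_series(n = 12, noise_sd = 0, seed = 84)
  expect_identical(as.character(order_series(sim$series)), sim$true_order)
  # already-ordered input is preserved
  s <- sim$series[match(sim$true_order, sim$series$vertebra_id), ]
  expect_identical(as.character(order_series(s)), sim$true_order)
  # a tie falls back to longer centrum first, then id
  tie <- data.frame(vertebra_id = c("a", "c", "b"),
                    length = c(50, 40, 40),
                    area = c(250, 160, 160),
                    has_diapophysis = FALSE,
                    anchor = c(TRUE, FALSE, FALSE))
  o <- order_series(tie)
  expect_identical(as.character(o), c("a", "b", "c"))
  expect_match(attr(o, "ties"), "ties")
  expect_error(order_series(rbind(tie, tie[2, ])), "duplicate")
})

test_that("order recovery stays strong under multiplicative noise
           (Kendall tau over seeds)", {
  taus <- vapply(1:20, function(sd_i) {
    sim <- simulate_caudal_series(n = 15, noise_sd = 0.05, seed = 8000 + sd_i)
    ord <- order_series(sim$series)
    cor(match(sim$true_order, ord), seq_along(ord), method = "kendall")
  }, numeric(1))
  expect_gte(mean(taus), 0.9)
})

test_that("diapophysis bounds reproduce the comparative table", {
  expect_equal(diapophysis_bounds("Dilophosaurus"), 17L)
  expect_equal(diapophysis_bounds("Spinosaurus"), c(16L, 19L))
  expect_equal(diapophysis_bounds("Concavenator"), c(19L, 20L))
  expect_equal(diapophysis_bounds("Majungasaurus"), 25L)
  expect_equal(diapophysis_bounds("Gorgosaurus"), 12L)
  expect_equal(diapophysis_bounds("Tyrannosaurus"), 17L)
  expect_error(diapophysis_bounds("Allosaurus"), "unknown template taxon")
})

test_that("assign_positions: exact matches, constraints and infeasibility", {
  tpl <- data.frame(position = 1:10, pct_asi = 100 * 0.9^(0:9))
  # a vertebra matching one template value exactly, no conflicts
  out <- assign_positions(c(100, 100 * 0.9^3), tpl)
  expect_equal(out$position, c(1, 4))
  expect_equal(attr(out, "total_error"), 0)
  # diapophysis constraint pushes assignments forward
  tpl2 <- data.frame(position = 1:6, pct_asi = c(100, 90, 80, 70, 60, 50))
  out2 <- assign_positions(c(72, 52), tpl2,
                           diapophysis_flags = c(TRUE, TRUE),
                           last_diapophysis = 5)
  expect_true(all(out2$position <= 5))
  expect_true(all(diff(out2$position) > 0))
  # more diapophysis-bearing vertebrae than allowed positions -> error
  expect_error(
    assign_positions(c(90, 80, 70), tpl2, rep(TRUE, 3), last_diapophysis = 2),
    "infeasible")
  # NA template rows are unusable
  tpl3 <- data.frame(position = 1:4, pct_asi = c(100, NA, 80, 70))
  out3 <- assign_positions(c(95, 72), tpl3)
  expect_equal(out3$position, c(1, 4))
})

test_that("assign_positions equals the brute-force monotone alignment oracle
           (property, <=8 vertebrae x <=12 positions)", {
  set.seed(85)
  for (r in 1:40) {
    P <- sample(4:12, 1)
    m <- sample(2:min(8, P), 1)
    tpl <- data.frame(position = sort(sample(1:(P + 3), P)),
                      pct_asi = sort(runif(P, 5, 120), decreasing = TRUE))
    pct <- sort(runif(m, 5, 120), decreasing = TRUE)
    flags <- runif(m) < 0.3
    dia_max <- sample(tpl$position, 1)
    oracle <- brute_assign(pct, tpl, flags, dia_max)
    if (!is.finite(oracle$total)) {
      expect_error(assign_positions(pct, tpl, flags, dia_max), "infeasible")
      next
    }
    got <- assign_positions(pct, tpl, flags, dia_max)
    expect_equal(attr(got, "total_error"), oracle$total,
                 tolerance = 1e-9, label = paste("rep", r))
    expect_true(all(diff(got$position) > 0))
    expect_true(all(!flags | got$position <= dia_max))
  }
})
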