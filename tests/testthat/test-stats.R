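test_that("exact p-values match hand-enumerated cases", {
  res <- mann_whitney_exact(1:3, 4:6)
  expect_identical(res$U, 0)
  expect_equal(res$p_value, 0.1)        # 2 * 1/20
  expect_identical(res$method, "exact")
  # complete separation at 7 vs 7: 2 / choose(14, 7)
  res2 <- mann_whitney_exact(1:7, 8:14)
  expect_equal(res2$p_value, 2 / 3432)
  # identical samples
  res3 <- mann_whitney_exact(c(2, 2, 2), c(2, 2, 2))
  expect_identical(res3$p_value, 1)
  expect_identical(res3$method, "degenerate")
})

test_that("exact p agrees with the brute-force oracle for all n1, n2 <= 5", {
  set.seed(41)
  for (n1 in 2:5) for (n2 in 2:5) {
    for (rep in 1:3) {
      x <- sample(1:6, n1, replace = TRUE)   # heavy ties on purpose
      y <- sample(1:6, n2, replace = TRUE)
      got <- mann_whitney_exact(x, y)
      want <- oracle_mw(x, y)
      expect_equal(got$U, want$U)
      expect_equal(got$p_value, want$p_value)
    }
  }
})

test_that("tie-free exact p agrees with wilcox.test", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(6)
    y <- rnorm(7, 0.5)
    got <- mann_whitney_exact(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("U is antisymmetric: U(x,y) + U(y,x) = n1 * n2", {
  set.seed(43)
  for (rep in 1:10) {
    x <- sample(1:8, 5, replace = TRUE)
    y <- sample(1:8, 6, replace = TRUE)
    expect_equal(mann_whitney_exact(x, y)$U + mann_whitney_exact(y, x)$U,
                 5 * 6)
  }
})

test_that("large samples fall back to the tie-corrected normal method", {
  set.seed(44)
  x <- rnorm(12)
  y <- rnorm(12, 1)
  got <- mann_whitney_exact(x, y)
  expect_identical(got$method, "normal")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("small groups are rejected", {
  expect_error(mann_whitney_exact(1, 2:5), ">= 2")
})

test_that("group summaries flag effects and skip incomplete parameters", {
  df <- data.frame(
    group = rep(c("sham", "OVX"), each = 7),
    flat = rep(1.5, 14),
    shifted = c(rnorm(7, 10, 0.1), rnorm(7, 20, 0.1)),
    holey = c(NA, rnorm(13))
  )
  expect_warning(cmp <- summarize_groups(df), "holey")
  expect_setequal(cmp$parameter, c("flat", "shifted"))
  expect_false(cmp$significant[cmp$parameter == "flat"])
  expect_true(cmp$significant[cmp$parameter == "shifted"])
  expect_true(all(cmp$method %in% c("exact", "degenerate")))  # n = 14
  expect_equal(cmp$p_value[cmp$parameter == "shifted"], 2 / 3432)
})

test_that("a 3x roughness effect is detected in nearly every cohort", {
  cs <- cohort_spec(seed = NULL)
  set.seed(45)
  hits <- 0L
  for (r in 1:100) {
    lat <- cartiqus:::draw_cohort_parameters(cs)
    tab <- lat$sites$MTP
    p <- mann_whitney_exact(tab$surface_roughness_sd[tab$group == "sham"],
                            tab$surface_roughness_sd[tab$group == "OVX"])
    hits <- hits + (p$p_value <= 0.05)
  }
  expect_gte(hits, 95)
})

test_that("the exact test controls type-I error under the null", {
  cs_null <- cohort_spec(
    ovx_effects = list(MTP = c(surface_roughness_sd = 1),
                       LTP = c(surface_roughness_sd = 1),
                       bone = c(radius_vox = 1)),
    seed = NULL)
  # attained size of the discrete two-sided test at nominal 0.05,
  # from the exact null distribution of U at n = 7 + 7
  r <- rank(1:14)
  idx <- utils::combn(14, 7)
  u_all <- colSums(matrix(r[idx], nrow = 7)) - 7 * 8 / 2
  p_all <- vapply(u_all, function(u) {
    min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
  }, numeric(1))
  alpha_star <- mean(p_all <= 0.05)
  expect_lte(alpha_star, 0.05)

  set.seed(46)
  n_rep <- 1000L
  rejections <- 0L
  for (r_ in seq_len(n_rep)) {
    lat <- cartiqus:::draw_cohort_parameters(cs_null)
    tab <- lat$sites$MTP
    p <- mann_whitney_exact(tab$surface_roughness_sd[tab$group == "sham"],
                            tab$surface_roughness_sd[tab$group == "OVX"])
    rejections <- rejections + (p$p_value <= 0.05)
  }
  bounds <- stats::qbinom(c(0.0025, 0.9975), n_rep, alpha_star)
  expect_gte(rejections, bounds[1])
  expect_lte(rejections, bounds[2])
})
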