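test_that("truncation intensities reproduce the breeders'-table values", {
  expect_equal(round(selection_intensity(0.05), 2), 2.06)
  expect_equal(selection_intensity(0.10), 1.755, tolerance = 1e-3)
  expect_equal(round(selection_intensity(0.20), 1), 1.4)
  expect_equal(selection_intensity(0.50), dnorm(0) / 0.5, tolerance = 1e-12)
  expect_error(selection_intensity(0), "strictly")
  expect_error(selection_intensity(1), "strictly")
})

test_that("intensity decreases strictly in pressure and vanishes at p = 1", {
  p <- seq(0.01, 0.99, by = 0.01)
  k <- selection_intensity(p)
  expect_true(all(diff(k) < 0))
  expect_lt(selection_intensity(0.9999), 0.01)
})

test_that("the among-family phenotypic standard deviation follows its formula", {
  expect_equal(family_phenotypic_sd(13.5, 4.7, 49.6, 2), sqrt(40.65))
  expect_equal(round(family_phenotypic_sd(13.5, 4.7, 49.6, 2), 3), 6.376)
  expect_equal(family_phenotypic_sd(9, 0, 0, 5), 3)
  expect_equal(family_phenotypic_sd(0, 0, 0, 2), 0)
})

test_that("predicted gain matches the worked shoot and root examples", {
  spf <- family_phenotypic_sd(13.5, 4.7, 49.6, 2)
  g5 <- predicted_gain(selection_plan(0.05), 13.5, spf, 11.4)
  expect_equal(round(g5$dG, 2), 2.18)
  expect_equal(round(g5$dG_percent), 19)
  g20 <- predicted_gain(selection_plan(0.20), 13.5, spf, 11.4)
  expect_equal(round(g20$dG_percent), 13)
  # zero intensity means zero gain; gain is linear in k and sigma_f2
  g0 <- predicted_gain(selection_plan(0.5, intensity = 0), 13.5, spf, 11.4)
  expect_equal(g0$dG, 0)
  g1 <- predicted_gain(selection_plan(0.5, intensity = 1), 13.5, spf, 11.4)
  g2 <- predicted_gain(selection_plan(0.5, intensity = 2), 13.5, spf, 11.4)
  expect_equal(g2$dG, 2 * g1$dG)
  gh <- predicted_gain(selection_plan(0.5, intensity = 1), 27, spf, 11.4)
  expect_equal(gh$dG, 2 * g1$dG)
  expect_error(predicted_gain(selection_plan(0.05), 13.5, 0, 11.4),
               "degenerate")
})

test_that("selection plans validate their domain", {
  expect_error(selection_plan(0), "pressure")
  expect_error(selection_plan(1.2), "pressure")
  expect_error(selection_plan(0.05, parental_control = 0), "parental_control")
  plan <- selection_plan(0.05)
  expect_equal(plan$parental_control, 0.5)
  expect_equal(plan$intensity, selection_intensity(0.05))
})

test_that("index coefficients solve the hand-worked 2x2 system", {
  P <- matrix(c(4, 1, 1, 2), 2)
  A <- matrix(c(2, 0.5, 0.5, 1), 2)
  b <- smith_hazel_coefficients(P, A, c(1, 1))
  expect_equal(unname(b), c(0.5, 0.5), tolerance = 1e-10)
  rhs <- A %*% c(1, 1)
  expect_lt(sqrt(sum((P %*% b - rhs)^2)) / sqrt(sum(rhs^2)), 1e-8)
})

test_that("index coefficients collapse to known special cases", {
  # P = A: b equals the weights
  P <- matrix(c(2, 0.3, 0.3, 1), 2)
  expect_equal(unname(smith_hazel_coefficients(P, P, c(1, 2))), c(1, 2),
               tolerance = 1e-10)
  # single trait: b = h2 * w
  b1 <- smith_hazel_coefficients(matrix(4), matrix(1.2), 2)
  expect_equal(unname(b1), (1.2 / 4) * 2)
  expect_error(smith_hazel_coefficients(matrix(c(1, 2, 3, 4), 2), P, c(1, 1)),
               "symmetric")
  expect_error(smith_hazel_coefficients(matrix(c(1, 2, 2, 1), 2), P, c(1, 1)),
               "positive-definite")
})

test_that("index scores rank families exactly as a brute-force sort", {
  set.seed(21)
  m <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("f%02d", 1:20), c("a", "b", "c")))
  b <- c(0.7, 0.2, 0.1)
  res <- index_scores(b, m)
  brute <- drop(m %*% b)
  expect_equal(res$family, names(sort(-brute)))
  expect_equal(res$rank, 1:20)
  # b = (1, 0): ranking equals the single-trait ranking
  r1 <- index_scores(c(1, 0, 0), m)
  expect_equal(r1$family, names(sort(-m[, "a"])))
  # equal half weights give the two-trait mean
  r2 <- index_scores(c(0.5, 0.5), m[, 1:2])
  expect_equal(setNames(r2$score, r2$family),
               sort(rowMeans(m[, 1:2]), decreasing = TRUE))
})

test_that("raising a family's traits never lowers its score under b >= 0", {
  set.seed(22)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(letters[1:10], NULL))
  b <- c(0.5, 0.3, 0.2)
  s0 <- index_scores(b, m)
  m2 <- m
  m2["d", ] <- m2["d", ] + 1
  s1 <- index_scores(b, m2)
  expect_gte(s1$score[s1$family == "d"], s0$score[s0$family == "d"])
  expect_lte(s1$rank[s1$family == "d"], s0$rank[s0$family == "d"])
})

test_that("families with missing traits are excluded with a warning", {
  m <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("x", "y", "z"), NULL))
  expect_warning(res <- index_scores(c(1, 1), m), "excluded")
  expect_equal(sort(res$family), c("x", "z"))
})

test_that("correlated response follows its product form and limits", {
  plan5 <- selection_plan(0.05, intensity = 2.06)
  expect_equal(correlated_response(plan5, 0.6, 0.5, 0, 3), 0)
  # rA = 1 with equal h reduces to the direct-response form k c h^2 sigma
  h <- sqrt(0.33)
  expect_equal(correlated_response(plan5, h, h, 1, 6.376),
               2.06 * 0.5 * 0.33 * 6.376)
  # worked arithmetic example
  expect_equal(round(correlated_response(plan5, sqrt(0.33), sqrt(0.24),
                                         0.62, sqrt(0.06)), 4), 0.044)
  # sign follows the genetic correlation
  expect_lt(correlated_response(plan5, 0.5, 0.5, -0.4, 2), 0)
  expect_error(correlated_response(plan5, 1.4, 0.5, 0.2, 1), "0, 1")
  expect_error(correlated_response(plan5, 0.5, 0.5, 1.2, 1), "r_a")
})

test_that("top-fraction selection sizes and tie-breaks are deterministic", {
  v <- setNames(120:1, sprintf("fam%03d", 1:120))
  expect_length(select_top(v, 0.05), 6)
  expect_length(select_top(v, 0.10), 12)
  expect_length(select_top(v, 0.20), 24)
  expect_equal(select_top(v, 0.05), sprintf("fam%03d", 1:6))
  ties <- setNames(rep(1, 10), sprintf("f%02d", 10:1))
  expect_warning(top <- select_top(ties, 0.3), "tie")
  expect_equal(top, sprintf("f%02d", 1:3))
  expect_error(select_top(numeric(0), 0.1), "empty")
  expect_error(select_top(v, 0), "\\(0, 1\\]")
})

test_that("overlap summaries count shared and unique families", {
  a <- c("f1", "f2", "f3")
  b <- c("f2", "f3", "f4")
  ov <- selection_overlap(list(A = a, B = b))
  expect_equal(ov$pairwise$overlap, 2)
  expect_equal(sort(ov$common), c("f2", "f3"))
  expect_equal(ov$unique$A, "f1")
  same <- selection_overlap(list(A = a, B = a))
  expect_equal(same$pairwise$overlap, 3)
  disj <- selection_overlap(list(A = a, B = c("f7", "f8")))
  expect_equal(disj$pairwise$overlap, 0)
  expect_length(disj$common, 0)
  expect_error(selection_overlap(list(a)), "2 sets")
})

test_that("correlated traits share more top selections than the null", {
  # two traits with additive correlation 0.62: the mean overlap of the two
  # top-10% selections must exceed the hypergeometric expectation 12^2/120
  r <- 0.62
  sig <- matrix(c(1, r, r, 1), 2)
  ov <- vapply(1:50, function(s) {
    set.seed(s)
    m <- rmvnorm_chol(120, sig)
    rownames(m) <- sprintf("f%03d", 1:120)
    s1 <- select_top(setNames(m[, 1], rownames(m)), 0.10)
    s2 <- select_top(setNames(m[, 2], rownames(m)), 0.10)
    length(intersect(s1, s2))
  }, numeric(1))
  expect_gt(mean(ov), 12^2 / 120)
})
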