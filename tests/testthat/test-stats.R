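test_that("Spearman matrices are symmetric, bounded, unit-diagonal", {
  set.seed(8)
  df <- data.frame(nc_yap = rnorm(50, 1.5, 0.3))
  df$prop_exposed <- plogis(df$nc_yap + rnorm(50, 0, 0.5))
  df$volume <- runif(50, 3000, 5000)
  df$stage <- 16
  cr <- correlate_records(df, c("nc_yap", "prop_exposed", "volume"))
  expect_identical(cr$rho, t(cr$rho))
  expect_true(all(abs(cr$rho) <= 1 + 1e-12))
  expect_equal(unname(diag(cr$rho)), rep(1, 3))
  # perfectly monotone pair
  df$mono <- exp(df$nc_yap)
  cr2 <- correlate_records(df, c("nc_yap", "mono"))
  expect_equal(cr2$rho["nc_yap", "mono"], 1)
  # constant column reported absent
  df$const <- 5
  cr3 <- correlate_records(df, c("nc_yap", "const"))
  expect_true(is.na(cr3$rho["nc_yap", "const"]))
})

test_that("independent columns show near-zero correlation", {
  hits <- vapply(1:10, function(s) {
    set.seed(700 + s)
    df <- data.frame(a = rnorm(200), b = rnorm(200), stage = 16)
    abs(correlate_records(df, c("a", "b"))$rho["a", "b"]) < 0.15
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("stage filters restrict the correlation sample", {
  df <- data.frame(a = rnorm(60), b = rnorm(60),
                   stage = rep(c(8, 16, 32), each = 20))
  cr <- correlate_records(df, c("a", "b"), stages = c(16, 32))
  expect_equal(cr$n["a", "b"], 40)
})

test_that("identical groups are not declared different", {
  set.seed(9)
  v <- rnorm(60)
  df <- data.frame(g = rep(c("a", "b"), each = 30), v = c(v[1:30], v[1:30]))
  gt <- group_tests(df, "g", "v")
  expect_gt(gt$p, 0.05)
})

test_that("the normality gate picks ANOVA for Gaussian, KW for log-normal", {
  set.seed(10)
  norm_df <- data.frame(g = rep(c("a", "b", "c"), each = 40),
                        v = rnorm(120, rep(c(0, 0.2, 0.4), each = 40)))
  gn <- group_tests(norm_df, "g", "v")
  expect_equal(gn$test, "anova")
  expect_true("comparison" %in% names(gn$posthoc))

  hits <- vapply(1:10, function(s) {
    set.seed(800 + s)
    sdlog <- 0.5
    ln_df <- data.frame(
      g = rep(c("a", "b"), each = 30),
      v = c(rlnorm(30, 0, sdlog),
            rlnorm(30, 0, sdlog) + exp(sdlog^2 / 2) *
              sqrt(exp(sdlog^2) - 1))) # shift by one sd of the log-normal
    gt <- group_tests(ln_df, "g", "v")
    gt$test == "kruskal-wallis" && gt$p < 0.01
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("Dunn post-hoc flags the shifted group with Holm adjustment", {
  set.seed(12)
  df <- data.frame(g = rep(c("a", "b", "c"), each = 25),
                   v = c(rlnorm(25), rlnorm(25), rlnorm(25, 1.5)))
  gt <- group_tests(df, "g", "v")
  expect_equal(gt$test, "kruskal-wallis")
  ph <- gt$posthoc
  expect_setequal(names(ph), c("group1", "group2", "z", "p", "p_adj"))
  expect_true(all(ph$p_adj >= ph$p))
  worst <- ph[which.min(ph$p_adj), ]
  expect_true("c" %in% c(worst$group1, worst$group2))
  expect_lt(worst$p_adj, 0.01)
  # the a-b contrast is null
  null_row <- ph[ph$group1 == "a" & ph$group2 == "b", ]
  expect_gt(null_row$p, 0.05)
})

test_that("small groups skip the omnibus test with a warning", {
  df <- data.frame(g = c("a", "a", "a", "b", "b"), v = rnorm(5))
  expect_warning(gt <- group_tests(df, "g", "v"), "fewer than 3")
  expect_true(is.na(gt$p))
})

test_that("Fisher's exact test matches the hypergeometric enumeration", {
  tab <- matrix(c(10, 0, 0, 10), 2)
  ft <- fisher_2x2(tab)
  # two-sided p for a diagonal 2x2 table: both extreme tables, each with
  # probability 1 / choose(20, 10)
  expect_equal(ft$p.value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(ft$p.value, 1e-4)
  expect_error(fisher_2x2(matrix(1, 3, 3)))
})

test_that("confinement comparison reports medians, shifts and composition", {
  set.seed(14)
  mk <- function(p_mu, nc_mu, n) {
    data.frame(prop_exposed = pmax(rnorm(n, p_mu, 0.05), 0),
               nc_yap = rnorm(n, nc_mu, 0.15), stage = 16)
  }
  ctl <- mk(0.35, 1.8, 80)
  cyl <- mk(0.20, 1.4, 80)
  rep_ <- suppressWarnings(confinement_compare(ctl, cyl))
  expect_lt(rep_$medians["confined", "prop_exposed"],
            rep_$medians["control", "prop_exposed"])
  expect_lt(rep_$medians["confined", "nc_yap"],
            rep_$medians["control", "nc_yap"])
  expect_lt(rep_$shift_tests$prop_exposed$p, 0.001)
  expect_equal(sum(rep_$composition["control", ]), 100, tolerance = 1e-9)
  # identical cohorts: no shift detected
  same <- suppressWarnings(confinement_compare(ctl, ctl))
  expect_gt(same$shift_tests$prop_exposed$p, 0.05)
})
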