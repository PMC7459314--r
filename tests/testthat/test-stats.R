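# Group statistics against closed-form hand computations and null
# simulations.

toy_table <- function(values) {
  # balanced 2x2 with 2 replicates per cell; `values` in cell-major order
  data.frame(strain = rep(c("A", "B"), each = 4),
             age_weeks = rep(rep(c(1, 2), each = 2), 2),
             y = values)
}

# closed-form balanced two-way SS from cell/marginal means
balanced_ss <- function(tab) {
  y <- tab$y
  A <- factor(tab$strain); B <- factor(tab$age_weeks)
  gm <- mean(y)
  n_cell <- length(y) / (nlevels(A) * nlevels(B))
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ss_a <- n_cell * nlevels(B) * sum((mA - gm)^2)
  ss_b <- n_cell * nlevels(A) * sum((mB - gm)^2)
  cellm <- tapply(y, list(A, B), mean)
  ss_ab <- n_cell * sum((sweep(sweep(cellm, 1, mA - gm), 2, mB - gm) - gm)^2)
  ss_res <- sum((y - ave(y, A, B))^2)
  list(a = ss_a, b = ss_b, ab = ss_ab, res = ss_res)
}

test_that("a flat table yields zero effect sums of squares", {
  a <- two_way_anova(toy_table(c(10, 10, 10, 10, 10, 10, 10, 10) + rep(0, 8)),
                     "y")
  expect_equal(a$table$sum_sq[1:3], rep(0, 3), tolerance = 1e-12)
})

test_that("balanced two-way SS match the closed-form oracle to 1e-10", {
  tab <- toy_table(c(1, 2, 3, 4, 5, 6, 7, 8))
  a <- two_way_anova(tab, "y")
  oracle <- balanced_ss(tab)
  got <- setNames(a$table$sum_sq, a$table$term)
  expect_equal(unname(got["strain"]), oracle$a, tolerance = 1e-10)
  expect_equal(unname(got["age_weeks"]), oracle$b, tolerance = 1e-10)
  expect_equal(unname(got["strain:age_weeks"]), oracle$ab, tolerance = 1e-10)
  expect_equal(unname(got["residuals"]), oracle$res, tolerance = 1e-10)
  # df partition: effects + residual = n - 1
  expect_equal(sum(a$table$df), nrow(tab) - 1)
})

test_that("empty or underfilled design cells are rejected by name", {
  tab <- toy_table(1:8)[-(1:2), ]
  expect_error(two_way_anova(tab, "y"), "empty design cell")
  tab2 <- toy_table(1:8)[-1, ]
  expect_error(two_way_anova(tab2, "y"), "2 replicates")
})

test_that("strain F test holds its nominal type-I error under the null", {
  # 2 x 4 design, n = 5 per cell, no effects; 2000 simulated studies
  set.seed(2024)
  n_rej <- 0L
  reps <- 2000L
  design <- expand.grid(r = 1:5, strain = c("A", "B"),
                        age_weeks = c(4, 8, 18, 24))
  for (i in seq_len(reps)) {
    design$y <- rnorm(nrow(design))
    a <- two_way_anova(design, "y")
    p <- a$table$p_value[a$table$term == "strain"]
    if (p < 0.05) n_rej <- n_rej + 1L
  }
  expect_equal(n_rej / reps, 0.05, tolerance = 0.01 / 0.05)
})

test_that("Fisher LSD reproduces the closed-form pooled t", {
  # identical cells: t = 0, p = 1
  tab <- toy_table(rep(c(3, 4), 4))
  a <- two_way_anova(tab, "y")
  same <- fisher_lsd(a, list(strain = "A", age_weeks = 1),
                     list(strain = "B", age_weeks = 1))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # hand-built cells: means 10 vs 12, MSE known from the fit
  tab2 <- data.frame(strain = rep(c("A", "B"), each = 10),
                     age_weeks = rep(rep(c(1, 2), each = 5), 2))
  set.seed(11)
  tab2$y <- rnorm(20) + ifelse(tab2$strain == "B", 2, 0)
  a2 <- two_way_anova(tab2, "y")
  lsd <- fisher_lsd(a2, list(strain = "A", age_weeks = 1),
                    list(strain = "B", age_weeks = 1))
  m <- tapply(tab2$y, interaction(tab2$strain, tab2$age_weeks), mean)
  t_hand <- (m[["A.1"]] - m[["B.1"]]) / sqrt(a2$mse * (1 / 5 + 1 / 5))
  expect_equal(lsd$statistic, t_hand, tolerance = 1e-10)
  expect_equal(lsd$p_value, 2 * pt(-abs(t_hand), a2$df_residual),
               tolerance = 1e-12)
  expect_error(fisher_lsd(a2, list(strain = "A", age_weeks = 9),
                          list(strain = "B", age_weeks = 1)), "no such")
})

test_that("uncorrected LSD inflates family-wise error under the null", {
  # the known liability of the procedure: with 8 cells and 28 pairwise
  # comparisons, the chance of at least one p < 0.05 exceeds 0.05
  set.seed(77)
  design <- expand.grid(r = 1:5, strain = c("A", "B"),
                        age_weeks = c(4, 8, 18, 24))
  cells <- expand.grid(strain = c("A", "B"), age_weeks = c(4, 8, 18, 24),
                       stringsAsFactors = FALSE)
  fwer_hits <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    design$y <- rnorm(nrow(design))
    a <- two_way_anova(design, "y")
    ps <- c()
    for (c1 in 1:7) for (c2 in (c1 + 1):8) {
      ps <- c(ps, fisher_lsd(a, as.list(cells[c1, ]),
                             as.list(cells[c2, ]))$p_value)
    }
    if (any(ps < 0.05)) fwer_hits <- fwer_hits + 1L
  }
  expect_gt(fwer_hits / reps, 0.05)
})

test_that("Pearson correlation matches hand computation", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  # product-moment sums by hand: r = 3 / 5 = 0.6
  pc <- pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(pc$r, 0.6, tolerance = 1e-12)
  # independent noise: |r| small
  set.seed(5)
  pc0 <- pearson_cor(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(pc0$r), 0.03)
  expect_error(pearson_cor(rep(1, 5), 1:5), "constant")
})

test_that("Student t matches the closed-form pooled statistic", {
  s <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(s$p_value, 1)
  expect_lt(student_t(c(1, 2, 3), c(11, 12, 13))$p_value, 0.01)
  # hand case (1,2,3,4) vs (2,3,4,5): pooled sd, t = -1 / sqrt(5/6 * ...)
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  s2 <- student_t(x, y)
  expect_equal(s2$statistic, t_hand, tolerance = 1e-10)
  expect_equal(s2$p_value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  expect_error(student_t(c(1, 1, 1), c(2, 2, 2)), "zero pooled variance")
})

test_that("min-max normalization maps metrics onto [0,1] and is idempotent", {
  tab <- data.frame(a = c(2, 4, 6), b = c(0, 0.5, 1))
  n1 <- minmax_normalize(tab, c("a", "b"))
  expect_identical(n1$a, c(0, 0.5, 1))
  expect_identical(n1$b, tab$b)  # already [0,1] with min 0 and max 1
  expect_identical(minmax_normalize(n1, c("a", "b")), n1)
  expect_error(minmax_normalize(data.frame(a = rep(1, 3)), "a"), "constant")
})
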