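# From-scratch two-way ANOVA oracle for a balanced 2x2 design (sums of
# squares computed directly from cell means), used to cross-check the
# model-based implementation.
balanced_anova_oracle <- function(df, response) {
  y <- df[[response]]
  g <- factor(df$genotype); te <- factor(df$temperature)
  n <- length(y) / 4
  gm <- mean(y)
  mg <- tapply(y, g, mean); mt <- tapply(y, te, mean)
  mc <- tapply(y, interaction(g, te), mean)
  ss_g <- 2 * n * sum((mg - gm)^2)
  ss_t <- 2 * n * sum((mt - gm)^2)
  cells <- expand.grid(g = levels(g), te = levels(te))
  ss_int <- n * sum(vapply(seq_len(nrow(cells)), function(i) {
    key <- paste(cells$g[i], cells$te[i], sep = ".")
    (mc[[key]] - mg[[cells$g[i]]] - mt[[as.character(cells$te[i])]] + gm)^2
  }, numeric(1)))
  ss_res <- sum((y - ave(y, g, te))^2)
  df_res <- length(y) - 4
  list(F_g = (ss_g / 1) / (ss_res / df_res),
       F_t = (ss_t / 1) / (ss_res / df_res),
       F_int = (ss_int / 1) / (ss_res / df_res), df_res = df_res)
}

perm_interaction_p <- function(df, response, n_perm = 2000, seed = 99) {
  f_obs <- balanced_anova_oracle(df, response)$F_int
  set.seed(seed)
  exceed <- replicate(n_perm, {
    d2 <- df
    d2[[response]] <- sample(d2[[response]])
    balanced_anova_oracle(d2, response)$F_int >= f_obs
  })
  (sum(exceed) + 1) / (n_perm + 1)
}

make_design <- function(n, fun) {
  df <- expand.grid(genotype = c("WT", "MUT"), temperature = c(22, 37),
                    rep = seq_len(n), stringsAsFactors = FALSE)
  df$y <- fun(df)
  df
}

test_that("equal group means with zero residual variance give F = 0, p = 1", {
  df <- make_design(4, function(d) rep(5, nrow(d)))
  res <- interactionAnova(df, "y")
  expect_true(all(res@effects$F == 0))
  expect_true(all(res@effects$p == 1))
  expect_true(res@stepdown_applied)
})

test_that("a pure interaction effect is detected and matches the oracles", {
  set.seed(21)
  df <- make_design(10, function(d)
    rnorm(nrow(d)) + 3 * (d$genotype == "MUT") * (d$temperature == 37) -
      1.5 * (d$genotype == "MUT") - 1.5 * (d$temperature == 37))
  res <- interactionAnova(df, "y")
  eff <- res@effects
  p_int <- eff$p[eff$effect == "genotype:temperature"]
  expect_lt(p_int, 0.001)
  expect_false(res@stepdown_applied)
  # F agrees with the from-scratch sum-of-squares computation
  orc <- balanced_anova_oracle(df, "y")
  expect_equal(eff$F[eff$effect == "genotype:temperature"], orc$F_int,
               tolerance = 1e-10)
  # and the permutation oracle on the same data also rejects
  expect_lt(perm_interaction_p(df, "y"), 0.005)
})

test_that("additive stepdown matches the from-scratch main-effect F values", {
  set.seed(31)
  df <- make_design(8, function(d)
    rnorm(nrow(d)) + 2 * (d$genotype == "MUT") + 1 * (d$temperature == 37))
  res <- interactionAnova(df, "y")
  expect_true(res@stepdown_applied)
  eff <- res@effects
  # balanced design: Type-II main-effect F equals the classical decomposition
  # computed under the interaction model with the additive residual
  fit_add <- lm(y ~ genotype + temperature, data = df)
  a <- anova(fit_add)
  expect_equal(eff$F[eff$effect == "genotype"], a["genotype", "F value"],
               tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "temperature"],
               a["temperature", "F value"], tolerance = 1e-10)
})

test_that("row order never changes the results", {
  set.seed(41)
  df <- make_design(6, function(d) rnorm(nrow(d), sd = 2))
  r1 <- interactionAnova(df, "y")
  r2 <- interactionAnova(df[sample(nrow(df)), ], "y")
  expect_equal(r1@effects, r2@effects, tolerance = 1e-12)
})

test_that("design deficiencies are named errors", {
  df <- make_design(4, function(d) rnorm(nrow(d)))
  expect_error(interactionAnova(df[df$genotype == "WT", ], "y"),
               "design-deficiency")
  expect_error(
    interactionAnova(df[!(df$genotype == "WT" & df$temperature == 37), ],
                     "y"), "design-deficiency")
  one <- data.frame(genotype = c("WT", "MUT"), voltage = 0, tau = c(1, 2))
  expect_error(perVoltageTests(one), "design-deficiency")
})

test_that("power grows monotonically with interaction effect size", {
  rates <- vapply(c(0, 1.5, 3), function(es) {
    set.seed(51)
    rej <- replicate(60, {
      df <- make_design(8, function(d)
        rnorm(nrow(d)) + es * (d$genotype == "MUT") * (d$temperature == 37))
      eff <- interactionAnova(df, "y")@effects
      eff$p[eff$effect == "genotype:temperature"] < 0.05
    })
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})

test_that("per-voltage contrasts behave at both extremes", {
  # identical noise-free tau values: no contrast is significant
  grid <- expand.grid(genotype = c("WT", "MUT"), voltage = seq(-30, 20, 10),
                      rep = 1:5, stringsAsFactors = FALSE)
  grid$tau <- 0.5 * exp(-grid$voltage / 25)
  res <- perVoltageTests(grid)
  expect_true(all(res$p == 1))
  # a genuine 1.485-fold rate difference at 5% cell scatter rejects everywhere
  set.seed(61)
  grid2 <- grid
  fac <- exp(rnorm(nrow(grid2), 0, 0.05))
  grid2$tau <- grid2$tau * fac / ifelse(grid2$genotype == "MUT", 1.485, 1)
  res2 <- perVoltageTests(grid2)
  expect_true(all(res2$p < 0.05))
  # non-positive tau is a transform error naming the cell
  grid2$tau[3] <- 0
  expect_error(perVoltageTests(grid2), "transform error")
})
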