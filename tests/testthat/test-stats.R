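test_that("degenerate and separated groups are handled explicitly", {
  # identical groups: F = 0, all pairwise p = 1, one shared letter
  same <- anova_tukey(list(a = c(2, 2, 2), b = c(2, 2, 2), c = c(2, 2, 2)))
  expect_true(same$degenerate)
  expect_identical(same$anova$F, 0)
  expect_true(all(same$tukey$p_adj == 1))
  expect_true(all(same$letters == "a"))
  # zero variance with separated means: p = 0, degenerate flag
  sep0 <- anova_tukey(list(a = c(1, 1), b = c(5, 5)))
  expect_true(sep0$degenerate)
  expect_identical(sep0$tukey$p_adj, 0)
  # complete separation with variance: tiny p, distinct letters
  cmp <- anova_tukey(list(g1 = c(1, 2, 3), g2 = c(101, 102, 103)))
  expect_lt(cmp$tukey$p_adj, 1e-6)
  expect_false(cmp$letters["g1"] == cmp$letters["g2"])
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Tukey adjusted p matches the studentized-range quadrature
           oracle", {
  set.seed(21)
  df <- data.frame(value = c(rnorm(4, 0), rnorm(4, 0.8), rnorm(4, 2.2)),
                   group = rep(c("a", "b", "c"), each = 4))
  cmp <- anova_tukey(df)
  fit <- aov(value ~ group, data = transform(df, group = factor(group)))
  mse <- sum(fit$residuals^2) / fit$df.residual
  gm <- tapply(df$value, df$group, mean)
  for (i in seq_len(nrow(cmp$tukey))) {
    g1 <- cmp$tukey$group1[i]; g2 <- cmp$tukey$group2[i]
    q_obs <- abs(gm[g2] - gm[g1]) / sqrt(mse / 4)
    p_oracle <- 1 - oracle_ptukey(q_obs, k = 3, df = fit$df.residual)
    expect_lt(abs(cmp$tukey$p_adj[i] - p_oracle), 1e-4)
  }
})

test_that("ANOVA holds its type-I error under the null", {
  set.seed(17)
  reps <- 1000L
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- data.frame(value = rnorm(15), group = rep(c("a", "b", "c"), 5))
    p[r] <- anova_tukey(d)$anova$p
  }
  alpha_hat <- mean(p < 0.05)
  expect_gte(alpha_hat, 0.03)
  expect_lte(alpha_hat, 0.07)
})

test_that("Tukey familywise error with four equal groups stays at level", {
  set.seed(31)
  reps <- 1000L
  any_sig <- logical(reps)
  for (r in seq_len(reps)) {
    d <- data.frame(value = rnorm(20), group = rep(letters[1:4], 5))
    any_sig[r] <- any(anova_tukey(d)$tukey$p_adj < 0.05)
  }
  expect_lte(mean(any_sig), 0.07)
})

test_that("letter display satisfies the share-iff-nonsignificant contract", {
  # chain: A != C significant, A-B and B-C not
  P <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  P["A", "C"] <- P["C", "A"] <- 0.001
  lt <- letter_display(P, alpha = 0.05)
  expect_identical(unname(lt), c("a", "ab", "b"))
  # a single letter cannot code the chain (minimality witness)
  expect_gt(length(unique(strsplit(paste(lt, collapse = ""), "")[[1]])), 1L)
  # all-significant: four distinct letters
  P4 <- matrix(0.001, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(P4) <- 1
  expect_identical(sort(unname(letter_display(P4))), c("a", "b", "c", "d"))
  # random p-matrices: contract holds pair by pair
  set.seed(8)
  for (rep_ in 1:25) {
    k <- sample(3:6, 1)
    P <- matrix(1, k, k)
    up <- upper.tri(P)
    P[up] <- runif(sum(up))
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
    dimnames(P) <- list(paste0("g", 1:k), paste0("g", 1:k))
    lt <- letter_display(P, alpha = 0.2)
    expect_true(all(nchar(lt) >= 1))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      share <- length(intersect(strsplit(lt[i], "")[[1]],
                                strsplit(lt[j], "")[[1]])) > 0
      expect_identical(share, P[i, j] >= 0.2)
    }
  }
})

test_that("fold changes report calibrated ratios against the baseline", {
  recs <- data.frame(apex_id = paste0("a", 1:4),
                     genotype = "WT",
                     condition = rep(c("veg", "domed"), each = 2),
                     meristem_area = c(4000, 4100, 16200, 15800),
                     cell_number = c(240, 236, 830, 850),
                     median_cell_area = c(10.5, 10.7, 19.1, 18.9))
  fc <- fold_changes(recs, baseline = "veg")
  base <- fc[fc$condition == "veg", ]
  expect_equal(base$area_ratio, 1.0)
  expect_equal(base$median_cell_area_change_pct, 0.0)
  domed <- fc[fc$condition == "domed", ]
  expect_equal(domed$area_ratio, mean(c(16200, 15800)) / mean(c(4000, 4100)))
  expect_equal(domed$cell_number_ratio, 840 / 238)
  expect_error(fold_changes(recs, baseline = "missing"), "absent")
})

test_that("the pipeline runner validates configs, writes a summary and is
           reproducible", {
  expect_error(run_pipeline(list(plan = list(list(preset = "domed",
                                                  seeds = 1)))),
               "output_dir")
  expect_error(run_pipeline(list(output_dir = tempfile())), "plan")
  overrides <- list(meristem_cap_area = 900, n_cells = 48L,
                    median_cell_area = 900 / 48, dome_height = 8,
                    primordium_radius = 4, primordium_height = 2.5)
  cfg <- list(output_dir = tempfile("pipe"),
              plan = list(list(preset = "vegetative", seeds = c(1, 2),
                               condition = "small_veg",
                               overrides = overrides),
                          list(preset = "domed", seeds = c(1, 2),
                               condition = "small_domed",
                               overrides = modifyList(overrides,
                                 list(meristem_cap_area = 1800,
                                      n_cells = 96L,
                                      median_cell_area = 1800 / 96,
                                      dome_height = 14)))),
              stats = list(baseline = "small_veg"))
  res <- suppressMessages(run_pipeline(cfg))
  expect_identical(nrow(res$summary), 4L)
  expect_true(file.exists(file.path(cfg$output_dir, "summary.csv")))
  expect_true(file.exists(file.path(cfg$output_dir, "run.log")))
  expect_true(file.exists(file.path(cfg$output_dir,
                                    "tukey_meristem_area.csv")))
  expect_identical(nrow(res$fold_changes), 2L)
  # a rerun of the identical config reproduces the summary
  cfg2 <- cfg
  cfg2$output_dir <- tempfile("pipe2")
  res2 <- suppressMessages(run_pipeline(cfg2))
  expect_identical(res$summary[, -1], res2$summary[, -1])
  expect_identical(res$summary$apex_id, res2$summary$apex_id)
})
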