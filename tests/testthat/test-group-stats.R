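test_that("aggregate_per_animal averages images within animal", {
  df <- data.frame(animal_id = c("a1", "a1", "a2"), group = "g",
                   metric = "m", value = c(2, 4, 10))
  out <- aggregate_per_animal(df)
  expect_equal(out$value[out$animal_id == "a1"], 3)
  expect_equal(out$n_images, c(2L, 1L))

  # unbalanced image counts must not weight animals unequally
  df2 <- data.frame(animal_id = c("a1", "a1", "a1", "a2"), group = "g",
                    metric = "m", value = c(0, 0, 0, 12))
  out2 <- aggregate_per_animal(df2)
  expect_equal(mean(out2$value), 6)          # animal-level mean
  expect_false(mean(df2$value) == 6)         # image-pooled mean differs (3)
  expect_error(aggregate_per_animal(
    data.frame(animal_id = NA, group = "g", metric = "m", value = 1)),
    "animal_id")
})

test_that("relative_to_control normalizes to control mean", {
  df <- data.frame(animal_id = paste0("a", 1:5),
                   group = c("young", "young", "young", "aged", "aged"),
                   value = c(8, 10, 12, 25, 35))
  rel <- relative_to_control(df, "young")
  sm <- rel$summary
  expect_equal(sm$relative_mean[sm$group == "young"], 1.0)
  expect_equal(rel$values$relative_value[4:5], c(2.5, 3.5))
  expect_equal(sm$relative_mean[sm$group == "aged"], 3.0)
  expect_equal(sm$sem[sm$group == "young"], sd(c(8, 10, 12) / 10) / sqrt(3))
  # SEM of {1,2,3} = 1/sqrt(3)
  expect_equal(sd(1:3) / sqrt(3), 0.5774, tolerance = 1e-4)
  # scale equivariance
  df2 <- df; df2$value <- df$value * 7.3
  expect_equal(relative_to_control(df2, "young")$values$relative_value,
               rel$values$relative_value)
  expect_error(relative_to_control(df, "nope"), "empty")
})

test_that("unpaired_t matches t.test and handles degenerate input", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  tt <- unpaired_t(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt$df, unname(ref$parameter))
  expect_equal(tt$p, ref$p.value, tolerance = 1e-10)

  # symmetry
  ts <- unpaired_t(b, a)
  expect_equal(ts$t, -tt$t)
  expect_equal(ts$p, tt$p)

  # identical groups
  same <- unpaired_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_warning(z <- unpaired_t(c(5, 5), c(7, 7)), "zero variance")
  expect_equal(z$p, 0)

  # Welch option
  set.seed(20)
  x <- rnorm(8); y <- rnorm(6, sd = 3)
  tw <- unpaired_t(x, y, var_equal = FALSE)
  rw <- t.test(x, y)
  expect_equal(tw$t, unname(rw$statistic), tolerance = 1e-10)
  expect_equal(tw$df, unname(rw$parameter), tolerance = 1e-10)
})

test_that("anova_tukey matches aov/TukeyHSD on the worked triple", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  at <- anova_tukey(g)
  expect_equal(at$F, 21.0)
  d <- data.frame(v = unlist(g), grp = factor(rep(names(g), each = 3)))
  fit <- aov(v ~ grp, d)
  ref <- anova(fit)
  expect_equal(at$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  tk <- TukeyHSD(fit)$grp
  expect_equal(at$pairwise$p_adj,
               unname(tk[paste(at$pairwise$group2, at$pairwise$group1,
                               sep = "-"), "p adj"]),
               tolerance = 1e-9)

  # location invariance
  g2 <- lapply(g, function(x) x + 100)
  at2 <- anova_tukey(g2)
  expect_equal(at2$F, at$F)
  expect_equal(at2$pairwise$p_adj, at$pairwise$p_adj)

  expect_warning(flat <- anova_tukey(list(a = c(1, 1), b = c(1, 1),
                                          c = c(1, 1))), "zero within")
  expect_equal(flat$p, 1)
  expect_error(anova_tukey(list(1:3, 4:6)), "3 groups")
})

test_that("t and ANOVA agree with reference implementations on random data", {
  set.seed(99)
  for (rep in 1:40) {
    a <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    tt <- unpaired_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(tt$p, ref$p.value, tolerance = 1e-6)

    g <- replicate(sample(3:5, 1),
                   rnorm(sample(3:8, 1), mean = runif(1, 0, 2)),
                   simplify = FALSE)
    names(g) <- paste0("g", seq_along(g))
    at <- anova_tukey(g)
    d <- data.frame(v = unlist(g),
                    grp = factor(rep(names(g), lengths(g))))
    fit <- aov(v ~ grp, d)
    expect_equal(at$F, anova(fit)$`F value`[1], tolerance = 1e-6)
    tk <- TukeyHSD(fit)$grp
    key <- paste(at$pairwise$group2, at$pairwise$group1, sep = "-")
    expect_equal(at$pairwise$p_adj, unname(tk[key, "p adj"]),
                 tolerance = 1e-6)
  }
})

test_that("linear_r2 matches cor.test and exact relations", {
  x <- 1:5
  expect_equal(linear_r2(x, 3 * x + 1)$r_squared, 1)
  xy <- list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 6))
  lr <- linear_r2(xy$x, xy$y)
  expect_equal(lr$r_squared, cor(xy$x, xy$y)^2, tolerance = 1e-12)
  ref <- cor.test(xy$x, xy$y)
  expect_equal(lr$p, ref$p.value, tolerance = 1e-10)
  expect_error(linear_r2(rep(1, 4), 1:4), "degenerate")
  set.seed(30)
  xr <- rnorm(200); yr <- rnorm(200)
  expect_lt(linear_r2(xr, yr)$r_squared, 0.05)
})

test_that("ddct_fold_change reproduces the worked table", {
  df <- rbind(
    data.frame(sample_id = c("y1", "y2", "y3", "t1"),
               group = c("young", "young", "young", "aged"),
               gene = "Apoe", replicate = 1,
               ct = c(25.0, 25.2, 24.8, 23.0)),
    data.frame(sample_id = c("y1", "y2", "y3", "t1"),
               group = c("young", "young", "young", "aged"),
               gene = "Actb", replicate = 1, ct = 20.0))
  ct <- ct_table(df, normalizers = "Actb", control_group = "young")
  fc <- ddct_fold_change(ct)

  t1 <- fc[fc$sample_id == "t1", ]
  expect_equal(t1$delta_ct, 3.0)
  expect_equal(t1$delta_delta_ct, -2.0)
  expect_equal(t1$fold_change, 4.0)
  expect_equal(t1$fold_unsigned, 4.0)

  yy <- fc[fc$group == "young", ]
  yy <- yy[order(yy$sample_id), ]
  expect_equal(yy$delta_delta_ct, c(0, 0.2, -0.2))
  expect_equal(yy$fold_unsigned, c(1, 2^-0.2, 2^0.2))
  expect_equal(yy$fold_change, c(1, -2^0.2, 2^0.2))  # signed convention
  # DE rule: 2 SD from the control signed folds
  ctrl_fold <- yy$fold_change
  expect_equal(t1$de_flag,
               abs(4 - mean(ctrl_fold)) > 2 * sd(ctrl_fold))
  expect_true(t1$de_flag)
  expect_false(any(yy$de_flag[1]))  # ddCt = 0 -> fold 1, not DE

  # replicate averaging: triplicates collapse to their mean Ct
  df3 <- df[rep(1:8, each = 3), ]
  df3$replicate <- rep(1:3, 8)
  df3$ct <- df3$ct + rep(c(-0.1, 0, 0.1), 8)
  fc3 <- ddct_fold_change(ct_table(df3, "Actb", "young"))
  expect_equal(fc3$fold_change, fc$fold_change, tolerance = 1e-12)
})

test_that("ddct invariances: global Ct shift and branch round-trip", {
  set.seed(40)
  genes <- c("Apoe", "Actb", "Gapdh")
  df <- expand.grid(sample_id = paste0("s", 1:6), gene = genes,
                    replicate = 1:3, stringsAsFactors = FALSE)
  df$group <- ifelse(df$sample_id %in% paste0("s", 1:3), "young", "aged")
  df$ct <- runif(nrow(df), 18, 30)
  # shift invariance holds exactly with a single normalizer (the study
  # design); with several, the geometric mean on the Ct scale is not
  # translation-equivariant, so the cancellation is only approximate
  base <- ddct_fold_change(ct_table(df, "Actb", "young"))
  df2 <- df; df2$ct <- df$ct + 3.21
  shifted <- ddct_fold_change(ct_table(df2, "Actb", "young"))
  expect_equal(shifted$fold_change, base$fold_change, tolerance = 1e-12)
  expect_equal(shifted$delta_delta_ct, base$delta_delta_ct,
               tolerance = 1e-12)
  multi <- ddct_fold_change(ct_table(df, c("Actb", "Gapdh"), "young"))
  multi2 <- ddct_fold_change(ct_table(df2, c("Actb", "Gapdh"), "young"))
  expect_equal(multi2$fold_change, multi$fold_change, tolerance = 0.05)

  # signed fold <-> ddCt round-trip on both branches
  ddct <- base$delta_delta_ct
  fold <- base$fold_change
  back <- ddct
  back[fold >= 1] <- -log2(fold[fold >= 1])
  back[fold < 1] <- log2(-fold[fold < 1])
  expect_equal(back, ddct, tolerance = 1e-12)

  expect_error(ct_table(transform(df, ct = ct - 40), "Actb", "young"),
               "onpositive")
  expect_warning(
    ddct_fold_change(ct_table(df[df$gene != "Actb" |
                                   df$sample_id != "s1", ],
                              "Actb", "young")),
    "lacks normalizer")
})
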