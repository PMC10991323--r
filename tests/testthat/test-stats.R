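# the group-level statistical battery

test_that("the ln(y+1) transform has its defining values and monotonicity", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  set.seed(1)
  y <- sort(runif(50, 0, 500))
  expect_true(all(diff(log_transform(y)) > 0))
  expect_error(log_transform(-1), class = "anttrail_domain_error")
})

test_that("ANOVA matches a hand sums-of-squares oracle", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      y_mm = c(1, 2, 3, 2, 3, 4))
  a <- one_way_anova(d, transform = "identity")
  # oracle: group means 2 and 3, grand mean 2.5 -> SSB = 1.5, SSW = 4
  expect_equal(a$statistic, 1.5)
  expect_equal(c(a$df1, a$df2), c(1, 4))
  expect_equal(tidy(a)$sumsq, c(1.5, 4))
})

test_that("balanced designs yield the design-determined degrees of freedom", {
  g13 <- simulate_group_distances(group_design(assay_groups(), 15, seed = 1))
  a13 <- one_way_anova(g13)
  expect_equal(c(a13$df1, a13$df2), c(12, 182))

  labels18 <- c(assay_groups(),
                paste0("extra:", 1:5))   # any 18-group layout
  g18 <- simulate_group_distances(group_design(labels18, 15, seed = 2))
  a18 <- one_way_anova(g18)
  expect_equal(c(a18$df1, a18$df2), c(17, 252))
})

test_that("degenerate inputs raise the documented errors", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3), y_mm = rep(2, 6))
  expect_error(one_way_anova(d), class = "anttrail_degenerate_variance")
  expect_error(one_way_anova(d[1:3, ]), class = "anttrail_input_error")
  expect_error(dunnett_vs_control(d, control = "zzz"),
               class = "anttrail_input_error")
  expect_error(pairwise_t(d, "a", "zzz"), class = "anttrail_input_error")
})

test_that("a single Dunnett comparison reduces to the pooled two-sample t-test", {
  set.seed(7)
  d <- tibble::tibble(group = rep(c("control", "t1"), each = 10),
                      y_mm = exp(rnorm(20, 3, 0.5)))
  dn <- tidy(dunnett_vs_control(d))
  tt <- pairwise_t(d, "t1", "control")
  expect_equal(dn$p.adj, tt$p.value, tolerance = 1e-6)
  expect_equal(dn$statistic, tt$statistic, tolerance = 1e-10)
})

test_that("Dunnett-adjusted p-values dominate the unadjusted ones", {
  g <- simulate_group_distances(group_design(assay_groups(), 15, seed = 5))
  dn <- tidy(dunnett_vs_control(g))
  expect_true(all(dn$p.adj >= dn$p.value))
  expect_true(all(dn$p.adj <= 1 & dn$p.adj >= 0))
})

test_that("Dunnett adjusted p agrees with multcomp and mvtnorm references", {
  skip_if_not_installed("multcomp")
  skip_if_not_installed("mvtnorm")
  g <- simulate_group_distances(group_design(
    assay_groups(), 15, effect_profile = c("2-tridecanol:10" = 1.2), seed = 9))
  mine <- tidy(dunnett_vs_control(g))

  Y <- log_transform(g$y_mm)
  grp <- stats::relevel(factor(g$group), "control")
  fit <- stats::aov(Y ~ grp)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett")))
  ref_groups <- sub(" - control$", "", names(mc$test$coefficients))
  ref_p <- as.numeric(mc$test$pvalues)
  expect_equal(mine$p.adj[match(ref_groups, mine$group)], ref_p,
               tolerance = 5e-3)

  # direct multivariate-t probability for the largest statistic
  k <- nrow(mine); n <- 15
  R <- matrix(0.5, k, k); diag(R) <- 1
  tmax <- max(abs(mine$statistic))
  ref <- 1 - mvtnorm::pmvt(lower = rep(-tmax, k), upper = rep(tmax, k),
                           corr = R, df = 13 * 14,
                           algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                          maxpts = 5e5))[1]
  expect_equal(min(mine$p.adj), ref, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("star codes follow the conventional thresholds", {
  g <- anttrail:::star_code(c(0.2, 0.04, 0.009, 9e-4, 9e-5))
  expect_equal(g, c("ns", "*", "**", "***", "****"))
})

test_that("pairwise t matches the from-formula oracle and is antisymmetric", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      y_mm = c(1, 2, 3, 2, 3, 4))
  r <- pairwise_t(d, "a", "b", transform = "identity")
  # pooled-variance formula: s2p = 1, se = sqrt(2/3), t = -1/se
  se <- sqrt(2 / 3)
  expect_equal(r$statistic, -1 / se)
  expect_equal(r$df, 4)
  expect_equal(r$p.value, 2 * pt(-abs(-1 / se), 4))

  rev <- pairwise_t(d, "b", "a", transform = "identity")
  expect_equal(rev$statistic, -r$statistic)
  expect_equal(rev$p.value, r$p.value)

  self <- pairwise_t(dplyr::bind_rows(d, dplyr::mutate(d, group = paste0(group, "2"))),
                     "a", "a2", transform = "identity")
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)
})

test_that("tidiers return well-formed tibbles", {
  g <- simulate_group_distances(group_design(assay_groups(), 15, seed = 4))
  a <- one_way_anova(g)
  expect_named(glance(a), c("statistic", "df1", "df2", "p.value",
                            "n_groups", "n_obs"))
  dn <- dunnett_vs_control(g)
  expect_equal(nrow(tidy(dn)), 12)
  expect_equal(glance(dn)$n_comparisons, 12)
  expect_s3_class(plot_dose_response(g, dn), "ggplot")
})

test_that("null ANOVA p-values are uniform (KS check over replicates)", {
  design <- group_design(assay_groups(), 15)
  pvals <- vapply(1:400, function(s) {
    d <- group_design(assay_groups(), 15, seed = 7000 + s)
    one_way_anova(simulate_group_distances(d))$p.value
  }, numeric(1))
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})
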