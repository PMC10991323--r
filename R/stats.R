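#' ln(y + 1) transform of walking distances
#'
#' The assay's response variable y (on-trail walked distance, mm) is
#' right-skewed with zeros; Y = ln(y + 1) is applied before any parametric
#' test so that group comparisons meet normal-theory assumptions.
#'
#' @param y Non-negative numeric vector of distances (mm).
#' @return ln(y + 1), strictly increasing in y with Y = 0 at y = 0.
#' @examples
#' log_transform(c(0, exp(1) - 1))  # 0, 1
#' @export
log_transform <- function(y) {
  if (any(y < 0, na.rm = TRUE)) {
    abort("walking distances must be non-negative", class = "anttrail_domain_error")
  }
  log1p(y)
}

transform_response <- function(y, transform) {
  switch(transform,
    log1p = log_transform(y),
    identity = y,
    abort("transform must be 'log1p' or 'identity'", class = "anttrail_parameter_error")
  )
}

#' One-way ANOVA across preparation groups
#'
#' Tests the overall dependence of the (transformed) on-trail walking
#' distance on the preparation applied to the trail line, with the classical
#' between/within decomposition: F = MSB/MSW on (k - 1, N - k) degrees of
#' freedom.
#'
#' @param data Group data: tibble with the response and a group column.
#' @param response,group Column names (strings).
#' @param transform `"log1p"` (default, the assay's standard) or
#'   `"identity"`.
#' @return Object of class `trail_anova` with `statistic`, `df1`, `df2`,
#'   `p.value` and the full ANOVA table; supports [tidy()] and [glance()].
#' @examples
#' d <- simulate_group_distances(group_design(assay_groups(), seed = 1))
#' glance(one_way_anova(d))
#' @export
one_way_anova <- function(data, response = "y_mm", group = "group",
                          transform = "log1p") {
  g <- factor(data[[group]])
  Y <- transform_response(data[[response]], transform)
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("need >= 2 groups with >= 2 observations each", class = "anttrail_input_error")
  }
  tab <- suppressWarnings(anova(lm(Y ~ g)))
  msw <- tab$`Mean Sq`[2]
  if (!is.finite(tab$`F value`[1]) || msw <= 1e-12 * (mean(Y^2) + 1e-12)) {
    abort("within-group variance is zero everywhere: F undefined",
          class = "anttrail_degenerate_variance")
  }
  structure(
    list(
      statistic = tab$`F value`[1],
      df1 = tab$Df[1], df2 = tab$Df[2],
      p.value = tab$`Pr(>F)`[1],
      table = tab,
      transform = transform,
      n_groups = nlevels(g), n_obs = length(Y)
    ),
    class = "trail_anova"
  )
}

#' @export
print.trail_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s-transformed distances: F(%d, %d) = %.3f, p = %.3g\n",
              x$transform, x$df1, x$df2, x$statistic, x$p.value))
  invisible(x)
}

#' @export
tidy.trail_anova <- function(x, ...) {
  tibble::tibble(
    term = c("group", "residuals"),
    df = x$table$Df,
    sumsq = x$table$`Sum Sq`,
    meansq = x$table$`Mean Sq`,
    statistic = x$table$`F value`,
    p.value = x$table$`Pr(>F)`
  )
}

#' @export
glance.trail_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df1 = x$df1, df2 = x$df2, p.value = x$p.value,
    n_groups = x$n_groups, n_obs = x$n_obs
  )
}

#' Dunnett many-to-one comparisons against the control
#'
#' Compares every treatment group's mean (transformed scale) with the
#' control using the pooled within-group variance from the one-way layout,
#' and adjusts the two-sided p-values for the family of comparisons with
#' Dunnett's procedure: each statistic is referred to the distribution of
#' the maximum absolute component of a multivariate t vector with the
#' product correlation structure of the common-control design. The
#' probability is evaluated by deterministic two-level Gauss-Legendre
#' quadrature over the control variate and the pooled scale.
#'
#' Star codes follow the usual thresholds: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `****` p < 0.0001.
#'
#' @inheritParams one_way_anova
#' @param control Label of the reference group (must be present).
#' @param alpha Family-wise level used only for the `significant` flag.
#' @return Object of class `trail_dunnett`; [tidy()] gives one row per
#'   comparison (`group`, `estimate` = mean difference on the transformed
#'   scale, `statistic`, `p.adj`, `stars`, `significant`).
#' @examples
#' d <- simulate_group_distances(
#'   group_design(assay_groups(), effect_profile = c("2-tridecanol:10" = 1.5),
#'                seed = 2))
#' tidy(dunnett_vs_control(d))
#' @export
dunnett_vs_control <- function(data, control = "control", response = "y_mm",
                               group = "group", transform = "log1p",
                               alpha = 0.05) {
  g <- as.character(data[[group]])
  if (!control %in% g) {
    abort(sprintf("control group '%s' not present", control),
          class = "anttrail_input_error")
  }
  Y <- transform_response(data[[response]], transform)
  labs <- unique(g)
  treat <- setdiff(labs, control)
  ns <- tapply(Y, g, length)
  ms <- tapply(Y, g, mean)
  vs <- tapply(Y, g, var)
  nu <- sum(ns) - length(labs)
  s2 <- sum((ns - 1) * vs) / nu            # pooled MSW over all groups
  if (s2 <= 0 || !is.finite(s2)) {
    abort("pooled within-group variance is zero", class = "anttrail_degenerate_variance")
  }
  n0 <- ns[[control]]
  est <- ms[treat] - ms[[control]]
  se <- sqrt(s2 * (1 / ns[treat] + 1 / n0))
  tstat <- est / se
  b <- sqrt(ns[treat] / (ns[treat] + n0))  # product-correlation loadings
  p_adj <- vapply(abs(tstat), dunnett_p, numeric(1), b = b, df = nu)
  p_raw <- 2 * pt(-abs(tstat), nu)
  comparisons <- tibble::tibble(
    group = treat,
    estimate = unname(est),
    se = unname(se),
    statistic = unname(tstat),
    p.value = unname(p_raw),
    p.adj = unname(pmax(p_adj, p_raw)),    # adjustment can never help
    stars = star_code(p_adj),
    significant = p_adj < alpha
  )
  structure(
    list(comparisons = comparisons, control = control, df = nu,
         pooled_sd = sqrt(s2), alpha = alpha, transform = transform),
    class = "trail_dunnett"
  )
}

star_code <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' @export
print.trail_dunnett <- function(x, ...) {
  cat(sprintf("Dunnett comparisons vs '%s' (df = %d, pooled SD = %.3f):\n",
              x$control, x$df, x$pooled_sd))
  print(as.data.frame(x$comparisons[, c("group", "estimate", "statistic",
                                        "p.adj", "stars")]), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.trail_dunnett <- function(x, ...) x$comparisons

#' @export
glance.trail_dunnett <- function(x, ...) {
  tibble::tibble(
    n_comparisons = nrow(x$comparisons),
    df = x$df, pooled_sd = x$pooled_sd, alpha = x$alpha,
    n_significant = sum(x$comparisons$significant)
  )
}

# P(max_j |T_j| > q) for a multivariate t with product correlation
# rho_jk = b_j b_k and df degrees of freedom. Conditional on the control
# variate z and the pooled scale w = s/sigma, the components are independent
# normals, so the joint cdf factorises under a two-dimensional integral:
#   P(all |T_j| <= q) = E_w E_z prod_j [ Phi((q w + b_j z)/c_j)
#                                      - Phi((-q w + b_j z)/c_j) ]
# with c_j = sqrt(1 - b_j^2). Evaluated by Gauss-Legendre quadrature.
dunnett_p <- function(q, b, df, n_nodes = 48) {
  if (!is.finite(q)) return(if (q > 0) 0 else 1)
  if (q <= 0) return(1)
  cj <- sqrt(1 - b^2)
  zq <- gauss_nodes(n_nodes, -8.5, 8.5)
  z_weight <- zq$w * stats::dnorm(zq$x)

  if (is.infinite(df)) {
    w_nodes <- 1; w_weight <- 1
  } else {
    lo <- sqrt(qchisq(1e-10, df) / df)
    hi <- sqrt(qchisq(1 - 1e-10, df) / df)
    wq <- gauss_nodes(n_nodes, lo, hi)
    w_nodes <- wq$x
    w_weight <- wq$w * exp((df / 2) * log(df / 2) - lgamma(df / 2) + log(2) +
                             (df - 1) * log(wq$x) - df * wq$x^2 / 2)
  }
  # full (z x w) grid, vectorised over both integration variables
  QW <- rep(q * w_nodes, each = length(zq$x))
  pr <- 1
  for (j in seq_along(b)) {
    BZ <- b[j] * zq$x
    pr <- pr * (pnorm((QW + BZ) / cj[j]) - pnorm((-QW + BZ) / cj[j]))
  }
  dim(pr) <- c(length(zq$x), length(w_nodes))
  cdf <- sum(w_weight * colSums(z_weight * pr))
  min(max(1 - cdf, 0), 1)
}

# memoised Gauss-Legendre nodes on [a, b]
gauss_nodes <- local({
  cache <- new.env(parent = emptyenv())
  function(n, a, b) {
    key <- paste(n, a, b, sep = "|")
    got <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(got)) return(got)
    gq <- pracma::gaussLegendre(n, a, b)
    val <- list(x = gq$x, w = gq$w)
    assign(key, val, envir = cache)
    val
  }
})

#' Unpaired t-test between two groups at matched concentration
#'
#' Two-sided unpaired t-test on the transformed response between two group
#' labels; the classic pooled-variance form by default (`var_equal = TRUE`),
#' with Welch's unequal-variance form as an option.
#'
#' @inheritParams one_way_anova
#' @param label_a,label_b Group labels to compare.
#' @param var_equal Use the pooled-variance statistic (default) or Welch.
#' @return One-row tibble: `group_a`, `group_b`, `estimate` (mean difference
#'   a - b, transformed scale), `statistic`, `df`, `p.value`.
#' @export
pairwise_t <- function(data, label_a, label_b, response = "y_mm",
                       group = "group", transform = "log1p",
                       var_equal = TRUE) {
  g <- as.character(data[[group]])
  for (lab in c(label_a, label_b)) {
    if (!lab %in% g) {
      abort(sprintf("unknown group label '%s'", lab), class = "anttrail_input_error")
    }
  }
  ya <- transform_response(data[[response]][g == label_a], transform)
  yb <- transform_response(data[[response]][g == label_b], transform)
  ht <- t.test(ya, yb, var.equal = var_equal)
  tibble::tibble(
    group_a = label_a, group_b = label_b,
    estimate = mean(ya) - mean(yb),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value
  )
}
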