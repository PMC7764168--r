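test_that("one-way ANOVA reduces to the squared t statistic for two groups", {
  d <- generate_replicate_groups(c(a = 0, b = 1), sd = 1,
                                 n_per_group = 6, seed = 14)
  fit <- anova_oneway(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-12)
  expect_gte(fit$F, 0)
})

test_that("degenerate and malformed grouped data are rejected", {
  d <- data.frame(group = rep(c("a", "b"), each = 3), value = rep(1, 6))
  expect_error(anova_oneway(d), "degenerate")
  expect_error(anova_oneway(data.frame(group = "a", value = 1)),
               "2 groups")
  expect_error(anova_oneway(data.frame(group = c("a", "a", "b"),
                                       value = c(1, 2, 3))),
               "2 replicates")
})

test_that("null type-I error is near its nominal level", {
  set.seed(1234)
  p <- vapply(1:400, function(i) {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                    value = rnorm(15))
    anova_oneway(d)$p
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("statistically indistinguishable groups share one letter", {
  d <- generate_replicate_groups(c(a = 1, b = 1.01, c = 0.99), sd = 1,
                                 n_per_group = 4, seed = 3)
  cld <- tukey_cld(d)
  expect_equal(unique(cld$letters), "a")
  expect_true(letters_consistent(cld))
})

test_that("well-separated groups earn all-distinct letters", {
  d <- generate_replicate_groups(c(lo = 0, mid = 10, hi = 20), sd = 0.5,
                                 n_per_group = 4, seed = 6)
  cld <- tukey_cld(d)
  expect_equal(sort(cld$letters), c("a", "b", "c"))
  expect_true(letters_consistent(cld))
  # highest mean gets "a"
  expect_equal(cld$letters[which.max(cld$mean)], "a")
})

test_that("a middle group straddling two extremes carries both letters", {
  # constructed so only the extremes differ significantly
  found <- FALSE
  for (s in 1:50) {
    d <- generate_replicate_groups(c(lo = 0, mid = 1, hi = 2), sd = 0.55,
                                   n_per_group = 4, seed = s)
    cld <- tukey_cld(d)
    expect_true(letters_consistent(cld))
    p <- attr(cld, "p_matrix")
    if (p["lo", "hi"] < 0.05 && p["lo", "mid"] >= 0.05 &&
        p["mid", "hi"] >= 0.05) {
      expect_equal(nchar(cld$letters[cld$group == "mid"]), 2L)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("letter displays agree with the pairwise matrix on random cases", {
  set.seed(77)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    means <- rnorm(k, sd = 2)
    names(means) <- paste0("g", 1:k)
    n_i <- sample(3:6, 1) # unbalanced handled via Tukey-Kramer
    d <- generate_replicate_groups(means, sd = 1, n_per_group = n_i,
                                   seed = 9000 + i)
    if (i %% 3 == 0) d <- d[-1, ] # knock a replicate out
    cld <- tryCatch(tukey_cld(d), error = function(e) NULL)
    if (is.null(cld)) next
    expect_true(letters_consistent(cld))
  }
})

test_that("permuting group order preserves the letter partition", {
  d <- generate_replicate_groups(c(a = 0, b = 1, c = 5, e = 5.2), sd = 0.8,
                                 n_per_group = 5, seed = 10)
  cld1 <- tukey_cld(d)
  d2 <- d[sample(nrow(d)), ]
  d2$group <- factor(as.character(d2$group),
                     levels = c("c", "a", "e", "b"))
  cld2 <- tukey_cld(d2)
  m1 <- cld1$letters[order(cld1$group)]
  m2 <- cld2$letters[order(cld2$group)]
  expect_identical(m1, m2)
})

test_that("our letters match the multcomp reference partition", {
  skip_if_not_installed("multcomp")
  for (s in c(3, 6, 10)) {
    d <- generate_replicate_groups(c(a = 0, b = 0.8, c = 2.5, e = 2.6),
                                   sd = 0.6, n_per_group = 5, seed = s)
    ours <- tukey_cld(d)
    fit <- stats::aov(value ~ group, data = d)
    ref <- multcomp::cld(multcomp::glht(fit,
                                        linfct = multcomp::mcp(group = "Tukey")),
                         level = 0.05)$mcletters$Letters
    same_letter <- function(lets, a, b)
      length(intersect(strsplit(lets[[a]], "")[[1]],
                       strsplit(lets[[b]], "")[[1]])) > 0
    ours_map <- setNames(ours$letters, ours$group)
    for (a in names(ref)) for (b in names(ref)) {
      if (a == b) next
      expect_identical(same_letter(ours_map, a, b),
                       same_letter(ref, a, b))
    }
  }
})
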