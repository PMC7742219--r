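test_that("Holm adjustment matches the step-down formula", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  out <- holm_adjust(c(0.5, 0.6, 0.7))
  expect_true(all(out <= 1))
  expect_true(all(diff(out[order(c(0.5, 0.6, 0.7))]) >= 0))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("Holm rejections sit between Bonferroni and unadjusted", {
  set.seed(12)
  for (i in 1:20) {
    p <- runif(10)^2
    r_raw <- sum(p < 0.05)
    r_holm <- sum(holm_adjust(p) < 0.05)
    r_bonf <- sum(p.adjust(p, "bonferroni") < 0.05)
    expect_lte(r_bonf, r_holm)
    expect_lte(r_holm, r_raw)
  }
})

test_that("one-sample t test matches the textbook formula", {
  z <- one_sample_t(c(-1, 1))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)

  w <- one_sample_t(1:5)
  expect_equal(w$t, 3 / sqrt(2.5 / 5), tolerance = 1e-6)
  expect_equal(w$t, 4.2426, tolerance = 1e-4)
  expect_equal(w$p, 2 * pt(-3 / sqrt(0.5), df = 4))
  expect_lt(abs(w$p - 0.0132), 1e-4)

  shifted <- one_sample_t(1:5 + 2, mu = 2)
  expect_equal(shifted$t, w$t)
  expect_equal(shifted$p, w$p)

  expect_error(one_sample_t(rep(3, 4)), class = "imcoh_degenerate_sample")
  expect_error(one_sample_t(5))
})

test_that("two-way rmANOVA agrees with the explicit SS decomposition", {
  set.seed(13)
  tab <- expand.grid(subject = 1:3, A = c("a1", "a2"), B = c("b1", "b2"),
                     stringsAsFactors = FALSE)
  tab$y <- rnorm(nrow(tab)) + as.numeric(factor(tab$A)) * 0.5
  got <- rm_anova(tab, "y", c("A", "B"))
  want <- oracle_rm_anova2(tab, "y", "A", "B")
  expect_equal(got$effect, want$effect)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2)
  expect_equal(got$F, want$F, tolerance = 1e-10)

  # larger design, random data
  tab2 <- expand.grid(subject = 1:11, A = paste0("m", 1:4),
                      B = c("ECC", "ISO", "CON"), stringsAsFactors = FALSE)
  tab2$y <- rnorm(nrow(tab2))
  got2 <- rm_anova(tab2, "y", c("A", "B"))
  want2 <- oracle_rm_anova2(tab2, "y", "A", "B")
  expect_equal(got2$F, want2$F, tolerance = 1e-10)
})

test_that("degenerate and unbalanced rmANOVA inputs are handled", {
  tab <- expand.grid(subject = 1:4, A = c("a1", "a2"), B = c("b1", "b2"),
                     stringsAsFactors = FALSE)
  tab$y <- 2
  got <- rm_anova(tab, "y", c("A", "B"))
  expect_equal(got$F, c(0, 0, 0))
  expect_equal(got$p, c(1, 1, 1))

  expect_error(rm_anova(tab[-1, ], "y", c("A", "B")), "missing",
               class = "imcoh_design_error")
  expect_error(rm_anova(tab[tab$subject < 3, ], "y", c("A", "B")),
               "3 subjects")
})

test_that("Greenhouse-Geisser epsilon is bounded and exact for 2 levels", {
  set.seed(14)
  tab <- expand.grid(subject = 1:8, A = c("a1", "a2"),
                     B = paste0("b", 1:4), stringsAsFactors = FALSE)
  tab$y <- rnorm(nrow(tab))
  got <- rm_anova(tab, "y", c("A", "B"), correction = "GG")
  eps <- setNames(got$gg_epsilon, got$effect)
  expect_equal(unname(eps["A"]), 1)                 # 2 levels: sphericity trivial
  expect_gte(eps[["B"]], 1 / 3)
  expect_lte(eps[["B"]], 1 + 1e-9)
  # for F > 1 the sphericity correction can only raise the p value
  big <- got$F > 1
  expect_true(all(got$p_gg[big] >= got$p[big] - 1e-9))
})

test_that("rmANOVA detects a planted within-subject effect", {
  set.seed(15)
  hits <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    tab <- expand.grid(subject = 1:11, muscle = paste0("m", 1:4),
                       period = c("ECC", "ISO", "CON"),
                       stringsAsFactors = FALSE)
    # subject effect + residual sd 1; muscle offsets with SD ~1 residual SD
    off <- c(m1 = -1.2, m2 = -0.4, m3 = 0.4, m4 = 1.2)
    tab$y <- rnorm(11)[tab$subject] + off[tab$muscle] + rnorm(nrow(tab))
    an <- rm_anova(tab, "y", c("muscle", "period"))
    hits <- hits + (an$p[an$effect == "muscle"] < 0.05)
  }
  expect_gt(hits / reps, 0.8)
})

test_that("pairwise post hocs form a Holm family and flag true contrasts", {
  set.seed(16)
  tab <- expand.grid(subject = 1:11, muscle = paste0("m", 1:3),
                     stringsAsFactors = FALSE)
  tab$y <- rnorm(nrow(tab), sd = 0.3) +
    c(m1 = 0, m2 = 0, m3 = 2)[tab$muscle]
  ph <- posthoc_pairwise(tab, "y", "muscle")
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adjusted >= ph$p_raw))
  expect_true(all(ph$significant == (ph$p_adjusted < 0.05)))
  sig <- ph$significant[grepl("m3", ph$comparison)]
  expect_true(all(sig))
  expect_false(ph$significant[ph$comparison == "m1 vs m2"])
})
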