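test_that("correlation ratio reproduces hand-computed cases and edge cases", {
  expect_equal(correlation_ratio(c("A", "A", "B", "B"), c(1, 1, 2, 2))$eta, 1)
  expect_equal(correlation_ratio(c("A", "A", "B", "B"), c(1, 3, 2, 2))$eta, 0)
  e <- correlation_ratio(c("A", "A", "B", "B"), c(1, 2, 3, 5))
  expect_equal(e$eta_squared, 6.25 / 8.75)
  expect_equal(e$eta, sqrt(6.25 / 8.75))
  expect_equal(e$eta, sqrt(e$eta_squared))

  expect_error(correlation_ratio(c("A", "A"), c(1, 2)), "one category")
  expect_error(correlation_ratio(c("A", "B"), c(2, 2)), "zero total variance")
  expect_error(correlation_ratio(c("A", "B"), 1), "equal length")
})

test_that("eta is invariant under affine transformation of the values", {
  set.seed(20)
  for (i in 1:20) {
    labels <- sample(letters[1:3], 30, replace = TRUE)
    values <- rnorm(30)
    if (stats::sd(values) == 0) next
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 4) * sample(c(-1, 1), 1)
    expect_equal(correlation_ratio(labels, values)$eta,
                 correlation_ratio(labels, a + b * values)$eta,
                 tolerance = 1e-9)
  }
})

test_that("eta^2 equals the one-way least-squares R^2", {
  set.seed(21)
  for (i in 1:20) {
    labels <- sample(c("pos", "neg", "mid")[1:sample(2:3, 1)], 40, replace = TRUE)
    if (length(unique(labels)) < 2) next
    values <- rnorm(40, mean = as.integer(factor(labels)))
    fit <- stats::lm(values ~ factor(labels))
    expect_equal(correlation_ratio(labels, values)$eta_squared,
                 summary(fit)$r.squared, tolerance = 1e-9)
  }
})

test_that("permutation null separates injected clade signal from random labels", {
  tr <- simulate_yule_tree(80, seed = 22)
  # perfectly clade-determined trait: observed eta above the 99th percentile
  sim <- simulate_trait(tr, focal = "t1", model = "clade_gain",
                        p_in = 1, p_out = 0, seed = 23)
  nd <- eta_null_distribution(tr, "t1", sim$outcomes, n_permutations = 500, seed = 24)
  expect_gt(nd$observed, stats::quantile(nd$null, 0.99))
  expect_equal(nd$percentile, 1)

  # random trait: observed eta sits inside the null
  simr <- simulate_trait(tr, focal = "t1", model = "random", base = 0.4, seed = 25)
  ndr <- eta_null_distribution(tr, "t1", simr$outcomes, n_permutations = 500, seed = 26)
  expect_lt(ndr$percentile, 0.995)

  nd1 <- eta_null_distribution(tr, "t1", sim$outcomes, n_permutations = 1, seed = 1)
  expect_length(nd1$null, 1)
})

test_that("outcome association joins, binarizes, and reports eta plus rank test", {
  tr <- simulate_yule_tree(50, seed = 27)
  sim <- simulate_trait(tr, focal = "t1", model = "clade_gain", seed = 28)
  a <- outcome_distance_association(sim$outcomes, tr, "t1",
                                    outcome_column = "outcome",
                                    key_column = "leaf")
  g <- glance(a)
  expect_true(g$eta >= 0 && g$eta <= 1)
  expect_equal(g$eta, sqrt(g$eta_squared))
  expect_equal(g$n_positive + g$n_negative, 50)

  # excluding the focal drops one row and matches a direct computation
  a2 <- outcome_distance_association(sim$outcomes, tr, "t1",
                                     outcome_column = "outcome",
                                     key_column = "leaf", include_focal = FALSE)
  expect_equal(nrow(a2$data), 49)
  d <- distances_from(tr, "t1")
  oc <- stats::setNames(sim$outcomes$outcome, sim$outcomes$leaf)
  expect_equal(a2$eta$eta, correlation_ratio(oc[d$leaf], d$distance)$eta)

  # single-category outcomes are an error
  allpos <- sim$outcomes
  allpos$outcome <- "+"
  expect_error(
    outcome_distance_association(allpos, tr, "t1",
                                 outcome_column = "outcome", key_column = "leaf"),
    "association undefined")

  # unjoinable rows are listed
  bad <- sim$outcomes
  bad$leaf[1:2] <- c("nope1", "nope2")
  bad <- bad[bad$leaf != "t1", ]
  expect_error(
    outcome_distance_association(bad, tr, "t1",
                                 outcome_column = "outcome", key_column = "leaf"),
    "nope1, nope2")
})

test_that("partial outcomes flip groups with partial_positive", {
  tr <- read_newick("((A:1,B:2):1,(C:3,D:1):2);")
  tab <- tibble::tibble(
    species_strain = c("A", "B", "C", "D"),
    complement_aerobic = c("+", "partial", "-", "+")
  )
  pos <- outcome_distance_association(tab, tr, "A", include_focal = FALSE,
                                      partial_positive = TRUE)
  expect_equal(sum(pos$data$outcome == "positive"), 2) # B and D (focal excluded)
  # with partial_positive = FALSE, partial is neither "+" nor "-": dropped
  neg <- outcome_distance_association(tab, tr, "A", include_focal = FALSE,
                                      partial_positive = FALSE)
  expect_equal(sum(neg$data$outcome == "positive"), 1)
  expect_equal(nrow(neg$data), 2)
})

test_that("trait crosstab reproduces the anaerobe recovery cell and margins", {
  nada <- screen_nada()
  anaerobic_only <- nada[!nada$is_host_control &
                           nada$complement_aerobic == "-" &
                           nada$complement_anaerobic == "+", ]
  xt <- trait_crosstab(anaerobic_only, "o2_tolerance", "complement_anaerobic")
  expect_equal(xt$`+`[xt$o2_tolerance == "-"], 5)
  expect_equal(xt$total[xt$o2_tolerance == "total"], 8)

  empty <- trait_crosstab(nada[0, ], "o2_tolerance", "complement_anaerobic")
  expect_equal(empty$total, 0)

  single <- trait_crosstab(nada[1, ], "o2_tolerance", "complement_aerobic")
  expect_equal(single$total[single$o2_tolerance == "total"], 1)

  expect_error(trait_crosstab(nada, "no_such", "complement_aerobic"), "not found")
})
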