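test_that("normative limits follow the closed-form Gaussian construction", {
  flat <- function(v) rnfltnorm:::new_profile(rep(v, 720))
  # two constant profiles 80 and 120: mean 100, sd 28.28, lower95 44.57
  nm <- build_normative(list(flat(80), flat(120)))
  expect_equal(unique(nm$angle$mean_um), 100)
  expect_equal(unique(nm$angle$sd_um), sd(c(80, 120)))
  expect_equal(unique(nm$angle$sd_um), 28.28, tolerance = 1e-3)
  # lower95 = 100 - 1.96 * 28.284 ~= 44.57
  expect_equal(unique(nm$angle$lower95_um),
               100 - 1.96 * sd(c(80, 120)))
  expect_equal(unique(nm$angle$lower95_um), 44.57, tolerance = 1e-3)
  expect_equal(unique(nm$angle$lower99_um), 100 - 2.576 * sd(c(80, 120)))
  expect_true(all(nm$sector$lower99_um <= nm$sector$lower95_um))
  expect_true(all(nm$sector$lower95_um <= nm$sector$mean_um))
  # identical profiles: sd 0, limits equal mean
  nm2 <- build_normative(list(flat(90), flat(90), flat(90)))
  expect_true(all(nm2$angle$sd_um == 0))
  expect_equal(nm2$angle$lower95_um, nm2$angle$mean_um)
  expect_error(build_normative(list(flat(90))), "at least 2")
})

test_that("about 2.5% of held-out Gaussian subjects fall below lower95", {
  set.seed(71)
  mu <- 100; sigma <- 12
  train <- purrr::map(1:400, ~ rnfltnorm:::new_profile(rep(rnorm(1, mu, sigma), 720)))
  nm <- build_normative(train)
  held <- rnorm(4000, mu, sigma)
  frac <- mean(held < nm$angle$lower95_um[1])
  expect_gt(frac, 0.013)
  expect_lt(frac, 0.040)
})

test_that("categorization thresholds and monotonicity are respected", {
  mu <- 100; s <- 10
  l95 <- mu - 1.96 * s
  l99 <- mu - 2.576 * s
  expect_equal(as.character(classify_rnflt(mu, l95, l99)), "normal")
  expect_equal(as.character(classify_rnflt(mu - 2.2 * s, l95, l99)),
               "borderline")
  expect_equal(as.character(classify_rnflt(mu - 3 * s, l95, l99)),
               "abnormal")
  # exact boundaries: at lower95 still normal, at lower99 borderline
  expect_equal(as.character(classify_rnflt(l95, l95, l99)), "normal")
  expect_equal(as.character(classify_rnflt(l99, l95, l99)), "borderline")
  # lowering a value never moves the label toward normal
  vals <- seq(130, 40, by = -0.5)
  labs <- as.integer(classify_rnflt(vals, l95, l99))
  expect_true(all(diff(labs) >= 0))
  expect_error(classify_rnflt(90, 80, 85), "must not exceed")
})

test_that("sector tables are scale-invariant in CoV and handle flat cohorts", {
  co <- generate_cohort(cohort_config(n_subjects = 10, seed = 14))
  tab <- sector_table(co$profile)
  scaled <- purrr::map(co$profile, function(p) {
    p$thickness_um <- p$thickness_um * 3.7
    p
  })
  tab2 <- sector_table(scaled)
  expect_equal(tab2$cov_pct, tab$cov_pct, tolerance = 1e-12)
  expect_equal(tab2$mean_um, tab$mean_um * 3.7)
  # identical subjects: CoV 0 everywhere
  same <- rep(co$profile[1], 3)
  expect_true(all(sector_table(same)$cov_pct == 0))
})

test_that("CoV reduction arithmetic matches its definition", {
  expect_equal(round(cov_reduction(18.40, 16.49), 2), 10.38)
  expect_equal(cov_reduction(20, 20), 0)
  expect_equal(round(cov_reduction(25.26, 21.16), 2), 16.23)
  expect_error(cov_reduction(0, 5), "positive")
})

test_that("category-change counts match a nested-loop oracle", {
  set.seed(31)
  labs <- c("normal", "borderline", "abnormal")
  mk <- function() tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:8), each = 12),
    ch = rep(1:12, 8),
    label = factor(sample(labs, 96, replace = TRUE,
                          prob = c(0.8, 0.15, 0.05)), levels = labs)
  )
  before <- mk(); after <- mk()
  res <- count_category_changes(before, after)
  n_sect <- 0; subj <- character()
  for (i in seq_len(nrow(before))) {
    if (before$label[i] != after$label[i]) {
      n_sect <- n_sect + 1
      subj <- union(subj, before$subject_id[i])
    }
  }
  expect_equal(res$n_sectors_changed, n_sect)
  expect_equal(res$n_subjects_changed, length(subj))
  expect_equal(sum(res$transitions$n), n_sect)
  # identical tables: no changes
  none <- count_category_changes(before, before)
  expect_equal(none$n_sectors_changed, 0)
  expect_equal(none$n_subjects_changed, 0)
  # a single borderline -> normal flip: 1 subject, 1 sector
  after1 <- before
  i <- which(before$label == "borderline")[1]
  after1$label[i] <- "normal"
  one <- count_category_changes(before, after1)
  expect_equal(one$n_subjects_changed, 1)
  expect_equal(one$n_sectors_changed, 1)
  expect_error(count_category_changes(before, after[1:24, ]), "identical")
})
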