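test_that("config enumeration is a deterministic Cartesian product", {
  g27 <- enumerate_configs()
  expect_equal(nrow(g27), 27)
  expect_equal(nrow(unique(g27)), 27)
  expect_equal(nrow(enumerate_configs("tiny", "UNDER", "NONE")), 1)
  expect_equal(nrow(enumerate_configs(c("a", "b"), c("c", "d"),
                                      c("e", "f"))), 8)
  expect_identical(enumerate_configs(), enumerate_configs())
  expect_error(enumerate_configs(character(0)), class = "cxr_input_error")
})

test_that("stage-1 ranking reproduces the published fold-1 ordering", {
  ref <- reference_results("stage1")
  expect_equal(nrow(ref), 27)
  s1 <- stage_one(ref, n_keep = 5)
  expect_equal(s1$top$macro_mae[1], 0.3953)
  expect_equal(s1$top$architecture[1], "chexnet121")
  expect_equal(s1$top$balancing[1], "UNDER")
  expect_equal(s1$top$segmentation[1], "NONE")
  expect_equal(max(s1$top$macro_mae), 0.4151)
  expect_equal(s1$top$architecture[5], "vgg16")
  expect_equal(s1$top$segmentation[5], "SPINE")
  # ranking is a permutation: nothing lost or duplicated
  expect_setequal(cxrgrade:::config_key(s1$table),
                  cxrgrade:::config_key(ref))
  expect_equal(s1$table$rank, 1:27)
  # n_keep beyond the table returns everything, ordered
  all_rows <- stage_one(ref, n_keep = 100)
  expect_equal(nrow(all_rows$top), 27)
  expect_true(!is.unsorted(all_rows$table$macro_mae))
  dup <- rbind(ref, ref[1, ])
  expect_error(stage_one(dup), class = "cxr_input_error")
})

test_that("cross-fold summaries use the sample standard deviation", {
  folds <- c(0.40, 0.42, 0.38, 0.41, 0.39)
  expect_equal(mean(folds), 0.40)
  expect_equal(sd(folds), sqrt(sum((folds - 0.4)^2) / 4))
  # identical metrics across folds give zero spread
  expect_equal(sd(rep(0.4, 5)), 0)
})

test_that("the rank-sum rule picks the best MAE/HCS compromise", {
  tab <- data.frame(architecture = c("a", "b", "c"),
                    balancing = "UNDER", segmentation = "NONE",
                    macro_mae_mean = c(0.40, 0.41, 0.45),
                    ma_hcs_mean = c(0.20, 0.25, 0.10))
  # a: ranks (1,2)=3; b: (2,1)=3; c: (3,3)=6 — tie to lower MAE
  best <- choose_best(tab)
  expect_equal(best$architecture, "a")
  one <- choose_best(tab[2, ])
  expect_equal(one$architecture, "b")
  # invariant to row order
  best2 <- choose_best(tab[c(3, 1, 2), ])
  expect_equal(best2$architecture, "a")
  expect_error(choose_best(tab[0, ]), class = "cxr_input_error")
})

test_that("the published cross-validation table selects the ResNet-50 model", {
  cv <- reference_results("crossval")
  best <- choose_best(cv)
  expect_equal(best$architecture, "resnet50")
  expect_equal(best$balancing, "UNDER")
  expect_equal(best$segmentation, "NONE")
  expect_equal(best$macro_mae_mean, 0.4099)
  expect_equal(best$ma_hcs_mean, 0.1830)
})

test_that("a synthesized second reader deviates at the perturbation rate", {
  man <- meta_cohort(300, seed = 14)
  rd <- synthesize_oobtr(man, flip_prob = 0.1, seed = 15)
  mae <- mean(abs(c(rd$oobtr_left, rd$oobtr_right) -
                    c(man$left_grade, man$right_grade)))
  n <- 2 * nrow(man)
  tol <- 4 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mae - 0.1), tol)
  # perturbed labels stay valid grades one step away
  d <- abs(rd$oobtr_left - man$left_grade)
  expect_true(all(d %in% 0:1))
})

test_that("subgroup metrics reduce to overall metrics and conserve counts", {
  man <- meta_cohort(80, seed = 16)
  man$pred_left <- pmin(pmax(man$left_grade +
                               sample(c(-1, 0, 1), nrow(man), TRUE), 0), 3)
  man$pred_right <- man$right_grade
  # single group containing everyone equals the overall computation
  man$race <- "White"
  sg <- subgroup_metrics(man, "race")
  expect_equal(nrow(sg), 1)
  overall <- metric_report(man$left_grade, man$pred_left, r2 = FALSE)
  expect_equal(sg$left_macro_mae, overall$macro_mae)
  # disjoint groups partition the cohort
  man$race <- sample(c("White", "Black", "Asian"), nrow(man), TRUE)
  sg3 <- subgroup_metrics(man, "race")
  expect_equal(sum(sg3$n), nrow(man))
  # identical label distributions and predictions give identical metrics
  half <- nrow(man) / 2
  dup <- man[rep(1:10, 2), ]
  dup$sex <- rep(c("Male", "Female"), each = 10)
  sgp <- subgroup_metrics(dup, "sex")
  expect_equal(sgp$avg_macro_mae[1], sgp$avg_macro_mae[2])
  expect_equal(sgp$f1[1], sgp$f1[2])
  expect_error(subgroup_metrics(man[, !names(man) %in% "covid_status"],
                                "covid"),
               class = "cxr_input_error")
})

test_that("reader-comparison pairings use the full metric set", {
  man <- meta_cohort(40, seed = 17)
  or <- c(man$left_grade, man$right_grade)
  rep <- cxrgrade:::pairing_report(or, or)
  expect_equal(rep$mae, 0)
  expect_equal(rep$f1, 100)
  expect_equal(rep$r_squared, 1)
  expect_equal(nrow(rep$binary), 3)
})
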