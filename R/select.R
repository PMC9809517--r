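# Three-stage model selection, reader comparison, and subgroup analysis.
#
# Stage 1 trains every (architecture x balancing x segmentation) grid
# point on fold 1 only and ranks by macro-MAE. Stage 2 retrains the top
# configurations across all folds and adds the macro-averaged Heatmap
# Concordance Score. The best model minimizes the equal-weight rank sum
# of macro-MAE (ascending) and MA-HCS (descending). Stage 3 retrains the
# winner on a fresh split and compares it with the original-reader (OR)
# and second-reader (OOBTR) grades on the OOB hold-out.

#' Bundled reference results tables
#'
#' Stage-1 (27-configuration), five-fold cross-validation, and
#' reader-comparison results reported by the full-scale clinical
#' evaluation this framework was developed for; used as worked examples
#' of the selection rules.
#'
#' @param which `"stage1"`, `"crossval"` or `"reader"`.
#' @return data frame.
#' @export
reference_results <- function(which = c("stage1", "crossval", "reader")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "cxrgrade", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Enumerate the model-configuration grid
#'
#' Cartesian product of architectures, balancing schemes and segmentation
#' schemes, in deterministic lexicographic order of the supplied axes.
#' Each configuration is trained once per lung side, so the full default
#' grid is 27 configurations per side (54 models).
#'
#' @param architectures,balancers,schemes non-empty character axes.
#' @return data frame with columns `architecture`, `balancing`,
#'   `segmentation`.
#' @export
enumerate_configs <- function(architectures = c("resnet50", "vgg16",
                                                "chexnet121"),
                              balancers = c("UNDER", "OVER", "DOUBLE"),
                              schemes = c("NONE", "LUNG", "SPINE")) {
  if (!length(architectures) || !length(balancers) || !length(schemes))
    stop_input("all three axes must be non-empty")
  g <- expand.grid(segmentation = schemes, balancing = balancers,
                   architecture = architectures, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("architecture", "balancing", "segmentation")]
}

config_key <- function(df)
  paste(df$architecture, df$balancing, df$segmentation, sep = "/")

#' Stage-1 ranking: retain the top configurations by macro-MAE
#'
#' Ranks a one-row-per-configuration results table ascending by
#' macro-MAE, breaking ties by higher F1 and then lexicographic
#' configuration key, and retains the best `n_keep`.
#'
#' @param results_table data frame with `architecture`, `balancing`,
#'   `segmentation`, `f1` and `macro_mae` columns (one row per config).
#' @param n_keep configurations to retain.
#' @return a `stage_one_result`: `table` (all rows, ranked, with `rank`),
#'   `top` (first `n_keep` rows).
#' @export
stage_one <- function(results_table, n_keep = 5) {
  if (anyDuplicated(config_key(results_table)))
    stop_input("duplicate configurations in results table")
  if (any(!is.finite(results_table$macro_mae)))
    stop_input("non-finite macro_mae")
  ord <- order(results_table$macro_mae, -results_table$f1,
               config_key(results_table))
  tab <- results_table[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 top = head(tab, min(n_keep, nrow(tab))),
                 n_keep = n_keep),
            class = "stage_one_result")
}

#' @export
print.stage_one_result <- function(x, ...) {
  cat(sprintf("Stage-1 ranking of %d configurations; top %d retained:\n",
              nrow(x$table), nrow(x$top)))
  print(x$top[, c("rank", "architecture", "balancing", "segmentation",
                  "macro_mae")], row.names = FALSE)
  invisible(x)
}

binary_block <- function(y_true, y_pred) {
  do.call(rbind, lapply(1:3, function(t) {
    b <- binarize(y_true, y_pred, t)
    pr <- weighted_prf(b$y_true, b$y_pred, k = 2L)
    data.frame(threshold = t, precision = 100 * pr$precision_overall,
               recall = 100 * pr$recall_overall,
               f1 = 100 * pr$f1_overall,
               mae = macro_mae(b$y_true, b$y_pred, k = 2L)$macro)
  }))
}

# train both per-side classifiers of one configuration on one fold and
# evaluate on that fold's test rows
eval_config_on_fold <- function(config, manifest, fold_set, fold, schedule,
                                seed, hcs_n = 0, roi_caches = new.env(),
                                pretrained_map = NULL,
                                return_models = FALSE) {
  spec <- backbone_spec(config$architecture)
  tr <- fold_rows(manifest, fold_set, fold, "train")
  va <- fold_rows(manifest, fold_set, fold, "val")
  te <- fold_rows(manifest, fold_set, fold, "test")
  side_metrics <- list()
  models <- list()
  preds <- list()
  for (side in c("left", "right")) {
    ckey <- paste(config$segmentation, side, spec$input_size, sep = "|")
    if (is.null(roi_caches[[ckey]])) roi_caches[[ckey]] <- new.env()
    loader <- make_roi_loader(config$segmentation, side,
                              input_size = spec$input_size,
                              channels = spec$input_channels,
                              cache = roi_caches[[ckey]])
    plan <- balance_classes(tr, config$balancing,
                            paste0(side, "_grade"),
                            seed = derive_seed(seed, "bal", fold, side))
    model <- build_classifier(config$architecture, side,
                              seed = derive_seed(seed, "init", fold, side),
                              pretrained =
                                pretrained_map[[side]][[config$architecture]])
    sch <- schedule
    sch$seed <- derive_seed(seed, "fit", fold, side)
    model <- fit_two_stage(model, plan, va, sch, loader)
    model$config <- config
    p <- predict(model, loader(te)$x)
    side_metrics[[side]] <- metric_report(te[[paste0(side, "_grade")]],
                                          p$grades, r2 = FALSE)
    models[[side]] <- model
    preds[[side]] <- p$grades
  }
  avg <- function(f) mean(c(f(side_metrics$left), f(side_metrics$right)))
  y_all <- c(te$left_grade, te$right_grade)
  p_all <- c(preds$left, preds$right)
  hcs_df <- NULL
  if (hcs_n > 0) {
    ix <- head(seq_len(nrow(te)), hcs_n)
    vals <- classes <- numeric(0)
    for (i in ix) {
      img <- read_gray_png(te$image_path[i])
      hm <- combine_lr(attention_heatmap(models$left, img),
                       attention_heatmap(models$right, img))
      lmask <- read_gray_png(te$left_mask_path[i]) > 0.5
      rmask <- read_gray_png(te$right_mask_path[i]) > 0.5
      v <- tryCatch(hcs(hm, lmask | rmask), error = function(e) NA_real_)
      if (!is.na(v)) {
        vals <- c(vals, v)
        classes <- c(classes, max(te$left_grade[i], te$right_grade[i]))
      }
    }
    hcs_df <- if (length(vals)) macro_hcs(vals, classes) else NULL
  }
  res <- data.frame(architecture = config$architecture,
                    balancing = config$balancing,
                    segmentation = config$segmentation, fold = fold,
                    precision = 100 * avg(function(m) m$precision),
                    recall = 100 * avg(function(m) m$recall),
                    f1 = 100 * avg(function(m) m$f1),
                    macro_mae = avg(function(m) m$macro_mae),
                    ma_hcs = if (!is.null(hcs_df)) hcs_df$ma_hcs
                             else NA_real_,
                    stringsAsFactors = FALSE)
  out <- list(metrics = res, binary = binary_block(y_all, p_all))
  if (return_models) {
    out$models <- models
    out$test_rows <- te
    out$preds <- preds
  }
  out
}

#' Stage-1 grid evaluation on fold 1
#'
#' Trains every configuration of the grid on the first fold and returns
#' the one-row-per-configuration results table consumed by [stage_one()].
#'
#' @param configs data frame from [enumerate_configs()].
#' @param manifest prepared cohort manifest (with ground-truth mask
#'   columns for ROI extraction and HCS).
#' @param fold_set a [make_patient_splits()] fold set.
#' @param schedule a [training_schedule()].
#' @param seed integer seed for balancing/initialization/shuffling.
#' @param pretrained_map optional nested list of [pretrain_backbone()]
#'   weights indexed as `[[side]][[architecture]]`.
#' @export
stage_one_grid <- function(configs, manifest, fold_set,
                           schedule = training_schedule(), seed = 1,
                           pretrained_map = NULL) {
  caches <- new.env()
  rows <- lapply(seq_len(nrow(configs)), function(i)
    eval_config_on_fold(configs[i, ], manifest, fold_set, 1L, schedule,
                        seed, roi_caches = caches,
                        pretrained_map = pretrained_map)$metrics)
  do.call(rbind, rows)
}

#' Stage-2 cross-validation of the retained configurations
#'
#' Retrains each retained configuration on every fold; reports per-config
#' means and sample standard deviations of the headline metrics, the mean
#' MA-HCS, and the three binary-collapse blocks averaged over folds.
#' A configuration whose training fails on any fold is flagged and
#' excluded from best-model choice.
#'
#' @param top_configs data frame of configurations (e.g. `stage_one()$top`).
#' @inheritParams stage_one_grid
#' @param hcs_n test images per fold entering the HCS.
#' @inheritParams stage_one_grid
#' @return a `crossval_result`: `summary` data frame, `per_fold`,
#'   `binary` (per config x threshold means), `flagged`.
#' @export
stage_two <- function(top_configs, manifest, fold_set,
                      schedule = training_schedule(), seed = 1,
                      hcs_n = 10, pretrained_map = NULL) {
  caches <- new.env()
  summaries <- list(); per_fold <- list(); binaries <- list()
  flagged <- character(0)
  for (i in seq_len(nrow(top_configs))) {
    cfg <- top_configs[i, ]
    key <- config_key(cfg)
    fold_res <- list()
    failed <- NULL
    for (f in seq_along(fold_set$folds)) {
      r <- tryCatch(
        eval_config_on_fold(cfg, manifest, fold_set, f, schedule, seed,
                            hcs_n = hcs_n, roi_caches = caches,
                            pretrained_map = pretrained_map),
        error = function(e) e)
      if (inherits(r, "error")) { failed <- conditionMessage(r); break }
      fold_res[[f]] <- r
    }
    if (!is.null(failed)) {
      flagged <- c(flagged, stats::setNames(failed, key))
      next
    }
    m <- do.call(rbind, lapply(fold_res, `[[`, "metrics"))
    per_fold[[key]] <- m
    summaries[[key]] <- data.frame(
      architecture = cfg$architecture, balancing = cfg$balancing,
      segmentation = cfg$segmentation,
      precision_mean = mean(m$precision), precision_sd = sd(m$precision),
      recall_mean = mean(m$recall), recall_sd = sd(m$recall),
      f1_mean = mean(m$f1), f1_sd = sd(m$f1),
      macro_mae_mean = mean(m$macro_mae), macro_mae_sd = sd(m$macro_mae),
      ma_hcs_mean = mean(m$ma_hcs, na.rm = TRUE),
      stringsAsFactors = FALSE)
    b <- do.call(rbind, lapply(fold_res, `[[`, "binary"))
    binaries[[key]] <- do.call(rbind, lapply(split(b, b$threshold),
      function(d) data.frame(architecture = cfg$architecture,
                             balancing = cfg$balancing,
                             segmentation = cfg$segmentation,
                             threshold = d$threshold[1],
                             precision = mean(d$precision),
                             recall = mean(d$recall), f1 = mean(d$f1))))
  }
  structure(list(summary = do.call(rbind, c(summaries,
                                            make.row.names = FALSE)),
                 per_fold = per_fold,
                 binary = do.call(rbind, c(binaries,
                                           make.row.names = FALSE)),
                 flagged = flagged),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("Cross-validation summary:\n")
  print(x$summary[, c("architecture", "balancing", "segmentation",
                      "macro_mae_mean", "ma_hcs_mean")], row.names = FALSE)
  if (length(x$flagged))
    cat("flagged:", paste(names(x$flagged), collapse = ", "), "\n")
  invisible(x)
}

#' Choose the best configuration by joint macro-MAE / MA-HCS rank sum
#'
#' Configurations are ranked ascending by mean macro-MAE and descending
#' by mean MA-HCS; the winner minimizes the equal-weight rank sum, ties
#' broken by the lower macro-MAE and then by configuration key. The rule
#' is recorded in the result for auditability and is invariant to row
#' order.
#'
#' @param cv a `crossval_result`, or a data frame shaped like its
#'   `summary` (columns `macro_mae_mean`, `ma_hcs_mean`).
#' @return one-row data frame of the chosen configuration, with ranks and
#'   the selection rule as attributes.
#' @export
choose_best <- function(cv) {
  tab <- if (inherits(cv, "crossval_result")) cv$summary else cv
  if (is.null(tab) || nrow(tab) == 0) stop_input("no unflagged configs")
  r_mae <- rank(tab$macro_mae_mean, ties.method = "min")
  r_hcs <- rank(-tab$ma_hcs_mean, ties.method = "min")
  rs <- r_mae + r_hcs
  ord <- order(rs, tab$macro_mae_mean, config_key(tab))
  best <- tab[ord[1], , drop = FALSE]
  rownames(best) <- NULL
  attr(best, "ranks") <- data.frame(config = config_key(tab),
                                    rank_mae = r_mae, rank_hcs = r_hcs,
                                    rank_sum = rs)
  attr(best, "rule") <- "equal-weight rank sum of macro-MAE (asc) and MA-HCS (desc); ties to lower macro-MAE"
  best
}

#' Synthesize a second-reader grading
#'
#' Emulates an independent expert re-read: each per-lung grade is moved
#' one ordinal step (direction random, clamped to 0..3) with probability
#' `flip_prob`.
#'
#' @param rows manifest rows carrying `left_grade`/`right_grade`.
#' @param flip_prob per-label perturbation probability.
#' @param seed integer seed.
#' @return `rows` with added `oobtr_left`, `oobtr_right` columns.
#' @export
synthesize_oobtr <- function(rows, flip_prob = 0.1, seed = NULL) {
  perturb <- function(y) {
    flip <- runif(length(y)) < flip_prob
    step <- sample(c(-1L, 1L), length(y), replace = TRUE)
    out <- ifelse(flip, pmin(pmax(y + step, 0L), 3L), y)
    # clamping at the ends must still move the grade
    out <- ifelse(flip & out == y, pmin(pmax(y - step, 0L), 3L), out)
    as.integer(out)
  }
  with_seed(seed, {
    rows$oobtr_left <- perturb(rows$left_grade)
    rows$oobtr_right <- perturb(rows$right_grade)
  })
  rows
}

pairing_report <- function(y_a, y_b) {
  rep <- metric_report(y_a, y_b)
  list(mae = rep$macro_mae, precision = 100 * rep$precision,
       recall = 100 * rep$recall, f1 = 100 * rep$f1,
       r_squared = rep$r_squared, binary = binary_block(y_a, y_b))
}

#' Stage-3: final training and reader comparison on the OOB hold-out
#'
#' Retrains the chosen configuration on a fresh train/val/test split of
#' the non-OOB patients, predicts the OOB images, and evaluates the three
#' pairings (OOBTR vs OR, model vs OR, model vs OOBTR) with the full
#' metric set and the three binary collapses, pooling both lungs. When
#' OOBTR columns are absent that pairing is omitted with a warning.
#'
#' @param best_config one-row configuration data frame.
#' @param manifest prepared manifest.
#' @param fold_set fold set whose OOB hold-out is evaluated.
#' @param schedule a [training_schedule()].
#' @param seed integer seed (the fresh split derives from it).
#' @param oob_rows OOB manifest rows, optionally with
#'   `oobtr_left`/`oobtr_right` second-reader grades.
#' @inheritParams stage_one_grid
#' @return a `reader_comparison`: `pairings` (named list of metric
#'   blocks), `predictions` (OOB rows + `pred_left`/`pred_right`),
#'   `models`.
#' @export
stage_three <- function(best_config, manifest, fold_set,
                        schedule = training_schedule(), seed = 1,
                        oob_rows = NULL, pretrained_map = NULL) {
  oob_rows <- oob_rows %||% fold_rows(manifest, fold_set, "oob")
  if (nrow(oob_rows) == 0) stop_input("empty OOB hold-out")
  pool <- manifest[!manifest$patient_id %in% fold_set$oob, , drop = FALSE]
  fresh <- make_patient_splits(pool, oob_n_images = 0, n_folds = 1,
                               seed = derive_seed(seed, "fresh-split"))
  spec <- backbone_spec(best_config$architecture)
  models <- list(); preds <- list()
  for (side in c("left", "right")) {
    loader <- make_roi_loader(best_config$segmentation, side,
                              input_size = spec$input_size,
                              channels = spec$input_channels)
    plan <- balance_classes(fold_rows(pool, fresh, 1, "train"),
                            best_config$balancing, paste0(side, "_grade"),
                            seed = derive_seed(seed, "bal3", side))
    model <- build_classifier(best_config$architecture, side,
                              seed = derive_seed(seed, "init3", side),
                              pretrained =
                                pretrained_map[[side]][[
                                  best_config$architecture]])
    sch <- schedule
    sch$seed <- derive_seed(seed, "fit3", side)
    model <- fit_two_stage(model, plan, fold_rows(pool, fresh, 1, "val"),
                           sch, loader)
    model$config <- best_config
    models[[side]] <- model
    preds[[side]] <- predict(model, loader(oob_rows)$x)$grades
  }
  oob_rows$pred_left <- preds$left
  oob_rows$pred_right <- preds$right
  or <- c(oob_rows$left_grade, oob_rows$right_grade)
  mdl <- c(preds$left, preds$right)
  pairings <- list(model_or = pairing_report(or, mdl))
  if (!is.null(oob_rows$oobtr_left)) {
    oobtr <- c(oob_rows$oobtr_left, oob_rows$oobtr_right)
    pairings$oobtr_or <- pairing_report(or, oobtr)
    pairings$model_oobtr <- pairing_report(oobtr, mdl)
  } else {
    warning("no OOBTR grades supplied; reader-reader pairings omitted")
  }
  structure(list(pairings = pairings, predictions = oob_rows,
                 models = models, config = best_config),
            class = "reader_comparison")
}

#' @export
print.reader_comparison <- function(x, ...) {
  cat("Reader comparison on the OOB hold-out:\n")
  for (nm in names(x$pairings)) {
    p <- x$pairings[[nm]]
    cat(sprintf("  %-12s MAE %.4f | P %.2f | R %.2f | F1 %.2f\n", nm,
                p$mae, p$precision, p$recall, p$f1))
  }
  invisible(x)
}

#' Per-subgroup performance of a set of predictions
#'
#' @param predictions data frame with `left_grade`, `right_grade`,
#'   `pred_left`, `pred_right` and the demographic columns (e.g. the
#'   `predictions` element of [stage_three()]).
#' @param grouping `"race"`, `"sex"` or `"covid"`.
#' @return data frame keyed by group with n (images), left/right/average
#'   macro-MAE, and side-averaged F1, precision, recall; empty groups are
#'   omitted.
#' @export
subgroup_metrics <- function(predictions, grouping = c("race", "sex",
                                                       "covid")) {
  grouping <- match.arg(grouping)
  col <- c(race = "race", sex = "sex", covid = "covid_status")[[grouping]]
  if (is.null(predictions[[col]]))
    stop_input("predictions lack column ", col)
  out <- lapply(split(predictions, predictions[[col]]), function(d) {
    if (nrow(d) == 0) return(NULL)
    ml <- metric_report(d$left_grade, d$pred_left, r2 = FALSE)
    mr <- metric_report(d$right_grade, d$pred_right, r2 = FALSE)
    data.frame(group = d[[col]][1], n = nrow(d),
               avg_macro_mae = mean(c(ml$macro_mae, mr$macro_mae)),
               left_macro_mae = ml$macro_mae,
               right_macro_mae = mr$macro_mae,
               f1 = 100 * mean(c(ml$f1, mr$f1)),
               precision = 100 * mean(c(ml$precision, mr$precision)),
               recall = 100 * mean(c(ml$recall, mr$recall)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Run the full selection pipeline end to end
#'
#' Stage-1 grid on fold 1, ranking, stage-2 cross-validation with MA-HCS,
#' best-model choice, stage-3 reader comparison on the OOB hold-out (a
#' synthesized second reader is used when the manifest has no OOBTR
#' grades), and subgroup reports. All reports are returned and, when
#' `out_dir` is given, written as JSON/CSV.
#'
#' @param manifest prepared cohort manifest.
#' @param fold_set a fold set with an OOB hold-out.
#' @param configs configuration grid (default reduced tiny-family grid).
#' @param schedule a [training_schedule()].
#' @param n_keep stage-1 survivors.
#' @param seed master seed.
#' @param hcs_n HCS sample size per fold.
#' @param out_dir optional report directory.
#' @param pretrain pretrain each buildable architecture per side on the
#'   synthetic source domain before fine-tuning.
#' @param pretrain_n,pretrain_epochs source-domain size and epochs.
#' @export
run_pipeline <- function(manifest, fold_set,
                         configs = enumerate_configs(
                           c("tiny", "tiny2"), c("UNDER", "DOUBLE"),
                           c("NONE", "SPINE")),
                         schedule = training_schedule(), n_keep = 2,
                         seed = 1, hcs_n = 6, out_dir = NULL,
                         pretrain = FALSE, pretrain_n = 320,
                         pretrain_epochs = 10) {
  pretrained_map <- NULL
  if (pretrain) {
    archs <- unique(configs$architecture)
    archs <- archs[vapply(archs, function(a) backbone_spec(a)$buildable,
                          logical(1))]
    pretrained_map <- lapply(
      c(left = "left", right = "right"), function(sd)
        stats::setNames(lapply(archs, function(a)
          pretrain_backbone(a, sd, n_images = pretrain_n,
                            epochs = pretrain_epochs,
                            seed = derive_seed(seed, "pretrain", a, sd))),
          archs))
  }
  grid_tab <- stage_one_grid(configs, manifest, fold_set, schedule, seed,
                             pretrained_map = pretrained_map)
  s1 <- stage_one(grid_tab, n_keep = n_keep)
  cv <- stage_two(s1$top[, c("architecture", "balancing", "segmentation")],
                  manifest, fold_set, schedule, seed, hcs_n = hcs_n,
                  pretrained_map = pretrained_map)
  best <- choose_best(cv)
  oob <- fold_rows(manifest, fold_set, "oob")
  if (is.null(oob$oobtr_left))
    oob <- synthesize_oobtr(oob, seed = derive_seed(seed, "oobtr"))
  s3 <- stage_three(best, manifest, fold_set, schedule, seed,
                    oob_rows = oob, pretrained_map = pretrained_map)
  pred <- s3$predictions
  subgroups <- lapply(c(race = "race", sex = "sex", covid = "covid"),
                      function(g) subgroup_metrics(pred, g))
  result <- list(stage1 = s1, crossval = cv, best = best, stage3 = s3,
                 subgroups = subgroups)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(s1$table, file.path(out_dir, "stage1_ranking.csv"),
              row.names = FALSE)
    write.csv(cv$summary, file.path(out_dir, "stage2_crossval.csv"),
              row.names = FALSE)
    write.csv(cv$binary, file.path(out_dir, "stage2_binary.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(best = best, rule = attr(best, "rule")),
                         file.path(out_dir, "best_model.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(lapply(s3$pairings, function(p)
      p[c("mae", "precision", "recall", "f1", "r_squared")]),
      file.path(out_dir, "stage3_reader_comparison.json"),
      auto_unbox = TRUE)
    for (g in names(subgroups))
      write.csv(subgroups[[g]],
                file.path(out_dir, paste0("subgroups_", g, ".csv")),
                row.names = FALSE)
  }
  result
}
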