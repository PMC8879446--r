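test_that("confusion counts match constructed cases and the brute-force tally", {
  reg <- c("pos", "neg")
  cc <- confusion_counts(c("pos", "pos", "neg"), c("pos", "pos", "neg"), reg)
  expect_equal(cc$fp, c(0, 0))
  expect_equal(cc$fn, c(0, 0))

  # binary with TP 9 / FN 1 / TN 8 / FP 2
  truths <- c(rep("pos", 10), rep("neg", 10))
  preds <- c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos")
  cc2 <- confusion_counts(preds, truths, reg)
  expect_equal(unlist(cc2[cc2$class == "pos", c("tp", "fp", "tn", "fn")]),
               c(tp = 9, fp = 2, tn = 8, fn = 1))

  withr::with_seed(13, {
    reg4 <- letters[1:4]
    truths4 <- sample(reg4, 60, replace = TRUE)
    preds4 <- sample(reg4, 60, replace = TRUE)
  })
  cc4 <- confusion_counts(preds4, truths4, reg4)
  oracle <- confusion_oracle(preds4, truths4, reg4)
  for (cls in reg4) {
    row <- cc4[cc4$class == cls, ]
    expect_equal(unlist(row[, c("tp", "fp", "tn", "fn")]), oracle[[cls]],
                 ignore_attr = TRUE)
    expect_equal(sum(row[, c("tp", "fp", "tn", "fn")]), 60)
  }
  expect_error(confusion_counts("z", "a", reg4), class = "mdcl_validation_error")
  expect_error(confusion_counts(c("a", "b"), "a", reg4), class = "mdcl_validation_error")
})

test_that("metrics reproduce the hand-computed binary case exactly", {
  truths <- c(rep("pos", 10), rep("neg", 10))
  preds <- c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos")
  rep_ <- compute_metrics(confusion_counts(preds, truths, c("pos", "neg")))
  pos <- rep_$per_class[rep_$per_class$class == "pos", ]
  expect_equal(rep_$overall$acc, 0.85)
  expect_equal(pos$tpr, 0.9)
  expect_equal(pos$tnr, 0.8)
  expect_equal(pos$ppv, 9 / 11)
  expect_equal(round(pos$ppv, 4), 0.8182)
  expect_equal(pos$f1, 6 / 7)
  expect_equal(round(pos$f1, 4), 0.8571)

  perfect <- compute_metrics(confusion_counts(truths, truths, c("pos", "neg")))
  expect_equal(unlist(perfect$overall[, c("acc", "tpr", "tnr", "ppv", "f1")]),
               c(acc = 1, tpr = 1, tnr = 1, ppv = 1, f1 = 1))
})

test_that("metrics match an independent formula oracle on random tables", {
  withr::with_seed(14, {
    for (i in 1:50) {
      w <- sample(2:5, 1)
      reg <- paste0("k", seq_len(w))
      truths <- sample(reg, 40, replace = TRUE)
      preds <- sample(reg, 40, replace = TRUE)
      rep_ <- compute_metrics(confusion_counts(preds, truths, reg))
      per <- rep_$per_class
      for (j in seq_len(w)) {
        tp <- per$tp[j]; fp <- per$fp[j]; tn <- per$tn[j]; fn <- per$fn[j]
        tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
        tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
        ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
        f1 <- if (ppv + tpr > 0) 2 * ppv * tpr / (ppv + tpr) else 0
        expect_equal(per$tpr[j], tpr, tolerance = 1e-12)
        expect_equal(per$tnr[j], tnr, tolerance = 1e-12)
        expect_equal(per$ppv[j], ppv, tolerance = 1e-12)
        expect_equal(per$f1[j], f1, tolerance = 1e-12)
      }
      present <- per$support > 0
      expect_equal(rep_$overall$acc, mean(preds == truths), tolerance = 1e-12)
      expect_equal(rep_$overall$f1, mean(per$f1[present]), tolerance = 1e-12)
    }
  })
})

test_that("macro F1 is invariant under registry permutation", {
  withr::with_seed(15, {
    reg <- letters[1:5]
    truths <- sample(reg, 80, replace = TRUE)
    preds <- sample(reg, 80, replace = TRUE)
    perm <- sample(reg)
  })
  f1_a <- compute_metrics(confusion_counts(preds, truths, reg))$overall$f1
  f1_b <- compute_metrics(confusion_counts(preds, truths, perm))$overall$f1
  expect_equal(f1_a, f1_b, tolerance = 1e-12)
})

test_that("zero-denominator ratios resolve to zero and are flagged", {
  # class 'b' never predicted and never true -> ppv and tpr undefined
  cc <- confusion_counts(c("a", "a"), c("a", "a"), c("a", "b"))
  rep_ <- compute_metrics(cc)
  b <- rep_$per_class[rep_$per_class$class == "b", ]
  expect_equal(b$tpr, 0)
  expect_equal(b$ppv, 0)
  expect_true(b$undefined)
  expect_gt(rep_$overall$n_undefined, 0)
})

test_that("forgetting curves have the right shape and flat no-change segments", {
  tasks <- tiny_benchmark(seed = 16)
  h <- run_sequence(tasks, train_config(epochs = 1, seed = 1))
  fc <- forgetting_curve(h)
  expect_equal(nrow(fc$series), 1)
  expect_equal(nrow(fc$drops), 0)

  # a no-change increment (duplicated state) yields zero drops
  h2 <- h
  h2$per_class <- c(h$per_class, h$per_class)
  h2$increments <- dplyr::bind_rows(h$increments, dplyr::mutate(h$increments, increment = 2))
  fc2 <- forgetting_curve(h2)
  expect_true(all(fc2$drops$drop == 0))
  expect_error(forgetting_curve(structure(list(increments = tibble::tibble()),
                                          class = "mdcl_history")),
               class = "mdcl_validation_error")
})

test_that("plain fine-tuning forgets: positive old-class drop after increment 2", {
  tasks <- tiny_benchmark(seed = 17, increments = 2)
  h <- run_sequence(tasks, train_config(epochs = 4, seed = 1, variant = "cross_entropy"))
  fc <- forgetting_curve(h)
  old_drop <- mean(fc$drops$drop[fc$drops$increment == 2])
  expect_gt(old_drop, 0)
})

test_that("the transferability grid has sane diagonal and count strings", {
  tasks <- tiny_benchmark(seed = 18)
  h <- run_sequence(tasks, train_config(epochs = 3, seed = 1))
  test_ds <- tasks$increments[[1]]$test
  grid <- transferability_matrix(list(alpha = h), list(alpha = test_ds))
  expect_equal(nrow(grid), 1)
  expect_equal(grid$accuracy, h$increments$accuracy[1])
  expect_equal(grid$classified, sprintf("%d/%d", grid$n_correct, grid$n_total))
  # determinism: same model, same test set
  grid2 <- transferability_matrix(list(alpha = h), list(alpha = test_ds))
  expect_identical(grid, grid2)
})

test_that("cross-domain transfer degrades when the modality differs", {
  # same shapes, same class names, different seeds vs different channel count
  mk <- function(name, channels, seed) {
    domain_spec(name, c(one = "bar", two = "disc"), channels = channels,
                image_size = 16, noise_sigma = 0.1, items_per_class = 60,
                seed = seed)
  }
  run_dom <- function(spec) {
    tasks <- generate_benchmark(list(spec),
                                list(list(domain = spec$name,
                                          classes = c("one", "two"))),
                                seed = 3)
    list(model = run_sequence(tasks, train_config(epochs = 6, seed = 2)),
         test = tasks$increments[[1]]$test)
  }
  a <- run_dom(mk("ga", 1, 21))
  b <- run_dom(mk("gb", 1, 22)) # identical spec, new seed
  c_ <- run_dom(mk("gc", 3, 23)) # colour modality
  grid <- transferability_matrix(
    list(ga = a$model, gc = c_$model),
    list(ga = a$test, gb = b$test, gc = c_$test)
  )
  same_mod <- grid[grid$train_domain == "ga" & grid$test_domain == "gb", ]
  diag_a <- grid[grid$train_domain == "ga" & grid$test_domain == "ga", ]
  cross_mod <- grid[grid$train_domain == "gc" & grid$test_domain == "ga", ]
  diag_c <- grid[grid$train_domain == "gc" & grid$test_domain == "gc", ]
  expect_lt(abs(same_mod$accuracy - diag_a$accuracy), 0.25)
  expect_lt(cross_mod$accuracy, diag_c$accuracy)
})

test_that("tau_sweep and loss_comparison handle degenerate argument lists", {
  tasks <- tiny_benchmark(seed = 19)
  cfg <- train_config(epochs = 2, seed = 1)
  sw <- tau_sweep(2, tasks, cfg, seeds = 5)
  expect_equal(nrow(sw), 1)
  h <- run_sequence(tasks, { c2 <- cfg; c2$temperature <- 2; c2$seed <- 5L; c2 })
  expect_equal(sw$mean_error, 1 - h$increments$accuracy[1])

  sw2 <- tau_sweep(c(2, 2), tasks, cfg, seeds = 5)
  expect_equal(sw2$mean_error[1], sw2$mean_error[2])

  cmp <- loss_comparison("cross_entropy", tasks, cfg, seeds = 5)
  expect_equal(nrow(cmp), 1)
  hce <- run_sequence(tasks, { c3 <- cfg; c3$variant <- "cross_entropy"
                               c3$temperature <- 1; c3$seed <- 5L; c3 })
  expect_equal(cmp$mean_accuracy, hce$increments$accuracy[1])
  expect_error(tau_sweep(c(1, -1), tasks, cfg), class = "mdcl_validation_error")
})

test_that("tidiers and plots expose the expected shapes", {
  tasks <- tiny_benchmark(seed = 20)
  h <- run_sequence(tasks, train_config(epochs = 1, seed = 1))
  td <- tidy(h)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("increment", "accuracy", "memory_reduction") %in% names(td)))
  gl <- glance(h)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$final_accuracy, td$accuracy[nrow(td)])
  rep_ <- h$reports[[1]]
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_equal(glance(rep_)$acc, rep_$overall$acc)
  expect_s3_class(autoplot(h), "ggplot")
  expect_s3_class(autoplot(forgetting_curve(h)), "ggplot")
  expect_s3_class(plot_loss_log(h$log), "ggplot")
})
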