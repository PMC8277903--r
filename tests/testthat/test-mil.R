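test_that("mean instance is the element-wise average", {
  inst <- toy_instances(c("b", "b"), gain = c(0, 1), loss = c(1, 0))
  m <- mean_instance(inst)
  expect_equal(unname(m[c("gain", "loss")]), c(0.5, 0.5))

  single <- toy_instances("b", h3k27ac_strength = 3)
  expect_equal(unname(mean_instance(single)["h3k27ac_strength"]), 3)

  three <- toy_instances(rep("b", 3), gain = c(0, 0, 3), loss = c(0, 0, 3))
  expect_equal(unname(mean_instance(three)[c("gain", "loss")]), c(1, 1))

  expect_error(mean_instance(toy_instances(character())), "no instances")
})

test_that("the embedding is the L1 distance to each reference instance", {
  bag_means <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("a", "b")))
  reference <- matrix(c(0, 1, 0.5, 0.5, 1, 0), 3, 2, byrow = TRUE,
                      dimnames = list(NULL, c("a", "b")))
  d <- miles_embed(bag_means, reference)
  expect_equal(as.numeric(d), c(1, 0, 1))  # |.5-0|+|.5-1| = 1; self = 0

  two <- matrix(runif(6), 2, 3)
  ref <- matrix(runif(9), 3, 3)
  expect_equal(dim(miles_embed(two, ref)), c(2, 3))
  expect_true(all(miles_embed(two, ref) >= 0))
  expect_error(miles_embed(two, matrix(0, 2, 2)), "dimension mismatch")

  # L2 option
  expect_equal(as.numeric(miles_embed(bag_means, reference[2, , drop = FALSE],
                                      metric = "l2")), 0)
})

test_that("bag capping preserves class balance and determinism", {
  bags <- tibble::tibble(
    pair_id = sprintf("b%04d", 1:1200), patient = "p", sv_id = "s",
    sv_type = "DEL", gene_id = "g", z = 0, n_reference = 10L,
    label = rep(c("positive", "negative"), 600)
  )
  capped <- subsample_bags(bags, cap = 700, seed = 5)
  expect_equal(nrow(capped), 700)
  expect_equal(sum(capped$label == "positive"), 350)
  expect_identical(subsample_bags(bags, 700, seed = 5),
                   subsample_bags(bags, 700, seed = 5))
  expect_identical(subsample_bags(bags[1:600, ], 700, seed = 5),
                   bags[1:600, ])
})

test_that("a separable problem is learnt and reproduced deterministically", {
  fx <- separable_bags()
  model <- train_model(fx$bags, fx$instances, seed = 11)
  pred <- predict(model, fx$bags, fx$instances)
  acc <- mean((pred$prob >= 0.5) == (fx$bags$label == "positive"))
  expect_equal(acc, 1)

  model2 <- train_model(fx$bags, fx$instances, seed = 11)
  expect_identical(predict(model2, fx$bags, fx$instances)$prob, pred$prob)

  single <- fx$bags[fx$bags$label == "positive", ]
  expect_error(train_model(single, fx$instances), "per class")
})

test_that("shuffled labels give chance-level AUC", {
  fx <- separable_bags(n_per_class = 15, n_patients = 10)
  aucs <- vapply(1:15, function(r) {
    set.seed(100 + r)
    shuffled <- dplyr::mutate(fx$bags, label = sample(label))
    cv <- suppressWarnings(
      leave_one_patient_out_cv(shuffled, fx$instances, num_trees = 50,
                               seed = r))
    compute_auc(cv$truth, cv$prob)
  }, 0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("LOPO folds partition the bags and never leak test instances", {
  fx <- separable_bags(n_per_class = 10, n_patients = 5)
  cv <- leave_one_patient_out_cv(fx$bags, fx$instances, seed = 2)
  # every bag predicted exactly once
  expect_setequal(cv$pair_id, fx$bags$pair_id)
  expect_false(any(duplicated(cv$pair_id)))

  # reference instances of each fold exclude the held-out patient
  for (p in unique(fx$bags$patient)) {
    train_bags <- fx$bags[fx$bags$patient != p, ]
    model <- train_model(train_bags, fx$instances, seed = 1)
    expect_false(p %in% model$reference_meta$patient)
  }
})

test_that("AUC matches the brute-force pairwise computation", {
  expect_equal(compute_auc(c("positive", "negative"), c(0.9, 0.1)), 1)
  expect_equal(compute_auc(c("positive", "negative"), c(0.1, 0.9)), 0)
  expect_equal(compute_auc(c("positive", "negative"), c(0.8, 0.8)), 0.5)
  expect_error(compute_auc(c("positive", "positive"), c(0.1, 0.9)),
               "single-class")

  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("positive", "negative")
    prob <- round(runif(n), sample(1:3, 1))  # rounded to force ties
    expect_equal(compute_auc(truth, prob), auc_bruteforce(truth, prob))
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  truth <- sample(c("positive", "negative"), 100, replace = TRUE)
  prob <- runif(100)
  expect_equal(
    compute_auc(truth, prob),
    as.numeric(pROC::auc(pROC::roc(truth == "positive", prob,
                                   quiet = TRUE, direction = "<")))
  )
})

test_that("operating point maximizes recall under the precision floor", {
  # perfectly separated: threshold at the lowest positive score
  op <- select_operating_point(rep(c("positive", "negative"), each = 3),
                               c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_equal(op$threshold, 0.7)
  expect_equal(op$recall, 1)
  expect_equal(op$precision, 1)

  # all scores equal with 30% positives: precision 0.3 < 0.5 everywhere
  expect_warning(
    op <- select_operating_point(c(rep("positive", 3), rep("negative", 7)),
                                 rep(0.5, 10)),
    "no threshold")
  expect_true(is.na(op$threshold))

  # exhaustive sweep oracle on random score sets
  sweep_oracle <- function(truth, prob, minp) {
    best <- NULL
    for (t in sort(unique(prob))) {
      call <- prob >= t
      if (sum(call) == 0) next
      prec <- sum(call & truth == "positive") / sum(call)
      rec <- sum(call & truth == "positive") / sum(truth == "positive")
      if (prec >= minp &&
          (is.null(best) || rec > best$recall ||
             (rec == best$recall && prec > best$precision))) {
        best <- list(threshold = t, precision = prec, recall = rec)
      }
    }
    best
  }
  set.seed(55)
  for (i in 1:15) {
    truth <- sample(c("positive", "negative"), 40, replace = TRUE)
    prob <- round(runif(40), 2)
    got <- suppressWarnings(select_operating_point(truth, prob, 0.5))
    want <- sweep_oracle(truth, prob, 0.5)
    if (is.null(want)) {
      expect_true(is.na(got$threshold))
    } else {
      expect_equal(got$recall, want$recall)
      expect_equal(got$threshold, want$threshold)
    }
  }
})

test_that("prediction respects schema and the operating point", {
  fx <- separable_bags()
  model <- train_model(fx$bags, fx$instances, seed = 3)
  model$operating_point <- 0.5
  pred <- predict(model, fx$bags[1, ], fx$instances)
  expect_true(pred$call)

  expect_equal(nrow(predict(model, fx$bags[0, ], fx$instances)), 0)
  broken <- fx$instances[, -match("dnase", names(fx$instances))]
  expect_error(predict(model, fx$bags, broken), "schema")
})

test_that("instance importances are normalized and rank planted signal", {
  fx <- separable_bags(n_per_class = 15)
  model <- train_model(fx$bags, fx$instances, seed = 9)
  imp <- rf_instance_importance(model)
  expect_equal(sum(imp$importance), 1)
  expect_false(is.unsorted(rev(imp$importance)))
  # instances from the signal-bearing positive bags reach the top decile
  top <- imp[seq_len(ceiling(nrow(imp) / 10)), ]
  pos_ids <- fx$bags$pair_id[fx$bags$label == "positive"]
  expect_true(any(top$pair_id %in% pos_ids))
})

test_that("tidy and glance summarise a fitted model", {
  fx <- separable_bags()
  model <- train_model(fx$bags, fx$instances, seed = 4)
  model$cv_predictions <- leave_one_patient_out_cv(fx$bags, fx$instances,
                                                   seed = 4)
  expect_equal(tidy(model), rf_instance_importance(model))
  g <- glance(model)
  expect_equal(g$n_bags, nrow(fx$bags))
  expect_gt(g$cv_auc, 0.9)
})
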