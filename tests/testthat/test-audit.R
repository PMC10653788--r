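test_that("empty submatrix extraction handles degenerate and toy cases", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("S", 1:4), paste0("g", 1:3)))
  idx <- extract_empty_submatrix(m, 50)
  expect_setequal(idx$sample_ids, rownames(m))
  expect_setequal(idx$genus_ids, colnames(m))

  # g1 present in 2 samples, g2 in none; threshold 2 retains g2 only and
  # every sample (all have g2 == 0)
  toy <- matrix(c(5L, 3L, 0L, 0L, 0L, 0L), 3, 2,
                dimnames = list(paste0("S", 1:3), c("g1", "g2")))
  idx <- extract_empty_submatrix(toy, 2)
  expect_identical(idx$genus_ids, "g2")
  expect_setequal(idx$sample_ids, paste0("S", 1:3))
})

test_that("empty submatrix equals the brute-force filter on small instances", {
  set.seed(99)
  for (n in c(1, 3, 6)) {
    for (g in c(1, 4, 6)) {
      for (rep in 1:4) {
        m <- matrix(sample(0:2, n * g, replace = TRUE), n, g,
                    dimnames = list(sprintf("S%d", 1:n),
                                    sprintf("g%d", 1:g)))
        storage.mode(m) <- "integer"
        for (thr in 1:3) {
          got <- extract_empty_submatrix(m, thr)
          want <- oracle_empty_submatrix(m, thr)
          expect_identical(got$sample_ids, want$sample_ids)
          expect_identical(got$genus_ids, want$genus_ids)
        }
      }
    }
  }
  # and on a larger seeded matrix
  big <- random_count_matrix(500, 100, seed = 123, lambda = 0.2)
  got <- extract_empty_submatrix(big, 50)
  want <- oracle_empty_submatrix(big, 50)
  expect_identical(got$sample_ids, want$sample_ids)
  expect_identical(got$genus_ids, want$genus_ids)
  # maximality: every retained cell is zero, every excluded sample has a hit
  sub <- big[got$sample_ids, got$genus_ids, drop = FALSE]
  expect_true(all(sub == 0))
  excluded <- setdiff(rownames(big), got$sample_ids)
  expect_true(all(rowSums(big[excluded, got$genus_ids, drop = FALSE] > 0)
                  > 0))
})

test_that("populating the empty matrix is an exact aligned lookup", {
  raw <- random_count_matrix(50, 20, seed = 7, lambda = 0.05)
  idx <- extract_empty_submatrix(raw, 5)
  # identity "normalization": all raw counts in the footprint are zero
  vals <- populate_from_normalized(idx, raw + 0)
  expect_true(all(vals == 0))

  norm <- matrix(rnorm(1000), 50, 20, dimnames = dimnames(raw))
  vals <- populate_from_normalized(idx, norm)
  set.seed(3)
  for (k in 1:100) {
    i <- sample(idx$sample_ids, 1)
    j <- sample(idx$genus_ids, 1)
    expect_identical(vals[i, j], norm[i, j])
  }
  bad <- norm[setdiff(rownames(norm), idx$sample_ids[1]), , drop = FALSE]
  expect_error(populate_from_normalized(idx, bad), "absent")
})

test_that("a perfectly separable feature yields a perfect audit", {
  n <- 60
  labels <- rep(c("A", "B"), each = n / 2)
  x <- cbind(f1 = as.numeric(labels == "A"),
             f2 = withr::with_seed(1, rnorm(n)))
  rep_ <- one_vs_all_audit(x, labels, cv_folds = 5, seed = 1)
  expect_equal(rep_$auroc, c(1, 1))
  expect_equal(rep_$sensitivity, c(1, 1))
  expect_equal(rep_$specificity, c(1, 1))
  # integer bookkeeping identities at the operating point
  tp <- rep_$sensitivity * rep_$n_pos
  expect_equal(tp, round(tp))
  pred_pos <- tp / rep_$ppv
  expect_equal(pred_pos, round(pred_pos))
})

test_that("audits of label-free data sit at chance level", {
  aurocs <- vapply(1:20, function(s) {
    x <- withr::with_seed(1000 + s, matrix(rnorm(200 * 5), 200, 5))
    labels <- withr::with_seed(2000 + s,
                               sample(rep(c("A", "B"), each = 100)))
    rep_ <- one_vs_all_audit(x, labels, cv_folds = 5, seed = s)
    rep_$auroc[1]
  }, numeric(1))
  expect_gt(mean(aurocs), 0.4)
  expect_lt(mean(aurocs), 0.6)
})

test_that("constant feature matrices are flagged as no-signal", {
  x <- matrix(3.25, 40, 4,
              dimnames = list(sprintf("S%02d", 1:40), paste0("g", 1:4)))
  labels <- rep(c("A", "B"), 20)
  rep_ <- one_vs_all_audit(x, labels, cv_folds = 5, seed = 1)
  expect_equal(rep_$auroc, c(0.5, 0.5))
  expect_equal(rep_$flag, c("no signal", "no signal"))
})

test_that("classes smaller than the fold count are skipped", {
  x <- matrix(rnorm(40), 20, 2)
  labels <- c(rep("A", 17), rep("B", 3))
  rep_ <- one_vs_all_audit(x, labels, cv_folds = 5, seed = 1)
  expect_equal(rep_$flag, c("skipped", "skipped"))
})

test_that("the glmnet backend also detects a separable class", {
  skip_if_not_installed("glmnet")
  n <- 60
  labels <- rep(c("A", "B"), each = n / 2)
  x <- cbind(f1 = as.numeric(labels == "A") + withr::with_seed(4,
             rnorm(n, 0, 0.01)), f2 = withr::with_seed(5, rnorm(n)))
  rep_ <- one_vs_all_audit(x, labels, cv_folds = 5, seed = 1,
                           backend = "glmnet")
  expect_gt(min(rep_$auroc), 0.95)
})

test_that("threshold rule metrics match brute-force confusion counts", {
  expect_equal(
    threshold_rule_metrics(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                           threshold = 2.5, positive_side = "le"),
    list(sensitivity = 1.0, error_fraction = 0.0)
  )
  set.seed(31)
  for (rep in 1:5) {
    v <- rnorm(200)
    l <- runif(200) < 0.3
    if (!any(l)) l[1] <- TRUE
    thr <- rnorm(1)
    for (side in c("le", "gt")) {
      got <- threshold_rule_metrics(v, l, thr, side)
      want <- oracle_threshold_metrics(v, l, thr, side)
      expect_equal(got, want)
    }
  }
  expect_error(threshold_rule_metrics(1:3, c(FALSE, FALSE, FALSE), 1),
               "no positives")
})

test_that("value multiplicity groups exactly with no tolerance", {
  v <- c(rep(3.07584214, 38), rep(3.07585718, 18), rep(3.076237397, 5),
         seq(10, 18))
  groups <- value_multiplicity(v)
  expect_equal(groups$size, c(38, 18, 5, rep(1, 9)))
  expect_equal(groups$value[1:3], c(3.07584214, 3.07585718, 3.076237397))
  expect_equal(sum(groups$size), length(v))

  distinct <- c(1.1, 2.2, 3.3)
  expect_equal(value_multiplicity(distinct)$size, rep(1, 3))

  # values differing in the last bits stay distinct
  a <- 1
  b <- 1 + .Machine$double.eps
  expect_equal(value_multiplicity(c(a, a, b))$size, c(2, 1))

  set.seed(8)
  for (rep in 1:5) {
    v <- round(rnorm(100), 1)
    expect_equal(value_multiplicity(v)$size, oracle_multiplicity(v))
  }
})

test_that("leakage score spots class indicators hidden in normalized zeros", {
  n <- 40
  labels <- rep(c("A", "B"), each = n / 2)
  raw <- rep(0L, n)
  expect_equal(leakage_score(raw, as.numeric(labels == "A"), labels), 1.0)

  # no zero-restricted samples: 0.5 by convention
  expect_equal(leakage_score(rep(1L, n), rnorm(n), labels), 0.5)

  # pure noise stays near chance
  noise <- withr::with_seed(10, rnorm(1000))
  lab2 <- rep(c("A", "B"), each = 500)
  expect_lte(leakage_score(rep(0L, 1000), noise, lab2), 0.6)
})

test_that("feature audit combines scores and duplicate diagnostics", {
  n <- 30
  labels <- rep(c("A", "B"), each = n / 2)
  raw <- cbind(gleak = rep(0L, n), gok = rep(1L, n))
  rownames(raw) <- sprintf("S%02d", 1:n)
  norm <- cbind(gleak = ifelse(labels == "A", 2.5, 7.5),
                gok = withr::with_seed(3, rnorm(n)))
  rownames(norm) <- rownames(raw)
  fa <- feature_audit(raw, norm, labels)
  expect_equal(fa$leakage_score[fa$feature == "gleak"], 1.0)
  expect_equal(fa$max_dup_group[fa$feature == "gleak"], 15L)
  expect_equal(fa$leakage_score[fa$feature == "gok"], 0.5)
})
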