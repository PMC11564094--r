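test_that("read_tabular parses tables, infers kinds and counts missingness", {
  f <- write_mixed_csv()
  fr <- read_tabular(f, index_column = "id")
  expect_equal(dim(fr), c(4L, 5L))
  expect_equal(fr$var["age", "kind"], "numeric")
  expect_equal(fr$var["weight", "kind"], "numeric")
  expect_equal(fr$var["sex", "kind"], "categorical")
  expect_equal(fr$uns$categories$sex, c("F", "M"))
  expect_equal(fr$var["smoker", "kind"], "boolean")
  expect_equal(fr$var["admit", "kind"], "datetime")
  expect_true(is.na(fr$X["c", "weight"]))
  expect_equal(fr$var["weight", "missing_frac"], 1 / 4)

  # purely numeric file gives a numeric matrix straight away
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,4", "2,5", "3,6"), f2)
  fr2 <- read_tabular(f2)
  expect_true(is.numeric(fr2$X))
  expect_equal(unname(fr2$X[, "a"]), c(1, 2, 3))

  # determinism: same file, same options, identical frame
  expect_identical(read_tabular(f, index_column = "id")$X, fr$X)
})

test_that("read_tabular rejects broken input", {
  expect_error(read_tabular(tempfile()), "cannot read")
  f <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3"), f)
  expect_error(read_tabular(f), "ragged")
  f2 <- write_mixed_csv()
  expect_error(read_tabular(f2, type_overrides = c(nope = "numeric")), "absent")
})

test_that("feature-kind inference applies the documented threshold rules", {
  expect_equal(ehrkit:::infer_kind(c("1.5", "2", NA)), "numeric")
  expect_equal(ehrkit:::infer_kind(c("M", "F", "M")), "categorical")
  expect_equal(ehrkit:::infer_kind(c("yes", "no")), "boolean")
  expect_equal(ehrkit:::infer_kind(c("2020-01-01", "1999-12-31")), "datetime")
  many <- paste0("s", seq_len(1000))
  expect_equal(ehrkit:::infer_kind(many, max_categories = 100), "text")
  expect_equal(ehrkit:::infer_kind(many[1:50], max_categories = 100), "categorical")
  expect_error(infer_feature_types(ehrframe(matrix(numeric(0), 0, 0))), "empty")
})

test_that("store round-trip is bitwise lossless for every component kind", {
  set.seed(42)
  fr <- mkframe(matrix(rnorm(30), 10, 3))
  fr$X[c(2, 17)] <- NA
  fr$obs$grp <- factor(rep(c("a", "b"), 5))
  fr$obs$score <- rnorm(10)
  fr$layers$raw <- fr$X * 2
  fr$obsm$X_pca <- matrix(rnorm(20), 10, 2,
                          dimnames = list(rownames(fr$X), c("PC1", "PC2")))
  fr$varm$load <- matrix(rnorm(6), 3, 2,
                         dimnames = list(colnames(fr$X), NULL))
  fr$obsp$rel <- diag(10)
  dimnames(fr$obsp$rel) <- list(rownames(fr$X), rownames(fr$X))
  fr$uns$note <- list(alpha = 0.12345678901234567, tag = "qc")
  st <- tempfile()
  write_store(fr, st)
  rt <- read_store(st)
  expect_identical(rt$X, fr$X)
  expect_identical(rt$obs, fr$obs)
  expect_identical(rt$var, fr$var)
  expect_identical(rt$layers$raw, fr$layers$raw)
  expect_identical(rt$obsm$X_pca, fr$obsm$X_pca)
  expect_identical(rt$varm$load, fr$varm$load)
  expect_identical(rt$obsp$rel, fr$obsp$rel)
  expect_identical(rt$uns$note$alpha, fr$uns$note$alpha)

  # mixed-type frame with missing tokens and category order
  fm <- read_tabular(write_mixed_csv(), index_column = "id")
  st2 <- tempfile()
  write_store(fm, st2)
  rt2 <- read_store(st2)
  expect_identical(rt2$X, fm$X)
  expect_identical(rt2$uns$categories$sex, fm$uns$categories$sex)
  expect_true(is.na(rt2$X["c", "weight"]))

  # corrupt store names the offending component
  unlink(file.path(st, "var.csv"))
  expect_error(read_store(st), "var.csv")
})

test_that("move_to_obs / move_to_x are inverse and keep alignment", {
  set.seed(7)
  Y <- matrix(rnorm(100 * 25), 100, 25)
  fr <- mkframe(Y)
  moved <- paste0("v", 1:6)
  fr2 <- move_to_obs(fr, moved)
  expect_equal(n_vars(fr2), 19)
  expect_true(all(moved %in% colnames(fr2$obs)))
  back <- move_to_x(fr2, moved)
  expect_equal(n_vars(back), 25)
  expect_equal(back$X[, sort(colnames(Y))], fr$X[, sort(colnames(Y))])

  # categorical round trip with native dtype in obs
  fm <- read_tabular(write_mixed_csv(), index_column = "id")
  fm2 <- move_to_obs(fm, "sex")
  expect_s3_class(fm2$obs$sex, "factor")
  expect_equal(levels(fm2$obs$sex), c("F", "M"))
  fm3 <- move_to_x(fm2, "sex")
  expect_equal(fm3$var["sex", "kind"], "categorical")
  expect_setequal(colnames(fm3$X), colnames(fm$X))

  expect_identical(move_to_obs(fm, character(0)), fm)
  expect_error(move_to_obs(fm, "ghost"), "unknown")
  expect_error(move_to_x(fm2, "ghost"), "unknown")
  fm4 <- fm2; fm4$obs$age <- 1  # collide with a variable name
  expect_error(move_to_x(fm4, "age"), "collision")
})

test_that("alignment invariants are enforced by the shared validator", {
  fr <- mkframe(matrix(1:6, 3, 2))
  bad <- fr; bad$obs <- bad$obs[1:2, , drop = FALSE]
  expect_error(validate_ehrframe(bad), "n_obs")
  bad2 <- fr; bad2$layers$l <- matrix(0, 2, 2)
  expect_error(validate_ehrframe(bad2), "layer")
  bad3 <- fr; rownames(bad3$X) <- c("a", "a", "b")
  expect_error(validate_ehrframe(bad3), "unique")
  # subsetting keeps all slots aligned
  fr$layers$l2 <- fr$X
  fr$obsm$m <- matrix(0, 3, 2, dimnames = list(rownames(fr$X), NULL))
  sub <- fr[1:2, 1]
  expect_equal(dim(sub), c(2L, 1L))
  expect_equal(dim(sub$layers$l2), c(2L, 1L))
  expect_equal(nrow(sub$obsm$m), 2L)
})
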