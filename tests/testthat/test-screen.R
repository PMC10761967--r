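panel4 <- c("human", "house_mouse", "bovine", "rabbit")

test_that("identity ratio implements pid(ref,focal) / pid(ref,base)", {
  m <- make_idm(panel4, list())
  expect_equal(identity_ratio(m), 1)

  m <- make_idm(c("human", "house_mouse", "bovine"),
                list("human:house_mouse" = 50, "human:bovine" = 100))
  expect_equal(identity_ratio(m), 0.5)

  expect_error(identity_ratio(make_idm(c("human", "bovine"), list())),
               "lacks species")
  mz <- make_idm(c("human", "house_mouse", "bovine"),
                 list("human:bovine" = 0))
  expect_error(identity_ratio(mz), "undefined")
})

test_that("extended identity ratio sums focal-vs-trio over trio pairs", {
  m <- make_idm(panel4, list())
  expect_equal(extended_identity_ratio(m), 1)

  m <- make_idm(panel4, list(
    "house_mouse:human" = 60, "house_mouse:bovine" = 55,
    "house_mouse:rabbit" = 65,
    "human:bovine" = 70, "human:rabbit" = 75, "bovine:rabbit" = 77))
  expect_equal(extended_identity_ratio(m), 180 / 222)
  expect_equal(round(extended_identity_ratio(m), 2), 0.81)

  # denominator is a symmetric sum: any trio ordering gives the same ratio
  for (perm in list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1))) {
    expect_equal(
      extended_identity_ratio(m, trio = c("human", "bovine", "rabbit")[perm]),
      180 / 222)
  }
})

test_that("IR and EIR are invariant to uniform matrix rescaling", {
  m <- make_idm(panel4, list(
    "house_mouse:human" = 62, "house_mouse:bovine" = 58,
    "house_mouse:rabbit" = 66, "human:bovine" = 71,
    "human:rabbit" = 74, "bovine:rabbit" = 70))
  m2 <- m * 0.5
  class(m2) <- class(m)
  expect_equal(identity_ratio(m2), identity_ratio(m))
  expect_equal(extended_identity_ratio(m2), extended_identity_ratio(m))
})

test_that("tukey summary matches hand-computed interpolated quartiles", {
  s <- tukey_summary(c(0.9, 0.95, 1.0, 1.05, 1.1))
  expect_equal(s$median, 1.0)
  expect_equal(s$q1, 0.95)
  expect_equal(s$q3, 1.05)
  expect_equal(s$lower_fence, 0.80)

  s <- tukey_summary(rep(0.97, 5))
  expect_equal(s$lower_fence, 0.97)
  expect_equal(s$iqr, 0)

  expect_error(tukey_summary(c(1, 2, 3)), "at least 4")
})

test_that("tukey summary equals an independent sort-and-interpolate oracle", {
  set.seed(61)
  x <- runif(100, 0.8, 1.2)
  s <- tukey_summary(x)
  q1 <- quantile_oracle(x, 0.25)
  q3 <- quantile_oracle(x, 0.75)
  expect_equal(s$median, quantile_oracle(x, 0.5))
  expect_equal(s$q1, q1)
  expect_equal(s$q3, q3)
  expect_equal(s$lower_fence, q1 - 1.5 * (q3 - q1))
})

test_that("screen ranks an accelerated gene first and flags it below the fence", {
  # four conserved genes (identical sequences across species) and one gene
  # whose focal-lineage ortholog diverged
  set.seed(71)
  base_seq <- random_aa(120)
  mk_group <- function(sym, focal_seq) {
    members <- setNames(lapply(panel4, function(sp) {
      s <- if (sp == "house_mouse") focal_seq else base_seq
      recs(c(paste0(sym, "_", sp), sym, sp, s))[1, ]
    }), panel4)
    ortholog_group(sym, members)
  }
  diverged <- strsplit(base_seq, "")[[1]]
  idx <- sample(120, 60)
  diverged[idx] <- sample(AA20, 60, replace = TRUE)
  groups <- list(mk_group("CONS1", base_seq), mk_group("CONS2", base_seq),
                 mk_group("CONS3", base_seq), mk_group("CONS4", base_seq),
                 mk_group("FAST1", paste(diverged, collapse = "")))
  rep <- run_screen(groups)
  expect_equal(rep$records$gene_symbol[1], "FAST1")
  expect_true(rep$records$outlier[1])
  expect_false(any(rep$records$outlier[-1]))

  # flag rule is exact: flagged set == { ratio < lower_fence }
  val <- rep$records$eir
  expect_equal(rep$records$outlier, val < rep$summary$lower_fence)

  # permuted input produces the identical report
  rep2 <- run_screen(groups[c(3, 5, 1, 2, 4)])
  expect_equal(rep2$records, rep$records)
  expect_equal(rep2$summary, rep$summary)
})

test_that("screen skips incomplete groups and errors when nothing is usable", {
  set.seed(72)
  s <- random_aa(60)
  full <- ortholog_group("FULL", setNames(lapply(panel4, function(sp)
    recs(c(paste0("f", sp), "FULL", sp, s))[1, ]), panel4))
  partial <- ortholog_group("PART", list(
    human = recs(c("ph", "PART", "human", s))[1, ]))
  expect_error(run_screen(list()), "no ortholog groups")
  expect_error(run_screen(list(partial)), "missing panel species")
  rep <- run_screen(list(full, full, full, full, partial))
  expect_equal(rep$skipped, "PART")
  expect_equal(nrow(rep$records), 4)
})

test_that("screen reports round-trip through the TSV writer", {
  set.seed(73)
  ds <- generate_screen_dataset(6, 0, 1, length = 80, seed = 99)
  rep <- run_screen(ds$groups)
  f <- tempfile(fileext = ".tsv")
  write_screen_report(rep, f, provenance = c(seed = "99"))
  lines <- readLines(f)
  expect_true(any(grepl("^# median=", lines)))
  expect_true(any(grepl("^# seed=99", lines)))
  tab <- utils::read.delim(f, comment.char = "#")
  expect_equal(tab$gene_symbol, rep$records$gene_symbol)
  expect_equal(tab$ir, as.numeric(sprintf("%.2f", rep$records$ir)))
})
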