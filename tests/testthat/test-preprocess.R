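make_table <- function(vals) {
  descriptor_table(vals, paste0("c", seq_len(nrow(vals))),
                   colnames(vals))
}

test_that("missing-value filter drops leaky descriptors and imputes the rest", {
  v <- cbind(a = c(NA, NA, 3:10), b = c(NA, 2:10), d = 1:10)
  tbl <- make_table(v)
  out <- drop_missing(tbl, max_missing = 1)
  expect_equal(out$descriptor_names, c("b", "d"))
  # the single allowed gap imputes to the column mean of observed rows
  expect_equal(out$values[1, "b"], mean(2:10))
  expect_false(anyNA(out$values))
  prov <- attr(out, "provenance")
  expect_true(any(vapply(prov, function(p) p$action == "drop", TRUE)))
  expect_true(any(vapply(prov, function(p) p$action == "impute", TRUE)))

  clean <- make_table(cbind(a = 1:5, b = 5:1))
  expect_equal(drop_missing(clean)$values, clean$values)

  allbad <- make_table(cbind(a = c(NA, NA, 1, 2)))
  expect_error(drop_missing(allbad), "all descriptors")
})

test_that("invariance filter removes non-discriminating descriptors", {
  v <- cbind(const = rep(5, 10), bin = rep(c(0, 1), 5),
             tiny = 1 + rnorm(10, sd = 1e-9), ok = 1:10)
  tbl <- make_table(v)
  out <- drop_invariant(tbl)
  expect_false("const" %in% out$descriptor_names)
  expect_false("tiny" %in% out$descriptor_names)   # var ~1e-18 < 1e-12
  expect_true(all(c("bin", "ok") %in% out$descriptor_names))
})

test_that("Spearman pruning removes one member of each collinear pair", {
  set.seed(21)
  x <- rnorm(50)
  y <- x + rnorm(50, sd = 0.1)
  tbl <- make_table(cbind(dup1 = x, dup2 = x, other = rnorm(50)))
  out <- spearman_prune(tbl, y)
  expect_equal(sum(c("dup1", "dup2") %in% out$table$descriptor_names), 1L)
  expect_true("other" %in% out$table$descriptor_names)
  expect_equal(nrow(out$dropped), 1L)
  expect_equal(out$dropped$pair_r2, 1)

  # independent columns survive
  set.seed(22)
  ind <- make_table(cbind(a = rnorm(200), b = rnorm(200)))
  resp <- rnorm(200)
  expect_equal(spearman_prune(ind, resp)$table$descriptor_names,
               c("a", "b"))

  # the threshold is a strict inequality
  r <- rank(rnorm(30))
  tied <- make_table(cbind(a = as.numeric(r), b = as.numeric(r)))
  keep_both <- spearman_prune(tied, rnorm(30), r2_threshold = 1)
  expect_equal(ncol(keep_both$table$values), 2L)
})

test_that("pruning keeps the member better rank-correlated with the response", {
  set.seed(23)
  y <- rnorm(100)
  strong <- y + rnorm(100, sd = 0.2)
  weak <- strong + rnorm(100, sd = 0.2)  # collinear, weaker link to y
  tbl <- make_table(cbind(weak = weak, strong = strong))
  out <- spearman_prune(tbl, y)
  expect_equal(out$table$descriptor_names, "strong")
  # column order does not change the outcome
  tbl2 <- make_table(cbind(strong = strong, weak = weak))
  expect_equal(spearman_prune(tbl2, y)$table$descriptor_names, "strong")
})

test_that("autoscaling centers and scales with the n-1 denominator", {
  tbl <- make_table(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  out <- normalize_table(tbl)
  expect_equal(unname(out$values[, "a"]), c(-1, 0, 1))
  expect_true(out$normalized)
  expect_equal(unname(out$norm_params$center), c(2, 30))
  expect_equal(unname(out$norm_params$scale[1]), 1)
  # recomputed column moments under n-1
  expect_lt(max(abs(colMeans(out$values))), 1e-9)
  expect_lt(max(abs(apply(out$values, 2, sd) - 1)), 1e-9)
  # idempotence on an already standardized column
  again <- normalize_table(out)
  expect_equal(again$values, out$values, tolerance = 1e-12)

  expect_error(normalize_table(make_table(cbind(a = c(5, 5, 5)))),
               "a")
})

test_that("stored parameters reproduce the training transform and extend beyond it", {
  set.seed(24)
  tbl <- make_table(cbind(a = rnorm(20, 5, 3), b = runif(20)))
  norm <- normalize_table(tbl)
  reapplied <- apply_normalization(tbl, norm$norm_params)
  expect_equal(reapplied$values, norm$values, tolerance = 1e-12)

  ident <- apply_normalization(tbl, list(
    center = c(a = 0, b = 0), scale = c(a = 1, b = 1)))
  expect_equal(ident$values, tbl$values)

  outside <- descriptor_table(cbind(a = 1e6, b = -50), "x1", c("a", "b"))
  tx <- apply_normalization(outside, norm$norm_params)
  expect_true(all(is.finite(tx$values)))

  expect_error(apply_normalization(
    make_table(cbind(c = 1:3)), norm$norm_params), "c")
})

test_that("ion classes partition compounds by pKa relative to pH 7", {
  pka <- function(values, types) data.frame(value = values, type = types,
                                            stringsAsFactors = FALSE)
  expect_equal(assign_ion_class(pka(c(10.2, 4.0), c("acid", "base"))),
               "zwitterion")
  expect_equal(assign_ion_class(pka(4.2, "acid")), "acid")
  expect_equal(assign_ion_class(pka(9.5, "base")), "base")
  expect_equal(assign_ion_class(pka(numeric(0), character(0))), "neutral")
  expect_equal(assign_ion_class(NULL), "neutral")
  # mixed pKa spanning 7 without the zwitterion signature
  expect_equal(assign_ion_class(pka(c(3, 9), c("acid", "acid"))),
               "neutral")
})

test_that("provenance log writes one JSON record per event", {
  v <- cbind(a = c(NA, NA, 3:10), b = c(NA, 2:10), d = 1:10)
  out <- drop_missing(make_table(v))
  path <- tempfile(fileext = ".jsonl")
  write_provenance(attr(out, "provenance"), path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$action, "drop")
  expect_equal(rec$descriptor, "a")
})
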