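# Stimulus generation: templates, dataset assembly, manifests, rendering.

test_that("templates have four short segments, one long, and are reproducible", {
  tpl <- make_templates(seed = 0)
  expect_length(tpl, 5)
  for (t in tpl) {
    expect_identical(sort(t$segments$role), c("long", rep("short", 4)))
    expect_true(all(t$segments$orientation %in% c("h", "v")))
  }
  expect_identical(make_templates(seed = 0), tpl)
  # a different seed must change at least one anchor layout
  tpl1 <- make_templates(seed = 1)
  expect_false(identical(
    lapply(tpl, function(t) t$segments),
    lapply(tpl1, function(t) t$segments)))
})

test_that("the five templates are pairwise non-congruent under quarter-turns", {
  for (seed in 0:2) {
    tpl <- make_templates(seed)
    keys <- vapply(tpl, function(t)
      shapebias:::canonical_cells(shapebias:::template_cells(t)), character(1))
    expect_length(unique(keys), 5)
  }
})

test_that("datasets are balanced, sized as requested, and stratified exactly", {
  m <- small_dataset("exp2", "b", n_train = 100, n_test = 20)
  expect_equal(sum(m$condition == "train"), 100)
  for (cond in c("both", "conflict", "shape", "nonshape"))
    expect_equal(sum(m$condition == cond), 20)
  counts <- table(m$label[m$condition == "train"])
  expect_true(all(counts == 20))
  # exact 80/20 split of shape-bearing training images, within every label
  tr <- m[m$condition == "train", ]
  by_label <- tapply(!is.na(tr$shape_id), tr$label, sum)
  expect_true(all(by_label == 16))
  expect_error(generate_dataset("exp1", "a", n_train = 7), "divisible")
  # tiny balanced case
  m10 <- generate_dataset("exp1", "a", n_train = 10, n_test_per_condition = 5, seed = 1)
  expect_true(all(table(m10$label[m10$condition == "train"]) == 2))
})

test_that("no-shape experiments only admit the nonshape test condition", {
  m <- small_dataset("exp5_segment", "noshape", n_train = 50, n_test = 10)
  expect_setequal(unique(m$condition), c("train", "nonshape"))
  expect_true(all(is.na(m$shape_id)))
  expect_error(sample_test_spec("exp5_size", "conflict", 1), "not defined")
  expect_error(generate_dataset("exp5_size", "a", 50, 10), "arg")
})

test_that("conflict rows pair distinct shape and non-shape categories", {
  for (exp in c("exp1", "exp2", "exp3", "exp4")) {
    m <- small_dataset(exp, "a", n_train = 5, n_test = 20)
    conf <- m[m$condition == "conflict", ]
    expect_true(all(!is.na(conf$shape_id)))
    expect_true(all(!is.na(conf$nonshape_category)))
    expect_true(all(conf$shape_id != conf$nonshape_category))
    expect_true(all(conf$nonshape_category == (conf$label %% 5) + 1))
    sh <- m[m$condition == "shape", ]
    expect_true(all(is.na(sh$nonshape_category)))
    ns <- m[m$condition == "nonshape", ]
    expect_true(all(is.na(ns$shape_id)))
  }
})

test_that("identical arguments give byte-identical manifests", {
  a <- generate_dataset("exp3", "b", n_train = 50, n_test_per_condition = 10, seed = 42)
  b <- generate_dataset("exp3", "b", n_train = 50, n_test_per_condition = 10, seed = 42)
  expect_identical(a, b)
  c <- generate_dataset("exp3", "b", n_train = 50, n_test_per_condition = 10, seed = 43)
  expect_false(identical(a$diag_json, c$diag_json))
})

test_that("manifests round-trip losslessly through CSV + JSON sidecar", {
  m <- small_dataset("exp2", "a", n_train = 25, n_test = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  back <- read_manifest(path)
  expect_equal(as.data.frame(back), as.data.frame(m))
  meta <- attr(back, "sb_meta")
  expect_equal(meta$palette$colours, sb_palette()$colours)
  expect_equal(shapebias:::templates_to_df(meta$templates),
               shapebias:::templates_to_df(attr(m, "sb_meta")$templates),
               ignore_attr = TRUE)
  # rendering from the read-back manifest matches the original
  expect_identical(render_stimulus(m[3, ], attr(m, "sb_meta"), size = 32),
                   render_stimulus(back[3, ], meta, size = 32))
})

test_that("empty manifests and corrupted labels are handled", {
  m <- small_dataset("exp3", "a", n_train = 5, n_test = 5)
  empty <- m[0, ]
  attr(empty, "sb_meta") <- attr(m, "sb_meta")
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(empty, path)
  expect_equal(nrow(read_manifest(path)), 0)

  write_manifest(m, path)
  lines <- readLines(path)
  lines[4] <- sub("^(([^,]*,){4})[0-9]+", "\\1banana", lines[4])
  writeLines(lines, path)
  expect_error(read_manifest(path), "label.*row|row.*label")
})

test_that("patch counts stay within the 30-55 budget and segment ranges hold", {
  for (exp in c("exp1", "exp2", "exp3")) {
    m <- small_dataset(exp, "a", n_train = 60, n_test = 20)
    meta <- attr(m, "sb_meta")
    geo <- lapply(seq_len(nrow(m)), function(i)
      shapebias:::stimulus_geometry(m[i, ], meta))
    n <- vapply(geo, function(g) g$n_patches, integer(1))
    expect_true(all(n >= 30 & n <= 55))
    segs <- t(vapply(geo, function(g) g$segment_counts, integer(5)))
    expect_true(all(segs[, 1] >= 10 & segs[, 1] <= 15)) # long
    expect_true(all(segs[, -1] >= 5 & segs[, -1] <= 10)) # shorts
  }
})

test_that("rendering is deterministic and leaves non-patch pixels background", {
  m <- small_dataset("exp2", "a", n_train = 10, n_test = 5)
  meta <- attr(m, "sb_meta")
  img <- render_stimulus(m[1, ], meta)
  expect_identical(img, render_stimulus(m[1, ], meta))
  expect_equal(dim(img), c(600, 600, 3))
  # every pixel is either background white or one of the 20 palette colours
  pal <- rbind(sb_palette()$colours, sb_palette()$background) / 255
  px <- unique(matrix(img, ncol = 3))
  keys <- apply(px, 1, paste, collapse = "/")
  legal <- apply(pal, 1, paste, collapse = "/")
  expect_true(all(keys %in% legal))
})

test_that("global-colour images use a single colour and scrambled rows scatter", {
  m <- small_dataset("exp4", "a", n_train = 10, n_test = 5)
  meta <- attr(m, "sb_meta")
  for (i in c(1, 2)) {
    g <- shapebias:::stimulus_geometry(m[i, ], meta)
    expect_length(unique(g$patches$colour), 1)
  }
  ns <- m[m$condition == "nonshape", ]
  g1 <- shapebias:::stimulus_geometry(ns[1, ], meta)
  expect_equal(nrow(g1$patches), g1$n_patches)
})

test_that("training images of one category vary in counts, layout and colours", {
  m <- small_dataset("exp1", "a", n_train = 100, n_test = 5)
  meta <- attr(m, "sb_meta")
  tr <- m[m$condition == "train" & m$label == 1, ]
  geo <- lapply(seq_len(nrow(tr)), function(i)
    shapebias:::stimulus_geometry(tr[i, ], meta))
  n <- vapply(geo, function(g) g$n_patches, integer(1))
  expect_gt(length(unique(n)), 1)
  firstxy <- t(vapply(geo, function(g) c(g$patches$x[1], g$patches$y[1]), numeric(2)))
  expect_gt(nrow(unique(firstxy)), 1)
  cols <- lapply(geo, function(g) g$patches$colour)
  expect_gt(length(unique(vapply(cols, paste, character(1), collapse = ","))), 1)
})

test_that("PNG export fills the image column with readable files", {
  m <- small_dataset("exp3", "a", n_train = 5, n_test = 5)
  dir <- withr::local_tempdir()
  out <- write_images(m[1:3, ], dir, size = 32)
  expect_true(all(file.exists(out$image[1:3])))
  img <- png::readPNG(out$image[1])
  expect_equal(dim(img), c(32, 32, 3))
})

test_that("single-spec sampling follows variant and condition contracts", {
  s <- sample_training_spec("exp1", "a", label = 3, seed = 5)
  expect_equal(s$shape_id, 3L)
  expect_equal(s$nonshape_category, 3L)
  d <- shapebias:::parse_diag(s$diag_json)
  expect_equal(d$loc, 3)
  expect_equal(d$colour, 3)
  s5 <- sample_training_spec("exp5_segment", "noshape", label = 1, seed = 2)
  expect_true(is.na(s5$shape_id))
  expect_error(sample_training_spec("exp1", "a", label = 9), "label")
  expect_error(sample_training_spec("exp1", "a", 1, shape_prob = 1.5), "shape_prob")
  t1 <- sample_test_spec("exp2", "conflict", label = 1, seed = 3)
  expect_equal(t1$shape_id, 1L)
  expect_equal(t1$nonshape_category, 2L)
  d1 <- shapebias:::parse_diag(t1$diag_json)
  expect_equal(d1$seg_colours[d1$diag_segment], 2)
  t2 <- sample_test_spec("exp4", "shape", label = 2, seed = 3)
  d2 <- shapebias:::parse_diag(t2$diag_json)
  expect_true(d2$colour %in% 6:20)
})
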