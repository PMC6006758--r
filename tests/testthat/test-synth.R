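test_that("generation is deterministic and respects declared ranges", {
  spec <- synth_spec(n_classes = 3, n_per_class = 4, length_range = c(20, 40),
                     delta = 4, seed = 9)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1, d2)

  lens <- vapply(d1$pssms, `[[`, 0L, "L")
  expect_true(all(lens >= 20 & lens <= 40))
  for (p in d1$pssms)
    expect_true(all(p$scores >= -9 & p$scores <= 11))
  expect_equal(unname(table(d1$labels)), rep(4, 3), ignore_attr = TRUE)
  expect_equal(nchar(d1$records$sequence), lens)

  # a different seed changes the data
  d3 <- generate_dataset(synth_spec(n_classes = 3, n_per_class = 4,
                                    length_range = c(20, 40), delta = 4,
                                    seed = 10))
  expect_false(identical(d1$pssms[[1]]$scores, d3$pssms[[1]]$scores))

  expect_warning(generate_dataset(spec, check_S = 25), "not larger")
})

test_that("class structure shows up in the features it is meant to drive", {
  spec <- synth_spec(n_classes = 2, n_per_class = 6, length_range = c(40, 60),
                     delta = 6, rho_lag = 0, pair_signal = 0, seed = 11)
  d <- generate_dataset(spec)
  means <- t(vapply(d$pssms, function(p)
    column_means(sigmoid_normalize(p)), numeric(20)))
  gap <- abs(colMeans(means[d$labels == 1, ]) -
               colMeans(means[d$labels == 2, ]))
  within <- apply(means, 2, function(v)
    mean(c(stats::sd(v[d$labels == 1]), stats::sd(v[d$labels == 2]))))
  expect_gt(max(gap / within), 3)  # delta = 6 separates the column means

  # delta = 0 removes that separation
  d0 <- generate_dataset(synth_spec(n_classes = 2, n_per_class = 6,
                                    length_range = c(40, 60), delta = 0,
                                    rho_lag = 0, pair_signal = 0, seed = 11))
  means0 <- t(vapply(d0$pssms, function(p)
    column_means(sigmoid_normalize(p)), numeric(20)))
  gap0 <- abs(colMeans(means0[d0$labels == 1, ]) -
                colMeans(means0[d0$labels == 2, ]))
  expect_lt(max(gap0), max(gap))
})

test_that("written datasets round trip through the file-based loaders", {
  spec <- synth_spec(n_classes = 2, n_per_class = 3, length_range = c(15, 25),
                     delta = 4, seed = 12)
  d <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  recs <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_equal(recs$id, d$records$id)
  expect_equal(recs$sequence, d$records$sequence)
  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(labs$label, unname(d$labels))
  p1 <- parse_psiblast_pssm(file.path(dir, "pssm",
                                      paste0(d$records$id[1], ".pssm")))
  expect_identical(p1$scores, d$pssms[[1]]$scores)
})

test_that("a batch with the 43/30/13/12 class layout is emitted consistently", {
  sizes <- c(43, 30, 13, 12)
  specs <- lapply(seq_along(sizes), function(cl)
    synth_spec(n_classes = 4, n_per_class = 1, length_range = c(10, 15),
               seed = cl))
  # build the unbalanced batch by relabeling a balanced pool
  pool <- generate_dataset(synth_spec(n_classes = 1, n_per_class = 98,
                                      length_range = c(10, 15), seed = 13))
  labels <- rep(1:4, times = sizes)
  dir <- withr::local_tempdir()
  ds <- list(records = transform(pool$records, label = labels),
             pssms = pool$pssms,
             labels = stats::setNames(labels, pool$records$id))
  write_dataset(ds, dir)
  expect_length(list.files(file.path(dir, "pssm")), 98L)
  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(unname(table(labs$label)), sizes, ignore_attr = TRUE)
  expect_equal(labs$id, pool$records$id)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(synth_spec(n_classes = 0))
  expect_error(synth_spec(rho_lag = 1))
  expect_error(synth_spec(length_range = c(1, 10)))
  expect_error(synth_spec(pair_signal = 1.5))
})
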