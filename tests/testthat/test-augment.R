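# Source-only augmentation contracts.

make_samples <- function(n = 10, seed = 4) {
  rec <- generate_reactions(synthetic_config(n, seed = seed))
  build_task_samples(rec, "product", include_reagents = TRUE)
}

test_that("factor 1 reproduces the unaugmented dataset exactly", {
  s <- make_samples()
  out <- augment_dataset(s, augmentation_spec(factor = 1, seed = 1))
  expect_identical(out$source, s$source)
  expect_identical(out$target, s$target)
})

test_that("factor k multiplies size and never touches targets", {
  s <- make_samples(10)
  out <- augment_dataset(s, augmentation_spec(factor = 5, seed = 2))
  expect_identical(nrow(out), 50L)
  expect_identical(sort(table(out$target)), sort(table(rep(s$target, 5))))
  for (i in seq_len(nrow(out)))
    expect_identical(out$target[i], s$target[out$origin[i]])  # byte equality
  # copy #1 is the original at every factor
  expect_identical(out$source[seq_len(10)], s$source)
})

test_that("variants preserve the canonical molecule multiset of their source", {
  s <- make_samples(15)
  out <- augment_dataset(s, augmentation_spec(factor = 4, seed = 3))
  canon_multiset <- function(x)
    sort(vapply(split_molecules(x), canonicalize_smiles, character(1),
                USE.NAMES = FALSE))
  for (i in seq_len(nrow(out)))
    expect_identical(canon_multiset(out$source[i]),
                     canon_multiset(s$source[out$origin[i]]))
})

test_that("augmentation is deterministic per seed and varies across seeds", {
  s <- make_samples(8)
  a <- augment_dataset(s, augmentation_spec(factor = 3, seed = 7))
  b <- augment_dataset(s, augmentation_spec(factor = 3, seed = 7))
  c <- augment_dataset(s, augmentation_spec(factor = 3, seed = 8))
  expect_identical(a, b)
  expect_false(identical(a$source, c$source))
})

test_that("preserve_order keeps source molecule order in variants", {
  s <- make_samples(12)
  out <- augment_dataset(s, augmentation_spec(factor = 3, seed = 5,
                                              preserve_order = TRUE))
  canon_vec <- function(x)
    vapply(split_molecules(x), canonicalize_smiles, character(1), USE.NAMES = FALSE)
  for (i in seq_len(nrow(out)))
    expect_identical(unname(canon_vec(out$source[i])),
                     unname(canon_vec(s$source[out$origin[i]])))
})

test_that("unparseable source molecules are reported with the sample index", {
  s <- tibble::tibble(source = c("CCO", "C1CC"), target = c("CCO", "CC"))
  expect_error(augment_dataset(s, augmentation_spec(factor = 2, seed = 1)),
               "sample 2", class = "rxn_invalid_molecule")
})

test_that("parallel text files round-trip", {
  s <- make_samples(6)
  src <- withr::local_tempfile(); tgt <- withr::local_tempfile()
  write_parallel_text(s, src, tgt)
  back <- read_parallel_text(src, tgt)
  expect_identical(back$source, s$source)
  expect_identical(back$target, s$target)
})
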