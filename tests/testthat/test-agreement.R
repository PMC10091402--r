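# Expert-label selection and tabulation.

test_that("review candidates are strict-miss, round-trip-success records", {
  rec <- generate_reactions(synthetic_config(30, seed = 33))
  samples <- build_task_samples(rec, "reactant")
  oracle <- template_forward_oracle()
  # record 1: strict hit; record 2: alternative precursors (strict miss,
  # round-trip success); record 3: junk (both fail)
  alt <- samples$target[1]  # valid precursor set for record 1's product
  records <- list(
    prediction_record(samples$source[1], samples$target[1],
                      candidates = samples$target[1],
                      products = samples$products[[1]]),
    prediction_record(samples$source[1], "CCCCCCC.CCCCCC",
                      candidates = alt, products = samples$products[[1]]),
    prediction_record(samples$source[1], samples$target[1],
                      candidates = "CCCCCCCC", products = samples$products[[1]])
  )
  expect_identical(select_agreement_candidates(records, oracle), 2L)
})

test_that("two-group tabulation partitions labels into the three categories", {
  labels <- tibble::tibble(
    reaction_id = as.character(1:447),
    group_a = c(rep("correct", 362), rep("wrong", 18), rep("correct", 67)),
    group_b = c(rep("semi", 362), rep("wrong", 18), rep("wrong", 67))
  )
  tab <- tabulate_agreement(labels)
  expect_identical(unname(tab$counts),
                   c(362L, 18L, 67L))
  expect_identical(sum(tab$counts), tab$n)
  expect_identical(unname(tab$percent), c(81, 4, 15))
  # permutation invariance
  set.seed(3)
  tab2 <- tabulate_agreement(labels[sample(447), ])
  expect_identical(tab2$counts, tab$counts)
})

test_that("degenerate label sets tabulate correctly", {
  all_ok <- tibble::tibble(reaction_id = "1", group_a = "correct", group_b = "correct")
  expect_identical(unname(tabulate_agreement(all_ok)$percent), c(100, 0, 0))
  contra <- tibble::tibble(reaction_id = "1", group_a = "correct", group_b = "wrong")
  expect_identical(unname(tabulate_agreement(contra)$percent), c(0, 0, 100))
  semi <- tibble::tibble(reaction_id = "1", group_a = "semi", group_b = "semi")
  expect_identical(unname(tabulate_agreement(semi)$counts[1]), 1L)  # semi is not wrong
  expect_error(tabulate_agreement(all_ok[0, ]), class = "rxn_undefined_metric")
  bad <- tibble::tibble(reaction_id = "1", group_a = "maybe", group_b = "wrong")
  expect_error(tabulate_agreement(bad), class = "rxn_config_error")
})

test_that("label files round-trip", {
  labels <- tibble::tibble(reaction_id = c("r1", "r2"),
                           group_a = c("correct", "wrong"),
                           group_b = c("semi", "wrong"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_agreement_labels(labels, path)
  back <- read_agreement_labels(path)
  expect_identical(back$group_a, labels$group_a)
  expect_identical(tabulate_agreement(back)$counts,
                   tabulate_agreement(labels)$counts)
})
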