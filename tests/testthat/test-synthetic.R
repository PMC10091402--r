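# Template-based synthetic reaction generation.

test_that("generation honours n_reactions and is seed-deterministic", {
  expect_identical(nrow(generate_reactions(synthetic_config(0))), 0L)
  a <- generate_reactions(synthetic_config(300, seed = 5))
  b <- generate_reactions(synthetic_config(300, seed = 5))
  expect_identical(a, b)
  c <- generate_reactions(synthetic_config(300, seed = 6))
  expect_false(identical(a, c))
})

test_that("reactant and reagent counts match the emulated corpus statistics", {
  rec <- generate_reactions(synthetic_config(10000, seed = 7))
  n_reag <- lengths(rec$reagents)
  n_rct <- lengths(rec$reactants)
  expect_lte(abs(mean(n_reag) - 3.03), 0.15)
  expect_identical(as.numeric(stats::median(n_reag)), 3)
  expect_true(all(n_reag >= 0 & n_reag <= 21))
  expect_lte(abs(mean(n_rct) - 1.78), 0.1)
  expect_identical(as.numeric(stats::median(n_rct)), 2)
  expect_true(all(n_rct >= 1 & n_rct <= 5))
})

test_that("every generated molecule parses and the product follows the template", {
  rec <- generate_reactions(synthetic_config(300, seed = 9))
  fwd <- template_forward_oracle()
  mols <- unique(unlist(c(rec$reactants, rec$reagents, rec$products)))
  expect_true(all(vapply(mols, is_valid_smiles, logical(1))))
  for (i in seq_len(nrow(rec))) {
    p <- fwd(join_molecules(rec$reactants[[i]]))
    expect_identical(canonicalize_smiles(p),
                     canonicalize_smiles(rec$products[[i]][1]))
  }
})

test_that("the forward oracle ignores appended reagents and rejects junk", {
  rec <- generate_reactions(synthetic_config(50, seed = 3))
  fwd <- template_forward_oracle()
  i <- which(lengths(rec$reagents) > 0)[1]
  with_r <- fwd(join_molecules(c(rec$reactants[[i]], rec$reagents[[i]])))
  without <- fwd(join_molecules(rec$reactants[[i]]))
  expect_identical(with_r, without)
  expect_identical(fwd("CCO"), "")        # no recognizable precursor set
  expect_identical(fwd("not-a-molecule"), "")
})

test_that("splitting uses largest-remainder rounding and permutes by seed", {
  rec <- tibble::tibble(x = 1:100)
  sp <- split_dataset(rec, c(0.85, 0.0625, 0.0875), seed = 3)
  expect_identical(vapply(sp, nrow, integer(1)),
                   c(train = 85L, valid = 6L, test = 9L))
  expect_identical(sort(unname(unlist(lapply(sp, `[[`, "x")))), 1:100)
  all_train <- split_dataset(rec, c(1, 0, 0), seed = 1)
  expect_identical(nrow(all_train$train), 100L)
  s1 <- split_dataset(rec, c(0.6, 0.2, 0.2), seed = 1)
  s2 <- split_dataset(rec, c(0.6, 0.2, 0.2), seed = 2)
  expect_identical(vapply(s1, nrow, integer(1)), vapply(s2, nrow, integer(1)))
  expect_false(identical(s1$train$x, s2$train$x))
  expect_error(split_dataset(rec, c(0.5, 0.2, 0.2)), class = "rxn_config_error")
})

test_that("task samples follow the source/target contracts with '.' joining", {
  rec <- tibble::tibble(
    reactants = list(c("CCO", "CCBr"), c("CC(=O)O", "CCO")),
    reagents = list("OS(=O)(=O)O", character(0)),
    products = list("CCOCC", "CC(=O)OCC"),
    template_id = c("williamson_ether", "esterification")
  )
  prod <- build_task_samples(rec, "product", include_reagents = TRUE)
  expect_identical(prod$source[1], "CCO.CCBr.OS(=O)(=O)O")
  expect_identical(prod$target[1], "CCOCC")
  expect_identical(prod$source[2], "CC(=O)O.CCO")  # zero reagents appends nothing
  rct <- build_task_samples(rec, "reactant", include_reagents = FALSE)
  expect_identical(rct$source[1], "CCOCC")
  expect_identical(rct$target[1], "CCO.CCBr")
  rgt <- build_task_samples(rec, "reagent")
  expect_identical(rgt$source[1], "CCO.CCBr.CCOCC")
  expect_identical(rgt$target[1], "OS(=O)(=O)O")
  expect_identical(nrow(rgt), 1L)                  # zero-reagent record skipped
  expect_identical(attr(rgt, "skipped"), 2L)
})

test_that("reaction-SMILES files round-trip through write and read", {
  rec <- generate_reactions(synthetic_config(25, seed = 2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_reaction_smiles(rec, path)
  lines <- readLines(path)
  expect_length(lines, 25L)
  expect_true(all(grepl("^[^>]+>[^>]*>[^>]+$", lines)))
  back <- read_reaction_smiles(path)
  expect_identical(back$reactants, rec$reactants)
  expect_identical(back$reagents, rec$reagents)
  expect_identical(back$products, rec$products)
})
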