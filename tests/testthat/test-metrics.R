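# Evaluation metrics: strict/lenient matching, top-k, round-trip, P/R/F,
# binning with weighted pooling.

test_that("strict matching is canonical set equality over molecules", {
  expect_true(strict_hit("CCO.CC", "CC.CCO"))        # order-invariant
  expect_true(strict_hit("C(O)C", "OCC"))            # canonical-form equality
  expect_false(strict_hit("CCO", "CCO.CC"))          # missing molecule
  expect_false(strict_hit("CCO.CC.N", "CCO.CC"))     # extra molecule
  expect_true(strict_hit("CCO.CCO", "CCO"))          # sets, not multisets
  expect_false(strict_hit("C1CC.CCO", "CCO"))        # invalid molecule: miss
})

test_that("lenient matching needs one shared molecule, ignoring invalid ones", {
  expect_true(lenient_hit("CCO.CCC", "CCO.N"))
  expect_false(lenient_hit("CCC", "CCO.N"))
  expect_true(lenient_hit("C1CC.CCO", "CCO.N"))      # invalid one dropped
  # strict implies lenient
  set.seed(13)
  recs <- random_prediction_records(40)
  for (r in recs)
    for (cand in r$candidates)
      if (strict_hit(cand, r$target)) expect_true(lenient_hit(cand, r$target))
})

test_that("top-k accuracy counts records with a hit in the first k ranks", {
  recs <- list(
    prediction_record("s", "CCO", candidates = c("CC", "CCO", "N")),   # hit at 2
    prediction_record("s", "CCO", candidates = c("CC", "N", "O"))      # no hit
  )
  expect_identical(topk_accuracy(recs, 1, "strict"), 0)
  expect_identical(topk_accuracy(recs, 2, "strict"), 0.5)
  expect_identical(topk_accuracy(recs, 10, "strict"), 0.5)  # short lists use all
  all_hit <- list(prediction_record("s", "CCO", candidates = "OCC"))
  for (k in 1:5) expect_identical(topk_accuracy(all_hit, k, "strict"), 1)
  expect_error(topk_accuracy(list(), 1), class = "rxn_undefined_metric")
  # shuffling candidates below rank k leaves top-k unchanged
  r <- prediction_record("s", "CCO", candidates = c("CCO", "N", "O", "CC"))
  r2 <- prediction_record("s", "CCO", candidates = c("CCO", "CC", "O", "N"))
  expect_identical(topk_accuracy(list(r), 1, "strict"),
                   topk_accuracy(list(r2), 1, "strict"))
})

test_that("top-k monotonicity and lenient >= strict hold on random fixtures", {
  set.seed(17)
  recs <- random_prediction_records(60)
  for (mode in c("strict", "lenient")) {
    accs <- vapply(1:5, function(k) topk_accuracy(recs, k, mode), numeric(1))
    expect_true(all(diff(accs) >= 0))
  }
  for (k in 1:5)
    expect_gte(topk_accuracy(recs, k, "lenient"), topk_accuracy(recs, k, "strict"))
})

test_that("round-trip accuracy scores rank-1 reactants through the forward model", {
  rec <- generate_reactions(synthetic_config(40, seed = 21))
  samples <- build_task_samples(rec, "reactant")
  # reactant model stub: true reactants for the first half, junk after
  n <- nrow(samples)
  records <- lapply(seq_len(n), function(i) {
    cand <- if (i <= n / 2) samples$target[i] else "CCCCCCCC"
    prediction_record(samples$source[i], samples$target[i], candidates = cand,
                      products = samples$products[[i]],
                      true_reagents = samples$reagents[[i]])
  })
  oracle <- template_forward_oracle()
  expect_identical(roundtrip_accuracy(records, oracle), 0.5)
  expect_identical(roundtrip_accuracy(records,
                                      function(s) join_molecules(records[[1]]$products)),
                   mean(vapply(records, function(r)
                     setequal(r$products, records[[1]]$products), logical(1))))
  expect_identical(roundtrip_accuracy(records, function(s) "CCCCCCCCC"), 0)
  # perfect reactant predictions give perfect round trip with the oracle
  perfect <- lapply(seq_len(n), function(i)
    prediction_record(samples$source[i], samples$target[i],
                      candidates = samples$target[i],
                      products = samples$products[[i]]))
  expect_identical(roundtrip_accuracy(perfect, oracle), 1)
})

test_that("round-trip with reagents requires and uses the true reagents", {
  rec <- generate_reactions(synthetic_config(20, seed = 22))
  samples <- build_task_samples(rec, "reactant", include_reagents = TRUE)
  oracle <- template_forward_oracle()
  records <- lapply(seq_len(nrow(samples)), function(i)
    prediction_record(samples$source[i], samples$target[i],
                      candidates = samples$target[i],
                      include_reagents = TRUE,
                      true_reagents = samples$reagents[[i]],
                      products = samples$products[[i]]))
  expect_identical(roundtrip_accuracy(records, oracle), 1)
  broken <- records
  broken[[1]]$true_reagents <- NULL
  expect_error(roundtrip_accuracy(broken, oracle), class = "rxn_config_error")
})

test_that("P/R/F at rank k follow the counting formulas", {
  # prediction set {A,B}, target {A,C,D}: P = 1/2, R = 1/3, F = 0.4
  r <- prediction_record("s", "CCO.CCN.CCC", candidates = "CCO.CC")
  prf <- prf_at_k(r, 1)
  expect_equal(unname(prf["P"]), 0.5)
  expect_equal(unname(prf["R"]), 1 / 3)
  expect_equal(unname(prf["F1"]), 0.4)
  perfect <- prf_at_k(prediction_record("s", "CCO.CC", candidates = "CC.CCO"), 1)
  expect_equal(unname(perfect[c("P", "R", "F1")]), c(1, 1, 1))
  disjoint <- prf_at_k(prediction_record("s", "CCO", candidates = "CC.N"), 1)
  expect_equal(unname(disjoint[c("P", "R", "F1")]), c(0, 0, 0))
  # molecules pool across ranks without double counting
  pooled <- prf_at_k(prediction_record("s", "CCO.CC",
                                       candidates = c("CCO", "CCO.CC")), 2)
  expect_equal(unname(pooled["N"]), 2)
  expect_equal(unname(pooled["P"]), 1)
  # invalid predicted molecules are dropped from N and counted
  inv <- prf_at_k(prediction_record("s", "CCO", candidates = "CCO.C1CC"), 1)
  expect_equal(unname(inv["N"]), 1)
  expect_equal(unname(inv["n_invalid"]), 1)
})

test_that("binned pooling weights bin means by record counts", {
  mk <- function(target, cand) prediction_record("s", target, candidates = cand)
  # bin n=3 with P=1, bin n=1 with P=0 -> pooled P = 0.75
  b1 <- lapply(1:3, function(i) mk("CCO", "CCO"))
  b2 <- list(mk("CCO.CC.CCN", "OS(=O)(=O)O.CCCC"))  # 3 reagents, all wrong
  pool <- bin_and_pool(c(b1, b2), k = 1, min_bin_n = 1)
  expect_equal(unname(pool$pooled["P"]), 0.75)
  single <- bin_and_pool(b1, k = 1, min_bin_n = 1)
  expect_equal(unname(single$pooled["P"]), unname(single$bins$P[1]))
  # a bin beyond max_bin is tabulated but excluded from pooling
  big <- list(mk(join_molecules(rep(fixture_molecules()[1:13], 1)), "CCO"))
  pool2 <- bin_and_pool(c(b1, big), k = 1, min_bin_n = 1, max_bin = 12)
  expect_true(13 %in% pool2$bins$n_reagents)
  expect_false(13 %in% pool2$retained$n_reagents)
  expect_equal(unname(pool2$pooled["P"]), 1)
  expect_error(bin_and_pool(big, k = 1, min_bin_n = 1), class = "rxn_undefined_metric")
})

test_that("weighted per-bin pooling equals direct pooling over retained records", {
  set.seed(19)
  recs <- random_prediction_records(80)
  pool <- bin_and_pool(recs, k = 3, min_bin_n = 1, max_bin = 12)
  key <- vapply(recs, function(r) length(split_molecules(r$target)), integer(1))
  keep <- key <= 12
  direct <- colMeans(t(vapply(recs[keep], prf_at_k, numeric(7), k = 3))[, c("P", "R", "F1")])
  expect_equal(unname(pool$pooled), unname(direct))
})

test_that("evaluation reports collect top-k curves and invalid rates", {
  recs <- list(
    prediction_record("s", "CCO", candidates = c("C1CC", "CCO")),
    prediction_record("s", "CC", candidates = c("CC", "N"))
  )
  rep <- evaluation_report(recs, ks = 1:2)
  expect_identical(rep$n, 2L)
  expect_equal(rep$topk$strict, c(0.5, 1))
  expect_true(all(rep$topk$lenient >= rep$topk$strict))
  expect_equal(rep$invalid_candidate_rate, 1 / 4)
})

test_that("prediction files round-trip", {
  set.seed(29)
  recs <- random_prediction_records(5)
  path <- withr::local_tempfile()
  write_predictions(recs, path)
  back <- read_predictions(path)
  expect_length(back, 5L)
  for (i in 1:5) {
    expect_identical(back[[i]]$candidate, recs[[i]]$candidates)
    expect_identical(back[[i]]$rank, seq_along(recs[[i]]$candidates))
  }
})
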