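test_that("classification inverts generation for every type and seed", {
  reg <- test_registry()
  for (seed in c(1, 2, 17)) {
    for (t in reg$label) {
      lab <- classify_order(generate_record(t, seed = seed, registry = reg)$order[[1]],
                            reg)
      expect_identical(lab, t, label = paste("type", t, "seed", seed))
    }
  }
})

test_that("length differences do not split a type; the pseudo-Pro does", {
  reg <- test_registry()
  a <- generate_record("III-C", seed = 1, registry = reg,
                       cr_lengths = c(1000, 1300))$order[[1]]
  b <- generate_record("III-C", seed = 2, registry = reg,
                       cr_lengths = c(1000, 1000))$order[[1]]
  expect_true(same_arrangement(a, b))
  # III-B vs III-B1: the extra pseudo-Pro upstream of CR1 separates them
  expect_false(same_arrangement(type_order("III-B"), type_order("III-B1")))
})

test_that("records token-identical to III are promoted to III-E only when asymmetric", {
  reg <- test_registry()
  sym <- generate_record("III", seed = 1, registry = reg)$order[[1]]
  expect_identical(classify_order(sym, reg), "III")
  asym <- generate_record("III", seed = 1, registry = reg,
                          cr_lengths = c(4110, 2878))$order[[1]]
  expect_identical(classify_order(asym, reg), "III-E")
  # ratio below the threshold stays III
  mild <- generate_record("III", seed = 1, registry = reg,
                          cr_lengths = c(1150, 1100))$order[[1]]
  expect_identical(classify_order(mild, reg), "III")
})

test_that("unmatched arrangements get deterministic NEW-k labels", {
  reg <- test_registry()
  can <- canonical_reference_order()
  expect_identical(classify_order(can, reg), "NEW-1")
  # two distinct novel arrangements, one repeated: labels in input order
  novel2 <- perturb(mito_records("x", order = list(can)),
                    event_annotation("LOSS", "G", from = c("COX3", "ND3")))$order[[1]]
  recs <- mito_records(c("a", "b", "c"), order = list(can, novel2, can))
  cl <- classify_records(recs, reg)
  expect_identical(cl$type, c("NEW-1", "NEW-2", "NEW-1"))
  expect_equal(nrow(attr(cl, "new_types")), 2L)
})

test_that("the type census counts records and distinct types", {
  reg <- test_registry()
  fx <- test_fixture()
  cl <- classify_records(fx$records, reg)
  cen <- type_census(cl)
  expect_equal(sum(cen$n), 65L)
  expect_equal(n_distinct_types(cen), 11L)
  # generated labels agree with the fixture assignment throughout
  expect_identical(cl$type, fx$tip_types$type)
  # single record census
  one <- type_census(classify_records(fx$records[1, ], reg))
  expect_equal(n_distinct_types(one), 1L)
  # Scolecophidia carry exactly types I and II
  scole <- cl[cl$family %in% c("Leptotyphlopidae", "Typhlopidae"), ]
  expect_setequal(unique(scole$type), c("I", "II"))
  # Viperidae: III-B throughout except the one III-B1 genome
  vip <- cl[cl$family == "Viperidae", ]
  expect_setequal(unique(vip$type), c("III-B", "III-B1"))
  expect_identical(vip$taxon_id[vip$type == "III-B1"], "Ovophis_okinavensis")
})

test_that("novel-type comparison against the prior registry finds the five new types", {
  reg <- test_registry()
  prior <- prior_registry()
  expect_identical(novel_types(reg, prior),
                   c("III-A", "III-D", "III-E", "III-F", "III-G"))
  expect_identical(novel_types(reg, reg), character(0))
  expect_identical(novel_types(reg, prior[0, ]), sort(reg$label))
})

test_that("registry integrity rejects unmarked duplicate arrangements", {
  reg <- test_registry()
  bad <- reg
  bad$key[bad$label == "III-A"] <- bad$key[bad$label == "III"]
  bad$asym_required[bad$label %in% c("III", "III-A")] <- FALSE
  expect_error(mitorder:::validate_registry(bad), "integrity")
})
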