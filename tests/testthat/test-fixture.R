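test_that("the fixture set satisfies its integrity invariants", {
  fx <- test_fixture()
  expect_equal(nrow(fx$records), 65L)
  expect_equal(dplyr::n_distinct(fx$taxa$family), 14L)
  expect_setequal(fx$tree$tip.label, fx$records$taxon_id)
  expect_true(all(fx$tip_types$type %in% fx$registry$label))
  expect_true(ape::is.rooted(fx$tree))
  # every generated record passes vocabulary validation and anchors
  for (ord in fx$records$order) {
    expect_silent(gene_order(ord$name, ord$strand, ord$length_bp))
    expect_true(any(c("F", "12S") %in% ord$name))
  }
})

test_that("fixture type assignments follow the published distribution", {
  fx <- test_fixture()
  tt <- fx$tip_types
  fam <- fx$taxa$family[match(tt$taxon_id, fx$taxa$taxon_id)]
  # blind snakes: type I in Leptotyphlopidae, II in Typhlopidae
  expect_true(all(tt$type[fam == "Leptotyphlopidae"] == "I"))
  expect_true(all(tt$type[fam == "Typhlopidae"] == "II"))
  expect_false(any(tt$type %in% c("I", "II") &
                     !fam %in% c("Leptotyphlopidae", "Typhlopidae")))
  # singleton types and their bearers
  singleton <- function(tp) tt$taxon_id[tt$type == tp]
  expect_identical(singleton("III-A"), "Tropidophis_haetianus")
  expect_identical(singleton("III-D"), "Ophiophagus_hannah")
  expect_identical(singleton("III-E"), "Imantodes_cenchoa")
  expect_identical(singleton("III-F"), "Leptodeira_septentrionalis")
  expect_identical(singleton("III-G"), "Sibon_nebulatus")
  # III-C is confined to Colubridae and Homalopsidae
  expect_setequal(unique(fam[tt$type == "III-C"]), c("Colubridae", "Homalopsidae"))
})

test_that("fixture generation is deterministic per seed", {
  fx1 <- build_fixture_set(seed = 1, registry = test_registry())
  fx2 <- build_fixture_set(seed = 1, registry = test_registry())
  expect_identical(lapply(fx1$records$order, as.data.frame),
                   lapply(fx2$records$order, as.data.frame))
  fx3 <- build_fixture_set(seed = 2, registry = test_registry())
  expect_false(identical(lapply(fx1$records$order, as.data.frame),
                         lapply(fx3$records$order, as.data.frame)))
  # but arrangements (and thus every downstream count) are seed-invariant
  expect_identical(vapply(fx1$records$order, canonical_key, ""),
                   vapply(fx3$records$order, canonical_key, ""))
})

test_that("simulate_types writes one GenBank file per record", {
  dir <- withr::local_tempdir()
  recs <- simulate_types(c("III-E"), seed = 1, dir = dir,
                         registry = test_registry())
  expect_equal(nrow(recs), 1L)
  files <- list.files(dir, pattern = "\\.gb$")
  expect_equal(length(files), 1L)
  # III-E defaults carry the published asymmetric CR lengths
  lens <- sort(recs$order[[1]]$length_bp[recs$order[[1]]$category == "CR"])
  expect_equal(lens, c(2878L, 4110L))
  expect_warning(simulate_types("III", n = 0, registry = test_registry()),
                 "nothing generated")
})

test_that("plot and census methods return ggplot objects", {
  fx <- test_fixture()
  cen <- type_census(classify_records(fx$records[1:5, ], test_registry()))
  expect_s3_class(ggplot2::autoplot(cen), "ggplot")
  expect_s3_class(plot_gene_order(type_order("III")), "ggplot")
})
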