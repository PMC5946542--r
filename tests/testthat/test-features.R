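test_that("OL detection: lost in blind-snake types, flanked by Asn/Cys elsewhere", {
  expect_false(detect_ol(type_order("I"))$present)
  expect_false(detect_ol(type_order("II"))$present)
  ol3 <- detect_ol(type_order("III"))
  expect_true(ol3$present)
  expect_equal(ol3$neighbors, c("N", "C"))
  expect_true(detect_ol(canonical_reference_order())$present)
  dup <- parse_order_string("F,12S,OL,V,OL")
  expect_error(detect_ol(dup), "integrity")
})

test_that("control-region counting and the asymmetry threshold", {
  cc <- count_control_regions(type_order("III-E"))
  expect_equal(cc$cr_count, 2L)
  expect_equal(sort(cc$cr_lengths), c(2878L, 4110L))
  expect_equal(max(cc$cr_lengths) / min(cc$cr_lengths), 1.428, tolerance = 1e-3)
  expect_true(cc$cr_asymmetric)
  eq <- count_control_regions(parse_order_string("F,CR:1000,T,CR:1000"))
  expect_false(eq$cr_asymmetric)
  one <- count_control_regions(type_order("I"))
  expect_equal(one$cr_count, 1L)
  expect_false(one$cr_asymmetric)
  # unknown lengths: asymmetry undefined, reported FALSE with a caveat
  expect_message(
    nolen <- count_control_regions(parse_order_string("F,CR,T,CR")),
    "unknown")
  expect_false(nolen$cr_asymmetric)
})

test_that("translocation detection reports the moved gene, not its bystanders", {
  can <- canonical_reference_order()
  # Gln moved from the IQM cluster into WANCY
  tr <- detect_translocations(type_order("I"), can)
  expect_equal(tr$gene, "Q")
  expect_equal(c(tr$ref_prev, tr$ref_next), c("I", "M"))
  expect_equal(c(tr$obs_prev, tr$obs_next), c("W", "A"))
  # Lys to 5' of ATP6: the equally-minimal ATP8 explanation loses to the
  # tRNA-mobility preference
  tr2 <- detect_translocations(type_order("III-A"), type_order("III"))
  expect_equal(tr2$gene, "K")
  expect_equal(tr2$obs_next, "ATP6")
  # self-comparison is empty, for every registry order
  for (t in test_registry()$label) {
    expect_equal(nrow(detect_translocations(type_order(t), type_order(t))), 0L)
  }
})

test_that("pseudogene, extra-copy and NC detectors match the per-type diagnostics", {
  # III-C: pseudo-Pro immediately 5' of CR2
  ps <- detect_pseudogenes(type_order("III-C"))
  expect_equal(ps$symbol, "P*")
  expect_equal(ps$next_, "CR")
  # III-D: duplicated Ile adjacent to a CR
  xc <- detect_extra_copies(type_order("III-D"))
  expect_equal(xc$gene, "I")
  expect_equal(xc$n_copies, 2L)
  ps_d <- detect_pseudogenes(type_order("III-D"))
  expect_equal(nrow(ps_d), 0L)
  # III: no pseudogenes, no extra copies
  expect_equal(nrow(detect_pseudogenes(type_order("III"))), 0L)
  expect_equal(nrow(detect_extra_copies(type_order("III"))), 0L)
  # III-G: the 5702 bp block between Cys and Tyr
  nc <- detect_nc_insertions(type_order("III-G"))
  expect_equal(nc$length_bp, 5702L)
  expect_equal(c(nc$prev, nc$next_), c("C", "Y"))
  # III-F: the 342 bp block between ND5 and ND6
  nc_f <- detect_nc_insertions(type_order("III-F"))
  expect_equal(nc_f$length_bp, 342L)
  expect_equal(c(nc_f$prev, nc_f$next_), c("ND5", "ND6"))
  expect_equal(nrow(detect_nc_insertions(type_order("II"))), 0L)
})

test_that("hotspot loci follow the CR-flank / WANCY rule", {
  reg <- test_registry()
  hs <- hotspot_assignment(reg)
  locus_of <- function(lab) sort(unique(hs$locus[hs$label == lab]))
  expect_equal(locus_of("III-G"), "WANCY")
  expect_equal(locus_of("III-C"), "CR-flank")
  expect_equal(locus_of("III-A"), "other")
  expect_equal(locus_of("II"), "WANCY")
  expect_setequal(locus_of("I"), c("WANCY", "other"))
  # seven types carry at least one CR-flank event
  cen <- hotspot_census(reg)
  expect_equal(cen$n_types[cen$locus == "CR-flank"], 7L)
  # WANCY-locus events occur in I and III-G plus the OL loss of II
  expect_setequal(unique(hs$label[hs$locus == "WANCY"]), c("I", "II", "III-G"))
})

test_that("the per-record feature report summarises each fixture genome", {
  fx <- test_fixture()
  rep <- suppressMessages(
    feature_report(fx$records[fx$records$taxon_id %in%
                                c("Leptotyphlops_dulcis", "Ovophis_okinavensis",
                                  "Sibon_nebulatus"), ]))
  expect_equal(rep$ol_present, c(FALSE, TRUE, TRUE))
  expect_equal(rep$cr_count, c(1L, 2L, 2L))
  expect_equal(rep$pseudogenes[[2]]$symbol, "P*")
  expect_equal(rep$nc_insertions[[3]]$length_bp, 5702L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_report(rep, f)
  expect_true(file.exists(f))
})
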