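test_that("event paths between reference orders match the per-type diagnostics", {
  reg <- test_registry()
  p3 <- type_order("III")
  # III -> III-C: pseudo-Pro appears at 5' of CR2
  ev <- infer_event_path(p3, type_order("III-C"))
  expect_equal(ev$kind, "PSEUDOGENIZATION")
  expect_equal(ev$subject, "P*")
  expect_equal(c(ev$to_prev, ev$to_next), c("I", "CR"))
  # III -> III-D: a second Ile copy at 5' of CR1
  ev <- infer_event_path(p3, type_order("III-D"))
  expect_equal(ev$kind, "DUPLICATION")
  expect_equal(ev$subject, "I")
  expect_equal(c(ev$to_prev, ev$to_next), c("P", "CR"))
  # III -> III-B: Pro moves from the CR1 junction to 5' of CR2
  ev <- infer_event_path(p3, type_order("III-B"))
  expect_equal(ev$kind, "TRANSLOCATION")
  expect_equal(ev$subject, "P")
  # III -> III-E: only the control-region asymmetry
  ev <- infer_event_path(p3, type_order("III-E"))
  expect_equal(ev$kind, "CR_ASYMMETRY")
  # identity gives the empty path
  expect_equal(nrow(infer_event_path(p3, p3)), 0L)
  expect_error(infer_event_path(p3[0, ], p3), "non-empty")
})

test_that("perturbation produces the intended arrangement and reverses cleanly", {
  reg <- test_registry()
  rec <- generate_record("III", seed = 2, registry = reg)
  # the pseudo-Pro insertion converts III into III-C
  rec2 <- perturb(rec, event_annotation("PSEUDOGENIZATION", "P*", to = c("I", "CR")))
  expect_identical(classify_order(rec2$order[[1]], reg), "III-C")
  # translocate Lys to 5' of ATP6 and back
  fwd <- event_annotation("TRANSLOCATION", "K",
                          from = c("COX2", "ATP8"), to = c("ATP8", "ATP6"))
  rev <- event_annotation("TRANSLOCATION", "K",
                          from = c("ATP8", "ATP6"), to = c("COX2", "ATP8"))
  moved <- perturb(rec, fwd)
  expect_identical(classify_order(moved$order[[1]], reg), "III-A")
  back <- perturb(moved, rev)
  expect_true(same_arrangement(back$order[[1]], rec$order[[1]]))
  # inapplicable events are rejected
  expect_error(perturb(rec, event_annotation("LOSS", "P*", from = c("I", "CR"))),
               "inapplicable")
  expect_error(perturb(rec, event_annotation("DUPLICATION", "K", to = c("F", "V"))),
               "not adjacent")
})

test_that("single random perturbations are recovered exactly by path inference", {
  reg <- test_registry()
  set.seed(23)
  n_done <- 0
  while (n_done < 100) {
    base <- generate_record(sample(reg$label, 1), seed = sample(1000, 1),
                            registry = reg)
    ev <- random_event(base$order[[1]])
    if (is.null(ev)) next
    after <- perturb(base, ev)
    path <- infer_event_path(base$order[[1]], after$order[[1]])
    expect_equal(nrow(path), 1L,
                 label = paste("single event recovered:", ev$kind, ev$subject))
    expect_identical(path$kind, ev$kind)
    expect_identical(path$subject, ev$subject)
    n_done <- n_done + 1
  }
})

test_that("the fixture derivation graph reproduces the published topology", {
  fx <- test_fixture()
  g <- derivation_graph(fx$registry, fx$tree, fx$tip_types)
  edges <- paste(g$edges$from, g$edges$to, sep = ">")
  expect_setequal(
    edges,
    c("UNKNOWN>I", "UNKNOWN>II", "UNKNOWN>III",
      "III>III-A", "III>III-B", "III>III-C", "III>III-D",
      "III>III-E", "III>III-F", "III>III-G", "III-B>III-B1"))
  # III-B1's sole parent is III-B
  expect_identical(g$edges$from[g$edges$to == "III-B1"], "III-B")
  # eight types descend from III directly or indirectly
  expect_equal(length(descendant_types(g, "III")), 8L)
  # III-C arises on six separate edges of the resolved tree
  expect_equal(g$edges$n_transitions[g$edges$to == "III-C"], 6L)
  # exports
  f <- withr::local_tempfile(fileext = ".dot")
  write_derivation_graph(g, f)
  expect_true(any(grepl("UNKNOWN", readLines(f))))
  td <- tidy(g)
  expect_true(all(c("from", "to", "kind", "subject") %in% names(td)))
})

test_that("a single-type dataset yields a one-node graph; cycles are refused", {
  fx <- test_fixture()
  sub <- fx$tip_types[fx$tip_types$type == "III-B", ]
  tr <- ape::keep.tip(fx$tree, sub$taxon_id)
  g <- derivation_graph(fx$registry, tr, sub)
  expect_equal(nrow(g$edges), 0L)
  expect_identical(g$nodes, "III-B")
  expect_error(
    mitorder:::assert_dag(c("A", "B"),
                          tibble::tibble(from = c("A", "B"), to = c("B", "A"))),
    "cycle")
})
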